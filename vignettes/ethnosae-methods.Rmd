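---
title: "Small-area estimation of family-planning indicators by ethnic group"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area estimation of family-planning indicators by ethnic group}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Household surveys such as the DHS measure contraceptive behaviour well at the
national and state level, but direct estimates for small domains — here,
ethnic group × state cells — are too imprecise to inform policy: many cells
contain a handful of respondents or none. A census observes everyone but asks
no family-planning questions. `ethnosae` implements a unit-level small-area
estimation (SAE) pipeline that borrows the survey's outcome information and
the census's coverage:

1. **Harmonization.** Covariates measured differently in the two sources are
   recoded onto a shared codebook (e.g. the many wall-material categories of
   each instrument collapse to a binary adequate/inadequate variable).
2. **Model fitting.** For each of three binary indicators — any
   contraceptive use, modern contraceptive use, unmet need — a logistic
   mixed model is fitted to the survey at the individual level:
   \[
   \operatorname{logit} p_{A,ed,i} = \mathbf{x}_{ed,i}^\top \beta_A + v_{A,ed},
   \qquad v_{A,ed} \sim N(0, \sigma_{v,A}^2),
   \]
   with one random intercept per ethnic-group × state domain \(ed\). The
   eligibility universe is married or in-union women aged 13–49.
3. **Census prediction.** Each fitted model is applied to every eligible
   census woman, \(\hat p_{A,i} = \operatorname{logit}^{-1}(\mathbf{x}_i^\top
   \hat\beta_A + \hat v_{A,ed})\), and the fourth indicator is derived as
   \(\hat p_{NS,i} = \hat p_{\text{modern},i} / (\hat p_{\text{any},i} +
   \hat p_{\text{unmet},i})\) — demand for family planning satisfied by
   modern methods.
4. **Benchmarking.** Census weights are calibrated so that the census-based
   estimates reproduce the direct survey estimates \(D_{A,j}\) at every
   trusted level \(j\) (national, each state, rural, urban) simultaneously.
5. **Uncertainty.** A parametric bootstrap for unit-level models gives a
   mean squared error per domain estimate.

The deliverable is one row per indicator × ethnic group × state, with an
estimate and its bootstrap MSE.

## The model and its assumptions

The response is assumed independent Bernoulli given the covariates and the
domain intercept. Clustering enters only through \(v_{A,ed}\): women in the
same ethnic-group × state cell share unobserved context (community norms,
service availability) that the covariates do not capture. Finer
disaggregation (e.g. municipality) would leave many empty cells and is not
supported. A single common \(\sigma_{v,A}^2\) per indicator is estimated;
per-domain variances would be unidentifiable with one realisation per
domain.

The degree of clustering is summarised by the latent-scale intraclass
correlation
\(\mathrm{ICC} = \sigma_v^2 / (\sigma_v^2 + \pi^2/3)\),
where \(\pi^2/3\) is the variance of the standard logistic individual term.
Its confidence interval is obtained by a nonparametric cluster bootstrap:
domains are resampled with replacement (each draw relabelled as a new
cluster), the model refitted, and the percentile interval taken over
replicates.

Estimation is by maximum likelihood via `lme4::glmer`. Two numerical notes:

* The default integrator is the Laplace approximation (`nagq = 1`).
  Replicated simulation studies (parameter recovery, ICC bootstrap,
  bootstrap MSE) use the marginal-profile approximation (`nagq = 0`), which
  on these designs agrees with the full Laplace fit to about 4·10⁻⁴ on the
  coefficients — two orders of magnitude below their standard errors — at a
  fraction of the cost.
* Design matrix columns dropped for rank deficiency (possible in degenerate
  subsets, e.g. single-ethnicity data) are reported in `dropped_terms` and
  predicted with coefficient 0.
* Survey weights do **not** enter the model fit by default: the model is a
  linking model, and the design information enters at the benchmarking
  stage. A weighted pseudo-likelihood fit is available (`weighted = TRUE`).

Complete separation of a binary covariate is detected before fitting and
reported as an error naming the covariate.

## Benchmarking: targets and solver

For a level \(j\) the survey provides a direct Hájek estimate
\(D_{A,j} = \sum_{i \in j} w_i y_{A,i} / \sum_{i \in j} w_i\), while the
census gives the unadjusted mean \(Y_{A,j}\) of the predictions; their ratio
\(R_j = D_{A,j} / Y_{A,j}\) measures the adjustment each level requires.
Because a single ratio per level cannot satisfy all levels at once, the
package solves for one set of census weights per indicator that meets every
level simultaneously: minimize \(\sum_i (w_i - 1)^2\) subject to the Hájek
constraints \(\sum_{i \in j} w_i \hat p_{A,i} / \sum_{i \in j} w_i =
D_{A,j}\) for all \(j\).

The solver sweeps the constraints iteratively. Each constraint alone has the
closed-form chi-square solution \(w_i \leftarrow w_i (1 + \delta (\hat p_i -
D_j))\) with \(\delta = -\sum w_i (\hat p_i - D_j) / \sum w_i (\hat p_i -
D_j)^2\); sweeps repeat until all residuals fall below `tol` (default
1e-8). Choices that matter:

* **Constraint order.** States first, then rural and urban, the national
  constraint last in each sweep — it is near-redundant given the states and
  its residual is the most informative diagnostic of inconsistency.
* **Positivity and bounds.** Steps that would drive a weight nonpositive
  are halved until they do not; weights are clamped to `bounds` (default
  `[0.2, 5]`) to prevent degenerate tilts. Damping and bound events are
  counted in the solution object.
* **Infeasible targets** (a direct estimate outside the range of the
  predictions) produce a non-converged solution with a full residual
  report and a warning — never a silent answer.
* **One weight set per indicator** is the default, since the constraint
  values depend on the indicator.
* Constraints whose level has no census members, or whose direct estimate
  is undefined (empty survey level), are dropped with a warning.

The need-satisfied indicator is aggregated as the mean of the individual
ratios by default (matching its individual-level definition); the
ratio-of-aggregated-means alternative is available via
`aggregation = "ratio_of_means"`.

## Bootstrap MSE

`bootstrap_mse()` implements the parametric bootstrap for unit-level models:
for each replicate, new domain effects \(v^* \sim N(0, \hat\sigma_v^2)\) are
drawn, outcomes are generated on both survey and census rows from the fitted
law, the bootstrap-true domain proportion is taken from the census outcomes,
the model is refitted on the bootstrap survey, and the domain estimate is
recomputed; the MSE is the mean squared deviation over replicates.
Replicates that fail to converge are dropped and counted (`B_effective`);
fewer than half converging is a hard error. `B` defaults to 200.
Recalibrating the benchmark weights inside each replicate is supported
(`benchmark = TRUE`) but off by default: the default measures the MSE of the
model-based estimator, the flag that of the benchmarked estimator, at about
four times the cost. `run_pipeline()` uses a joint three-model variant so
that the derived need-satisfied indicator also receives an MSE.

Relative uncertainty is reported as `rrmse_pct` \(= 100\sqrt{\mathrm{MSE}} /
\hat\theta\); the MSE-relative version is a trivial transformation of the
same columns (the two readings of "error relative to the estimate" differ,
so both are obtainable).

## The synthetic-data generator

Real DHS and census microdata cannot be redistributed, so the package ships
a generator whose defaults define its study conditions:

* **Geography and scale.** 6 states × 3 ethnic groups (Indigenous,
  Afro-descendant, non-ethnic) × rural/urban, 2,000 census rows per state,
  and a 25% stratified sample as the survey — desk scale, seconds to run.
  (The full-scale geography of 33 states is a single argument away.)
* **Truth.** The default coefficient vectors are the reference estimates
  from the Colombian 2015 DHS contraceptive-use models
  (`reference_coefficients()`), and the random-intercept SDs are set so the
  latent-scale ICCs equal the reported 0.076 / 0.07 / 0.058
  (`reference_sigma_v()`).
* **Covariates** are drawn independently within each ethnic × urbanicity
  cell from configurable marginals with plausible gradients (education and
  internet higher in urban cells, poor walls more common in rural and
  ethnic-minority cells, high ethnic homogamy). Only marginals are
  emulated — no attempt is made to copy the joint covariate law of any real
  population.
* **Outcomes** are drawn hierarchically so that the recorded data always
  satisfy the logical invariants (modern use ⊆ any use; unmet need only
  among non-users): any use from its model, modern use among users with
  probability \(\min(1, p_{\text{modern}}/p_{\text{any}})\), unmet need
  among non-users with probability \(\min(1, p_{\text{unmet}}/(1 -
  p_{\text{any}}))\). This reproduces all three marginal models whenever
  the caps do not bind; cap events are counted and returned
  (`cap_events`). With the default truth the modern-use cap binds for an
  appreciable share of rows — the three marginal models were estimated
  independently and are not jointly coherent — so the generator's
  modern-use margin sits slightly below its model's margin. This is a
  property of any generator consistent with the invariants, and is why the
  package's recovery studies target the any-use model.
* **Sampling.** Simple random sampling without replacement within state ×
  urbanicity strata; weights are inverse inclusion probabilities. Unequal
  fractions across strata emulate an unequal-probability design.

Passing tests on these data shows the pipeline's internal consistency and
its frequentist calibration under its own model; it does not validate the
model against real behaviour, nonresponse, measurement error, or informative
sampling within strata.

## Problem sizes used by the test suite

The suite exercises: coefficient recovery on 20 replicates of a ~50,000-row
survey (3·SE coverage ≥ 95% of replicate × coefficient cells); calibration
on the 6-state fixture with all state, rural, urban and national constraints
(residuals < 1e-6); a bootstrap-MSE calibration study comparing B = 100
bootstrap MSEs against the empirical MSE over 200 independent replications
(within a factor of 2 for ≥ 80% of domains); an ICC-interval coverage study
at 25 replicates × 60 bootstrap draws; and byte-identical reruns of the full
pipeline under a fixed seed. These sizes are the package's chosen balance of
statistical resolution against a test suite that completes in minutes.

## Known limitations

* Only one random-intercept level (ethnic × state); no crossed or nested
  structures, no municipality-level estimation.
* No analytic (Prasad–Rao) MSE approximation; bootstrap only.
* Direct estimates are treated as fixed benchmarking targets; their own
  sampling variance is not propagated.
* The three indicator models are fitted marginally; mutual coherence is
  monitored (clip and cap diagnostics) but not enforced in estimation.
* Missingness handling is listwise deletion at load time (optional); there
  is no imputation.
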