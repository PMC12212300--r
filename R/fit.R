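#' Fit the unit-level logistic mixed model for one indicator
#'
#' Fits the Bernoulli-logit model
#' `logit p_{A,ed,i} = x_{ed,i}' beta_A + v_{A,ed}`, with one random
#' intercept per (ethnic group, state) domain, by maximum likelihood with the
#' Laplace approximation (the glmer default). Survey weights are not used by
#' default: the model is a unit-level linking model and design weights enter
#' the pipeline only at the benchmarking stage; a weighted pseudo-likelihood
#' fit is available behind `weighted = TRUE`.
#'
#' @param survey Validated survey microdata (see [validate_microdata()]).
#' @param indicator One of `"use_any"`, `"use_modern"`, `"unmet"`.
#' @param codebook An [fp_codebook()].
#' @param weighted Use sampling weights as prior weights (off by default).
#' @param nagq Integration setting passed to [lme4::glmer()]: `1` (default)
#'   for the Laplace approximation, `0` for the faster marginal-profile
#'   approximation used in replicated simulation studies.
#' @param check_separation Pre-check each dummy covariate for complete
#'   separation and abort naming the covariate.
#' @return An object of class `fp_fit` with elements `indicator`, `beta`,
#'   `se`, `sigma_v`, `v_hat` (conditional modes keyed `"ethnic|state"`),
#'   `loglik`, `converged`, `n_obs`, `n_domains`, and the underlying `fit`.
#' @examples
#' \donttest{
#' sim <- simulate_fp_data(fp_truth(n_states = 3, rows_per_state = 400),
#'                         fraction = 0.5, seed = 7)
#' fit <- fit_glmm(sim$survey, "use_any", nagq = 0)
#' glance(fit)
#' }
#' @export
fit_glmm <- function(survey, indicator = c("use_any", "use_modern", "unmet"),
                     codebook = fp_codebook(), weighted = FALSE, nagq = 1,
                     check_separation = TRUE) {
  indicator <- match.arg(indicator)
  ycol <- paste0("y_", indicator)
  if (!ycol %in% names(survey)) {
    abort(sprintf("outcome column '%s' not present", ycol),
          class = "ethnosae_schema_error")
  }
  y <- as.integer(survey[[ycol]])
  X <- design_matrix(survey, codebook)
  dom <- domain_key(survey)
  # a single observed domain is allowed: the fit collapses to plain logistic
  # regression with sigma_v on the boundary at 0
  if (check_separation) {
    for (j in setdiff(colnames(X), "(Intercept)")) {
      x <- X[, j]
      if (length(unique(x)) < 2) next
      on1 <- y[x == 1]
      on0 <- y[x == 0]
      # a binary covariate perfectly aligned with the outcome
      if ((all(on1 == 1) && all(on0 == 0)) ||
          (all(on1 == 0) && all(on0 == 1))) {
        abort(sprintf("complete separation on covariate '%s'", j),
              class = "ethnosae_separation_error")
      }
    }
  }

  df <- as.data.frame(X[, -1, drop = FALSE])
  names(df) <- make.names(colnames(X)[-1])
  df$.y <- y
  df$.dom <- factor(dom)
  fml <- as.formula(paste(".y ~", paste(names(df)[seq_len(ncol(X) - 1)],
                                        collapse = " + "), "+ (1 | .dom)"))
  w <- if (weighted) survey$weight / mean(survey$weight) else NULL
  fit <- suppressMessages(lme4::glmer(
    fml, data = df, family = stats::binomial(), nAGQ = nagq, weights = w,
    control = lme4::glmerControl(calc.derivs = (nagq > 0),
                                 check.conv.singular = "ignore",
                                 check.nlev.gtr.1 = "ignore")
  ))

  # map fitted coefficients back to codebook terms; columns dropped for rank
  # deficiency get coefficient 0 (they contribute nothing to prediction)
  term_of <- setNames(colnames(X), c("(Intercept)",
                                     make.names(colnames(X)[-1])))
  fe <- lme4::fixef(fit)
  fe_se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  beta <- setNames(rep(0, ncol(X)), colnames(X))
  se <- setNames(rep(NA_real_, ncol(X)), colnames(X))
  beta[term_of[names(fe)]] <- fe
  se[term_of[names(fe)]] <- fe_se
  dropped <- setdiff(colnames(X), term_of[names(fe)])
  sigma_v <- sqrt(unname(lme4::VarCorr(fit)$.dom[1]))
  re <- lme4::ranef(fit)$.dom
  v_hat <- setNames(re[["(Intercept)"]], rownames(re))
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- fit@optinfo$conv$opt == 0 && is.null(msgs)
  structure(
    list(indicator = indicator, beta = beta, se = se, sigma_v = sigma_v,
         v_hat = v_hat, loglik = as.numeric(logLik(fit)),
         converged = converged,
         diagnostics = if (is.null(msgs)) character(0) else unlist(msgs),
         dropped_terms = dropped,
         n_obs = nrow(df), n_domains = nlevels(df$.dom),
         weighted = weighted, nagq = nagq, fit = fit),
    class = "fp_fit"
  )
}

#' @export
print.fp_fit <- function(x, ...) {
  cat("<fp_fit>", x$indicator, ":", x$n_obs, "obs,", x$n_domains,
      "domains; sigma_v =", signif(x$sigma_v, 4),
      "; ICC =", signif(icc(x), 3),
      if (!x$converged) "[NOT CONVERGED]" else "", "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted indicator model
#'
#' @param x An `fp_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `odds.ratio`.
#' @export
tidy.fp_fit <- function(x, ...) {
  z <- x$beta / x$se
  tibble(term = names(x$beta), estimate = unname(x$beta),
         std.error = unname(x$se), statistic = unname(z),
         p.value = unname(2 * stats::pnorm(-abs(z))),
         odds.ratio = unname(exp(x$beta)))
}

#' One-row model summary
#'
#' @param x An `fp_fit`.
#' @param ... Unused.
#' @return A tibble with `indicator`, `n_obs`, `n_domains`, `sigma_v`, `icc`,
#'   `logLik`, `converged`.
#' @export
glance.fp_fit <- function(x, ...) {
  tibble(indicator = x$indicator, n_obs = x$n_obs, n_domains = x$n_domains,
         sigma_v = x$sigma_v, icc = icc(x), logLik = x$loglik,
         converged = x$converged)
}

#' Latent-scale intraclass correlation
#'
#' Proportion of latent-scale outcome variance attributable to between-domain
#' differences under the logistic random-intercept model:
#' `sigma_v^2 / (sigma_v^2 + pi^2/3)`, where `pi^2/3` is the variance of the
#' standard logistic individual term.
#'
#' @param x An `fp_fit`, or a nonnegative random-intercept SD.
#' @return A value in `[0, 1)`.
#' @examples
#' icc(0)            # 0
#' icc(pi / sqrt(3)) # 0.5: between- and within-domain variance equal
#' @export
icc <- function(x) {
  sigma_v <- if (inherits(x, "fp_fit")) x$sigma_v else x
  if (any(sigma_v < 0)) abort("sigma_v must be nonnegative")
  sigma_v^2 / (sigma_v^2 + pi^2 / 3)
}

#' Bootstrap confidence interval for the ICC
#'
#' Nonparametric cluster bootstrap: domains (ethnic group x state cells) are
#' resampled with replacement, each drawn cluster is relabelled as a distinct
#' cluster, the model is refitted and the ICC recomputed; the interval is the
#' percentile 95\% interval over replicates. Replicates that fail to converge
#' are dropped and counted.
#'
#' @inheritParams fit_glmm
#' @param B Number of bootstrap replicates (default 500).
#' @param seed Integer seed.
#' @return A one-row tibble: `mean`, `lower95`, `upper95`, `B_effective`,
#'   `B_dropped`.
#' @export
icc_bootstrap_ci <- function(survey, indicator, B = 500, seed = 1,
                             codebook = fp_codebook(), nagq = 0) {
  if (B < 2) abort("B must be at least 2")
  set.seed(seed)
  doms <- unique(domain_key(survey))
  idx_by_dom <- split(seq_len(nrow(survey)), domain_key(survey))
  iccs <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    take <- sample(doms, length(doms), replace = TRUE)
    rows <- unlist(idx_by_dom[take], use.names = FALSE)
    boot <- survey[rows, , drop = FALSE]
    # relabel repeated clusters as distinct so the cluster count is preserved
    boot$state <- rep(seq_along(take),
                      times = lengths(idx_by_dom[take])) * 1000L +
      boot$state
    res <- tryCatch(
      fit_glmm(boot, indicator, codebook, nagq = nagq,
               check_separation = FALSE),
      error = function(e) NULL)
    if (!is.null(res)) iccs[b] <- icc(res)
  }
  ok <- iccs[!is.na(iccs)]
  tibble(mean = mean(ok),
         lower95 = unname(quantile(ok, 0.025, type = 6)),
         upper95 = unname(quantile(ok, 0.975, type = 6)),
         B_effective = length(ok), B_dropped = B - length(ok))
}

#' Odds ratios from a fitted model or coefficient vector
#'
#' Elementwise exponential of the logit-scale coefficients; reference
#' categories have OR 1 implicitly.
#'
#' @param x An `fp_fit` or a named numeric coefficient vector.
#' @return A tibble with `term`, `estimate` (logit scale), `or`.
#' @examples
#' odds_ratios(c(age13_14 = 1.955))  # OR about 7.06
#' @export
odds_ratios <- function(x) {
  beta <- if (inherits(x, "fp_fit")) x$beta else x
  if (is.null(names(beta))) abort("coefficients must be named")
  tibble(term = names(beta), estimate = unname(beta), or = unname(exp(beta)))
}

#' Combined odds ratio for a covariate profile
#'
#' The odds ratio for jointly switching several dummies on is the exponential
#' of the sum of their coefficients — e.g. the effect of being an
#' ethnic-minority woman with a same-ethnicity partner combines the minority
#' main effect with the minority x partner interaction.
#'
#' @param x An `fp_fit` or a named numeric coefficient vector.
#' @param terms Character vector of coefficient names to sum.
#' @return A single combined odds ratio.
#' @examples
#' combined_or(c(a = -0.008, b = -0.304), c("a", "b"))  # about 0.732
#' @export
combined_or <- function(x, terms) {
  beta <- if (inherits(x, "fp_fit")) x$beta else x
  missing <- setdiff(terms, names(beta))
  if (length(missing) > 0) {
    abort(paste0("unknown coefficient name(s): ",
                 paste(missing, collapse = ", ")))
  }
  exp(sum(beta[terms]))
}

#' Confusion-matrix classification metrics
#'
#' Metrics from the confusion counts of predicted versus observed outcomes:
#' accuracy `(P11 + P00) / (P11 + P00 + P01 + P10)`, precision
#' `P11 / (P11 + P01)`, sensitivity `P11 / (P11 + P10)`, and specificity
#' `P00 / (P00 + P01)`, where `P11` are true positives, `P00` true
#' negatives, `P01` false positives and `P10` false negatives. A metric with
#' an empty denominator is reported as `NA` (undefined), never propagated as
#' `NaN`.
#'
#' @param p11,p00,p01,p10 Confusion counts.
#' @return A one-row tibble `accuracy`, `precision`, `specificity`,
#'   `sensitivity`.
#' @examples
#' confusion_metrics(2, 3, 1, 1)$accuracy  # 5/7
#' @export
confusion_metrics <- function(p11, p00, p01, p10) {
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble(
    accuracy = safe_div(p11 + p00, p11 + p00 + p01 + p10),
    precision = safe_div(p11, p11 + p01),
    specificity = safe_div(p00, p00 + p01),
    sensitivity = safe_div(p11, p11 + p10)
  )
}

#' In-sample classification metrics of a fitted model
#'
#' Classifies each fitting observation as positive when its fitted
#' probability (fixed effects plus predicted domain intercept) reaches the
#' threshold, and reports the four confusion-matrix metrics.
#'
#' @param model An `fp_fit`.
#' @param survey The survey data the model was fitted to.
#' @param threshold Classification threshold in (0, 1); default 0.5.
#' @param codebook An [fp_codebook()].
#' @return A one-row tibble of metrics plus the four confusion counts.
#' @export
classification_metrics <- function(model, survey, threshold = 0.5,
                                   codebook = fp_codebook()) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  y <- as.integer(survey[[paste0("y_", model$indicator)]])
  p <- predict_individual(model, survey, codebook)$p
  yhat <- as.integer(p >= threshold)
  p11 <- sum(yhat == 1 & y == 1)
  p00 <- sum(yhat == 0 & y == 0)
  p01 <- sum(yhat == 1 & y == 0)
  p10 <- sum(yhat == 0 & y == 1)
  dplyr::bind_cols(confusion_metrics(p11, p00, p01, p10),
                   tibble(p11 = p11, p00 = p00, p01 = p01, p10 = p10))
}

#' Serialize a fitted model to JSON
#'
#' @param model An `fp_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(model, path) {
  jsonlite::write_json(
    list(indicator = model$indicator, beta = as.list(model$beta),
         se = as.list(model$se), sigma_v = model$sigma_v,
         v_hat = as.list(model$v_hat), loglik = model$loglik,
         converged = model$converged, diagnostics = model$diagnostics,
         n_obs = model$n_obs, n_domains = model$n_domains),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
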