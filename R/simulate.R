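#' Default per-domain covariate distributions
#'
#' Categorical covariate distributions keyed by ethnic group and urbanicity,
#' emulating the broad structure of Colombian survey/census microdata for
#' in-union women of reproductive age: an age profile concentrated in the
#' 20-40 bands, education gradients by urbanicity and ethnic group, poorer
#' housing conditions (walls, electricity, internet) in rural and
#' ethnic-minority domains, and ethnic homogamy rates that are high for all
#' groups. Only marginals are modelled; covariates are drawn independently
#' within a domain.
#'
#' @return A tibble with columns `ethnic_group`, `urbanicity`, `variable`,
#'   `category`, `prob`; probabilities sum to 1 per variable per cell.
#' @export
default_covariate_dists <- function() {
  cb <- fp_codebook()
  cells <- tidyr::expand_grid(
    ethnic_group = cb$ethnic_levels,
    urbanicity = cb$urbanicity_levels
  )
  age_probs <- c(0.005, 0.06, 0.14, 0.18, 0.185, 0.17, 0.14, 0.12)

  one_cell <- function(eth, urb) {
    rural <- urb == "rural"
    minority <- eth != "nonethnic"
    edu <- if (rural) c(0.10, 0.45, 0.38, 0.07) else c(0.03, 0.20, 0.50, 0.27)
    if (minority) {
      # shift mass one level down for minority domains
      edu <- c(edu[1] + 0.06, edu[2] + 0.06, edu[3] - 0.06, edu[4] - 0.06)
    }
    bern <- function(p) c(`0` = 1 - p, `1` = p)
    probs <- list(
      age_group = setNames(age_probs, cb$age_levels),
      education = setNames(edu, cb$education_levels),
      is_mother = bern(0.80),
      not_attending_school = bern(0.90),
      working = bern(if (rural) 0.40 else 0.55),
      poor_walls = bern(min(0.9, (if (rural) 0.25 else 0.05) +
                              (if (minority) 0.15 else 0))),
      house_or_apartment = bern(if (rural) 0.85 else 0.95),
      electricity = bern(if (rural) (if (minority) 0.70 else 0.85) else 0.99),
      internet = bern(if (rural) 0.15 else 0.60),
      partner_same_ethnic = bern(switch(eth, nonethnic = 0.90,
                                        indigenous = 0.70, afro = 0.60))
    )
    purrr::imap_dfr(probs, function(p, v) {
      tibble(variable = v, category = names(p), prob = unname(p))
    })
  }
  dplyr::bind_cols(
    cells[rep(seq_len(nrow(cells)),
              each = nrow(one_cell("nonethnic", "urban"))), ],
    purrr::pmap_dfr(cells, function(ethnic_group, urbanicity) {
      one_cell(ethnic_group, urbanicity)
    })
  )
}

#' Default domain population sizes
#'
#' Population counts per (state, ethnic group, urbanicity) cell. Ethnic
#' shares default to 25\% Indigenous, 25\% Afro-descendant, 50\% non-ethnic
#' per state; Indigenous women are predominantly rural (60\%) while the other
#' groups are predominantly urban (60\%).
#'
#' @param n_states Number of states.
#' @param rows_per_state Total census rows per state.
#' @return A tibble with columns `state`, `ethnic_group`, `urbanicity`, `n`.
#' @export
default_domain_sizes <- function(n_states = 6, rows_per_state = 2000) {
  eth_share <- c(indigenous = 0.25, afro = 0.25, nonethnic = 0.50)
  rural_share <- c(indigenous = 0.60, afro = 0.40, nonethnic = 0.40)
  tidyr::expand_grid(
    state = seq_len(n_states),
    ethnic_group = names(eth_share),
    urbanicity = c("rural", "urban")
  ) |>
    dplyr::mutate(
      n = round(rows_per_state * eth_share[.data$ethnic_group] *
                  ifelse(.data$urbanicity == "rural",
                         rural_share[.data$ethnic_group],
                         1 - rural_share[.data$ethnic_group]))
    )
}

#' Simulation truth parameters
#'
#' Bundles everything the generator needs: per-indicator fixed-effect
#' coefficient vectors aligned to the codebook, per-indicator random-intercept
#' standard deviations, per-domain covariate distributions, and domain
#' population sizes. Defaults are the reference Colombian DHS model
#' coefficients ([reference_coefficients()]) with random-intercept SDs
#' matching the reported intraclass correlations ([reference_sigma_v()]), at
#' a desk-scale geography of 6 states x 3 ethnic groups x 2,000 census rows
#' per state.
#'
#' @param n_states Number of states (domain sizes default accordingly).
#' @param rows_per_state Census rows per state for the default sizes.
#' @param beta Tibble of coefficients with columns `term`, `use_any`,
#'   `use_modern`, `unmet`, aligned to `codebook$terms`.
#' @param sigma_v Named nonnegative numeric vector of random-intercept SDs
#'   per indicator.
#' @param covariate_dists See [default_covariate_dists()].
#' @param domain_sizes See [default_domain_sizes()].
#' @param codebook An [fp_codebook()].
#' @return An object of class `fp_truth`.
#' @export
fp_truth <- function(n_states = 6, rows_per_state = 2000,
                     beta = reference_coefficients(),
                     sigma_v = reference_sigma_v(),
                     covariate_dists = default_covariate_dists(),
                     domain_sizes = default_domain_sizes(n_states,
                                                         rows_per_state),
                     codebook = fp_codebook()) {
  if (!identical(beta$term, codebook$terms)) {
    abort("beta$term must match codebook$terms exactly and in order")
  }
  if (any(sigma_v < 0) || !all(fp_indicators() %in% names(sigma_v))) {
    abort("sigma_v must be nonnegative and named over the three indicators")
  }
  sums <- covariate_dists |>
    dplyr::summarise(s = sum(.data$prob),
                     .by = c("ethnic_group", "urbanicity", "variable"))
  if (any(abs(sums$s - 1) > 1e-8)) {
    abort("covariate distributions must sum to 1 per variable per cell")
  }
  if (any(domain_sizes$n < 0)) abort("domain sizes must be nonnegative")
  structure(
    list(beta = beta, sigma_v = sigma_v[fp_indicators()],
         covariate_dists = covariate_dists, domain_sizes = domain_sizes,
         codebook = codebook),
    class = "fp_truth"
  )
}

#' @export
print.fp_truth <- function(x, ...) {
  cat("<fp_truth>", nrow(x$domain_sizes), "domain cells,",
      sum(x$domain_sizes$n), "women;",
      "sigma_v =", paste(signif(x$sigma_v, 3), collapse = "/"), "\n")
  invisible(x)
}

#' Generate a census-like population with known random effects
#'
#' Draws one woman per population slot, with covariates sampled
#' independently from the per-domain categorical distributions, and one
#' random intercept per indicator per (ethnic group, state) domain from
#' N(0, sigma_v^2). Outcomes are not assigned here; see [assign_outcomes()].
#'
#' @param truth An [fp_truth()].
#' @param seed Optional integer seed (restores nothing; seeds the global RNG).
#' @return A list with `population` (tibble of women, `in_union = 1`) and
#'   `v_draws` (tibble `indicator`, `ethnic_group`, `state`, `v`).
#' @export
generate_population <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "fp_truth"))
  if (nrow(truth$domain_sizes) == 0) {
    abort("domain_sizes is empty", class = "ethnosae_validation_error")
  }
  if (!is.null(seed)) set.seed(seed)

  dists <- truth$covariate_dists |>
    tidyr::nest(dist = c("category", "prob"))

  draw_cell <- function(state, ethnic_group, urbanicity, n) {
    if (n == 0) return(NULL)
    cell <- dists[dists$ethnic_group == ethnic_group &
                    dists$urbanicity == urbanicity, ]
    cols <- purrr::map(setNames(cell$dist, cell$variable), function(d) {
      sample(d$category, n, replace = TRUE, prob = d$prob)
    })
    out <- tibble(state = rep.int(state, n),
                  ethnic_group = rep.int(ethnic_group, n),
                  urbanicity = rep.int(urbanicity, n))
    for (v in names(cols)) {
      out[[v]] <- if (v %in% c("age_group", "education")) cols[[v]]
                  else as.integer(cols[[v]])
    }
    out
  }
  pop <- purrr::pmap_dfr(truth$domain_sizes, draw_cell)
  if (nrow(pop) > 0) {
    pop <- dplyr::mutate(pop,
                         id = sprintf("w%07d", dplyr::row_number()),
                         in_union = 1L, .before = 1)
  } else {
    pop <- dplyr::mutate(pop, id = character(0), in_union = integer(0))
  }

  doms <- dplyr::distinct(truth$domain_sizes[truth$domain_sizes$n > 0, ],
                          .data$ethnic_group, .data$state)
  v_draws <- tidyr::expand_grid(indicator = fp_indicators(),
                                doms) |>
    dplyr::mutate(v = rnorm(dplyr::n(), 0,
                            truth$sigma_v[.data$indicator]))
  list(population = pop, v_draws = v_draws)
}

#' Assign model-consistent binary outcomes
#'
#' Draws the three outcomes from the logistic linking models
#' `logit p_A = x' beta_A + v_{A,ed}` hierarchically, so that the recorded
#' outcomes always satisfy the data-model invariants (modern use implies any
#' use; unmet need only among non-users) while reproducing all three marginal
#' models whenever the implied conditional probabilities stay within (0,1):
#' any use is drawn from its own model; modern use among users with
#' probability `min(1, p_modern/p_any)`; unmet need among non-users with
#' probability `min(1, p_unmet/(1 - p_any))`. Rows where a cap binds are
#' counted in the `cap_events` attribute of the result.
#'
#' @param population A covariate tibble from [generate_population()].
#' @param truth The [fp_truth()] used to generate it.
#' @param v_draws The drawn random intercepts from [generate_population()].
#' @return `population` with integer columns `y_use_any`, `y_use_modern`,
#'   `y_unmet` added, and attribute `cap_events` (named count vector).
#' @export
assign_outcomes <- function(population, truth, v_draws) {
  stopifnot(inherits(truth, "fp_truth"))
  n <- nrow(population)
  if (n == 0) {
    out <- dplyr::mutate(population, y_use_any = integer(0),
                         y_use_modern = integer(0), y_unmet = integer(0))
    attr(out, "cap_events") <- c(modern = 0L, unmet = 0L)
    return(out)
  }
  X <- design_matrix(population, truth$codebook)
  key <- domain_key(population)
  p <- purrr::map(setNames(fp_indicators(), fp_indicators()), function(ind) {
    beta <- truth$beta[[ind]]
    v <- v_draws[v_draws$indicator == ind, ]
    vmap <- setNames(v$v, domain_key(v))
    plogis(drop(X %*% beta) + unname(vmap[key]))
  })
  y_any <- rbinom(n, 1, p$use_any)
  p_mod_cond <- ifelse(p$use_any > 0, pmin(1, p$use_modern / p$use_any), 0)
  p_unm_cond <- ifelse(p$use_any < 1, pmin(1, p$unmet / (1 - p$use_any)), 0)
  y_modern <- y_any * rbinom(n, 1, p_mod_cond)
  y_unmet <- (1L - y_any) * rbinom(n, 1, p_unm_cond)
  out <- dplyr::mutate(population,
                       y_use_any = as.integer(y_any),
                       y_use_modern = as.integer(y_modern),
                       y_unmet = as.integer(y_unmet))
  attr(out, "cap_events") <- c(modern = sum(p$use_modern > p$use_any),
                               unmet = sum(p$unmet > 1 - p$use_any))
  out
}

#' Draw a stratified survey with inverse-probability weights
#'
#' Simple random sampling without replacement within each state x urbanicity
#' stratum, at the stratum's sampling fraction; the design weight is the
#' inverse inclusion probability N_h / n_h. Unequal fractions across strata
#' emulate the unequal-probability design of a DHS-type survey.
#'
#' @param population A population tibble with outcomes.
#' @param fraction Scalar in (0, 1], or a tibble with columns `state`,
#'   `urbanicity`, `fraction` for per-stratum fractions.
#' @param seed Optional integer seed.
#' @return A survey tibble (sampled rows plus a `weight` column).
#' @export
draw_survey <- function(population, fraction = 0.25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(fraction) && length(fraction) == 1) {
    frac_tbl <- dplyr::distinct(population, .data$state, .data$urbanicity) |>
      dplyr::mutate(fraction = fraction)
  } else {
    frac_tbl <- as_tibble(fraction)
  }
  if (any(frac_tbl$fraction <= 0) || any(frac_tbl$fraction > 1)) {
    abort("sampling fractions must lie in (0, 1]",
          class = "ethnosae_validation_error")
  }
  population |>
    dplyr::inner_join(frac_tbl, by = c("state", "urbanicity")) |>
    dplyr::group_by(.data$state, .data$urbanicity) |>
    dplyr::group_modify(function(d, g) {
      n_h <- max(1L, round(d$fraction[1] * nrow(d)))
      take <- sample.int(nrow(d), n_h)
      dplyr::mutate(d[take, ], weight = nrow(d) / n_h)
    }) |>
    dplyr::ungroup() |>
    dplyr::select(-"fraction") |>
    dplyr::relocate("id")
}

#' Simulate a linked survey-census pair with known truth
#'
#' One call producing everything the pipeline consumes: a census-like
#' population with model-consistent outcomes, the census view of it (no
#' outcomes, no weights), a weighted stratified survey drawn from it, the
#' drawn random intercepts, and the true domain-level indicator values
#' computed from the full population (need satisfied as the ratio
#' `sum(modern) / (sum(any) + sum(unmet))` within each domain).
#'
#' @param truth An [fp_truth()].
#' @param fraction Sampling fraction(s) passed to [draw_survey()].
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return A list of class `fp_sim` with elements `population`, `census`,
#'   `survey`, `v_draws`, `truth_domains`, `cap_events`, `seed`.
#' @examples
#' sim <- simulate_fp_data(fp_truth(n_states = 2, rows_per_state = 200),
#'                         seed = 42)
#' sim$truth_domains
#' @export
simulate_fp_data <- function(truth = fp_truth(), fraction = 0.25, seed = 1) {
  set.seed(seed)
  gen <- generate_population(truth)
  pop <- assign_outcomes(gen$population, truth, gen$v_draws)
  survey <- draw_survey(pop, fraction)
  truth_domains <- pop |>
    dplyr::summarise(
      use_any = mean(.data$y_use_any),
      use_modern = mean(.data$y_use_modern),
      unmet = mean(.data$y_unmet),
      need_satisfied = sum(.data$y_use_modern) /
        (sum(.data$y_use_any) + sum(.data$y_unmet)),
      n = dplyr::n(),
      .by = c("ethnic_group", "state")
    )
  structure(
    list(population = pop, census = as_census(pop), survey = survey,
         v_draws = gen$v_draws, truth_domains = truth_domains,
         cap_events = attr(pop, "cap_events"), seed = seed),
    class = "fp_sim"
  )
}

#' @export
print.fp_sim <- function(x, ...) {
  cat("<fp_sim> census", nrow(x$census), "rows; survey", nrow(x$survey),
      "rows;", nrow(x$truth_domains), "domains; seed", x$seed, "\n")
  invisible(x)
}
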