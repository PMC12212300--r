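#' Benchmark levels
#'
#' A benchmark level is a population subset at which the census-based
#' estimates must match the direct survey estimates: `"national"` (everyone),
#' `"rural"` / `"urban"`, and `"state:<d>"` for each state code `d`.
#'
#' @param data A microdata or prediction tibble with `state` and `urbanicity`.
#' @param level A level id.
#' @return A logical membership vector.
#' @export
level_membership <- function(data, level) {
  if (level == "national") return(rep(TRUE, nrow(data)))
  if (level %in% c("rural", "urban")) {
    return(as.character(data$urbanicity) == level)
  }
  if (grepl("^state:", level)) {
    return(data$state == as.integer(sub("^state:", "", level)))
  }
  abort(sprintf("unknown benchmark level '%s'", level))
}

#' Default benchmark levels for a survey
#'
#' @param data A tibble with a `state` column.
#' @return `c("state:<d>" for each observed state, "rural", "urban",
#'   "national")`.
#' @export
default_levels <- function(data) {
  c(paste0("state:", sort(unique(data$state))), "rural", "urban", "national")
}

#' Direct survey estimates at benchmark levels
#'
#' Hajek (ratio-form) weighted estimates from the survey alone: for the three
#' modelled indicators the weighted mean `sum(w * y) / sum(w)` within each
#' level; for need satisfied the weighted demand-satisfaction ratio
#' `sum(w * y_modern) / sum(w * (y_any + y_unmet))`. Empty levels are
#' reported with `D = NA`.
#'
#' @param survey Validated survey microdata with weights.
#' @param indicator One of the four indicators.
#' @param levels Character vector of level ids; defaults to all states plus
#'   rural, urban, national.
#' @return A tibble `level`, `D`, `n`.
#' @export
direct_estimates <- function(survey, indicator = fp_all_indicators(),
                             levels = default_levels(survey)) {
  indicator <- match.arg(indicator, fp_all_indicators())
  purrr::map_dfr(levels, function(lev) {
    m <- level_membership(survey, lev)
    if (!any(m)) return(tibble(level = lev, D = NA_real_, n = 0L))
    w <- survey$weight[m]
    D <- if (indicator == "need_satisfied") {
      num <- sum(w * survey$y_use_modern[m])
      den <- sum(w * (survey$y_use_any[m] + survey$y_unmet[m]))
      if (den == 0) NA_real_ else num / den
    } else {
      y <- survey[[paste0("y_", indicator)]][m]
      sum(w * y) / sum(w)
    }
    tibble(level = lev, D = D, n = sum(m))
  })
}

#' Benchmark adjustment ratio
#'
#' The ratio `R_j = D_j / Y_j` between the direct survey estimate and the
#' unadjusted census estimate at level `j`; the target the calibrated census
#' weights must reproduce at every level simultaneously.
#'
#' @param D Direct estimate(s).
#' @param Y Census unadjusted mean(s), strictly positive.
#' @return `D / Y`.
#' @export
ratio_adjust <- function(D, Y) {
  if (any(Y == 0)) {
    abort("census estimate Y = 0: adjustment ratio undefined",
          class = "ethnosae_undefined_error")
  }
  D / Y
}

#' Calibrate census weights to direct estimates
#'
#' Finds per-row census weights, starting from 1, such that the weighted mean
#' of the predicted indicator within every benchmark level matches the
#' level's direct estimate: minimize the chi-square distance
#' `sum((w_i - 1)^2)` subject to
#' `sum_{i in j} w_i p_i / sum_{i in j} w_i = D_j` for all levels `j`.
#'
#' The solver sweeps the constraints iteratively (Deming-Stephan style): each
#' constraint is met exactly by the one-constraint chi-square tilt
#' `w_i <- w_i (1 + delta (p_i - D_j))` with
#' `delta = -sum w_i (p_i - D_j) / sum w_i (p_i - D_j)^2` over its members,
#' and sweeps repeat until every residual is below `tol`. Steps that would
#' drive a weight nonpositive are damped (halved until all factors stay
#' positive), weights are clamped to `bounds`, and the national constraint is
#' processed last in each sweep since it is typically near-redundant given
#' the state constraints. Infeasible systems return a non-converged solution
#' with the residual report and a warning, never silently.
#'
#' @param predictions A tibble with the predicted probability column `p` plus
#'   `state` and `urbanicity` (and optionally `id`).
#' @param constraints A tibble with columns `level` and `D`.
#' @param tol Convergence tolerance on the constraint residuals.
#' @param max_iter Maximum number of sweeps.
#' @param bounds Length-2 positive weight bounds, default `c(0.2, 5)`.
#' @return An object of class `fp_weights`: list with `weights` (tibble
#'   `id`, `weight`), `residuals` (tibble `level`, `D`, `achieved`,
#'   `residual`), `iterations`, `converged`, `n_damped`, `n_bound_hits`.
#' @export
calibrate_weights <- function(predictions, constraints, tol = 1e-8,
                              max_iter = 1000, bounds = c(0.2, 5)) {
  stopifnot(length(bounds) == 2, bounds[1] > 0, bounds[1] < bounds[2])
  p <- predictions$p
  n <- length(p)
  id <- predictions$id %||% as.character(seq_len(n))
  constraints <- as_tibble(constraints)
  if (nrow(constraints) > 0) {
    # national last: near-redundant given the state constraints
    ord <- order(constraints$level == "national")
    constraints <- constraints[ord, ]
  }
  members <- purrr::map(constraints$level, level_membership,
                        data = predictions)
  # constraints with no census members or no target are unusable: drop, report
  usable <- purrr::map_lgl(members, any) & !is.na(constraints$D)
  if (!all(usable)) {
    warn(paste0("dropping constraint(s) with no members or no target: ",
                paste(constraints$level[!usable], collapse = ", ")))
    constraints <- constraints[usable, ]
    members <- members[usable]
  }
  for (j in seq_along(members)) {
    rng <- range(p[members[[j]]])
    Dj <- constraints$D[j]
    if (Dj < rng[1] || Dj > rng[2]) {
      warn(sprintf(
        "constraint '%s' (D = %.4g) lies outside the prediction range [%.4g, %.4g]: infeasible",
        constraints$level[j], Dj, rng[1], rng[2]))
    }
  }

  w <- rep(1, n)
  n_damped <- 0L
  n_bound <- 0L
  iter <- 0L
  achieved <- function(j) {
    m <- members[[j]]
    sum(w[m] * p[m]) / sum(w[m])
  }
  resid <- function() {
    vapply(seq_along(members), function(j) achieved(j) - constraints$D[j],
           numeric(1))
  }
  if (nrow(constraints) > 0) {
    while (iter < max_iter) {
      iter <- iter + 1L
      for (j in seq_along(members)) {
        m <- members[[j]]
        r <- p[m] - constraints$D[j]
        num <- sum(w[m] * r)
        den <- sum(w[m] * r^2)
        if (den == 0) next
        delta <- -num / den
        fac <- 1 + delta * r
        while (any(fac <= 0)) {   # damp steps that would cross zero
          delta <- delta / 2
          fac <- 1 + delta * r
          n_damped <- n_damped + 1L
        }
        wn <- w[m] * fac
        hits <- wn < bounds[1] | wn > bounds[2]
        n_bound <- n_bound + sum(hits)
        w[m] <- pmin(pmax(wn, bounds[1]), bounds[2])
      }
      if (max(abs(resid())) <= tol) break
    }
  }
  res <- if (nrow(constraints) > 0) resid() else numeric(0)
  converged <- length(res) == 0 || max(abs(res)) <= tol
  if (!converged) {
    warn(sprintf(
      "calibration did not converge in %d sweeps (max residual %.3g)",
      iter, max(abs(res))))
  }
  structure(
    list(weights = tibble(id = id, weight = w),
         residuals = tibble(level = constraints$level, D = constraints$D,
                            achieved = constraints$D + res, residual = res),
         iterations = iter, converged = converged,
         n_damped = n_damped, n_bound_hits = n_bound),
    class = "fp_weights"
  )
}

#' @export
print.fp_weights <- function(x, ...) {
  cat("<fp_weights>", nrow(x$weights), "rows;", nrow(x$residuals),
      "constraints;", x$iterations, "sweeps;",
      if (x$converged) "converged" else
        sprintf("NOT converged (max residual %.3g)",
                max(abs(x$residuals$residual))), "\n")
  invisible(x)
}

#' Write calibrated weights and their residual report
#'
#' @param x An `fp_weights`.
#' @param weights_path CSV path for `id,weight`.
#' @param residuals_path Optional JSON path for the per-constraint residuals.
#' @return `weights_path`, invisibly.
#' @export
write_weights <- function(x, weights_path, residuals_path = NULL) {
  readr::write_csv(x$weights, weights_path, progress = FALSE)
  if (!is.null(residuals_path)) {
    jsonlite::write_json(
      setNames(as.list(x$residuals$residual), x$residuals$level),
      residuals_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(weights_path)
}

#' Benchmarked domain estimates
#'
#' Weighted mean of the predicted indicator within each (ethnic group, state)
#' domain under the calibrated census weights. With the need-satisfied
#' indicator, `aggregation = "mean_of_ratios"` (default) averages the
#' individual ratios, while `"ratio_of_means"` forms the ratio of the
#' weighted aggregate components.
#'
#' @param predictions Wide prediction tibble from [predict_indicators()].
#' @param weights An `fp_weights` object, a numeric vector, or `NULL` for
#'   unit weights.
#' @param indicator One of the four indicators.
#' @param aggregation Aggregation rule for need satisfied.
#' @return A tibble `ethnic_group`, `state`, `estimate`, `n`.
#' @export
benchmarked_domain_estimates <- function(predictions, weights = NULL,
                                         indicator = fp_all_indicators(),
                                         aggregation = c("mean_of_ratios",
                                                         "ratio_of_means")) {
  indicator <- match.arg(indicator, fp_all_indicators())
  aggregation <- match.arg(aggregation)
  w <- if (is.null(weights)) rep(1, nrow(predictions))
       else if (inherits(weights, "fp_weights")) weights$weights$weight
       else weights
  stopifnot(length(w) == nrow(predictions))
  df <- dplyr::mutate(predictions, .w = w)
  if (indicator == "need_satisfied" && aggregation == "ratio_of_means") {
    df |>
      dplyr::summarise(
        estimate = sum(.data$.w * .data$p_use_modern) /
          sum(.data$.w * (.data$p_use_any + .data$p_unmet)),
        n = dplyr::n(), .by = c("ethnic_group", "state")) |>
      dplyr::arrange(.data$ethnic_group, .data$state)
  } else {
    col <- paste0("p_", indicator)
    df |>
      dplyr::summarise(
        estimate = sum(.data$.w * .data[[col]]) / sum(.data$.w),
        n = dplyr::n(), .by = c("ethnic_group", "state")) |>
      dplyr::arrange(.data$ethnic_group, .data$state)
  }
}
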