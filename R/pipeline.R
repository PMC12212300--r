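#' Validate a pipeline run configuration
#'
#' Accepts a YAML path or a named list and checks every field, reporting all
#' problems at once rather than stopping at the first. Required fields:
#' `survey` and `census` (paths to CSV microdata, or data frames). Optional
#' fields with defaults: `harmonization_maps` (YAML path or map list),
#' `indicators` (all four), `levels` (all states + rural + urban + national),
#' `calibration` (`tol` 1e-8, `max_iter` 1000, `bounds` c(0.2, 5)),
#' `bootstrap` (`B` 200), `seed` (1), `weighted_fit` (FALSE),
#' `benchmark_in_bootstrap` (FALSE), `aggregation` (`"mean_of_ratios"`),
#' `nagq` (1), `out_dir` (NULL: nothing written).
#'
#' @param config A YAML file path or a named list.
#' @return A validated config of class `fp_config`, or an abort listing every
#'   error.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(sprintf("config file '%s' does not exist", config),
            class = "ethnosae_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)

  for (field in c("survey", "census")) {
    x <- config[[field]]
    if (is.null(x)) note(sprintf("missing required field '%s'", field))
    else if (is.character(x) && !file.exists(x)) {
      note(sprintf("%s path '%s' does not exist", field, x))
    } else if (!is.character(x) && !is.data.frame(x)) {
      note(sprintf("'%s' must be a file path or a data frame", field))
    }
  }
  defaults <- list(
    harmonization_maps = NULL,
    indicators = fp_all_indicators(),
    levels = NULL,
    calibration = list(),
    bootstrap = list(),
    seed = 1L,
    weighted_fit = FALSE,
    benchmark_in_bootstrap = FALSE,
    aggregation = "mean_of_ratios",
    nagq = 1,
    out_dir = NULL
  )
  config <- utils::modifyList(defaults, config, keep.null = TRUE)
  config$calibration <- utils::modifyList(
    list(tol = 1e-8, max_iter = 1000, bounds = c(0.2, 5)),
    config$calibration)
  config$bootstrap <- utils::modifyList(list(B = 200), config$bootstrap)

  bad_ind <- setdiff(config$indicators, fp_all_indicators())
  if (length(bad_ind) > 0) {
    note(paste0("unknown indicator(s): ", paste(bad_ind, collapse = ", ")))
  }
  if (!is.numeric(config$bootstrap$B) || config$bootstrap$B < 2) {
    note("bootstrap B must be at least 2")
  }
  cal <- config$calibration
  if (!is.numeric(cal$tol) || cal$tol <= 0) note("calibration tol must be > 0")
  if (length(cal$bounds) != 2 || cal$bounds[1] <= 0 ||
      cal$bounds[1] >= cal$bounds[2]) {
    note("calibration bounds must be two increasing positive numbers")
  }
  if (!config$aggregation %in% c("mean_of_ratios", "ratio_of_means")) {
    note("aggregation must be 'mean_of_ratios' or 'ratio_of_means'")
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1) {
    note("seed must be a single integer")
  }
  if (length(errors) > 0) {
    abort(paste0("invalid configuration:\n",
                 paste0("  - ", errors, collapse = "\n")),
          class = "ethnosae_config_error")
  }
  structure(config, class = "fp_config")
}

load_side <- function(x, source, maps) {
  if (is.character(x)) {
    if (!is.null(maps)) {
      raw <- readr::read_csv(x, show_col_types = FALSE, progress = FALSE)
      raw <- harmonize(raw, maps, source)
      return(validate_microdata(raw, source))
    }
    return(read_microdata(x, source))
  }
  if (!is.null(maps)) x <- harmonize(x, maps, source)
  validate_microdata(x, source)
}

#' Run the five-step estimation pipeline end to end
#'
#' Orchestrates harmonization, eligibility filtering, the three mixed-model
#' fits, individual-level census prediction (including the derived
#' need-satisfied indicator), direct estimation at the benchmark levels,
#' weight calibration, benchmarked domain estimation, and parametric-
#' bootstrap MSE, producing one row per indicator x ethnic group x state.
#'
#' The run is deterministic given `config$seed`; the attached manifest
#' records the configuration hash, seed, per-stage row counts and
#' diagnostics, which is sufficient to reproduce the output exactly.
#'
#' @param config An `fp_config` (see [validate_config()]) or anything it
#'   accepts.
#' @return A tibble of domain estimates with columns `indicator`,
#'   `ethnic_group`, `state`, `estimate`, `mse`, `rrmse_pct`, with
#'   attributes `manifest` (list) and `weights` (per-indicator calibration
#'   solutions).
#' @examples
#' \donttest{
#' sim <- simulate_fp_data(fp_truth(n_states = 3, rows_per_state = 300),
#'                         fraction = 0.5, seed = 3)
#' res <- run_pipeline(list(survey = sim$survey, census = sim$census,
#'                          bootstrap = list(B = 4), nagq = 0, seed = 3))
#' head(res)
#' }
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "fp_config")) config <- validate_config(config)
  stage <- "load"
  result <- tryCatch({
    maps <- config$harmonization_maps
    if (is.character(maps)) maps <- read_harmonization_maps(maps)
    survey <- load_side(config$survey, "survey", maps)
    census <- load_side(config$census, "census", maps)
    counts <- list(survey_loaded = nrow(survey), census_loaded = nrow(census))

    stage <- "filter_eligible"
    if ("in_union" %in% names(survey)) survey <- filter_eligible(survey)
    if ("in_union" %in% names(census)) census <- filter_eligible(census)
    counts$survey_eligible <- nrow(survey)
    counts$census_eligible <- nrow(census)

    stage <- "fit_glmm"
    set.seed(config$seed)
    models <- purrr::map(
      setNames(fp_indicators(), fp_indicators()),
      function(ind) fit_glmm(survey, ind, weighted = config$weighted_fit,
                             nagq = config$nagq))

    stage <- "predict"
    preds <- predict_indicators(models, census)

    stage <- "benchmark"
    cal <- purrr::map(
      setNames(config$indicators, config$indicators),
      function(ind) {
        D <- direct_estimates(survey, ind, config$levels %||%
                                default_levels(survey))
        D <- D[!is.na(D$D), ]
        calibrate_weights(
          tibble(p = preds[[paste0("p_", ind)]], state = preds$state,
                 urbanicity = preds$urbanicity, id = preds$id),
          D[, c("level", "D")],
          tol = config$calibration$tol,
          max_iter = config$calibration$max_iter,
          bounds = config$calibration$bounds)
      })
    points <- purrr::imap_dfr(cal, function(w, ind) {
      benchmarked_domain_estimates(preds, w, ind,
                                   aggregation = config$aggregation) |>
        dplyr::mutate(indicator = ind, .before = 1)
    })

    stage <- "bootstrap_mse"
    mse <- bootstrap_mse_joint(
      models, survey, census, B = config$bootstrap$B, seed = config$seed,
      nagq = 0, aggregation = config$aggregation,
      benchmark = config$benchmark_in_bootstrap,
      levels = config$levels)
    out <- points |>
      dplyr::left_join(mse, by = c("indicator", "ethnic_group", "state")) |>
      dplyr::mutate(rrmse_pct = relative_rmse(.data$mse, .data$estimate)) |>
      dplyr::select("indicator", "ethnic_group", "state", "estimate",
                    "mse", "rrmse_pct") |>
      dplyr::arrange(.data$indicator, .data$ethnic_group, .data$state)

    manifest <- list(
      package = "ethnosae",
      version = as.character(utils::packageVersion("ethnosae")),
      seed = config$seed,
      config_hash = rlang::hash(unclass(config)),
      counts = counts,
      n_domains = length(unique(domain_key(census))),
      indicators = config$indicators,
      bootstrap_B = config$bootstrap$B,
      need_satisfied_clipped = attr(preds, "ns_clipped"),
      frac_modern_exceeds_any = attr(preds, "frac_modern_exceeds_any"),
      calibration = purrr::map(cal, function(w) {
        list(converged = w$converged, iterations = w$iterations,
             max_residual = if (nrow(w$residuals)) max(abs(w$residuals$residual)) else 0)
      }),
      model_convergence = purrr::map_lgl(models, "converged")
    )
    attr(out, "manifest") <- manifest
    attr(out, "weights") <- cal
    attr(out, "models") <- models

    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      readr::write_csv(out, file.path(config$out_dir, "estimates.csv"),
                       progress = FALSE)
      jsonlite::write_json(manifest,
                           file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    out
  }, error = function(e) {
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)),
          class = "ethnosae_pipeline_error", parent = e)
  })
  result
}

#' Joint parametric-bootstrap MSE for all four indicators
#'
#' Like [bootstrap_mse()], but simulates the three modelled outcomes in each
#' replicate, refits all three models, and derives the need-satisfied
#' replicate truth (`sum(y_modern) / (sum(y_any) + sum(y_unmet))` on the
#' census bootstrap outcomes) and replicate estimate, so the derived fourth
#' indicator gets an MSE on the same footing as the modelled three.
#'
#' @inheritParams bootstrap_mse
#' @param models Named list of the three converged `fp_fit` objects.
#' @param aggregation Need-satisfied aggregation rule (see
#'   [benchmarked_domain_estimates()]).
#' @return A tibble `indicator`, `ethnic_group`, `state`, `mse`,
#'   `B_effective`.
#' @export
bootstrap_mse_joint <- function(models, survey, census, B = 200, seed = 1,
                                codebook = fp_codebook(), nagq = 0,
                                aggregation = "mean_of_ratios",
                                benchmark = FALSE, levels = NULL) {
  stopifnot(all(fp_indicators() %in% names(models)))
  if (B < 2) abort("B must be at least 2")
  Xs <- design_matrix(survey, codebook)
  Xc <- design_matrix(census, codebook)
  key_s <- domain_key(survey)
  key_c <- domain_key(census)
  doms <- sort(unique(c(key_s, key_c)))
  doms_out <- sort(unique(key_c))
  eta_s <- purrr::map(models[fp_indicators()],
                      function(m) drop(Xs %*% m$beta))
  eta_c <- purrr::map(models[fp_indicators()],
                      function(m) drop(Xc %*% m$beta))

  acc <- purrr::map(setNames(fp_all_indicators(), fp_all_indicators()),
                    function(i) matrix(NA_real_, B, length(doms_out),
                                       dimnames = list(NULL, doms_out)))
  ok <- logical(B)
  boot_survey <- survey
  for (b in seq_len(B)) {
    set.seed(seed + b)
    y_s <- list()
    y_c <- list()
    for (ind in fp_indicators()) {
      v_star <- setNames(rnorm(length(doms), 0, models[[ind]]$sigma_v), doms)
      y_s[[ind]] <- rbinom(nrow(survey), 1,
                           plogis(eta_s[[ind]] + v_star[key_s]))
      y_c[[ind]] <- rbinom(nrow(census), 1,
                           plogis(eta_c[[ind]] + v_star[key_c]))
    }
    boot_survey$y_use_any <- y_s$use_any
    boot_survey$y_use_modern <- y_s$use_modern
    boot_survey$y_unmet <- y_s$unmet

    fits_b <- purrr::map(
      setNames(fp_indicators(), fp_indicators()),
      function(ind) tryCatch(
        fit_glmm(boot_survey, ind, codebook, nagq = nagq,
                 check_separation = FALSE),
        error = function(e) NULL))
    if (any(purrr::map_lgl(fits_b, is.null)) ||
        !all(purrr::map_lgl(fits_b, "converged"))) next

    preds_b <- purrr::map(fits_b, function(f) {
      predict_individual(f, census, codebook)$p
    })
    ns_b <- suppressWarnings(
      need_satisfied(preds_b$use_modern, preds_b$use_any, preds_b$unmet))

    truth <- list(
      use_any = tapply(y_c$use_any, key_c, mean),
      use_modern = tapply(y_c$use_modern, key_c, mean),
      unmet = tapply(y_c$unmet, key_c, mean),
      need_satisfied = tapply(y_c$use_modern, key_c, sum) /
        (tapply(y_c$use_any, key_c, sum) + tapply(y_c$unmet, key_c, sum))
    )
    wts <- purrr::map(setNames(fp_all_indicators(), fp_all_indicators()),
                      function(i) rep(1, nrow(census)))
    if (benchmark) {
      lv <- levels %||% default_levels(boot_survey)
      pcols <- c(fp_indicators(), "need_satisfied")
      pvals <- c(preds_b, list(need_satisfied = ns_b))
      names(pvals) <- pcols
      for (ind in pcols) {
        D <- direct_estimates(boot_survey, ind, lv)
        D <- D[!is.na(D$D), ]
        cal_b <- suppressWarnings(calibrate_weights(
          tibble(p = pvals[[ind]], state = census$state,
                 urbanicity = as.character(census$urbanicity),
                 id = census$id),
          D[, c("level", "D")]))
        wts[[ind]] <- cal_b$weights$weight
      }
    }
    wmean <- function(x, w) tapply(w * x, key_c, sum) / tapply(w, key_c, sum)
    est <- list(
      use_any = wmean(preds_b$use_any, wts$use_any),
      use_modern = wmean(preds_b$use_modern, wts$use_modern),
      unmet = wmean(preds_b$unmet, wts$unmet),
      need_satisfied = if (aggregation == "mean_of_ratios") {
        wmean(ns_b, wts$need_satisfied)
      } else {
        w <- wts$need_satisfied
        (tapply(w * preds_b$use_modern, key_c, sum)) /
          (tapply(w * (preds_b$use_any + preds_b$unmet), key_c, sum))
      }
    )
    for (ind in fp_all_indicators()) {
      acc[[ind]][b, doms_out] <-
        (est[[ind]][doms_out] - truth[[ind]][doms_out])^2
    }
    ok[b] <- TRUE
  }
  B_eff <- sum(ok)
  if (B_eff < B / 2) {
    abort(sprintf("only %d of %d bootstrap replicates converged", B_eff, B))
  }
  purrr::imap_dfr(acc, function(a, ind) {
    tibble(indicator = ind,
           ethnic_group = sub("\\|.*", "", doms_out),
           state = as.integer(sub(".*\\|", "", doms_out)),
           mse = unname(colMeans(a[ok, , drop = FALSE])),
           B_effective = B_eff)
  })
}
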