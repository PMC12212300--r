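# Shared fixtures, built in code and cached for the test run.

.fixture_env <- new.env(parent = emptyenv())

# Desk-scale study conditions: 6 states x 3 ethnic groups, 2,000 census rows
# per state, 25% stratified sampling, reference-model truth.
fixture_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_fp_data(fp_truth(n_states = 6),
                                         fraction = 0.25, seed = 101)
  }
  .fixture_env$sim
}

fixture_fits <- function() {
  if (is.null(.fixture_env$fits)) {
    sim <- fixture_sim()
    .fixture_env$fits <- purrr::map(
      setNames(c("use_any", "use_modern", "unmet"),
               c("use_any", "use_modern", "unmet")),
      function(ind) fit_glmm(sim$survey, ind, nagq = 0))
  }
  .fixture_env$fits
}

fixture_predictions <- function() {
  if (is.null(.fixture_env$preds)) {
    .fixture_env$preds <- suppressWarnings(
      predict_indicators(fixture_fits(), fixture_sim()$census))
  }
  .fixture_env$preds
}

# One or more rows at the reference profile of every categorical variable;
# override fields via ...
toy_women <- function(n = 1, source = c("survey", "census"), ...) {
  source <- match.arg(source)
  base <- tibble::tibble(
    id = sprintf("t%03d", seq_len(n)),
    state = 1L, ethnic_group = "nonethnic", urbanicity = "urban",
    age_group = "45-49", in_union = 1L, is_mother = 0L, education = "none",
    not_attending_school = 0L, working = 0L, poor_walls = 0L,
    house_or_apartment = 0L, electricity = 0L, internet = 0L,
    partner_same_ethnic = 0L)
  if (source == "survey") {
    base <- dplyr::mutate(base, weight = 1, y_use_any = 0L,
                          y_use_modern = 0L, y_unmet = 0L)
  }
  dplyr::mutate(base, ...)
}

# Random valid microdata rows for property-style checks
random_women <- function(n, seed, source = "survey") {
  set.seed(seed)
  cb <- fp_codebook()
  out <- toy_women(n, source = source)
  out$state <- sample(1:4, n, replace = TRUE)
  out$ethnic_group <- sample(cb$ethnic_levels, n, replace = TRUE)
  out$urbanicity <- sample(cb$urbanicity_levels, n, replace = TRUE)
  out$age_group <- sample(cb$age_levels, n, replace = TRUE)
  out$education <- sample(cb$education_levels, n, replace = TRUE)
  for (v in cb$binary_vars) out[[v]] <- sample(0:1, n, replace = TRUE)
  if (source == "survey") {
    out$weight <- stats::runif(n, 0.5, 4)
    out$y_use_any <- sample(0:1, n, replace = TRUE)
    out$y_use_modern <- as.integer(out$y_use_any *
                                     sample(0:1, n, replace = TRUE))
    out$y_unmet <- as.integer((1L - out$y_use_any) *
                                sample(0:1, n, replace = TRUE))
  }
  out
}
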