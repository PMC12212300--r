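test_that("degenerate truth parameters behave as specified", {
  truth <- fp_truth(n_states = 2, rows_per_state = 100)
  # all-zero domain sizes: empty population, no error
  truth0 <- fp_truth(n_states = 2, rows_per_state = 100,
                     domain_sizes = dplyr::mutate(
                       default_domain_sizes(2, 100), n = 0L))
  gen0 <- generate_population(truth0, seed = 1)
  expect_equal(nrow(gen0$population), 0)
  # empty domain table errors
  expect_error(generate_population(
    fp_truth(domain_sizes = default_domain_sizes(2, 100)[0, ]), seed = 1),
    class = "ethnosae_validation_error")
  # sigma_v = 0: every drawn random intercept is exactly 0
  truth_s0 <- fp_truth(n_states = 2, rows_per_state = 100,
                       sigma_v = c(use_any = 0, use_modern = 0, unmet = 0))
  gen <- generate_population(truth_s0, seed = 1)
  expect_true(all(gen$v_draws$v == 0))
})

test_that("empirical covariate frequencies match the target distributions", {
  sizes <- default_domain_sizes(3, 2000)
  truth <- fp_truth(n_states = 3, rows_per_state = 2000,
                    domain_sizes = sizes)
  gen <- generate_population(truth, seed = 7)
  pop <- gen$population
  # within each ethnic x urbanicity cell, observed frequencies within 3
  # binomial SDs of the target
  checks <- truth$covariate_dists |>
    dplyr::filter(variable %in% c("education", "internet", "age_group"))
  for (i in seq_len(nrow(checks))) {
    row <- checks[i, ]
    cell <- pop[pop$ethnic_group == row$ethnic_group &
                  pop$urbanicity == row$urbanicity, ]
    n <- nrow(cell)
    obs <- mean(as.character(cell[[row$variable]]) == row$category)
    se <- sqrt(row$prob * (1 - row$prob) / n)
    expect_lt(abs(obs - row$prob), max(3 * se, 3 / n))
  }
})

test_that("null coefficients give 50% outcome rates and a saturating intercept gives none", {
  cb <- fp_codebook()
  beta0 <- reference_coefficients() |>
    dplyr::mutate(dplyr::across(c("use_any", "use_modern", "unmet"), ~0))
  truth0 <- fp_truth(n_states = 3, rows_per_state = 1200, beta = beta0,
                     sigma_v = c(use_any = 0, use_modern = 0, unmet = 0))
  sim0 <- simulate_fp_data(truth0, seed = 5)
  n <- nrow(sim0$population)
  se3 <- 3 * sqrt(0.25 / n)
  expect_lt(abs(mean(sim0$population$y_use_any) - 0.5), se3)

  sat <- reference_coefficients() |>
    dplyr::mutate(dplyr::across(c("use_any", "use_modern", "unmet"),
                                ~ ifelse(dplyr::row_number() == 1, -20, 0)))
  simsat <- simulate_fp_data(
    fp_truth(n_states = 2, rows_per_state = 500, beta = sat,
             sigma_v = c(use_any = 0, use_modern = 0, unmet = 0)),
    seed = 5)
  expect_equal(sum(simsat$population$y_use_any), 0)
  expect_equal(sum(simsat$population$y_use_modern), 0)
  expect_equal(sum(simsat$population$y_unmet), 0)
})

test_that("generated outcomes always satisfy the data-model invariants", {
  sim <- fixture_sim()
  pop <- sim$population
  expect_true(all(pop$y_use_modern <= pop$y_use_any))
  expect_true(all(pop$y_unmet + pop$y_use_any <= 1))
  expect_silent(validate_microdata(sim$survey, "survey"))
  expect_silent(validate_microdata(sim$census, "census"))
})

test_that("the same seed reproduces population and survey exactly", {
  truth <- fp_truth(n_states = 2, rows_per_state = 300)
  a <- simulate_fp_data(truth, fraction = 0.5, seed = 33)
  b <- simulate_fp_data(truth, fraction = 0.5, seed = 33)
  expect_identical(a$population, b$population)
  expect_identical(a$survey, b$survey)
  expect_identical(a$v_draws, b$v_draws)
})

test_that("survey weights are inverse inclusion probabilities", {
  sim <- fixture_sim()
  pop <- sim$population
  # fraction 1 everywhere: the survey is the population with unit weights
  full <- draw_survey(pop[pop$state == 1, ], fraction = 1, seed = 2)
  expect_equal(nrow(full), sum(pop$state == 1))
  expect_true(all(full$weight == 1))
  # fraction 0.5 in a single stratum: weights 2 there
  one <- pop[pop$state == 2 & pop$urbanicity == "urban", ]
  half <- draw_survey(one, fraction = 0.5, seed = 2)
  expect_equal(unique(half$weight), nrow(one) / nrow(half))
  expect_equal(unique(half$weight), 2, tolerance = 0.01)
  expect_error(draw_survey(one, fraction = 0),
               class = "ethnosae_validation_error")
})

test_that("the Hajek weighted mean is design-unbiased over repeated draws", {
  truth <- fp_truth(n_states = 2, rows_per_state = 400)
  sim <- simulate_fp_data(truth, seed = 17)
  pop <- sim$population
  mu <- mean(pop$y_use_any)
  # unequal fractions by urbanicity to make the weighting informative
  fr <- dplyr::distinct(pop, state, urbanicity) |>
    dplyr::mutate(fraction = ifelse(urbanicity == "rural", 0.4, 0.15))
  est <- vapply(1:200, function(s) {
    sv <- draw_survey(pop, fr, seed = 1000 + s)
    sum(sv$weight * sv$y_use_any) / sum(sv$weight)
  }, numeric(1))
  se_mc <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - mu), 4 * se_mc)
})
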