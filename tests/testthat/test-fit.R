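test_that("under null truth the fit finds neither effects nor clustering", {
  beta0 <- reference_coefficients() |>
    dplyr::mutate(dplyr::across(c("use_any", "use_modern", "unmet"), ~0))
  truth <- fp_truth(n_states = 6, rows_per_state = 3400, beta = beta0,
                    sigma_v = c(use_any = 0, use_modern = 0, unmet = 0))
  sim <- simulate_fp_data(truth, fraction = 1, seed = 23)
  fit <- fit_glmm(sim$survey, "use_any", nagq = 0)
  expect_true(all(abs(fit$beta) < 3 * fit$se))
  expect_lt(fit$sigma_v, 0.05)
})

test_that("single-domain data reduce to plain logistic regression", {
  set.seed(4)
  w <- random_women(2000, seed = 4)
  w$state <- 1L
  w$ethnic_group <- "nonethnic"
  # outcomes from a simple logistic law over a few covariates
  X <- design_matrix(w)
  eta <- -0.4 + 0.8 * X[, "is_mother"] + 0.5 * X[, "internet"] -
    0.6 * X[, "working"]
  w$y_use_any <- rbinom(2000, 1, plogis(eta))
  w$y_use_modern <- pmin(w$y_use_modern, w$y_use_any)
  w$y_unmet <- as.integer(w$y_unmet * (1 - w$y_use_any))

  fit <- fit_glmm(w, "use_any", nagq = 1, check_separation = FALSE)
  # independent IRLS oracle: unpenalized glm on the same design
  df <- as.data.frame(X[, -1])
  df$y <- w$y_use_any
  oracle <- stats::glm(y ~ ., data = df, family = stats::binomial())
  expect_lt(fit$sigma_v, 1e-4)
  # single-domain all-nonethnic data make the ethnicity columns all-zero;
  # both routes drop them, compare the identified coefficients
  bo <- stats::coef(oracle)
  keep <- !is.na(bo)
  expect_equal(unname(fit$beta[c(TRUE, keep[-1])]), unname(bo[keep]),
               tolerance = 1e-4)
  expect_identical(fit$dropped_terms,
                   c("ethnic_minority", "ethnic_minority_x_partner"))
})

test_that("complete separation is detected and named", {
  w <- random_women(200, seed = 11)
  w$y_use_any <- w$internet  # internet perfectly predicts the outcome
  w$y_use_modern <- pmin(w$y_use_modern, w$y_use_any)
  w$y_unmet <- as.integer(w$y_unmet * (1 - w$y_use_any))
  expect_error(fit_glmm(w, "use_any"), regexp = "internet",
               class = "ethnosae_separation_error")
})

test_that("icc follows the latent-scale closed form and is monotone", {
  expect_equal(icc(0), 0)
  expect_equal(icc(pi / sqrt(3)), 0.5)
  expect_equal(icc(0.3), 0.09 / (0.09 + pi^2 / 3))
  expect_equal(icc(0.3), 0.0266, tolerance = 5e-3)
  sigmas <- seq(0, 2, by = 0.1)
  expect_true(all(diff(icc(sigmas)) > 0))
  expect_error(icc(-1))
})

test_that("odds ratios are the elementwise exponential with log as inverse", {
  or <- odds_ratios(c(age13_14 = 1.955, age15_19 = 0.815, zero = 0))
  expect_equal(or$or, c(7.063, 2.259, 1), tolerance = 0.01 / 7)
  fit <- fixture_fits()$use_any
  tab <- odds_ratios(fit)
  expect_equal(log(tab$or), unname(fit$beta), tolerance = 1e-12)
})

test_that("combined odds ratios are exponentials of coefficient sums", {
  b <- c(partner = 0.213, minority = -0.008, interaction = -0.304)
  expect_equal(combined_or(b, c("minority", "interaction")), exp(-0.312))
  expect_error(combined_or(b, "nope"), regexp = "nope")
})

test_that("model log-likelihood at the optimum beats the null model", {
  fit <- fixture_fits()$use_any
  y <- fixture_sim()$survey$y_use_any
  # null: beta = 0, sigma_v = 0, so p = 1/2 for everyone
  loglik_null <- length(y) * log(0.5)
  expect_gt(fit$loglik, loglik_null)
})

test_that("confusion metrics follow the printed formulas and handle empty classes", {
  perfect <- confusion_metrics(5, 5, 0, 0)
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1,
                                  specificity = 1, sensitivity = 1))
  m <- confusion_metrics(2, 3, 1, 1)
  expect_equal(m$accuracy, 5 / 7)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$specificity, 3 / 4)
  expect_equal(m$sensitivity, 2 / 3)
  none_pos <- confusion_metrics(0, 10, 0, 0)
  expect_true(is.na(none_pos$precision))
  expect_true(is.na(none_pos$sensitivity))
  expect_equal(none_pos$accuracy, 1)
})

test_that("in-sample classification counts match a brute-force confusion oracle", {
  sim <- fixture_sim()
  survey <- sim$survey[1:500, ]
  fit <- fit_glmm(survey, "use_any", nagq = 0, check_separation = FALSE)
  got <- classification_metrics(fit, survey, threshold = 0.5)
  p <- plogis(drop(design_matrix(survey) %*% fit$beta) +
                ifelse(is.na(fit$v_hat[domain_key(survey)]), 0,
                       fit$v_hat[domain_key(survey)]))
  yhat <- as.integer(p >= 0.5)
  y <- survey$y_use_any
  expect_equal(got$p11, sum(yhat & y))
  expect_equal(got$p00, sum(!yhat & !y))
  expect_equal(got$p01, sum(yhat & !y))
  expect_equal(got$p10, sum(!yhat & y))
  expect_error(classification_metrics(fit, survey, threshold = 1))
})

test_that("tidy and glance summarise the fit consistently", {
  fit <- fixture_fits()$use_modern
  td <- tidy(fit)
  expect_identical(td$term, fp_codebook()$terms)
  expect_equal(td$odds.ratio, exp(td$estimate))
  gl <- glance(fit)
  expect_equal(gl$icc, icc(fit))
  expect_equal(gl$n_obs, nrow(fixture_sim()$survey))
})

test_that("fitted-model JSON serialization round-trips the key fields", {
  fit <- fixture_fits()$unmet
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$sigma_v, fit$sigma_v)
  expect_equal(unlist(back$beta), fit$beta, tolerance = 1e-12)
  expect_true(all(grepl("\\|", names(back$v_hat))))
})
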