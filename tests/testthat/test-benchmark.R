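test_that("direct estimates are Hajek weighted means per level", {
  sv <- toy_women(4, weight = 1,
                  y_use_any = c(1L, 0L, 1L, 1L),
                  y_use_modern = c(1L, 0L, 0L, 1L),
                  state = c(1L, 1L, 2L, 2L))
  D <- direct_estimates(sv, "use_any", c("state:1", "state:2", "national"))
  expect_equal(D$D, c(0.5, 1, 0.75))
  # doubling one weight equals duplicating that row
  sv2 <- sv
  sv2$weight[1] <- 2
  dup <- dplyr::bind_rows(sv, sv[1, ])
  expect_equal(direct_estimates(sv2, "use_any", "national")$D,
               direct_estimates(dup, "use_any", "national")$D)
})

test_that("direct estimates match an independent weighted-mean oracle", {
  sv <- random_women(300, seed = 21)
  lv <- default_levels(sv)
  D <- direct_estimates(sv, "use_modern", lv)
  for (j in seq_along(lv)) {
    m <- level_membership(sv, lv[j])
    expect_equal(D$D[j],
                 weighted.mean(sv$y_use_modern[m], sv$weight[m]),
                 tolerance = 1e-12)
  }
  # need satisfied is the weighted demand-satisfaction ratio
  Dns <- direct_estimates(sv, "need_satisfied", "national")
  expect_equal(Dns$D,
               sum(sv$weight * sv$y_use_modern) /
                 sum(sv$weight * (sv$y_use_any + sv$y_unmet)),
               tolerance = 1e-12)
})

test_that("ratio adjustment is plain division with a zero guard", {
  expect_equal(ratio_adjust(0.3, 0.3), 1)
  expect_equal(ratio_adjust(0.2, 0.4), 0.5)
  set.seed(8)
  D <- runif(20)
  Y <- runif(20, 0.1, 1)
  expect_identical(ratio_adjust(D, Y), D / Y)
  expect_error(ratio_adjust(0.2, 0), class = "ethnosae_undefined_error")
})

test_that("already-satisfied constraints return unit weights immediately", {
  preds <- tibble::tibble(p = c(0.2, 0.4, 0.6, 0.8),
                          state = c(1L, 1L, 2L, 2L),
                          urbanicity = "urban",
                          id = as.character(1:4))
  sol <- calibrate_weights(preds,
                           tibble::tibble(level = "national", D = 0.5))
  expect_true(sol$converged)
  expect_equal(sol$iterations, 1L)
  expect_equal(sol$weights$weight, rep(1, 4))
  # zero constraints: identity
  sol0 <- calibrate_weights(preds, tibble::tibble(level = character(0),
                                                  D = numeric(0)))
  expect_true(sol0$converged)
  expect_equal(sol0$weights$weight, rep(1, 4))
})

test_that("a single constraint reproduces the closed-form chi-square tilt", {
  set.seed(13)
  preds <- tibble::tibble(p = runif(50, 0.2, 0.8), state = 1L,
                          urbanicity = "rural",
                          id = as.character(1:50))
  D <- 0.45
  sol <- calibrate_weights(preds, tibble::tibble(level = "national", D = D))
  expect_true(sol$converged)
  expect_lt(max(abs(sol$residuals$residual)), 1e-8)
  # Lagrange solution of min sum (w-1)^2 s.t. sum w (p - D) = 0
  r <- preds$p - D
  w_closed <- 1 - (sum(r) / sum(r^2)) * r
  expect_equal(sol$weights$weight, w_closed, tolerance = 1e-6)
})

test_that("the overlapping state/rural/urban/national system rakes to convergence", {
  sim <- fixture_sim()
  preds <- fixture_predictions()
  D <- direct_estimates(sim$survey, "use_any")
  sol <- calibrate_weights(
    tibble::tibble(p = preds$p_use_any, state = preds$state,
                   urbanicity = preds$urbanicity, id = preds$id),
    D[, c("level", "D")])
  expect_true(sol$converged)
  expect_lt(max(abs(sol$residuals$residual)), 1e-6)
  expect_true(all(sol$weights$weight > 0))
  expect_true(all(sol$weights$weight >= 0.2 & sol$weights$weight <= 5))
  expect_lt(sol$iterations, 1000)

  # self-consistency: recomputing every constraint reproduces D_j
  w <- sol$weights$weight
  for (j in seq_len(nrow(D))) {
    m <- level_membership(preds, D$level[j])
    expect_equal(sum(w[m] * preds$p_use_any[m]) / sum(w[m]), D$D[j],
                 tolerance = 1e-6)
  }
})

test_that("infeasible targets are reported, never silently absorbed", {
  preds <- tibble::tibble(p = runif(30, 0.4, 0.6), state = 1L,
                          urbanicity = "urban", id = as.character(1:30))
  warnings <- testthat::capture_warnings(
    sol <- calibrate_weights(preds,
                             tibble::tibble(level = "national", D = 0.95),
                             max_iter = 50))
  expect_match(warnings, "infeasible|converge", all = FALSE)
  expect_false(sol$converged)
  expect_gt(max(abs(sol$residuals$residual)), 1e-6)
})

test_that("benchmarked domain estimates are weighted means with expected identities", {
  preds <- fixture_predictions()
  # unit weights equal the plain domain mean
  plain <- benchmarked_domain_estimates(preds, NULL, "use_any")
  oracle <- dplyr::summarise(preds, estimate = mean(p_use_any),
                             .by = c("ethnic_group", "state")) |>
    dplyr::arrange(ethnic_group, state)
  expect_equal(plain$estimate, oracle$estimate, tolerance = 1e-12)

  sim <- fixture_sim()
  D <- direct_estimates(sim$survey, "use_any", "national")
  sol <- calibrate_weights(
    tibble::tibble(p = preds$p_use_any, state = preds$state,
                   urbanicity = preds$urbanicity, id = preds$id),
    D[, c("level", "D")])
  est <- benchmarked_domain_estimates(preds, sol, "use_any")
  w <- sol$weights$weight
  # the national aggregate reproduces the direct estimate by construction
  expect_equal(sum(w * preds$p_use_any) / sum(w), D$D, tolerance = 1e-8)
  # per-domain values agree with a brute-force weighted mean
  for (i in sample(nrow(est), 5)) {
    m <- preds$ethnic_group == est$ethnic_group[i] &
      preds$state == est$state[i]
    expect_equal(est$estimate[i],
                 sum(w[m] * preds$p_use_any[m]) / sum(w[m]),
                 tolerance = 1e-12)
  }
  # Hajek estimates are invariant to rescaling all weights
  est2 <- benchmarked_domain_estimates(preds, w * 7.3, "use_any")
  expect_equal(est$estimate, est2$estimate, tolerance = 1e-12)
})

test_that("state-level estimates aggregate to the national under common weights", {
  preds <- fixture_predictions()
  sim <- fixture_sim()
  D <- direct_estimates(sim$survey, "use_modern")
  sol <- calibrate_weights(
    tibble::tibble(p = preds$p_use_modern, state = preds$state,
                   urbanicity = preds$urbanicity, id = preds$id),
    D[, c("level", "D")])
  w <- sol$weights$weight
  by_state <- vapply(sort(unique(preds$state)), function(s) {
    m <- preds$state == s
    sum(w[m] * preds$p_use_modern[m]) / sum(w[m])
  }, numeric(1))
  state_wsum <- vapply(sort(unique(preds$state)),
                       function(s) sum(w[preds$state == s]), numeric(1))
  national <- sum(w * preds$p_use_modern) / sum(w)
  expect_equal(sum(by_state * state_wsum) / sum(state_wsum), national,
               tolerance = 1e-12)
})
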