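test_that("binary eligibility needs more than five zero pairs", {
  expect_true(check_binary_eligibility(
    pairwise_jaccard(simulate_margin_matrix(45, 11))))
  expect_false(check_binary_eligibility(
    pairwise_jaccard(simulate_margin_matrix(55, 3))))
  # boundary: six zeros qualifies, five does not
  expect_true(check_binary_eligibility(
    pairwise_jaccard(simulate_margin_matrix(15, 6))))
  expect_false(check_binary_eligibility(
    pairwise_jaccard(simulate_margin_matrix(15, 5))))
})

test_that("the logistic slope matches a Newton-Raphson oracle to high precision", {
  set.seed(42)
  n <- 300
  d <- runif(n)
  y <- rbinom(n, 1, plogis(1 - 2.5 * d))
  pairs <- manual_pair_table(ji = ifelse(y == 1, 0.5, 0))
  dissim <- manual_dissim(pairs, d)
  res <- fit_binary(pairs, dissim, "all_traits")
  want <- oracle_irls_logistic(d, y)
  expect_equal(res$estimate, want$coef[2], tolerance = 1e-8)
  expect_equal(res$std_error, want$se[2], tolerance = 1e-6)
  expect_equal(res$statistic, want$z[2], tolerance = 1e-6)
  expect_equal(res$statistic, res$estimate / res$std_error, tolerance = 1e-9)
  expect_true(res$converged)
  expect_equal(res$n_obs, n)
})

test_that("a deterministic threshold outcome is reported as separation, not an error", {
  d <- seq(0.05, 0.95, length.out = 40)
  y <- as.integer(d < median(d))
  pairs <- manual_pair_table(ji = ifelse(y == 1, 0.5, 0))
  dissim <- manual_dissim(pairs, d)
  res <- fit_binary(pairs, dissim, "all_traits")
  expect_false(res$converged)
  expect_lt(res$estimate, 0)
  expect_match(res$reason, "separation")
})

test_that("an ineligible matrix yields a withheld binary record", {
  pairs <- pairwise_jaccard(simulate_margin_matrix(55, 3))
  dissim <- manual_dissim(pairs, seq_len(nrow(pairs)) / nrow(pairs))
  res <- fit_binary(pairs, dissim, "all_traits")
  expect_false(res$eligible)
  expect_true(is.na(res$estimate))
  expect_match(res$reason, "zero pairs")
})

test_that("a constant predictor is a computation error for both fits", {
  pairs <- manual_pair_table(ji = c(0, 0, 0, 0, 0, 0, 0.2, 0.4, 0.5, 0.7))
  dissim <- manual_dissim(pairs, rep(0.3, nrow(pairs)))
  expect_error(fit_binary(pairs, dissim, "all_traits"),
               class = "tc_computation_error")
  expect_error(fit_strength(pairs, dissim, "all_traits"),
               class = "tc_computation_error")
})

test_that("a noiseless log-linear relationship is recovered exactly", {
  d <- seq(0.1, 0.9, by = 0.1)
  pairs <- manual_pair_table(ji = exp(-0.1 - 3 * d))
  dissim <- manual_dissim(pairs, d)
  # summary.lm warns that a zero-residual fit is "essentially perfect"
  res <- suppressWarnings(fit_strength(pairs, dissim, "all_traits"))
  expect_equal(res$estimate, -3, tolerance = 1e-9)
  expect_lt(res$p_value, 1e-12)
  expect_equal(res$n_obs, length(d))
})

test_that("the OLS slope matches the closed-form oracle on a 3-point fixture", {
  d <- c(0.2, 0.5, 0.9)
  ji <- c(0.6, 0.35, 0.3)
  pairs <- manual_pair_table(ji = ji)
  dissim <- manual_dissim(pairs, d)
  res <- fit_strength(pairs, dissim, "all_traits")
  want <- oracle_ols(d, log(ji))
  expect_equal(res$estimate, want$slope, tolerance = 1e-12)
  expect_equal(res$std_error, want$se, tolerance = 1e-12)
  expect_equal(res$statistic, want$t, tolerance = 1e-12)
  expect_equal(res$p_value, want$p, tolerance = 1e-12)
})

test_that("strength inference is invariant to response shifts and predictor rescaling", {
  set.seed(8)
  d <- runif(30, 0.1, 0.9)
  ji <- exp(-0.5 - d + rnorm(30, sd = 0.2))
  ji <- pmin(ji, 1)
  pairs <- manual_pair_table(ji = ji)
  res <- fit_strength(pairs, manual_dissim(pairs, d), "all_traits")

  # multiplying ji by a constant shifts log(ji): intercept-only change
  pairs_scaled <- manual_pair_table(ji = ji * 0.5)
  res_shift <- fit_strength(pairs_scaled, manual_dissim(pairs_scaled, d), "all_traits")
  expect_equal(res_shift$estimate, res$estimate, tolerance = 1e-10)
  expect_equal(res_shift$std_error, res$std_error, tolerance = 1e-10)
  expect_equal(res_shift$statistic, res$statistic, tolerance = 1e-10)

  # rescaling the predictor scales the slope and SE, not t or p
  res_resc <- fit_strength(pairs, manual_dissim(pairs, 2 * d), "all_traits")
  expect_equal(res_resc$estimate, res$estimate / 2, tolerance = 1e-10)
  expect_equal(res_resc$std_error, res$std_error / 2, tolerance = 1e-10)
  expect_equal(res_resc$statistic, res$statistic, tolerance = 1e-10)
  expect_equal(res_resc$p_value, res$p_value, tolerance = 1e-10)

  # same invariances for the binary fit: z and p unchanged under rescaling
  set.seed(9)
  db <- runif(100)
  yb <- rbinom(100, 1, plogis(0.5 - db))
  pb <- manual_pair_table(ji = ifelse(yb == 1, 0.5, 0))
  resb <- fit_binary(pb, manual_dissim(pb, db), "all_traits")
  resb2 <- fit_binary(pb, manual_dissim(pb, 2 * db), "all_traits")
  expect_equal(resb2$estimate, resb$estimate / 2, tolerance = 1e-6)
  expect_equal(resb2$statistic, resb$statistic, tolerance = 1e-6)
})

test_that("too few positive pairs withholds the strength fit with a reason", {
  pairs <- manual_pair_table(ji = c(0, 0, 0, 0, 0, 0, 0, 0.4, 0.6))
  dissim <- manual_dissim(pairs, seq(0.1, 0.9, by = 0.1))
  res <- fit_strength(pairs, dissim, "all_traits")
  expect_true(is.na(res$estimate))
  expect_match(res$reason, "positive pairs")
  expect_equal(res$n_obs, 2L)
})
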