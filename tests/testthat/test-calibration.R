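test_that("robust fit recovers a noisy line and keeps a real intercept", {
  std <- make_standards(n = 11, slope = 0.5, intercept = 3, noise_sd = 0.1,
                        seed = 7)
  fit <- fit_calibration(std)
  ols <- lm(known_mass ~ response, data = std)
  se <- summary(ols)$coefficients[, "Std. Error"]
  # without gross outliers the robust fit must agree with the OLS oracle
  expect_lt(abs(fit$slope - coef(ols)[2]), 2 * se[2])
  expect_false(is.na(fit$intercept))
  expect_lt(abs(fit$intercept - coef(ols)[1]), 2 * se[1])
  expect_lt(abs(fit$slope - 0.5), 0.01)
  expect_lt(abs(fit$intercept - 3), 1)
})

test_that("a gross outlier barely moves the robust slope", {
  std <- make_standards(n = 22, slope = 2, intercept = 0, noise_sd = 0.5,
                        seed = 11)
  clean_slope <- coef(lm(known_mass ~ response, data = std))[2]
  contaminated <- std
  contaminated$known_mass[22] <- contaminated$known_mass[22] * 10
  dirty_ols <- coef(lm(known_mass ~ response, data = contaminated))[2]
  fit <- fit_calibration(contaminated)
  expect_lt(abs(fit$slope - clean_slope) / clean_slope, 0.01)
  expect_gt(abs(dirty_ols - clean_slope) / clean_slope,
            abs(fit$slope - clean_slope) / clean_slope)
})

test_that("a spurious intercept is pruned", {
  std <- make_standards(n = 11, slope = 2, intercept = 0, noise_sd = 0.05,
                        seed = 3)
  fit <- fit_calibration(std)
  # OLS oracle: intercept t-test is non-significant on this design
  ols <- summary(lm(known_mass ~ response, data = std))$coefficients
  expect_gt(ols[1, "Pr(>|t|)"], 0.05)
  expect_true(is.na(fit$intercept))
  expect_lt(abs(fit$slope - 2), 0.01)
})

test_that("slope survives perturbing any single standard by +50%", {
  std <- rbind(make_standards(n = 11, slope = 0.5, intercept = 2,
                              noise_sd = 0.3, seed = 5),
               make_standards(n = 11, slope = 0.5, intercept = 2,
                              noise_sd = 0.3, seed = 6))
  base <- fit_calibration(std)$slope
  for (i in seq_len(nrow(std))) {
    pert <- std
    pert$known_mass[i] <- pert$known_mass[i] * 1.5
    expect_lt(abs(fit_calibration(pert)$slope - base) / base, 0.05,
              label = sprintf("slope change after perturbing standard %d", i))
  }
})

test_that("degenerate standard sets are rejected", {
  std <- make_standards(n = 11, seed = 1)
  expect_error(fit_calibration(std[1:2, ]), "at least 3")
  flat <- std
  flat$response <- 100
  expect_error(fit_calibration(flat), "variance")
})

test_that("prediction interval matches the closed form at the centroid", {
  std <- make_standards(n = 11, slope = 0.5, intercept = 3, noise_sd = 0.5,
                        seed = 9)
  fit <- fit_calibration(std)
  at_centroid <- predict_mass(fit, fit$x_mean)
  expect_equal(at_centroid$sigma_m,
               fit$t_crit * fit$sigma_res * sqrt(1 + 1 / fit$n_s))
  # hand-evaluated case: n_S = 11, sigma_res = 1, s_x = 10, x - xbar = 20,
  # with the independently tabulated t quantile 1.052515 (9 df, 68% PI)
  hand <- fit
  hand$n_s <- 11L
  hand$sigma_res <- 1
  hand$s_x <- 10
  hand$x_mean <- 0
  hand$t_crit <- 1.052515
  hand$x_range <- c(-50, 50)
  expect_equal(predict_mass(hand, 20)$sigma_m,
               1.052515 * sqrt(1 + 1 / 11 + 400 / (10 * 100)),
               tolerance = 1e-6)
})

test_that("sigma_M is zero for an exact fit and grows away from the centroid", {
  std <- make_standards(n = 11, noise_sd = 0, seed = 2)
  fit <- fit_calibration(std)
  expect_equal(fit$sigma_res, 0)
  expect_equal(predict_mass(fit, c(10, 200, 400))$sigma_m, rep(0, 3))
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-9)
  expect_equal(predict_mass(fit, 100)$mass, 0.5 * 100 + 3, tolerance = 1e-9)

  noisy <- fit_calibration(make_standards(n = 11, noise_sd = 0.5, seed = 4))
  xs <- noisy$x_mean + seq(0, 300, by = 25)
  sig <- suppressWarnings(predict_mass(noisy, xs)$sigma_m)
  expect_true(all(diff(sig) > 0))
  sym <- suppressWarnings(
    predict_mass(noisy, noisy$x_mean + c(-40, 40))$sigma_m)
  expect_equal(sym[1], sym[2])
})

test_that("responses beyond the standards warn but still predict", {
  fit <- fit_calibration(make_standards(n = 11, noise_sd = 0.1, seed = 8))
  expect_warning(predict_mass(fit, fit$x_range[2] * 2), "extrapolat")
})

test_that("run stability: identical sets stable, drifted slope flagged", {
  std <- make_standards(n = 11, noise_sd = 0.2, seed = 12)
  fit1 <- fit_calibration(std, prune_intercept = FALSE)
  expect_false(detect_unstable_run(fit1, fit1))

  drifted <- make_standards(n = 11, slope = 0.5 * 1.5, intercept = 3,
                            noise_sd = 0.2, seed = 13)
  fit2 <- fit_calibration(drifted, prune_intercept = FALSE)
  fit2$run <- fit1$run
  expect_true(detect_unstable_run(fit1, fit2))

  other_run <- fit_calibration(make_standards(n = 11, run = 2L, seed = 14))
  expect_error(detect_unstable_run(fit1, other_run), "different runs")
})
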