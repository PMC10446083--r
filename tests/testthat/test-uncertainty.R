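test_that("scaled duplicate differences follow the sqrt-2 convention", {
  same <- scaled_difference(10, 10)
  expect_equal(same$delta, 0)
  expect_equal(same$delta_r, 0)
  pair <- scaled_difference(12, 10)
  expect_equal(pair$delta, sqrt(2), tolerance = 1e-12)
  expect_equal(pair$delta_r, sqrt(2) / 11, tolerance = 1e-12)
  expect_true(is.na(scaled_difference(5, -5)$delta_r))
})

test_that("relative differences are scale-free", {
  set.seed(17)
  d1 <- runif(50, 1, 40)
  d2 <- d1 * (1 + rnorm(50, 0, 0.2))
  base <- scaled_difference(d1, d2)$delta_r
  for (c_scale in c(0.01, 3, 1e4)) {
    expect_equal(scaled_difference(c_scale * d1, c_scale * d2)$delta_r, base,
                 tolerance = 1e-12)
  }
})

test_that("robust SD matches a brute-force percentile oracle", {
  expect_equal(robust_sd(rep(4.2, 10)), 0)
  expect_equal(robust_sd(1:10), robust_sd_oracle(1:10))
  expect_equal(robust_sd(1:10), (8.56 - 2.44) / 2)  # hand interpolation
  set.seed(23)
  for (i in 1:100) {
    v <- rnorm(sample(5:60, 1), sd = runif(1, 0.1, 10))
    expect_equal(robust_sd(v), robust_sd_oracle(v), tolerance = 1e-12)
  }
  expect_error(robust_sd(3), "at least 2")
})

test_that("robust SD of a standard normal sample is near z(0.84)", {
  set.seed(29)
  n <- 1e6
  est <- robust_sd(rnorm(n))
  # Monte-Carlo SE of the interpercentile estimator from the asymptotic
  # quantile variance: sd(P_p) ~ sqrt(p(1-p)/n)/phi(z_p)
  se_q <- sqrt(0.84 * 0.16 / n) / dnorm(qnorm(0.84))
  se_est <- se_q / sqrt(2) # two nearly independent quantiles, halved range
  expect_lt(abs(est - qnorm(0.84)), 3 * se_est)
})

test_that("sigma_r estimation recovers known duplicate noise", {
  set.seed(41)
  truth <- 0.12
  c_true <- runif(500, 2, 40)
  pairs <- data.frame(
    d1 = c_true * (1 + rnorm(500, 0, truth)),
    d2 = c_true * (1 + rnorm(500, 0, truth)),
    zone = "productive"
  )
  est <- estimate_sigma_r(pairs)
  expect_lt(abs(est$sigma_r[["productive"]] - truth), 0.015)
  # identical duplicates: zero spread
  same <- data.frame(d1 = c_true, d2 = c_true, zone = "productive")
  expect_equal(unname(estimate_sigma_r(same)$sigma_r), 0)
})

test_that("sigma_r excludes flagged pairs and non-positive means", {
  pairs <- data.frame(
    d1 = c(10, 12, 9, 11, 100, 2, -4),
    d2 = c(11, 10, 10, 12, 500, -2, 2),
    zone = "productive",
    excluded = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  )
  expect_warning(est <- estimate_sigma_r(pairs), "non-positive")
  clean <- suppressWarnings(estimate_sigma_r(pairs[1:4, ]))
  expect_equal(est$sigma_r, clean$sigma_r)
  expect_error(suppressWarnings(
    estimate_sigma_r(data.frame(d1 = 1, d2 = 1.2, zone = "productive"))),
    "fewer than 2")
})

test_that("experimental sigma scales linearly with concentration", {
  expect_equal(sigma_c_experimental(10, 0.12), 1.2)
  expect_equal(sigma_c_experimental(7, 0.35), 2.45)
  expect_equal(sigma_c_experimental(0, 0.35), 0)
  expect_error(sigma_c_experimental(10, -0.1), "sigma_r")
})

test_that("volume errors add in quadrature and propagate to concentration", {
  expect_equal(volume_uncertainty(1), 0.010)
  expect_equal(volume_uncertainty(4), 0.020)
  expect_equal(sigma_c_volume(47, 4, 0.020), 47 * 0.020 / 16)
  expect_equal(sigma_c_volume(47, 4, volume_uncertainty(4, 0)), 0)
  expect_error(sigma_c_volume(47, 0, 0.02), "positive")
})

test_that("calibration uncertainty handles correlation limits", {
  expect_equal(calibration_uncertainty(2, 2, 1, 4), 0)
  expect_equal(calibration_uncertainty(3, 4, 0, 2), sqrt(9 + 16) / 2)
  expect_equal(calibration_uncertainty(2, 2, 0.5, 4), 0.5)  # sqrt(4)/4
  # symmetric in the two mass uncertainties
  expect_equal(calibration_uncertainty(1.3, 2.9, 0.4, 3),
               calibration_uncertainty(2.9, 1.3, 0.4, 3))
  expect_error(calibration_uncertainty(2, 2, 1.2, 4), "r")
})

test_that("contamination uncertainty uses the blank SEM and scales as 1/V", {
  blanks <- blank_set(c(2, 2, 2), acidified_masses = c(3, 4, 5),
                      nonacidified_masses = c(3, 3, 3))
  expect_equal(blanks$sigma_eta, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(contamination_uncertainty(blanks, 4), sqrt(2) / sqrt(3) / 4,
               tolerance = 1e-12)
  expect_equal(contamination_uncertainty(blanks, 8),
               contamination_uncertainty(blanks, 4) / 2)
  same <- blank_set(c(2, 2, 2), c(4, 4, 4), c(3, 3, 3))
  expect_equal(contamination_uncertainty(same, 4), 0)
})

test_that("mass correlation is clamped and needs enough pairs", {
  u <- c(10, 20, 30, 40)
  expect_equal(estimate_mass_correlation(u, 0.2 * u), 1)
  expect_equal(estimate_mass_correlation(c(1, 2, 3), c(3, 2, 1)), -1)
  set.seed(3)
  r <- estimate_mass_correlation(rnorm(1000), rnorm(1000))
  expect_lt(abs(r), 3 / sqrt(1000))
  expect_error(estimate_mass_correlation(c(1, 2), c(1, 2)), "at least 3")
  expect_equal(estimate_mass_correlation(c(1, 1, 1), c(1, 2, 3)), 0)
})

test_that("budget shares and unquantified remainders are consistent", {
  b <- assemble_budget(2, 0.5, 0.5, 0.5)
  expect_equal(b$u_v, 0.25)
  b2 <- assemble_budget(1, 0.03, 0.2, 0.03)
  expect_equal(b2$unquantified_linear, 0.74)
  b3 <- assemble_budget(1, 0, 0, 0)
  expect_equal(b3$unquantified_linear, 1)
  expect_equal(b3$unquantified_variance, 1)
  # undefined budgets are flagged, not dropped
  b4 <- assemble_budget(c(2, 0), c(0.5, 0.1), c(0.5, 0.1), c(0.5, 0.1))
  expect_false(b4$budget_defined[2])
  expect_true(is.na(b4$u_v[2]))
  # variance convention never goes negative
  b5 <- assemble_budget(1, 0.9, 0.9, 0.9)
  expect_equal(b5$unquantified_variance, 0)
})
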