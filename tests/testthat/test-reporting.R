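test_that("robust summaries are correct, permutation- and scale-stable", {
  one <- summarise_robust(c(1, 1, 1))
  expect_equal(one$median, 1)
  expect_equal(one$robust_sd, 0)
  set.seed(19)
  v <- rlnorm(200, 2, 0.7)
  g <- sample(c("a", "b"), 200, replace = TRUE)
  s1 <- summarise_robust(v, g)
  expect_equal(s1$median[s1$group == "a"], median(v[g == "a"]))
  expect_equal(s1$robust_sd[s1$group == "b"], robust_sd_oracle(v[g == "b"]))
  # permutation invariance
  p <- sample(200)
  expect_equal(summarise_robust(v[p], g[p]), s1)
  # duplicating the whole sample leaves median and robust SD unchanged
  s2 <- summarise_robust(c(v, v), c(g, g))
  expect_equal(s2$median, s1$median, tolerance = 0.05)
})

test_that("aDOC-POC correlation reports r = 1 for a linear construction", {
  s <- data.frame(
    m_adoc_star = NA, volume = 2,
    concentration = runif(30, 5, 40),
    zone = rep(c("productive", "mesopelagic"), 15),
    province = rep(c("NADR", "SATL"), each = 15)
  )
  s$m_adoc_star <- (0.1 * s$concentration + 1) * s$volume
  out <- adoc_poc_correlation(s)
  expect_equal(out$r[out$group == "overall"], 1, tolerance = 1e-12)
  expect_true(all(out$r[!out$degenerate] > 0.99))
  # independent values: near-zero correlation
  set.seed(7)
  big <- data.frame(
    m_adoc_star = rnorm(1200, 8, 1), volume = 2,
    concentration = runif(1200, 5, 40),
    zone = "productive", province = "SATL"
  )
  out2 <- adoc_poc_correlation(big)
  expect_lt(abs(out2$r[out2$group == "overall"]), 3 / sqrt(1200))
  # degenerate variance flagged
  s3 <- s
  s3$m_adoc_star <- 4
  expect_true(adoc_poc_correlation(s3)$degenerate[1])
})

test_that("particle-loss correction follows its construction", {
  s <- data.frame(
    depth = c(10, 50, 300, 500),
    zone = c("productive", "productive", "mesopelagic", "mesopelagic"),
    m_adoc_star = c(9, 9, 5, 5),
    m_poc = c(40, 40, 20, 20),
    volume = 2
  )
  out <- particle_loss_correction(s)
  # every productive mass rises by exactly the aDOC excess over deep median
  expect_equal(out$samples$m_poc_corrected, c(44, 44, 20, 20))
  expect_equal(out$summary$median[out$summary$group == "productive"], 10)
  # all-equal aDOC: nothing changes
  s$m_adoc_star <- 6
  out2 <- particle_loss_correction(s)
  expect_equal(out2$samples$m_poc_corrected, s$m_poc)
  expect_error(particle_loss_correction(s[s$depth < 200, ]), "200")
})

test_that("mass ratios recover an exact fraction and flag bad pairs", {
  s <- data.frame(
    m_upoc_star = c(50, 80, 120, -3),
    m_adoc_star = c(5, 8, 12, 2),
    zone = "productive"
  )
  out <- mass_ratio_summary(s)
  expect_equal(out$summary$median, 10)
  expect_equal(out$summary$robust_sd, 0)
  expect_equal(out$n_flagged, 1)
})

test_that("blank scenarios collapse when the lower filter carries nothing", {
  # construct a pipeline-like object where aDOC raw masses and all blanks
  # are zero: every scenario equals the paired-blank POC
  cfg <- noise_free_config(seed = 55)
  cfg$adoc_baseline_mass <- 0
  cfg$adoc_poc_fraction <- 0
  cfg$capsule_mass_mean <- 0
  cfg$clean_filter_extra_mass_mean <- 0
  cfg$acidification_contamination_mean <- 0
  pp <- process_cruise(generate_cruise(cfg)$tables)
  out <- blank_scenarios(pp)
  expect_lt(max(abs(out$summary$median)), 1e-7)
  # with a real aDOC load, the raw-uPOC scenario overshoots POC
  pp2 <- process_cruise(generate_cruise(noise_free_config(seed = 56))$tables)
  out2 <- blank_scenarios(pp2)
  raw <- out2$summary[out2$summary$scenario == "raw_upoc", ]
  expect_true(all(raw$median > 5))
})

test_that("single deep-blank scenario approaches zero bias at depth", {
  pp <- process_cruise(generate_cruise(noise_free_config(seed = 57))$tables)
  out <- blank_scenarios(pp)
  deep <- out$summary[out$summary$scenario == "single_deep_adoc", ]
  raw <- out$summary[out$summary$scenario == "raw_upoc", ]
  expect_lt(abs(deep$median[deep$group == "mesopelagic"]),
            abs(raw$median[raw$group == "mesopelagic"]))
})
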