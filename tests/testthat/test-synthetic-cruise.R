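test_that("invalid configurations are rejected with a message", {
  expect_error(synthetic_config(response_noise_sd = -1), "SD")
  expect_error(synthetic_config(adoc_poc_fraction = 1), "adoc_poc_fraction")
  expect_error(synthetic_config(poc_decay_scale = Inf), "finite")
  expect_error(synthetic_config(capsule_mass_mean = NA), "finite")
  expect_error(synthetic_config(depths_per_station = c(-5, 100)), "depths")
  expect_error(synthetic_config(unstable_runs = 20), "unstable_runs")
})

test_that("identical seed and config give byte-identical CSV output", {
  cfg <- small_noisy_config(seed = 77)
  d1 <- file.path(tempdir(), "cruise_a")
  d2 <- file.path(tempdir(), "cruise_b")
  write_cruise(generate_cruise(cfg), d1)
  write_cruise(generate_cruise(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6),
                     label = paste("bytes of", f))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("different seeds give different data", {
  t1 <- generate_cruise(small_noisy_config(seed = 1))$tables
  t2 <- generate_cruise(small_noisy_config(seed = 2))$tables
  expect_false(isTRUE(all.equal(t1$upoc$response, t2$upoc$response)))
})

test_that("the cruise layout matches the design", {
  cfg <- small_noisy_config(seed = 5)
  cr <- generate_cruise(cfg)
  tb <- cr$tables
  # per run: 11 + 8 standards, 3 capsules, 3 non-acidified blanks;
  # per desiccator: 3 acidified blanks
  expect_equal(nrow(tb$standards), cfg$n_runs * (11 + 8))
  expect_equal(as.vector(table(tb$capsules$run)), rep(3L, cfg$n_runs))
  expect_equal(as.vector(table(tb$nonacidified$run)), rep(3L, cfg$n_runs))
  expect_equal(nrow(tb$acidified), 3 * 2 * cfg$n_runs)
  # one sample per station x depth plus one duplicate pair per station
  expect_equal(nrow(tb$upoc), cfg$n_stations * 6)
  expect_equal(nrow(tb$dup_upoc), cfg$n_stations)
  expect_equal(nrow(tb$upoc), nrow(tb$adoc))
  # paired filters share run and desiccator; duplicates are fumed apart
  expect_equal(tb$upoc$desiccator, tb$adoc$desiccator)
  partner <- match(paste(tb$dup_upoc$station, tb$dup_upoc$depth),
                   paste(tb$upoc$station, tb$upoc$depth))
  expect_false(any(tb$dup_upoc$desiccator == tb$upoc$desiccator[partner]))
  # every sample traces to exactly one ground-truth record
  truth_ids <- cr$truth$samples$sample_id
  expect_setequal(c(tb$upoc$sample_id, tb$dup_upoc$sample_id), truth_ids)
  expect_equal(anyDuplicated(truth_ids), 0L)
  # calibration standards span the expected filter-mass range
  cal <- tb$standards[tb$standards$type == "calibration", ]
  expect_equal(range(cal$known_mass), c(5, 300), tolerance = 1e-9)
})

test_that("the volume rule stays within 1-8 L and sets bottle counts", {
  cr <- generate_cruise(synthetic_config(n_stations = 30, rng_seed = 8))
  v <- cr$tables$upoc$volume
  expect_true(all(v >= 1 & v <= 8))
  expect_true(any(v < 3) && any(v > 5))  # rule actually adapts
  expect_equal(cr$tables$upoc$n_bottles, as.integer(ceiling(v / 2.2)))
})

test_that("aDOC masses correlate with POC masses when coupled", {
  coupled <- generate_cruise(synthetic_config(n_stations = 40, rng_seed = 9))
  tr <- coupled$truth$samples
  expect_gt(cor(tr$true_poc_mass, tr$true_adoc_mass), 0.3)
  free <- generate_cruise(synthetic_config(n_stations = 40,
                                           adoc_poc_fraction = 0,
                                           rng_seed = 9))
  expect_lt(abs(cor(free$truth$samples$true_poc_mass,
                    free$truth$samples$true_adoc_mass)), 0.15)
})

test_that("noise-free generation is exactly invertible", {
  cr <- generate_cruise(noise_free_config())
  tr <- cr$truth$samples
  # responses invert to the exact filter masses through the true line
  runs <- cr$truth$runs
  std <- cr$tables$standards
  m <- runs$slope[match(std$run, runs$run)]
  expect_equal(m * std$response + runs$intercept[1], std$known_mass,
               tolerance = 1e-9)
  expect_equal(tr$true_volume, tr$volume)
  expect_equal(tr$true_conc * tr$volume, tr$true_poc_mass, tolerance = 1e-12)
})
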