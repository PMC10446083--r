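# Shared generator configurations for the test suite.

# Small cruise with every noise source switched off: the pipeline must
# reproduce the ground truth exactly.
noise_free_config <- function(n_stations = 12, seed = 101) {
  synthetic_config(
    n_stations = n_stations,
    n_runs = 4,
    surface_poc_by_station = rep(20, n_stations),
    surface_poc_sdlog = 0,
    adoc_baseline_sd = 0,
    capsule_mass_sd = 0, capsule_mass_between_sd = 0,
    clean_filter_extra_mass_sd = 0, clean_filter_extra_mass_between_sd = 0,
    acidification_contamination_sd = 0,
    acidification_contamination_between_sd = 0,
    run_slope_jitter = 0,
    response_noise_sd = 0, response_noise_rel = 0,
    volume_noise_per_bottle_sd = 0,
    sigma_r_true_productive = 0, sigma_r_true_mesopelagic = 0,
    unstable_runs = integer(0),
    rng_seed = seed
  )
}

# Small noisy cruise for structural tests.
small_noisy_config <- function(seed = 202) {
  synthetic_config(n_stations = 10, n_runs = 4, unstable_runs = 2L,
                   rng_seed = seed)
}

# Duplicate-noise recovery design: many duplicate pairs in one zone, all
# instrument and handling noise off so only the duplicate noise remains.
recovery_config <- function(sigma_r, n_pairs = 500, seed = 1) {
  synthetic_config(
    n_stations = n_pairs,
    depths_per_station = 300,
    n_runs = 4,
    surface_poc_sdlog = 0.3,
    adoc_baseline_sd = 0,
    capsule_mass_sd = 0, capsule_mass_between_sd = 0,
    clean_filter_extra_mass_sd = 0, clean_filter_extra_mass_between_sd = 0,
    acidification_contamination_sd = 0,
    acidification_contamination_between_sd = 0,
    run_slope_jitter = 0,
    response_noise_sd = 0, response_noise_rel = 0,
    volume_noise_per_bottle_sd = 0,
    sigma_r_true_productive = sigma_r, sigma_r_true_mesopelagic = sigma_r,
    unstable_runs = integer(0),
    rng_seed = seed
  )
}

# Independent brute-force percentile with linear interpolation between order
# statistics (oracle for robust_sd).
percentile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

robust_sd_oracle <- function(x) {
  (percentile_oracle(x, 0.84) - percentile_oracle(x, 0.16)) / 2
}

# Standards on a known line with optional noise, for calibration tests.
make_standards <- function(n = 11, slope = 0.5, intercept = 3, noise_sd = 0.1,
                           run = 1L, mass_range = c(5, 300), seed = 1) {
  set.seed(seed)
  mass <- exp(seq(log(mass_range[1]), log(mass_range[2]), length.out = n))
  x <- (mass - intercept) / slope
  data.frame(run = run, type = "calibration",
             standard_id = sprintf("STD_%d", seq_len(n)),
             known_mass = mass + rnorm(n, 0, noise_sd), response = x)
}
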