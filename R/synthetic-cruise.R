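#' Configuration of a synthetic CHN cruise
#'
#' Bundles every ground-truth quantity the generator needs: the POC depth
#' field, the DOC-adsorption model of the lower filters, the blank carbon
#' levels, the instrument calibration, and the zone-specific duplicate noise.
#' Defaults emulate a meridional Atlantic transect analysed in 16 CHN runs:
#' ~390 stacked-filter samples from six depths in the upper 500 m, one
#' duplicate pair per station, filtered volumes between 1 and 8 L in ~2.2 L
#' bottles, 11 calibration standards spanning 5--300 ug per run plus
#' interleaved stability standards, capsule blanks near 2 ug, clean filter
#' blanks near 3 ug, acid-fumed blanks near 4 ug, and relative duplicate
#' noise of 12% in the productive and 35% in the mesopelagic zone. Two runs
#' are made unstable (the stability standards see a drifted instrument
#' sensitivity), mirroring the kind of mid-run drift the stability standards
#' exist to catch.
#'
#' @param n_stations number of stations along the transect.
#' @param depths_per_station sampling depths (m, positive down).
#' @param surface_poc_by_station per-station surface POC (mg/m^3); if `NULL`,
#'   drawn lognormally with median `surface_poc_median` and log-sd
#'   `surface_poc_sdlog` (spatial variability along the transect).
#' @param surface_poc_median,surface_poc_sdlog lognormal parameters of the
#'   surface POC field.
#' @param poc_decay_scale e-folding depth (m) of the POC decline.
#' @param poc_deep_floor deep asymptotic POC (mg/m^3).
#' @param adoc_baseline_mass,adoc_baseline_sd baseline adsorbed-DOC carbon
#'   per filter (ug) and its between-sample spread.
#' @param adoc_poc_fraction fraction of the POC mass that co-deposits on the
#'   lower filter (particle leakage / shared depth structure); reproduces the
#'   observed positive aDOC--POC correlation. In [0, 1).
#' @param capsule_mass_mean,capsule_mass_sd residual carbon of empty tin
#'   capsules (ug): `capsule_mass_between_sd` is the run-to-run drift of the
#'   capsule batch level (a new combustion tube per run), `capsule_mass_sd`
#'   the capsule-to-capsule scatter within a run.
#' @param capsule_mass_between_sd run-level SD of the capsule carbon (ug).
#' @param clean_filter_extra_mass_mean,clean_filter_extra_mass_sd carbon of a
#'   pre-combusted filter beyond the capsule (ug); between-run and
#'   within-run components as for capsules.
#' @param clean_filter_extra_mass_between_sd run-level SD of the filter
#'   carbon (ug).
#' @param acidification_contamination_mean,acidification_contamination_sd
#'   carbon picked up during acid fuming and drying (ug): the mean level
#'   varies between desiccator batches
#'   (`acidification_contamination_between_sd`) and filter-to-filter within
#'   one (`acidification_contamination_sd`).
#' @param acidification_contamination_between_sd desiccator-level SD (ug).
#' @param instrument_slope,instrument_intercept true calibration line
#'   (ug per response unit; ug).
#' @param run_slope_jitter relative between-run variation of the true slope.
#' @param response_noise_sd baseline additive noise on the instrument
#'   response (response units); the implied mass noise floor is
#'   `instrument_slope * response_noise_sd`.
#' @param response_noise_rel signal-proportional component of the response
#'   noise (combustion noise grows with the carbon load), as a fraction of
#'   the response.
#' @param volume_noise_per_bottle_sd difference between true and recorded
#'   volume, per bottle (L); 0 means volumes are recorded exactly.
#' @param n_runs number of CHN runs.
#' @param n_calibration_standards,standards_per_run calibration and stability
#'   standards per run.
#' @param standard_mass_range mass range (ug) covered by the standards.
#' @param sigma_r_true_productive,sigma_r_true_mesopelagic true relative
#'   duplicate noise per zone (dimensionless).
#' @param target_filter_mass volume rule: volumes aim to put about this much
#'   carbon (ug) on the filter, within `volume_range`.
#' @param volume_range admissible filtered volumes (L), rounded to 0.5 L.
#' @param bottle_volume capacity (L) of one filtration bottle.
#' @param zone_boundary productive/mesopelagic boundary depth (m).
#' @param unstable_runs indices of runs whose stability standards see a
#'   drifted sensitivity.
#' @param unstable_slope_factor multiplicative slope drift in unstable runs.
#' @param desiccators_per_run acid-fuming desiccators per run.
#' @param start_date date of the first cast.
#' @param rng_seed integer seed; identical seed and config give
#'   byte-identical output tables.
#' @return a validated `poc_synthetic_config` list.
#' @export
synthetic_config <- function(
    n_stations = 65,
    depths_per_station = c(5, 50, 125, 250, 400, 500),
    surface_poc_by_station = NULL,
    surface_poc_median = 22,
    surface_poc_sdlog = 0.45,
    poc_decay_scale = 130,
    poc_deep_floor = 5.5,
    adoc_baseline_mass = 2,
    adoc_baseline_sd = 2,
    adoc_poc_fraction = 0.09,
    capsule_mass_mean = 2,
    capsule_mass_sd = 0.25,
    capsule_mass_between_sd = 0.8,
    clean_filter_extra_mass_mean = 1,
    clean_filter_extra_mass_sd = 0.2,
    clean_filter_extra_mass_between_sd = 0.4,
    acidification_contamination_mean = 1,
    acidification_contamination_sd = 0.3,
    acidification_contamination_between_sd = 0.5,
    instrument_slope = 0.5,
    instrument_intercept = 1,
    run_slope_jitter = 0.02,
    response_noise_sd = 1.0,
    response_noise_rel = 0.012,
    volume_noise_per_bottle_sd = 0.010,
    n_runs = 16,
    n_calibration_standards = 11,
    standards_per_run = 8,
    standard_mass_range = c(5, 300),
    sigma_r_true_productive = 0.12,
    sigma_r_true_mesopelagic = 0.35,
    target_filter_mass = 60,
    volume_range = c(1, 8),
    bottle_volume = 2.2,
    zone_boundary = 200,
    unstable_runs = c(3L, 11L),
    unstable_slope_factor = 1.15,
    desiccators_per_run = 2,
    start_date = "2014-09-25",
    rng_seed = 1L) {
  cfg <- as.list(environment())
  maybe_null <- c("surface_poc_by_station")
  text_fields <- c("start_date")
  for (nm in setdiff(names(cfg), c(maybe_null, text_fields))) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || !all(is.finite(v))) {
      stop("synthetic_config: '", nm, "' must be finite and numeric")
    }
  }
  if (!is.null(cfg$surface_poc_by_station) &&
      (!is.numeric(cfg$surface_poc_by_station) ||
         !all(is.finite(cfg$surface_poc_by_station)))) {
    stop("synthetic_config: 'surface_poc_by_station' must be finite")
  }
  sds <- c(cfg$surface_poc_sdlog, cfg$adoc_baseline_sd, cfg$capsule_mass_sd,
           cfg$capsule_mass_between_sd, cfg$clean_filter_extra_mass_sd,
           cfg$clean_filter_extra_mass_between_sd,
           cfg$acidification_contamination_sd,
           cfg$acidification_contamination_between_sd,
           cfg$response_noise_sd, cfg$response_noise_rel,
           cfg$volume_noise_per_bottle_sd,
           cfg$run_slope_jitter, cfg$sigma_r_true_productive,
           cfg$sigma_r_true_mesopelagic)
  if (any(sds < 0)) stop("synthetic_config: all noise SDs must be >= 0")
  if (any(c(cfg$adoc_baseline_mass, cfg$capsule_mass_mean,
            cfg$clean_filter_extra_mass_mean,
            cfg$acidification_contamination_mean,
            cfg$target_filter_mass) < 0)) {
    stop("synthetic_config: mean masses must be >= 0")
  }
  if (cfg$adoc_poc_fraction < 0 || cfg$adoc_poc_fraction >= 1) {
    stop("synthetic_config: adoc_poc_fraction must be in [0, 1)")
  }
  if (any(cfg$depths_per_station < 0)) stop("depths must be >= 0")
  if (cfg$instrument_slope <= 0) stop("instrument_slope must be > 0")
  if (cfg$n_stations < 1 || cfg$n_runs < 1) stop("need >= 1 station and run")
  if (any(cfg$unstable_runs > cfg$n_runs)) {
    stop("unstable_runs outside 1..n_runs")
  }
  structure(cfg, class = "poc_synthetic_config")
}

# Longhurst-style province label from latitude (labels are inputs to the
# reporting layer, not a biogeographic computation).
province_from_lat <- function(lat) {
  cut(lat, breaks = c(-Inf, -38, -5, 12, 25, 40, Inf),
      labels = c("SSTC", "SATL", "WTRA", "NATL", "NAST", "NADR"),
      right = FALSE)
}

#' Generate a synthetic cruise dataset with known ground truth
#'
#' Builds, per CHN run, calibration and stability standards, capsule blanks,
#' non-acidified filter blanks, and per-desiccator acidified filter blanks;
#' and, per station and depth, a paired uPOC/aDOC filter record plus one
#' duplicate pair per station (acidified in a different desiccator than its
#' partner, as at sea). Instrument responses are obtained by inverting the
#' run's true calibration line and adding response noise; duplicate-level
#' noise is multiplicative with the zone's true relative sigma. Each table is
#' generated under its own RNG stream derived from `rng_seed`, so regenerating
#' with the same seed gives byte-identical tables.
#'
#' @param config a [synthetic_config()].
#' @return list with `tables` (named data frames in the deposited CSV layout:
#'   `standards`, `capsules`, `nonacidified`, `acidified`, `upoc`, `adoc`,
#'   `dup_upoc`, `dup_adoc`), `truth` (per-sample ground truth, per-run true
#'   calibration lines, true per-zone sigma_r), and `config`.
#' @export
generate_cruise <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "poc_synthetic_config"))
  cfg <- config
  seed <- as.integer(cfg$rng_seed)

  ## --- stations and field --------------------------------------------------
  set.seed(seed + 1L)
  st <- data.frame(
    station = seq_len(cfg$n_stations),
    latitude = seq(48, -48, length.out = cfg$n_stations),
    longitude = -20 + 8 * sin(seq(0, pi, length.out = cfg$n_stations))
  )
  st$province <- as.character(province_from_lat(st$latitude))
  st$cast <- ifelse(st$station %% 2L == 1L, "predawn", "noon")
  day0 <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = "UTC")
  st$datetime <- format(day0 + ((st$station - 1L) %/% 2L) * 86400 +
                          ifelse(st$cast == "predawn", 4L, 12L) * 3600,
                        "%Y-%m-%d %H:%M:%S")
  surface <- cfg$surface_poc_by_station
  if (is.null(surface)) {
    surface <- cfg$surface_poc_median * exp(stats::rnorm(
      cfg$n_stations, 0, cfg$surface_poc_sdlog))
  }
  if (length(surface) != cfg$n_stations) {
    stop("surface_poc_by_station must have one value per station")
  }
  st$surface_poc <- surface
  st$run <- pmin(cfg$n_runs,
                 ceiling(st$station * cfg$n_runs / cfg$n_stations))

  ## --- per-run true calibration -------------------------------------------
  set.seed(seed + 2L)
  runs <- data.frame(
    run = seq_len(cfg$n_runs),
    slope = cfg$instrument_slope *
      (1 + stats::rnorm(cfg$n_runs, 0, cfg$run_slope_jitter)),
    intercept = cfg$instrument_intercept
  )
  runs$unstable <- runs$run %in% cfg$unstable_runs

  ## --- sample grid (main + duplicates) ------------------------------------
  set.seed(seed + 3L)
  grid <- expand.grid(depth = cfg$depths_per_station,
                      station = st$station)[, c("station", "depth")]
  dup_depth <- cfg$depths_per_station[
    sample.int(length(cfg$depths_per_station), cfg$n_stations, replace = TRUE)]
  dup <- data.frame(station = st$station, depth = dup_depth)
  grid$is_duplicate <- FALSE
  dup$is_duplicate <- TRUE
  samples <- rbind(grid, dup)
  samples <- merge(samples, st, by = "station", sort = FALSE)
  samples <- samples[order(samples$station, samples$is_duplicate,
                           samples$depth), ]
  samples$zone <- assign_zone(samples$depth, cfg$zone_boundary)
  samples$sample_id <- sprintf("S%03d_z%03d%s", samples$station,
                               round(samples$depth),
                               ifelse(samples$is_duplicate, "_dup", ""))

  # field concentration and the volume rule (recorded volumes, 0.5 L steps)
  samples$field_conc <- samples$surface_poc *
    exp(-samples$depth / cfg$poc_decay_scale) + cfg$poc_deep_floor
  v_raw <- cfg$target_filter_mass / samples$field_conc
  samples$volume <- pmin(cfg$volume_range[2L],
                         pmax(cfg$volume_range[1L], round(v_raw * 2) / 2))
  samples$n_bottles <- as.integer(ceiling(samples$volume / cfg$bottle_volume))

  # desiccator assignment: alternate within run; duplicates are shifted by
  # one so they are acidified apart from their partner
  ord <- order(samples$run, samples$station, samples$depth)
  samples <- samples[ord, ]
  idx_in_run <- stats::ave(seq_len(nrow(samples)), samples$run,
                           FUN = seq_along)
  d_idx <- ((idx_in_run - 1L) %% cfg$desiccators_per_run) + 1L
  key <- paste(samples$station, samples$depth)
  partner <- match(key[samples$is_duplicate], key[!samples$is_duplicate])
  d_idx[samples$is_duplicate] <-
    (d_idx[!samples$is_duplicate][partner] %% cfg$desiccators_per_run) + 1L
  samples$desiccator <- sprintf("R%02d_D%d", samples$run, d_idx)

  ## --- true masses ---------------------------------------------------------
  set.seed(seed + 4L)
  n <- nrow(samples)
  sigma_r_zone <- ifelse(samples$zone == "mesopelagic",
                         cfg$sigma_r_true_mesopelagic,
                         cfg$sigma_r_true_productive)
  eps <- stats::rnorm(n, 0, 1) * sigma_r_zone
  samples$true_volume <- samples$volume + stats::rnorm(n, 0, 1) *
    (cfg$volume_noise_per_bottle_sd * sqrt(samples$n_bottles))
  samples$sampled_conc <- samples$field_conc * (1 + eps)
  samples$true_poc_mass <- samples$sampled_conc * samples$true_volume
  samples$true_adoc_mass <- pmax(0, cfg$adoc_baseline_mass +
    stats::rnorm(n, 0, cfg$adoc_baseline_sd) +
    cfg$adoc_poc_fraction * samples$true_poc_mass)
  # concentration the pipeline should recover from this filter pair
  samples$true_conc <- samples$true_poc_mass / samples$volume

  ## --- per-filter handling biases -----------------------------------------
  # capsule and filter carbon levels drift between runs (new combustion tube
  # and capsule batch per run); acid-fuming contamination varies between
  # desiccator batches; individual filters scatter around those levels
  set.seed(seed + 5L)
  desic <- expand.grid(d = seq_len(cfg$desiccators_per_run),
                       run = runs$run)[, c("run", "d")]
  desic$desiccator <- sprintf("R%02d_D%d", desic$run, desic$d)
  cap_lvl <- cfg$capsule_mass_mean +
    stats::rnorm(cfg$n_runs, 0, 1) * cfg$capsule_mass_between_sd
  ext_lvl <- cfg$clean_filter_extra_mass_mean +
    stats::rnorm(cfg$n_runs, 0, 1) * cfg$clean_filter_extra_mass_between_sd
  con_lvl <- cfg$acidification_contamination_mean +
    stats::rnorm(nrow(desic), 0, 1) *
      cfg$acidification_contamination_between_sd
  names(con_lvl) <- desic$desiccator
  draw_cap <- function(run) cap_lvl[run] +
    stats::rnorm(length(run), 0, 1) * cfg$capsule_mass_sd
  draw_ext <- function(run) ext_lvl[run] +
    stats::rnorm(length(run), 0, 1) * cfg$clean_filter_extra_mass_sd
  draw_con <- function(des) con_lvl[des] +
    stats::rnorm(length(des), 0, 1) * cfg$acidification_contamination_sd
  upoc_filter_mass <- pmax(0, samples$true_poc_mass +
    samples$true_adoc_mass + draw_cap(samples$run) + draw_ext(samples$run) +
    draw_con(samples$desiccator))
  adoc_filter_mass <- pmax(0, samples$true_adoc_mass +
    draw_cap(samples$run) + draw_ext(samples$run) +
    draw_con(samples$desiccator))

  ## --- lab blanks and standards -------------------------------------------
  set.seed(seed + 6L)
  blanks_per_type <- 3L
  run_rep <- rep(runs$run, each = blanks_per_type)
  capsules <- data.frame(
    run = run_rep,
    capsule_id = sprintf("CAP_R%02d_%d", run_rep,
                         sequence(rep(blanks_per_type, cfg$n_runs))),
    mass = pmax(0, draw_cap(run_rep))
  )
  nonacid <- data.frame(
    run = run_rep,
    blank_id = sprintf("NAC_R%02d_%d", run_rep,
                       sequence(rep(blanks_per_type, cfg$n_runs))),
    mass = pmax(0, draw_cap(run_rep) + draw_ext(run_rep))
  )
  des_rep <- rep(desic$desiccator, each = blanks_per_type)
  acid <- data.frame(
    run = rep(desic$run, each = blanks_per_type),
    desiccator = des_rep,
    blank_id = sprintf("AC_%s_%d", des_rep,
                       sequence(rep(blanks_per_type, nrow(desic)))),
    mass = pmax(0, draw_cap(rep(desic$run, each = blanks_per_type)) +
                  draw_ext(rep(desic$run, each = blanks_per_type)) +
                  draw_con(des_rep))
  )

  set.seed(seed + 7L)
  cal_mass <- exp(seq(log(cfg$standard_mass_range[1L]),
                      log(cfg$standard_mass_range[2L]),
                      length.out = cfg$n_calibration_standards))
  standards <- do.call(rbind, lapply(runs$run, function(k) {
    stab_mass <- stats::runif(cfg$standards_per_run,
                              cfg$standard_mass_range[1L],
                              cfg$standard_mass_range[2L])
    data.frame(
      run = k,
      type = rep(c("calibration", "stability"),
                 c(cfg$n_calibration_standards, cfg$standards_per_run)),
      standard_id = sprintf("STD_R%02d_%d", k,
                            seq_len(cfg$n_calibration_standards +
                                      cfg$standards_per_run)),
      known_mass = c(cal_mass, stab_mass)
    )
  }))

  ## --- responses: invert the true line, add response noise -----------------
  set.seed(seed + 8L)
  true_response <- function(mass, run, drifted = FALSE) {
    m <- runs$slope[match(run, runs$run)]
    b <- runs$intercept[match(run, runs$run)]
    drift <- ifelse(drifted & runs$unstable[match(run, runs$run)],
                    cfg$unstable_slope_factor, 1)
    x0 <- (mass - b) / (m * drift)
    x0 + stats::rnorm(length(mass), 0, 1) *
      (cfg$response_noise_sd + cfg$response_noise_rel * abs(x0))
  }
  standards$response <- true_response(standards$known_mass, standards$run,
                                      drifted = standards$type == "stability")
  capsules$response <- true_response(capsules$mass, capsules$run)
  nonacid$response <- true_response(nonacid$mass, nonacid$run)
  acid$response <- true_response(acid$mass, acid$run)
  resp_u <- true_response(upoc_filter_mass, samples$run)
  resp_a <- true_response(adoc_filter_mass, samples$run)
  capsules$mass <- nonacid$mass <- acid$mass <- NULL

  ## --- assemble tables ------------------------------------------------------
  meta <- c("sample_id", "station", "depth", "latitude", "longitude",
            "datetime", "province", "cast", "run", "desiccator", "volume",
            "n_bottles", "is_duplicate")
  upoc_tab <- cbind(samples[meta], response = resp_u)
  adoc_tab <- cbind(samples[c("sample_id", "station", "depth", "run",
                              "desiccator", "is_duplicate")],
                    response = resp_a)
  rownames(upoc_tab) <- rownames(adoc_tab) <- NULL
  main <- !samples$is_duplicate

  truth_samples <- samples[c("sample_id", "station", "depth", "zone",
                             "is_duplicate", "volume", "true_volume",
                             "field_conc", "sampled_conc", "true_poc_mass",
                             "true_adoc_mass", "true_conc")]
  rownames(truth_samples) <- NULL

  list(
    tables = list(
      standards = standards,
      capsules = capsules,
      nonacidified = nonacid,
      acidified = acid,
      upoc = upoc_tab[main, ],
      adoc = adoc_tab[main, ],
      dup_upoc = upoc_tab[!main, ],
      dup_adoc = adoc_tab[!main, ]
    ),
    truth = list(
      samples = truth_samples,
      runs = runs,
      sigma_r = c(productive = cfg$sigma_r_true_productive,
                  mesopelagic = cfg$sigma_r_true_mesopelagic)
    ),
    config = cfg
  )
}
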