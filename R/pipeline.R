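#' Run the full POC determination and uncertainty pipeline
#'
#' Orchestrates every stage on a set of linked cruise tables:
#' \enumerate{
#'   \item fit the per-run robust calibration on the pooled calibration and
#'     stability standards, and flag unstable runs by comparing the two
#'     standard sets;
#'   \item predict carbon masses (with prediction-interval uncertainties) for
#'     every capsule, blank and filter;
#'   \item blank-correct each uPOC/aDOC pair with its run's capsule and
#'     non-acidified blanks and its desiccator's acidified blanks, and divide
#'     by the filtered volume;
#'   \item compute IUPAC critical value and detection limit from the pooled
#'     capsule masses and flag (never drop) samples below them;
#'   \item form duplicate pairs, estimate the per-zone experimental
#'     uncertainty sigma_r (excluding unstable runs), and scale it into a
#'     per-sample sigma_C;
#'   \item propagate the modelled components (volume, calibration,
#'     contamination) and assemble the per-sample uncertainty budget.
#' }
#'
#' @param tables cruise tables as returned by [read_cruise()] or
#'   `generate_cruise()$tables`.
#' @param zone_boundary productive/mesopelagic boundary depth (m).
#' @param sigma_vn per-bottle volume uncertainty (L).
#' @param alpha_unstable significance level of the run-stability test.
#' @param exclude_unstable exclude unstable-run pairs from sigma_r.
#' @param residual_mode convention for the unquantified budget share.
#' @return a `poc_pipeline` list: `calibrations` (per-run summary data frame
#'   and fit objects), `blank_sets`, `limits`, `samples` (one row per
#'   uPOC/aDOC pair, duplicates included, with masses, concentration, zone,
#'   flags, uncertainty components and budget), `duplicates`, `sigma_r`,
#'   `sigma_r_diagnostics`.
#' @export
process_cruise <- function(tables,
                           zone_boundary = 200,
                           sigma_vn = 0.010,
                           alpha_unstable = 0.05,
                           exclude_unstable = TRUE,
                           residual_mode = c("linear", "variance")) {
  residual_mode <- match.arg(residual_mode)

  ## calibrations ------------------------------------------------------------
  run_ids <- sort(unique(tables$standards$run))
  fits <- lapply(run_ids, function(k) {
    std_k <- tables$standards[tables$standards$run == k, ]
    pooled <- fit_calibration(std_k, include_stability = TRUE)
    cal <- std_k[std_k$type == "calibration", ]
    stab <- std_k[std_k$type == "stability", ]
    unstable <- if (nrow(cal) >= 3L && nrow(stab) >= 3L) {
      detect_unstable_run(fit_calibration(cal, prune_intercept = FALSE),
                          fit_calibration(stab, prune_intercept = FALSE),
                          alpha = alpha_unstable)
    } else FALSE
    list(fit = pooled, unstable = unstable)
  })
  names(fits) <- as.character(run_ids)
  cal_summary <- do.call(rbind, lapply(fits, function(f) {
    data.frame(run = f$fit$run, slope = f$fit$slope,
               intercept = f$fit$intercept, sigma_res = f$fit$sigma_res,
               n_s = f$fit$n_s, stable = !f$unstable)
  }))
  rownames(cal_summary) <- NULL
  unstable_runs <- cal_summary$run[!cal_summary$stable]

  fit_of <- function(run) fits[[as.character(run)]]$fit
  predict_by_run <- function(df) {
    out <- data.frame(mass = rep(NA_real_, nrow(df)),
                      sigma_m = rep(NA_real_, nrow(df)))
    for (k in unique(df$run)) {
      sel <- df$run == k
      out[sel, ] <- suppressWarnings(predict_mass(fit_of(k),
                                                  df$response[sel]))
    }
    out
  }

  ## predicted masses ---------------------------------------------------------
  capsules <- cbind(tables$capsules, predict_by_run(tables$capsules))
  nonacid <- cbind(tables$nonacidified, predict_by_run(tables$nonacidified))
  acid <- cbind(tables$acidified, predict_by_run(tables$acidified))
  upoc <- rbind(tables$upoc, tables$dup_upoc)
  adoc <- rbind(tables$adoc, tables$dup_adoc)
  upoc <- cbind(upoc, predict_by_run(upoc))
  adoc_pred <- predict_by_run(adoc)
  idx <- match(upoc$sample_id, adoc$sample_id)
  upoc$adoc_mass <- adoc_pred$mass[idx]
  upoc$adoc_sigma_m <- adoc_pred$sigma_m[idx]

  ## blank sets per run x desiccator ------------------------------------------
  blank_sets <- list()
  for (k in run_ids) {
    caps_k <- capsules$mass[capsules$run == k]
    nac_k <- nonacid$mass[nonacid$run == k]
    for (d in unique(acid$desiccator[acid$run == k])) {
      ac_kd <- acid$mass[acid$run == k & acid$desiccator == d]
      blank_sets[[d]] <- blank_set(caps_k, ac_kd, nac_k,
                                   run = k, desiccator = d)
    }
  }

  ## blank correction and concentration ---------------------------------------
  samples <- upoc
  names(samples)[names(samples) == "mass"] <- "upoc_mass"
  names(samples)[names(samples) == "sigma_m"] <- "upoc_sigma_m"
  samples$m_upoc_star <- samples$m_adoc_star <- samples$m_poc <- NA_real_
  for (d in names(blank_sets)) {
    sel <- samples$desiccator == d
    if (!any(sel)) next
    corr <- blank_correct(samples$upoc_mass[sel], samples$adoc_mass[sel],
                          blank_sets[[d]], run = samples$run[sel],
                          desiccator = samples$desiccator[sel])
    samples$m_upoc_star[sel] <- corr$m_upoc_star
    samples$m_adoc_star[sel] <- corr$m_adoc_star
    samples$m_poc[sel] <- corr$m_poc
  }
  samples$concentration <- concentration(samples$m_poc, samples$volume)
  samples$zone <- assign_zone(samples$depth, zone_boundary)
  samples$run_stable <- !(samples$run %in% unstable_runs)

  ## detection limits (pooled capsules from all runs) --------------------------
  limits <- detection_limits(capsules$mass)
  samples$below_ld <- samples$m_poc < limits$l_d
  samples$below_lc <- samples$m_poc < limits$l_c

  ## duplicates and sigma_r -----------------------------------------------------
  is_dup <- samples$is_duplicate
  key <- paste(samples$station, samples$depth)
  partner <- match(key[is_dup], key[!is_dup])
  duplicates <- data.frame(
    station = samples$station[is_dup],
    depth = samples$depth[is_dup],
    zone = samples$zone[is_dup],
    d1 = samples$concentration[!is_dup][partner],
    d2 = samples$concentration[is_dup],
    run_1 = samples$run[!is_dup][partner],
    run_2 = samples$run[is_dup]
  )
  duplicates$excluded <- exclude_unstable &
    (duplicates$run_1 %in% unstable_runs |
       duplicates$run_2 %in% unstable_runs)
  sr <- estimate_sigma_r(duplicates, by_zone = TRUE)
  duplicates <- sr$pairs
  sigma_r <- sr$sigma_r

  ## per-sample uncertainties and budget ---------------------------------------
  samples$sigma_r <- sigma_r[samples$zone]
  samples$sigma_c <- sigma_c_experimental(samples$concentration,
                                          samples$sigma_r)
  samples$sigma_v <- volume_uncertainty(samples$n_bottles, sigma_vn)
  samples$sigma_c_v <- sigma_c_volume(samples$m_poc, samples$volume,
                                      samples$sigma_v)

  # within-run correlation of the paired masses; pooled fallback for small runs
  r_pooled <- tryCatch(
    estimate_mass_correlation(samples$upoc_mass, samples$adoc_mass),
    error = function(e) 0)
  samples$mass_correlation <- NA_real_
  for (k in run_ids) {
    sel <- samples$run == k
    r_k <- if (sum(sel) >= 3L) {
      tryCatch(estimate_mass_correlation(samples$upoc_mass[sel],
                                         samples$adoc_mass[sel]),
               error = function(e) {
                 message("run ", k,
                         ": too few pairs, using pooled mass correlation")
                 r_pooled
               })
    } else {
      message("run ", k, ": too few pairs, using pooled mass correlation")
      r_pooled
    }
    samples$mass_correlation[sel] <- r_k
  }
  samples$sigma_c_m <- calibration_uncertainty(
    samples$upoc_sigma_m, samples$adoc_sigma_m,
    samples$mass_correlation, samples$volume)
  samples$sigma_eta <- vapply(samples$desiccator,
                              function(d) blank_sets[[d]]$sigma_eta,
                              numeric(1))
  samples$sigma_c_eta <- contamination_uncertainty(samples$sigma_eta,
                                                   samples$volume)
  samples <- cbind(samples, assemble_budget(
    samples$sigma_c, samples$sigma_c_v, samples$sigma_c_m,
    samples$sigma_c_eta, residual_mode = residual_mode))
  rownames(samples) <- NULL

  structure(list(
    calibrations = list(summary = cal_summary,
                        fits = lapply(fits, `[[`, "fit")),
    unstable_runs = unstable_runs,
    blank_sets = blank_sets,
    capsules = capsules,
    nonacidified = nonacid,
    acidified = acid,
    limits = limits,
    samples = samples,
    duplicates = duplicates,
    sigma_r = sigma_r,
    sigma_r_diagnostics = sr$diagnostics,
    zone_boundary = zone_boundary
  ), class = "poc_pipeline")
}

#' @export
print.poc_pipeline <- function(x, ...) {
  s <- x$samples[!x$samples$is_duplicate & x$samples$run_stable, ]
  cat("POC pipeline result\n")
  cat("  runs:", nrow(x$calibrations$summary),
      sprintf("(%d unstable)", length(x$unstable_runs)), "\n")
  cat("  samples:", sum(!x$samples$is_duplicate),
      sprintf("(+%d duplicates)", sum(x$samples$is_duplicate)), "\n")
  for (z in names(x$sigma_r)) {
    cz <- s$concentration[s$zone == z]
    cat(sprintf("  %s: n=%d, median POC %.1f mg/m3, sigma_r %.1f%%\n",
                z, length(cz), stats::median(cz), 100 * x$sigma_r[[z]]))
  }
  cat(sprintf("  detection: L_C %.2f ug, L_D %.2f ug (%d capsules)\n",
              x$limits$l_c, x$limits$l_d, x$limits$df + 1L))
  invisible(x)
}
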