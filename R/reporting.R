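#' Grouped medians with robust standard deviations
#'
#' All summary values in this package are reported as median with a
#' percentile-based robust SD (see [robust_sd()]): the median resists the
#' skewed, outlier-prone distributions typical of field POC data, and the
#' robust SD reduces to the ordinary SD for Gaussian data.
#'
#' @param values numeric vector.
#' @param group_keys optional vector or data frame of grouping keys (zone,
#'   province, cast time, filter role, ...); `NULL` summarises everything as
#'   one group.
#' @return data frame with `group`, `n`, `median`, `robust_sd`.
#' @export
summarise_robust <- function(values, group_keys = NULL) {
  if (is.null(group_keys)) {
    group_keys <- rep("all", length(values))
  }
  if (is.data.frame(group_keys)) {
    group_keys <- do.call(paste, c(group_keys, sep = "/"))
  }
  groups <- split(values, group_keys)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]][is.finite(groups[[g]])]
    data.frame(group = g, n = length(v),
               median = stats::median(v),
               robust_sd = if (length(v) >= 2L) robust_sd(v) else 0)
  }))
  rownames(out) <- NULL
  out
}

#' Correlation between aDOC and POC concentrations
#'
#' Because filtered volumes track expected POC and all filters are treated
#' identically, the adsorbed-DOC concentration should be roughly constant; a
#' positive correlation with POC instead points to particle leakage through
#' the upper filter. Pearson r and p are reported overall, per zone and per
#' province.
#'
#' @param samples pipeline sample table (needs `m_adoc_star`, `volume`,
#'   `concentration`, `zone`, `province`).
#' @param min_n smallest group size for which a correlation is computed.
#' @return data frame with `group`, `n`, `r`, `p` (`NA` when the group is too
#'   small or degenerate, flagged via `degenerate`).
#' @export
adoc_poc_correlation <- function(samples, min_n = 3L) {
  adoc_conc <- samples$m_adoc_star / samples$volume
  poc_conc <- samples$concentration
  groups <- c(list(overall = seq_len(nrow(samples))),
              split(seq_len(nrow(samples)), samples$zone),
              split(seq_len(nrow(samples)), samples$province))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    i <- groups[[g]]
    ok <- is.finite(adoc_conc[i]) & is.finite(poc_conc[i])
    i <- i[ok]
    degenerate <- length(i) < min_n ||
      stats::sd(adoc_conc[i]) == 0 || stats::sd(poc_conc[i]) == 0
    if (degenerate) {
      data.frame(group = g, n = length(i), r = NA_real_, p = NA_real_,
                 degenerate = TRUE)
    } else {
      ct <- stats::cor.test(adoc_conc[i], poc_conc[i])
      data.frame(group = g, n = length(i), r = unname(ct$estimate),
                 p = ct$p.value, degenerate = FALSE)
    }
  }))
  rownames(out) <- NULL
  out
}

#' Correct POC masses for particle loss onto the lower filter
#'
#' If particles leak through the upper filter, the aDOC blank overestimates
#' adsorption wherever particles are abundant. Deep aDOC filters, where
#' particles are scarce, better represent pure adsorption: each sample's
#' excess is its bias-corrected aDOC mass minus the median bias-corrected
#' aDOC mass below `deep_threshold`, and this excess is added back to the POC
#' mass.
#'
#' @param samples pipeline sample table.
#' @param deep_threshold depth (m) above which aDOC is considered
#'   particle-affected; default 200.
#' @return list with `samples` (adds `adoc_excess`, `m_poc_corrected`,
#'   `concentration_corrected`, `percent_change`), `deep_median_adoc`, and
#'   `summary` (median +/- robust SD percent change per zone).
#' @export
particle_loss_correction <- function(samples, deep_threshold = 200) {
  deep <- samples$depth >= deep_threshold
  if (!any(deep)) stop("no aDOC filters at or below ", deep_threshold, " m")
  deep_median <- stats::median(samples$m_adoc_star[deep])
  samples$adoc_excess <- samples$m_adoc_star - deep_median
  samples$m_poc_corrected <- samples$m_poc + samples$adoc_excess
  samples$concentration_corrected <- samples$m_poc_corrected / samples$volume
  samples$percent_change <- 100 *
    (samples$m_poc_corrected - samples$m_poc) / samples$m_poc
  list(samples = samples,
       deep_median_adoc = deep_median,
       summary = summarise_robust(samples$percent_change, samples$zone))
}

#' Compare blank-correction strategies for uPOC concentrations
#'
#' Quantifies what the POC estimates would have been with fewer (or no) aDOC
#' blanks. Four scenarios per sample, each compared with the paired-blank POC
#' concentration as a per-sample percent difference summarised by
#' median(+/- robust SD) per zone:
#' \describe{
#'   \item{raw_upoc}{no correction at all: `M_uPOC / V`;}
#'   \item{minus_nonacidified}{subtract the cruise-median clean filter blank;}
#'   \item{minus_acidified}{subtract the cruise-median acidified blank;}
#'   \item{single_deep_adoc}{subtract one pooled value, the median raw aDOC
#'     mass from deep (>= `deep_threshold` m) samples.}
#' }
#'
#' @param pipeline a `poc_pipeline` result (scenario blanks come from its
#'   predicted blank masses).
#' @param deep_threshold depth (m) defining the deep aDOC pool.
#' @return list with `per_sample` (scenario concentrations and percent
#'   differences) and `summary` (per scenario and zone).
#' @export
blank_scenarios <- function(pipeline, deep_threshold = 200) {
  s <- pipeline$samples
  med_nac <- stats::median(pipeline$nonacidified$mass)
  med_ac <- stats::median(pipeline$acidified$mass)
  deep <- s$depth >= deep_threshold
  if (!any(deep)) stop("no deep samples for the single-blank scenario")
  med_deep_adoc <- stats::median(s$adoc_mass[deep])
  scen <- data.frame(
    sample_id = s$sample_id,
    zone = s$zone,
    raw_upoc = s$upoc_mass / s$volume,
    minus_nonacidified = (s$upoc_mass - med_nac) / s$volume,
    minus_acidified = (s$upoc_mass - med_ac) / s$volume,
    single_deep_adoc = (s$upoc_mass - med_deep_adoc) / s$volume
  )
  scen_names <- c("raw_upoc", "minus_nonacidified", "minus_acidified",
                  "single_deep_adoc")
  summaries <- list()
  for (nm in scen_names) {
    pct <- 100 * (scen[[nm]] - s$concentration) / s$concentration
    scen[[paste0(nm, "_pct_diff")]] <- pct
    sm <- summarise_robust(pct, s$zone)
    sm$scenario <- nm
    summaries[[nm]] <- sm
  }
  summary <- do.call(rbind, summaries)
  rownames(summary) <- NULL
  list(per_sample = scen,
       blanks = c(median_nonacidified = med_nac, median_acidified = med_ac,
                  median_deep_adoc = med_deep_adoc),
       summary = summary[, c("scenario", "group", "n", "median", "robust_sd")])
}

#' Ratio of adsorbed-DOC to uncorrected-POC carbon mass
#'
#' The bias-corrected mass ratio `M*_aDOC / M*_uPOC` measures how important
#' DOC adsorption is relative to the total carbon load of the upper filter.
#'
#' @param samples pipeline sample table.
#' @return list with `summary` (per-zone median +/- robust SD of the ratio in
#'   percent), `range` (percent), and `n_flagged` (pairs with non-positive
#'   corrected uPOC mass, excluded from the ratio and flagged).
#' @export
mass_ratio_summary <- function(samples) {
  bad <- !(samples$m_upoc_star > 0)
  ratio <- ifelse(bad, NA_real_,
                  100 * samples$m_adoc_star / samples$m_upoc_star)
  list(summary = summarise_robust(ratio[!bad], samples$zone[!bad]),
       range = range(ratio[!bad]),
       n_flagged = sum(bad))
}
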