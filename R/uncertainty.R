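#' Scaled and relative difference of a duplicate pair
#'
#' Two co-sampled filters give two estimates `D1`, `D2` of the same
#' concentration. Their difference carries the uncertainty of both, adding in
#' quadrature, so the single-measurement uncertainty is
#' \eqn{\Delta = (D_1 - D_2)/\sqrt 2}. Because \eqn{\Delta} grows with
#' concentration, the relative difference \eqn{\Delta_r = \Delta / \bar D}
#' (with \eqn{\bar D} the pair mean) is the scale-free quantity pooled across
#' the cruise.
#'
#' @param d1,d2 duplicate concentrations (mg/m^3); vectorised.
#' @return data frame with `dbar`, `delta`, `delta_r` (`delta_r` is `NA` when
#'   the pair mean is zero).
#' @export
scaled_difference <- function(d1, d2) {
  dbar <- (d1 + d2) / 2
  delta <- (d1 - d2) / sqrt(2)
  delta_r <- ifelse(dbar == 0, NA_real_, delta / dbar)
  data.frame(dbar = dbar, delta = delta, delta_r = delta_r)
}

#' Percentile-based robust standard deviation
#'
#' Half the distance between the 84th and 16th percentiles (linear
#' interpolation between order statistics). For Gaussian data this equals the
#' ordinary standard deviation, but it is insensitive to the outliers that
#' contaminate duplicate-difference distributions.
#'
#' @param values numeric vector, at least 2 finite values.
#' @return robust SD (same units as `values`).
#' @export
robust_sd <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("robust_sd needs at least 2 finite values")
  q <- stats::quantile(values, c(0.16, 0.84), names = FALSE, type = 7)
  (q[2L] - q[1L]) / 2
}

#' Whole-dataset relative experimental uncertainty from duplicate pairs
#'
#' \eqn{\sigma_r} per zone is the robust SD of the relative duplicate
#' differences \eqn{\Delta_r}, pooling all non-excluded pairs in that zone.
#' Pairs from unstable CHN runs are excluded (their inflated calibration
#' scatter would bias the cruise-wide precision upward), as are pairs with a
#' non-positive mean concentration, for which \eqn{\Delta_r} is meaningless.
#' Ordinary linear fits of \eqn{|\Delta|} and \eqn{|\Delta_r|} against
#' \eqn{\bar D} are reported as diagnostics of the concentration dependence
#' that motivates the relative formulation.
#'
#' @param pairs data frame with columns `d1`, `d2`, `zone` and optionally
#'   `excluded` (logical).
#' @param by_zone estimate per zone (default) or pooled.
#' @return list with `sigma_r` (named vector), `n_pairs`, and `diagnostics`
#'   (per group: Pearson r and p of `|delta|` vs `dbar` and `|delta_r|` vs
#'   `dbar`).
#' @export
estimate_sigma_r <- function(pairs, by_zone = TRUE) {
  stopifnot(all(c("d1", "d2") %in% names(pairs)))
  if (is.null(pairs$excluded)) pairs$excluded <- FALSE
  sd_cols <- scaled_difference(pairs$d1, pairs$d2)
  pairs <- cbind(pairs, sd_cols)
  usable <- !pairs$excluded & is.finite(pairs$delta_r) & pairs$dbar > 0
  if (any(!pairs$excluded & !(is.finite(pairs$delta_r) & pairs$dbar > 0))) {
    warning("duplicate pair(s) with non-positive mean concentration ",
            "excluded from sigma_r")
  }
  groups <- if (by_zone) {
    stopifnot("zone" %in% names(pairs))
    split(pairs[usable, ], pairs$zone[usable], drop = FALSE)
  } else {
    list(all = pairs[usable, ])
  }
  sigma_r <- vapply(names(groups), function(g) {
    d <- groups[[g]]
    if (nrow(d) < 2L) stop("fewer than 2 usable duplicate pairs in zone '",
                           g, "'")
    robust_sd(d$delta_r)
  }, numeric(1))
  diagnostics <- lapply(groups, function(d) {
    if (nrow(d) < 3L || stats::sd(d$dbar) == 0 ||
        stats::sd(abs(d$delta)) == 0 || stats::sd(abs(d$delta_r)) == 0) {
      return(NULL)
    }
    abs_fit <- stats::cor.test(abs(d$delta), d$dbar)
    rel_fit <- stats::cor.test(abs(d$delta_r), d$dbar)
    data.frame(
      statistic = c("abs_delta_vs_dbar", "rel_delta_vs_dbar"),
      r = c(unname(abs_fit$estimate), unname(rel_fit$estimate)),
      p = c(abs_fit$p.value, rel_fit$p.value)
    )
  })
  list(sigma_r = sigma_r,
       n_pairs = vapply(groups, nrow, integer(1)),
       diagnostics = diagnostics,
       pairs = pairs)
}

#' Per-sample experimental uncertainty
#'
#' \eqn{\sigma_C = \sigma_r C}: the zone's whole-dataset relative uncertainty
#' scaled by the sample's own concentration.
#'
#' @param c_poc concentration (mg/m^3).
#' @param sigma_r relative uncertainty (dimensionless, >= 0).
#' @return absolute uncertainty (mg/m^3).
#' @export
sigma_c_experimental <- function(c_poc, sigma_r) {
  stopifnot(all(sigma_r >= 0))
  sigma_r * c_poc
}

#' Volume uncertainty and its propagation into concentration
#'
#' Each ~2.2 L bottle's volume is read off a measuring cylinder to half a
#' graduation mark (10 ml); with `n` bottles per sample the volume errors add
#' in quadrature, \eqn{\sigma_V = \sigma_{V_n}\sqrt n}, and propagate as
#' \eqn{\sigma_C(V) = M \sigma_V / V^2}.
#'
#' @param n_bottles bottles filtered per sample (>= 1).
#' @param sigma_vn per-bottle volume uncertainty (L), default 0.010.
#' @return `volume_uncertainty`: \eqn{\sigma_V} in litres.
#' @export
volume_uncertainty <- function(n_bottles, sigma_vn = 0.010) {
  stopifnot(all(n_bottles >= 1), sigma_vn >= 0)
  sigma_vn * sqrt(n_bottles)
}

#' @rdname volume_uncertainty
#' @param m_poc POC mass (ug).
#' @param volume filtered volume (L).
#' @param sigma_v combined volume uncertainty (L).
#' @return `sigma_c_volume`: \eqn{\sigma_C(V)} in mg/m^3.
#' @export
sigma_c_volume <- function(m_poc, volume, sigma_v) {
  if (any(volume <= 0, na.rm = TRUE)) stop("volume must be positive")
  abs(m_poc) * sigma_v / volume^2
}

#' Calibration uncertainty of a concentration
#'
#' Propagates the prediction-interval mass uncertainties of the paired
#' filters through the POC difference and the volume division:
#' \deqn{\sigma_C(M) = \frac1V\sqrt{\sigma_{M_{uPOC}}^2 + \sigma_{M_{aDOC}}^2
#'   - 2\,\sigma_{M_{uPOC}}\sigma_{M_{aDOC}}\,r}}
#' where `r` is the correlation between the two predicted masses (see
#' [estimate_mass_correlation()]). The quadratic form is bounded below by
#' \eqn{(\sigma_1-\sigma_2)^2 \ge 0}, so the result is always real; it is
#' symmetric in the two mass uncertainties.
#'
#' @param sigma_m_upoc,sigma_m_adoc mass uncertainties (ug); vectorised.
#' @param r correlation coefficient, `|r| <= 1`.
#' @param volume filtered volume (L).
#' @return \eqn{\sigma_C(M)} in mg/m^3.
#' @export
calibration_uncertainty <- function(sigma_m_upoc, sigma_m_adoc, r, volume) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| must not exceed 1")
  if (any(volume <= 0, na.rm = TRUE)) stop("volume must be positive")
  quad <- sigma_m_upoc^2 + sigma_m_adoc^2 - 2 * sigma_m_upoc * sigma_m_adoc * r
  sqrt(pmax(quad, 0)) / volume
}

#' Contamination uncertainty of a concentration
#'
#' The handling contamination of the uPOC and aDOC filters is assumed equal
#' and estimated from the acidified filter blanks of the sample's desiccator;
#' its uncertainty \eqn{\sigma_\eta} is their standard error of the mean.
#' Since both filters of a pair are affected,
#' \eqn{\sigma_C(\eta) = \sqrt{2}\,\sigma_\eta / V}.
#'
#' @param blanks a `poc_blank_set` (provides `sigma_eta`), or a bare numeric
#'   \eqn{\sigma_\eta} in ug.
#' @param volume filtered volume (L).
#' @return \eqn{\sigma_C(\eta)} in mg/m^3.
#' @export
contamination_uncertainty <- function(blanks, volume) {
  sigma_eta <- if (inherits(blanks, "poc_blank_set")) blanks$sigma_eta
               else blanks
  if (any(volume <= 0, na.rm = TRUE)) stop("volume must be positive")
  sqrt(2) * sigma_eta / volume
}

#' Correlation of the paired filter masses within a CHN run
#'
#' Eq.-15-style propagation needs the correlation between the predicted
#' uPOC and aDOC masses; it is estimated empirically as the Pearson
#' correlation of the pairs processed in the same run (clamped to [-1, 1]).
#' Runs with fewer than 3 pairs fall back to the pooled cross-run
#' correlation, with a message.
#'
#' @param m_upoc,m_adoc predicted masses (ug) of the paired filters.
#' @return Pearson r in [-1, 1].
#' @export
estimate_mass_correlation <- function(m_upoc, m_adoc) {
  keep <- is.finite(m_upoc) & is.finite(m_adoc)
  if (sum(keep) < 3L) stop("need at least 3 paired samples")
  if (stats::sd(m_upoc[keep]) == 0 || stats::sd(m_adoc[keep]) == 0) {
    return(0)
  }
  r <- stats::cor(m_upoc[keep], m_adoc[keep])
  max(-1, min(1, r))
}

#' Assemble the per-sample uncertainty budget
#'
#' Each modelled component is expressed relative to the experimental
#' uncertainty, \eqn{u_x = \sigma_C(x)/\sigma_C}, and the remainder the model
#' cannot account for is reported under two conventions: `linear`,
#' \eqn{1 - \sum u_x} (the arithmetic used in the budget table), and
#' `variance`, \eqn{\sqrt{\max(0, 1 - \sum u_x^2)}} (comparing modelled and
#' experimental variances). Both are returned; `residual_mode` selects which
#' one fills the `unquantified` column.
#'
#' @param sigma_c experimental uncertainty (mg/m^3); samples with
#'   `sigma_c <= 0` get an all-`NA` budget row (flagged, not dropped).
#' @param sigma_c_v,sigma_c_m,sigma_c_eta modelled components (mg/m^3).
#' @param residual_mode `"linear"` or `"variance"`.
#' @return data frame with `u_v`, `u_m`, `u_eta`, `explained_linear`,
#'   `explained_variance`, `unquantified_linear`, `unquantified_variance`,
#'   `unquantified`, `budget_defined`.
#' @export
assemble_budget <- function(sigma_c, sigma_c_v, sigma_c_m, sigma_c_eta,
                            residual_mode = c("linear", "variance")) {
  residual_mode <- match.arg(residual_mode)
  defined <- is.finite(sigma_c) & sigma_c > 0
  u_v <- ifelse(defined, sigma_c_v / sigma_c, NA_real_)
  u_m <- ifelse(defined, sigma_c_m / sigma_c, NA_real_)
  u_eta <- ifelse(defined, sigma_c_eta / sigma_c, NA_real_)
  expl_lin <- u_v + u_m + u_eta
  expl_var <- u_v^2 + u_m^2 + u_eta^2
  unq_lin <- 1 - expl_lin
  unq_var <- sqrt(pmax(0, 1 - expl_var))
  data.frame(
    u_v = u_v, u_m = u_m, u_eta = u_eta,
    explained_linear = expl_lin,
    explained_variance = expl_var,
    unquantified_linear = unq_lin,
    unquantified_variance = unq_var,
    unquantified = if (residual_mode == "linear") unq_lin else unq_var,
    budget_defined = defined
  )
}
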