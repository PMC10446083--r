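#' Blank-correct the carbon masses of a stacked filter pair
#'
#' Both filters of a pair carry, besides their analyte, the residual carbon of
#' the tin capsule, of the pre-combusted filter itself, and any contamination
#' picked up during acid fuming. These biases are removed with the run's
#' capsule blanks and the desiccator's acidified / the run's non-acidified
#' filter blanks:
#' \deqn{M^*_{uPOC} = M_{uPOC} - \bar M_{cap} - (\bar M_{ac} - \bar M_{nac})}
#' and likewise for the aDOC filter. The POC mass is
#' \eqn{M = M^*_{uPOC} - M^*_{aDOC}}; because both filters share the same
#' blank terms this is algebraically identical to
#' \eqn{M_{uPOC} - M_{aDOC}}, which is why pairing filters within one
#' desiccator and run matters: shared biases cancel exactly.
#'
#' @param upoc_mass,adoc_mass predicted carbon masses (ug) of the paired
#'   filters; vectorised.
#' @param blanks a `poc_blank_set` for the same run and desiccator (see
#'   [blank_set()]).
#' @param run,desiccator optional ids of the sample pair; when given they are
#'   checked against `blanks` (the bias-cancellation argument fails across
#'   runs or desiccators).
#' @return data frame with `m_upoc_star`, `m_adoc_star`, `m_poc` (ug).
#' @export
blank_correct <- function(upoc_mass, adoc_mass, blanks,
                          run = NULL, desiccator = NULL) {
  stopifnot(inherits(blanks, "poc_blank_set"))
  if (!is.null(run) && !all(run == blanks$run)) {
    stop("sample from run ", run[which(run != blanks$run)[1L]],
         " corrected with blanks of run ", blanks$run)
  }
  if (!is.null(desiccator) && !all(desiccator == blanks$desiccator)) {
    stop("sample from desiccator ",
         desiccator[which(desiccator != blanks$desiccator)[1L]],
         " corrected with blanks of desiccator ", blanks$desiccator)
  }
  bias <- blanks$m_cap + (blanks$m_ac - blanks$m_nac)
  m_u <- upoc_mass - bias
  m_a <- adoc_mass - bias
  data.frame(m_upoc_star = m_u, m_adoc_star = m_a, m_poc = m_u - m_a)
}

#' Assemble the blank statistics for one run and desiccator
#'
#' @param capsule_masses predicted masses (ug) of the run's empty tin
#'   capsules.
#' @param acidified_masses masses of the filter blanks acid-fumed in this
#'   desiccator.
#' @param nonacidified_masses masses of the run's clean filter blanks kept
#'   outside the desiccators.
#' @param run,desiccator identifiers carried along for pairing checks.
#' @return a `poc_blank_set`: means of the three blank types and `sigma_eta`,
#'   the standard error of the mean of the acidified blank masses, which
#'   quantifies how uncertain the handling-contamination correction is.
#' @export
blank_set <- function(capsule_masses, acidified_masses, nonacidified_masses,
                      run = NA, desiccator = NA) {
  for (v in list(capsule_masses, acidified_masses, nonacidified_masses)) {
    if (length(v) < 2L) stop("each blank type needs at least 2 measurements")
  }
  structure(list(
    run = run,
    desiccator = desiccator,
    capsule_masses = capsule_masses,
    acidified_masses = acidified_masses,
    nonacidified_masses = nonacidified_masses,
    m_cap = mean(capsule_masses),
    m_ac = mean(acidified_masses),
    m_nac = mean(nonacidified_masses),
    sigma_eta = stats::sd(acidified_masses) / sqrt(length(acidified_masses))
  ), class = "poc_blank_set")
}

#' POC concentration from mass and filtered volume
#'
#' `C = M / V`; with masses in ug and volumes in litres the result is in
#' ug/L, numerically identical to mg/m^3. Negative masses (aDOC exceeding
#' uPOC) are preserved, not clipped: clipping would bias the medians reported
#' downstream.
#'
#' @param m_poc POC mass (ug), vectorised.
#' @param volume filtered volume (L), vectorised.
#' @return concentration (mg/m^3).
#' @export
concentration <- function(m_poc, volume) {
  if (any(volume <= 0, na.rm = TRUE)) {
    stop("filtered volume must be positive")
  }
  m_poc / volume
}

#' IUPAC critical value and detection limit from blank measurements
#'
#' The critical value \eqn{L_C = \bar x_0 + s_0 t_{0.95;df}} is the smallest
#' result distinguishable from the blank; the detection limit
#' \eqn{L_D = L_C + s_0 t_{0.95;df} = \bar x_0 + 2 s_0 t_{0.95;df}} is the
#' smallest mass reliably detected 95% of the time. The blank material here
#' is the pooled set of empty tin capsules from all runs; `s_0` is the
#' ordinary standard deviation and the t quantile is one-tailed with
#' `n - 1` degrees of freedom.
#'
#' @param blank_masses predicted carbon masses (ug) of the blank material.
#' @param quantile one-tailed coverage, default 0.95.
#' @return list with `x0_mean`, `s0`, `df`, `t`, `l_c`, `l_d` (masses in ug).
#' @export
detection_limits <- function(blank_masses, quantile = 0.95) {
  blank_masses <- blank_masses[is.finite(blank_masses)]
  n <- length(blank_masses)
  if (n < 2L) stop("detection limits need at least 2 blank measurements")
  x0 <- mean(blank_masses)
  s0 <- stats::sd(blank_masses)
  t_q <- stats::qt(quantile, df = n - 1L)
  list(x0_mean = x0, s0 = s0, df = n - 1L, t = t_q,
       l_c = x0 + s0 * t_q, l_d = x0 + 2 * s0 * t_q)
}
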