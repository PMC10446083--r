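#' Fit a per-run robust calibration of carbon mass against instrument response
#'
#' Each CHN run is calibrated with pre-weighed acetanilide standards spanning
#' the expected mass range. The response--mass relation `M = m x + b` is fitted
#' by iteratively reweighted least squares (bisquare weights), which limits the
#' leverage of occasional gross outliers among the standards. The intercept is
#' removed and the model refitted once when it is not statistically significant
#' (p > 0.05). The residual scale `sigma_res` is the percentile-based robust
#' standard deviation of the mass residuals, so a single bad standard does not
#' inflate the prediction-interval widths downstream.
#'
#' @param standards data frame with columns `known_mass` (ug) and `response`
#'   (instrument signal); optionally `run` (single value) and `type`.
#' @param include_stability if `FALSE`, rows with `type == "stability"` are
#'   dropped before fitting; by default both standard sets are pooled.
#' @param intercept_alpha significance level above which the intercept is
#'   pruned.
#' @param prune_intercept set `FALSE` to always keep the intercept; fits that
#'   are to be compared coefficient-by-coefficient (see
#'   [detect_unstable_run()]) must share the same model form, otherwise a
#'   pruned intercept is absorbed into the other fit's slope and mimics
#'   drift.
#' @return an object of class `poc_calibration`: list with `run`, `slope`,
#'   `intercept` (`NA` when pruned), `slope_se`, `intercept_se`, `sigma_res`,
#'   `n_s`, `x_mean`, `s_x`, `t_crit` (Student t, `n_s - 2` df, 68% prediction
#'   level), `x_range`, `residuals`.
#' @seealso [predict_mass()], [detect_unstable_run()]
#' @export
fit_calibration <- function(standards, include_stability = TRUE,
                            intercept_alpha = 0.05, prune_intercept = TRUE) {
  if (!include_stability && "type" %in% names(standards)) {
    standards <- standards[standards$type != "stability", , drop = FALSE]
  }
  mass <- standards$known_mass
  x <- standards$response
  keep <- is.finite(mass) & is.finite(x)
  mass <- mass[keep]
  x <- x[keep]
  n <- length(x)
  if (n < 3L) {
    stop("calibration needs at least 3 standards, got ", n)
  }
  if (any(mass <= 0)) {
    stop("standards must have positive known masses")
  }
  if (stats::sd(x) <= 0) {
    stop("standards have zero response variance; cannot calibrate")
  }

  fit <- robust_line(x, mass)
  b <- fit$coef[1L]
  b_se <- fit$se[1L]

  # Prune a non-significant intercept with a single refit through the origin.
  drop_intercept <- prune_intercept &&
    if (fit$exact) abs(b) <= 1e-8 else {
      p_b <- 2 * stats::pt(-abs(b / b_se), df = n - 2L)
      is.na(p_b) || p_b > intercept_alpha
    }
  if (drop_intercept) {
    fit <- robust_line(x, mass, intercept = FALSE)
  }

  res <- fit$residuals
  sigma_res <- if (fit$exact) 0 else robust_sd(res)

  # OLS coefficients with HC3 sandwich SEs, kept for the run-stability test:
  # combustion noise grows with the carbon load, and at these sample sizes
  # only the HC3 form gives the slope-difference t-test its nominal size.
  X <- cbind(1, x)
  ols <- stats::lm.fit(X, mass)
  h <- pmin(rowSums((X %*% solve(crossprod(X))) * X), 1 - 1e-8)
  u <- ols$residuals / (1 - h)
  bread <- solve(crossprod(X))
  hc3 <- bread %*% crossprod(X * u, X * u) %*% bread

  structure(list(
    run = if ("run" %in% names(standards)) standards$run[1L] else NA,
    slope = unname(if (drop_intercept) fit$coef[1L] else fit$coef[2L]),
    intercept = if (drop_intercept) NA_real_ else unname(fit$coef[1L]),
    slope_se = unname(if (drop_intercept) fit$se[1L] else fit$se[2L]),
    intercept_se = if (drop_intercept) NA_real_ else unname(fit$se[1L]),
    sigma_res = sigma_res,
    n_s = n,
    x_mean = mean(x),
    s_x = stats::sd(x),
    t_crit = stats::qt(1 - 0.32 / 2, df = n - 2L),
    x_range = range(x),
    residuals = res,
    ols_coef = c(intercept = unname(ols$coefficients[1L]),
                 slope = unname(ols$coefficients[2L])),
    ols_se_hc3 = c(intercept = sqrt(hc3[1L, 1L]),
                   slope = sqrt(hc3[2L, 2L]))
  ), class = "poc_calibration")
}

# IRLS straight line with OLS fallback when the data are exactly collinear
# (rlm's MAD scale degenerates at zero residuals). Coefficient SEs are
# heteroscedasticity-consistent sandwich estimates treating the converged
# IRLS weights as fixed: CHN combustion noise grows with the carbon load, so
# homoscedastic SEs would understate the slope variance and inflate the
# unstable-run false-alarm rate.
robust_line <- function(x, y, intercept = TRUE) {
  ols <- if (intercept) stats::lm(y ~ x) else stats::lm(y ~ x - 1)
  s_ols <- sqrt(sum(stats::residuals(ols)^2) / stats::df.residual(ols))
  exact <- s_ols < 1e-9 * max(stats::sd(y), 1e-12)
  if (exact) {
    sm <- suppressWarnings(summary(ols))  # "essentially perfect fit"
    return(list(coef = stats::coef(ols), se = sm$coefficients[, "Std. Error"],
                residuals = stats::residuals(ols), exact = TRUE))
  }
  rfit <- suppressWarnings(
    if (intercept) MASS::rlm(y ~ x, psi = MASS::psi.bisquare, maxit = 100)
    else MASS::rlm(y ~ x - 1, psi = MASS::psi.bisquare, maxit = 100)
  )
  X <- if (intercept) cbind(1, x) else cbind(x)
  e <- stats::residuals(rfit)
  w <- rfit$w
  n <- length(y)
  p <- ncol(X)
  bread <- solve(crossprod(X * w, X))
  meat <- crossprod(X * (w * e), X * (w * e)) * n / (n - p)
  se <- sqrt(diag(bread %*% meat %*% bread))
  names(se) <- names(stats::coef(rfit))
  list(coef = stats::coef(rfit), se = se, residuals = e, exact = FALSE)
}

#' Predict carbon mass and its prediction-interval uncertainty
#'
#' Converts an instrument response to a carbon mass via the run's calibration
#' line and attaches the 68% prediction-interval half-width as the mass
#' uncertainty:
#' \deqn{\sigma_M = t_{1-\alpha/2}\,\sigma_{res}
#'   \sqrt{1 + 1/n_S + (x - \bar x)^2 / ((n_S - 1) s_x^2)}}
#' with \eqn{\alpha = 0.32} and \eqn{n_S - 2} degrees of freedom. A prediction
#' interval (rather than a confidence interval for the mean response) is used
#' because each filter is a single future observation from the fitted line.
#'
#' @param fit a `poc_calibration` object.
#' @param response instrument signal(s); vectorised.
#' @return data frame with columns `mass` and `sigma_m` (both ug).
#' @export
predict_mass <- function(fit, response) {
  stopifnot(inherits(fit, "poc_calibration"))
  b <- if (is.na(fit$intercept)) 0 else fit$intercept
  out_of_range <- response < fit$x_range[1L] | response > fit$x_range[2L]
  if (any(out_of_range, na.rm = TRUE)) {
    warning(sum(out_of_range, na.rm = TRUE),
            " response(s) outside the standards' range; extrapolating")
  }
  mass <- fit$slope * response + b
  sigma_m <- fit$t_crit * fit$sigma_res *
    sqrt(1 + 1 / fit$n_s +
           (response - fit$x_mean)^2 / ((fit$n_s - 1) * fit$s_x^2))
  data.frame(mass = mass, sigma_m = sigma_m)
}

#' Flag a CHN run whose calibration drifted during sample processing
#'
#' The calibration standards (analysed before the filters) and the stability
#' standards (interleaved with them) should yield statistically
#' indistinguishable calibration coefficients. A significant difference
#' indicates instrument instability during the run; such runs are excluded
#' from the duplicate-based uncertainty estimate so that their inflated
#' scatter does not bias the whole-dataset precision.
#'
#' @param fit_cal,fit_stab `poc_calibration` fits of the two standard sets
#'   from the same run.
#' @param alpha significance level of the Welch-type t-test on the slope
#'   difference (the intercept difference is tested too when both fits
#'   retain one). The test compares the stored OLS coefficients with their
#'   HC3 sandwich standard errors -- under signal-proportional combustion
#'   noise this is the combination whose false-alarm rate matches `alpha`.
#' @return `TRUE` when the run is unstable.
#' @export
detect_unstable_run <- function(fit_cal, fit_stab, alpha = 0.05) {
  stopifnot(inherits(fit_cal, "poc_calibration"),
            inherits(fit_stab, "poc_calibration"))
  if (!identical(fit_cal$run, fit_stab$run)) {
    stop("fits come from different runs: ", fit_cal$run, " vs ", fit_stab$run)
  }
  unstable <- coef_differs(
    fit_cal$ols_coef["slope"], fit_cal$ols_se_hc3["slope"], fit_cal$n_s,
    fit_stab$ols_coef["slope"], fit_stab$ols_se_hc3["slope"], fit_stab$n_s,
    alpha)
  if (!is.na(fit_cal$intercept) && !is.na(fit_stab$intercept)) {
    unstable <- unstable || coef_differs(
      fit_cal$ols_coef["intercept"], fit_cal$ols_se_hc3["intercept"],
      fit_cal$n_s,
      fit_stab$ols_coef["intercept"], fit_stab$ols_se_hc3["intercept"],
      fit_stab$n_s, alpha)
  }
  unname(unstable)
}

coef_differs <- function(c1, se1, n1, c2, se2, n2, alpha) {
  se <- sqrt(se1^2 + se2^2)
  scale <- max(abs(c1), abs(c2), 1)
  # exact fits give SEs at rounding-error level; compare coefficients directly
  if (!is.finite(se) || se < 1e-8 * scale) {
    return(abs(c1 - c2) > 1e-8 * scale)
  }
  t_stat <- (c1 - c2) / se
  # Welch-Satterthwaite df from the coefficient variances
  df <- se^4 / (se1^4 / (n1 - 2L) + se2^4 / (n2 - 2L))
  2 * stats::pt(-abs(t_stat), df = df) < alpha
}
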