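# Derived clinical measures: pulse wave velocity, Friedewald LDL and the
# nitrite calibration curve.

#' Pulse wave velocity
#'
#' Arterial stiffness expressed as the pulse path distance divided by the
#' pulse transit time, in m/s. For the carotid-radial segment the distance
#' is the measured brachial-radial path length and the transit time is the
#' ECG-gated delay between the two pulse waves.
#'
#' @param distance_m Path distance in metres (> 0).
#' @param transit_time_s Pulse transit time in seconds (> 0).
#' @return Velocity in m/s. Vectorised with recycling.
#' @export
#' @examples
#' pulse_wave_velocity(0.25, 0.05)  # 5 m/s
pulse_wave_velocity <- function(distance_m, transit_time_s) {
  if (any(!is.finite(distance_m)) || any(!is.finite(transit_time_s))) {
    abort("distance and transit time must be finite",
          class = "dietresponder_domain_error")
  }
  if (any(distance_m <= 0) || any(transit_time_s <= 0)) {
    abort("distance and transit time must both be positive",
          class = "dietresponder_domain_error")
  }
  distance_m / transit_time_s
}

#' Friedewald estimate of LDL-cholesterol
#'
#' LDL-C (mmol/L) = total cholesterol - HDL-C - triglycerides / 5, all in
#' mmol/L. The estimate can go negative when triglycerides are very high;
#' such values are returned unchanged but flagged (attribute
#' `implausible`, plus a warning), because clamping would hide a data
#' problem and break the formula's linearity.
#'
#' @param total_chol,hdl,triglycerides Concentrations in mmol/L, all >= 0.
#' @return LDL-cholesterol in mmol/L with a logical `implausible`
#'   attribute marking negative estimates.
#' @export
#' @examples
#' friedewald_ldl(5.0, 1.5, 1.0)  # 3.3
friedewald_ldl <- function(total_chol, hdl, triglycerides) {
  args <- list(total_chol, hdl, triglycerides)
  if (any(vapply(args, function(x) any(!is.finite(x)), logical(1)))) {
    abort("lipid inputs must be finite", class = "dietresponder_domain_error")
  }
  if (any(total_chol < 0) || any(hdl < 0) || any(triglycerides < 0)) {
    abort("lipid concentrations cannot be negative",
          class = "dietresponder_domain_error")
  }
  ldl <- total_chol - hdl - triglycerides / 5
  bad <- ldl < 0
  if (any(bad)) {
    warn(sprintf("%d implausible (negative) LDL estimate(s); check inputs",
                 sum(bad)))
  }
  attr(ldl, "implausible") <- bad
  ldl
}

#' Fit a calibration curve to standard solutions
#'
#' Ordinary least-squares straight line of detector signal on standard
#' concentration, as used to quantify plasma nitrite from a dilution
#' series of sodium nitrite standards. No weighting is applied by default;
#' `log_log = TRUE` fits on the log10-log10 scale instead, which can suit
#' standards spanning several orders of magnitude.
#'
#' @param concentration Standard concentrations (same molar unit
#'   throughout), all > 0, at least 2 distinct values.
#' @param signal Detector responses, one per standard.
#' @param log_log Fit log10(signal) on log10(concentration) instead of the
#'   linear scale.
#' @return An object of class `calibration_curve` with elements
#'   `concentration`, `signal`, `slope`, `intercept`, `r_squared`,
#'   `log_log`.
#' @export
#' @examples
#' fit_calibration_curve(c(1, 2, 3), c(2, 4, 6))
fit_calibration_curve <- function(concentration, signal, log_log = FALSE) {
  if (length(concentration) != length(signal)) {
    abort("concentration and signal must have the same length",
          class = "dietresponder_fit_error")
  }
  if (length(concentration) < 2L) {
    abort("at least 2 standards are required to fit a line",
          class = "dietresponder_fit_error")
  }
  if (anyDuplicated(concentration)) {
    abort("standard concentrations must be distinct",
          class = "dietresponder_fit_error")
  }
  if (any(concentration <= 0)) {
    abort("standard concentrations must be positive",
          class = "dietresponder_fit_error")
  }
  ord <- order(concentration)
  concentration <- concentration[ord]
  signal <- signal[ord]
  x <- if (log_log) log10(concentration) else concentration
  y <- if (log_log) log10(signal) else signal
  fit <- lm(y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  slope <- unname(coef(fit)[2])
  # a numerically flat response (e.g. identical signals) is as invalid as
  # a negative one
  if (slope <= 1e-10 * max(abs(y))) {
    warn("calibration slope is not positive; curve is invalid for quantification")
  }
  structure(
    list(concentration = concentration, signal = signal,
         slope = slope, intercept = unname(coef(fit)[1]),
         r_squared = r2, log_log = log_log),
    class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve (%s scale): signal = %.6g + %.6g * conc\n",
              if (x$log_log) "log10-log10" else "linear",
              x$intercept, x$slope))
  cat(sprintf("  %d standards spanning [%.4g, %.4g]; r^2 = %.4f\n",
              length(x$concentration), min(x$concentration),
              max(x$concentration), x$r_squared))
  invisible(x)
}

#' Interpolate a concentration from a calibration curve
#'
#' Inverts the fitted line: concentration = (signal - intercept) / slope
#' (back-transformed when the curve was fitted log-log). Signals outside
#' the range covered by the standards are still converted but flagged as
#' extrapolated.
#'
#' @param curve A `calibration_curve`.
#' @param signal Detector response(s) to convert.
#' @return Concentration(s) in the standards' unit, with a logical
#'   `extrapolated` attribute.
#' @export
interpolate_concentration <- function(curve, signal) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) {
    abort("calibration slope is zero; cannot invert the curve",
          class = "dietresponder_fit_error")
  }
  if (curve$log_log) {
    conc <- 10^((log10(signal) - curve$intercept) / curve$slope)
  } else {
    conc <- (signal - curve$intercept) / curve$slope
  }
  lo <- min(curve$signal)
  hi <- max(curve$signal)
  out <- signal < lo | signal > hi
  if (any(out)) {
    warn(sprintf("%d signal(s) outside the calibrated range [%.4g, %.4g]; extrapolating",
                 sum(out), lo, hi))
  }
  attr(conc, "extrapolated") <- out
  conc
}
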