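## Size-exclusion chromatography: standards-based molecular-weight
## calibration (log-linear in elution volume) and apparent-MW
## prediction.

#' Fit a SEC calibration curve
#'
#' Least-squares line `log10(MW in Da) = slope * Ve + intercept` over
#' the protein standards.  For a well-behaved column the slope is
#' negative (larger species elute earlier); a non-negative slope is
#' reported with a warning.
#'
#' @param standards data.frame with columns `mw` (Da) and `ve` (mL), at
#'   least two standards with distinct elution volumes.
#' @return a [CalibrationCurve-class].
#' @export
secCalibrate <- function(standards) {
  s <- as.data.frame(standards)
  nm <- tolower(names(s))
  mi <- match(TRUE, nm %in% c("mw", "mass", "mw_da"))
  vi <- match(TRUE, nm %in% c("ve", "elution", "volume"))
  if (is.na(mi) || is.na(vi)) { mi <- 1L; vi <- 2L }
  mw <- as.numeric(s[[mi]]); ve <- as.numeric(s[[vi]])
  if (length(mw) < 2L) stop("need at least two standards")
  if (anyDuplicated(ve)) stop("duplicate elution volumes")
  fit <- lm(log10(mw) ~ ve)
  sl <- unname(coef(fit)[2]); ic <- unname(coef(fit)[1])
  y <- log10(mw)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  if (sl >= 0) warning("non-SEC-like calibration: slope is not negative")
  new("CalibrationCurve", slope = sl, intercept = ic, r2 = r2,
      ve_range = range(ve))
}

#' Apparent molecular weight from a calibration curve
#'
#' `MW = 10^(slope * Ve + intercept)`; elution volumes outside the
#' calibration range are flagged as extrapolations.
#'
#' @param curve a [CalibrationCurve-class].
#' @param ve elution volume(s) in mL.
#' @return data.frame with `ve`, `mw` (Da) and `extrapolated`.
#' @export
predictMw <- function(curve, ve) {
  stopifnot(is(curve, "CalibrationCurve"))
  mw <- 10^(curve@slope * ve + curve@intercept)
  data.frame(ve = ve, mw = mw,
             extrapolated = ve < curve@ve_range[1] | ve > curve@ve_range[2])
}
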