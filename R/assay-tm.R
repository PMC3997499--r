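## Melting-temperature extraction from thermal-shift (differential
## scanning fluorimetry) curves.

.asMeltingCurve <- function(curve) {
  if (is.matrix(curve)) curve <- as.data.frame(curve)
  nm <- tolower(names(curve))
  ti <- match(TRUE, nm %in% c("temperature", "t", "temp"))
  fi <- match(TRUE, nm %in% c("fluorescence", "f", "signal"))
  if (is.na(ti) || is.na(fi)) { ti <- 1L; fi <- 2L }
  out <- data.frame(temperature = as.numeric(curve[[ti]]),
                    fluorescence = as.numeric(curve[[fi]]))
  if (nrow(out) < 10L) stop("melting curve needs at least 10 points")
  if (any(!is.finite(out$temperature)) || any(!is.finite(out$fluorescence)))
    stop("non-finite values in melting curve")
  if (any(diff(out$temperature) <= 0))
    stop("temperatures must be strictly increasing")
  out
}

.movavg <- function(x, w) {
  if (w <= 1L) return(x)
  k <- rep(1 / w, w)
  n <- length(x)
  pad <- (w - 1L) %/% 2L
  xp <- c(rep(x[1], pad), x, rep(x[n], pad))
  as.numeric(stats::filter(xp, k, sides = 2))[(pad + 1L):(pad + n)]
}

#' Melting temperature from the derivative of the fluorescence
#'
#' The fluorescence is smoothed with a centered moving average, the
#' finite-difference dF/dT is computed, and Tm is the temperature of the
#' derivative maximum on the rising transition, refined by a 3-point
#' parabolic interpolation of the peak.  A transition is only accepted
#' when the peak derivative exceeds a noise floor of 3x the median
#' absolute derivative; flat or monotonically decreasing curves raise
#' "no transition detected".
#'
#' @param curve data.frame with `temperature` (deg C, strictly
#'   increasing) and `fluorescence` columns, >= 10 points.
#' @param window odd smoothing window in points (default 5).
#' @return a [TmResult-class] with method `"derivative"`.
#' @export
tmFromDerivative <- function(curve, window = 5L) {
  cv <- .asMeltingCurve(curve)
  if (window %% 2L == 0L) stop("smoothing window must be odd")
  f <- .movavg(cv$fluorescence, window)
  t <- cv$temperature
  n <- length(t)
  ## centered differences (one-sided at the ends)
  d <- c(diff(f)[1] / diff(t)[1],
         (f[3:n] - f[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)]),
         diff(f)[n - 1] / diff(t)[n - 1])
  floorLvl <- 3 * median(abs(d))
  i <- which.max(d)
  if (!is.finite(d[i]) || d[i] <= 0 || d[i] <= floorLvl)
    stop("no transition detected")
  tm <- t[i]
  ## sub-grid refinement: local quadratic fit of the derivative peak
  lo <- max(1L, i - 4L); hi <- min(n, i + 4L)
  if (hi - lo >= 2L) {
    b <- coef(lm(d[lo:hi] ~ stats::poly(t[lo:hi], 2, raw = TRUE)))
    vertex <- -b[2] / (2 * b[3])
    if (is.finite(vertex) && vertex >= t[lo] && vertex <= t[hi])
      tm <- unname(vertex)
  }
  new("TmResult", tm = tm, method = "derivative",
      diagnostics = list(peak_derivative = d[i], noise_floor = floorLvl,
                         peak_index = i))
}

#' Melting temperature by Boltzmann sigmoid fit
#'
#' Least-squares fit of
#' `F(T) = f_min + (f_max - f_min) / (1 + exp((tm - T)/s))` over the
#' pre-aggregation region (temperatures up to the smoothed fluorescence
#' maximum), initialized from the derivative estimate.
#'
#' @param curve as in [tmFromDerivative()].
#' @return a [TmResult-class] with method `"sigmoid-fit"`; diagnostics
#'   carry the fitted slope `s` and the residual norm.
#' @export
tmSigmoidFit <- function(curve) {
  cv <- .asMeltingCurve(curve)
  fs <- .movavg(cv$fluorescence, 5L)
  cut <- which.max(fs)
  reg <- cv[seq_len(max(cut, 5L)), ]
  if (nrow(reg) < 5L) stop("fewer than 5 points in the transition region")
  tm0 <- tryCatch(tmFromDerivative(cv)@tm,
                  error = function(e) median(reg$temperature))
  start <- list(fmin = min(reg$fluorescence), fmax = max(reg$fluorescence),
                tm = tm0, s = 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      fluorescence ~ fmin + (fmax - fmin) / (1 + exp((tm - temperature) / s)),
      data = reg, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("sigmoid fit did not converge: ",
                             conditionMessage(e)))
  cf <- coef(fit)
  res <- sqrt(sum(stats::residuals(fit)^2))
  if (cf[["tm"]] < min(cv$temperature) || cf[["tm"]] > max(cv$temperature))
    stop("fitted Tm outside the measured temperature range")
  new("TmResult", tm = unname(cf[["tm"]]), method = "sigmoid-fit",
      diagnostics = list(slope = unname(cf[["s"]]), residual_norm = res,
                         f_min = unname(cf[["fmin"]]),
                         f_max = unname(cf[["fmax"]])))
}
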