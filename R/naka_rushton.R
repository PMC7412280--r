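#' Naka-Rushton intensity-response function
#'
#' The hyperbolic relation between stimulus intensity and ERG response
#' amplitude, `V = V_max * I^n / (I^n + K^n)`: `V_max` is the saturating
#' amplitude, `K` the intensity eliciting half of it, and `n` the slope
#' exponent.
#'
#' @param intensity Stimulus intensity `I >= 0` (vectorized), in the same
#'   units as `k` (here photons cm^-2 s^-1).
#' @param v_max Maximum response amplitude (> 0).
#' @param k Half-saturation intensity (> 0).
#' @param n Exponent (> 0).
#' @return Response amplitude in `[0, v_max)`.
#' @examples
#' naka_rushton(1e10, v_max = 10, k = 1e10, n = 1)  # half of v_max
#' @export
naka_rushton <- function(intensity, v_max, k, n) {
  stopifnot(v_max > 0, k > 0, n > 0)
  if (any(intensity < 0)) stop("intensity must be >= 0", call. = FALSE)
  ## compute on the log scale to stay stable for extreme I/K ratios
  r <- n * (log(intensity) - log(k))            # log((I/K)^n); -Inf at I = 0
  v_max * stats::plogis(r)
}

#' Invert the Naka-Rushton function
#'
#' Maps a sub-saturating response amplitude back to the log10 equivalent
#' stimulus intensity — the linearization step that converts ERG amplitudes
#' into intensities before taking reciprocals for spectral sensitivity.
#'
#' @inheritParams naka_rushton
#' @param v Response amplitude, strictly inside `(0, v_max)` (vectorized).
#' @return `log10(I)` of the equivalent intensity; monotone increasing in `v`.
#' @export
naka_rushton_inverse <- function(v, v_max, k, n) {
  stopifnot(v_max > 0, k > 0, n > 0)
  if (any(v <= 0)) stop("response must be positive to invert", call. = FALSE)
  if (any(v >= v_max))
    stop("response at or above V_max: saturated, no finite intensity",
         call. = FALSE)
  log10(k) + log10(v / (v_max - v)) / n
}

#' Fit the Naka-Rushton function to an intensity-response series
#'
#' Nonlinear least squares on the parameterization
#' `(V_max, log10 K, n)` (the log-intensity scale keeps the problem well
#' conditioned when intensities span several decades, as in a 4-log-unit ERG
#' calibration series). Uses Levenberg-Marquardt with box constraints.
#'
#' @param intensity Stimulus intensities (>= 4 distinct values, ideally
#'   spanning about 4 log units).
#' @param response Response amplitudes, same length.
#' @return Object of class `naka_rushton_fit` with components `coefficients`
#'   (`v_max`, `k`, `n`), `fitted`, `residuals`, `rss`, `convergence` and the
#'   data. Standard `print()`, `coef()`, `predict()` and `residuals()`
#'   methods apply.
#' @export
fit_naka_rushton <- function(intensity, response) {
  stopifnot(length(intensity) == length(response))
  keep <- intensity > 0
  intensity <- intensity[keep]; response <- response[keep]
  if (length(unique(intensity)) < 4L)
    stop("need at least 4 distinct positive intensities", call. = FALSE)
  if (stats::sd(response) == 0)
    stop("degenerate input: responses are constant, cannot fit", call. = FALSE)

  logI <- log10(intensity)
  vmax0 <- max(response) * 1.05
  ## start K at the intensity whose response is closest to half the ceiling
  k0 <- logI[which.min(abs(response - vmax0 / 2))]
  fn <- function(par) {
    response - naka_rushton(intensity, par[1L], 10^par[2L], par[3L])
  }
  fit <- minpack.lm::nls.lm(
    par = c(vmax = vmax0, log10k = k0, n = 1),
    fn = fn,
    lower = c(1e-12, min(logI) - 6, 0.05),
    upper = c(Inf, max(logI) + 6, 20),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info < 1 || fit$info > 4)
    stop("Naka-Rushton fit did not converge: ", fit$message, call. = FALSE)
  par <- fit$par
  co <- c(v_max = unname(par[1L]), k = unname(10^par[2L]), n = unname(par[3L]))
  fitted <- naka_rushton(intensity, co[["v_max"]], co[["k"]], co[["n"]])
  structure(list(coefficients = co,
                 fitted = fitted,
                 residuals = response - fitted,
                 rss = sum((response - fitted)^2),
                 convergence = fit$info,
                 message = fit$message,
                 intensity = intensity,
                 response = response),
            class = "naka_rushton_fit")
}

#' @export
print.naka_rushton_fit <- function(x, ...) {
  co <- x$coefficients
  cat("Naka-Rushton fit\n")
  cat(sprintf("  V_max = %.4g   K = %.4g   n = %.4g\n",
              co[["v_max"]], co[["k"]], co[["n"]]))
  cat(sprintf("  RSS = %.4g on %d points\n", x$rss, length(x$response)))
  invisible(x)
}

#' @export
coef.naka_rushton_fit <- function(object, ...) object$coefficients

#' @export
residuals.naka_rushton_fit <- function(object, ...) object$residuals

#' @export
predict.naka_rushton_fit <- function(object, newdata = NULL, ...) {
  co <- object$coefficients
  I <- if (is.null(newdata)) object$intensity else as.numeric(newdata)
  naka_rushton(I, co[["v_max"]], co[["k"]], co[["n"]])
}

#' @export
plot.naka_rushton_fit <- function(x, ...) {
  co <- x$coefficients
  logI <- log10(x$intensity)
  graphics::plot(logI, x$response, xlab = "log10 intensity",
                 ylab = "response amplitude", ...)
  xx <- seq(min(logI), max(logI), length.out = 200)
  graphics::lines(xx, naka_rushton(10^xx, co[["v_max"]], co[["k"]], co[["n"]]))
  invisible(x)
}
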