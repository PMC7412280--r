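#' ERG spectral-scan dataset
#'
#' Per-wavelength response amplitudes from repeated spectral scans of the
#' compound eye, together with the calibrated quantum flux of each stimulus.
#' In the reference protocol stimuli are 10-nm-bandwidth flashes from 300 to
#' 700 nm, each adjusted to approximately equal quantum flux
#' (~1e11 photons cm^-2 s^-1), and a bidirectional sweep repeated five times
#' yields ten scans.
#'
#' @param wavelength_nm Stimulus wavelength of each record.
#' @param scan Integer scan identifier.
#' @param amplitude Non-negative response amplitude.
#' @param flux Quantum flux of the stimulus at that wavelength
#'   (photons cm^-2 s^-1).
#' @return Object of class `erg_dataset` (a data frame with those columns).
#' @export
erg_dataset <- function(wavelength_nm, scan, amplitude, flux) {
  d <- data.frame(wavelength_nm = as.numeric(wavelength_nm),
                  scan = as.integer(scan),
                  amplitude = as.numeric(amplitude),
                  flux = as.numeric(flux))
  if (any(d$amplitude < 0))
    stop("ERG amplitudes must be non-negative", call. = FALSE)
  if (any(d$flux <= 0))
    stop("quantum flux must be positive", call. = FALSE)
  wl_by_scan <- tapply(d$wavelength_nm, d$scan, function(w) sort(unique(w)))
  if (length(unique(vapply(wl_by_scan, paste, collapse = ",",
                           FUN.VALUE = ""))) != 1L)
    stop("all scans must share one wavelength set", call. = FALSE)
  class(d) <- c("erg_dataset", "data.frame")
  d
}

#' @export
print.erg_dataset <- function(x, ...) {
  cat(sprintf("<erg_dataset: %d wavelengths x %d scans>\n",
              length(unique(x$wavelength_nm)), length(unique(x$scan))))
  invisible(x)
}

#' Spectral sensitivity from ERG amplitudes
#'
#' Converts per-wavelength response amplitudes into a spectral sensitivity
#' curve: each mean amplitude is mapped through the inverse Naka-Rushton
#' function to the equivalent stimulus intensity, divided by the delivered
#' quantum flux, and the resulting relative sensitivities are normalized to a
#' maximum of 1. This is the reciprocal-intensity construction: a wavelength
#' that reaches the criterion (half-maximal) response at a lower intensity is
#' proportionally more sensitive. Zero amplitudes map to zero sensitivity;
#' amplitudes at or above `V_max` raise a saturation error.
#'
#' @param d An [erg_dataset].
#' @param params A [fit_naka_rushton()] result, or a named list/vector with
#'   `v_max`, `k`, `n`.
#' @return Object of class `sensitivity_curve`: a list with `spectrum` (a
#'   [spectrum] of kind `sensitivity`, values in \[0, 1\]), `dispersion`
#'   (per-wavelength SD of per-scan sensitivities on the normalized scale),
#'   `n_scans` and a `metadata` record of the criterion convention.
#' @export
sensitivity_from_erg <- function(d, params) {
  stopifnot(inherits(d, "erg_dataset"))
  co <- if (inherits(params, "naka_rushton_fit")) params$coefficients
        else unlist(params)
  v_max <- co[["v_max"]]; k <- co[["k"]]; n <- co[["n"]]

  sens_one <- function(amp, flux) {
    s <- numeric(length(amp))
    pos <- amp > 0
    if (any(amp >= v_max))
      stop("saturated ERG response (amplitude >= V_max); cannot invert",
           call. = FALSE)
    s[pos] <- 10^naka_rushton_inverse(amp[pos], v_max, k, n) / flux[pos]
    s
  }

  agg <- stats::aggregate(cbind(amplitude, flux) ~ wavelength_nm, data = d,
                          FUN = mean)
  agg <- agg[order(agg$wavelength_nm), ]
  s_mean <- sens_one(agg$amplitude, agg$flux)
  smax <- max(s_mean)
  if (smax <= 0) stop("all responses zero: no sensitivity", call. = FALSE)
  s_norm <- s_mean / smax

  scans <- sort(unique(d$scan))
  n_scans <- length(scans)
  disp <- se <- rep(NA_real_, nrow(agg))
  if (n_scans > 1L) {
    ## per-scan normalized sensitivities (NA where a scan saturates/zeroes)
    per_scan <- vapply(scans, function(sc) {
      di <- d[d$scan == sc, ]
      di <- di[order(di$wavelength_nm), ]
      s <- rep(NA_real_, nrow(di))
      ok <- di$amplitude > 0 & di$amplitude < v_max
      s[ok] <- 10^naka_rushton_inverse(di$amplitude[ok], v_max, k, n) /
        di$flux[ok] / smax
      s[di$amplitude == 0] <- 0
      s
    }, numeric(nrow(agg)))
    disp <- apply(per_scan, 1L, stats::sd, na.rm = TRUE)
    ## The additive amplitude noise is (near) homoscedastic; pool its spread
    ## and propagate through the Naka-Rushton inverse by the delta method,
    ## ds/dV = s * V_max / (n * V * (V_max - V)), for the SE of each mean.
    amp_sd <- as.numeric(tapply(d$amplitude, d$wavelength_nm, stats::sd))
    sigma_v <- sqrt(mean(amp_sd^2)) / sqrt(n_scans)
    v <- agg$amplitude
    pos <- v > 0
    se[pos] <- sigma_v * s_norm[pos] * v_max / (n * v[pos] * (v_max - v[pos]))
    se[!pos] <- max(se[pos])       # zero response: sensitivity poorly resolved
  }

  structure(list(spectrum = spectrum(agg$wavelength_nm, s_norm, "sensitivity"),
                 dispersion = disp,
                 se = se,
                 n_scans = n_scans,
                 metadata = list(criterion = "half-maximal response",
                                 naka_rushton = co)),
            class = "sensitivity_curve")
}

#' @export
print.sensitivity_curve <- function(x, ...) {
  wl <- x$spectrum$wavelength_nm
  cat(sprintf("<sensitivity_curve: %d wavelengths, peak at %g nm, %d scan(s)>\n",
              length(wl), wl[which.max(x$spectrum$value)], x$n_scans))
  invisible(x)
}

#' @export
plot.sensitivity_curve <- function(x, ...) {
  plot(x$spectrum, ylab = "relative sensitivity", ...)
  invisible(x)
}

## weighted residuals between an observed curve and a candidate receptor set
.receptor_residuals <- function(par, grid, obs, w, family, beta_band) {
  rs <- receptor_set(lambda_max_nm = par[1:3],
                     amplitudes = c(1, par[4L], par[5L]),
                     family = family, beta_band = beta_band)
  ## par[6] is a free overall scale: the observed curve is normalized by its
  ## noisy maximum, so pinning the model to exactly 1 at the green peak would
  ## bias every other parameter.
  w * (obs - par[6L] * composite_sensitivity(rs, grid)$value)
}

#' Decompose a spectral sensitivity curve into three pigment templates
#'
#' Fits the peak wavelengths and relative amplitudes of a UV/blue/green
#' pigment triple so that their amplitude-weighted template sum (normalized at
#' the green peak) reproduces the measured curve, by bounded
#' Levenberg-Marquardt least squares. Box bounds of \[310, 390\],
#' \[400, 480\] and \[490, 620\] nm keep the three receptors in their
#' spectral classes and prevent label swapping; amplitudes are constrained
#' non-negative. Because the composite is scale-free, the S amplitude is fixed
#' at 1 and amplitudes are reported as a ratio to it.
#'
#' When the input is a [sensitivity_curve] carrying per-scan information,
#' residuals are weighted by the reciprocal standard error of each mean
#' sensitivity: the Naka-Rushton inversion makes noise strongly
#' heteroscedastic (near-saturated responses at the peak invert to much
#' noisier sensitivities than mid-range responses), and unweighted least
#' squares would let the noisy peak region drown out the weakly expressed
#' blue receptor. A free overall scale multiplies the composite during
#' fitting, because the observed curve is normalized by its noisy maximum;
#' amplitude ratios are unaffected.
#'
#' @param curve A [sensitivity_curve], or a [spectrum] of kind `sensitivity`.
#' @param init A [receptor_set] giving starting values; defaults to peaks at
#'   355/440/540 nm (the curve's two visible maxima plus a blue start), flat
#'   amplitude guesses.
#' @param weights Optional per-wavelength residual weights. `NULL` (default)
#'   uses inverse standard errors from the curve's scan dispersion when
#'   available, otherwise equal weights.
#' @param weber_fractions Carried through unchanged into the fitted set.
#' @param family Template family tag (default `"auto"`: Stavenga below 400 nm,
#'   Govardovskii above).
#' @param beta_band Length-3 logical, per pigment.
#' @param lower,upper Per-receptor lambda_max bounds (length-3 each).
#' @return Object of class `receptor_fit` with the fitted [receptor_set],
#'   coefficient table with standard errors and 95% CIs, residuals, RSS and
#'   convergence info. Methods: `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot`.
#' @export
fit_receptor_set <- function(curve,
                             init = receptor_set(lambda_max_nm = c(355, 440, 540),
                                                 amplitudes = c(1, 1, 5)),
                             weber_fractions = c(0.13, 0.06, 0.12),
                             family = "auto",
                             beta_band = c(FALSE, FALSE, TRUE),
                             lower = c(310, 400, 490),
                             upper = c(390, 480, 620),
                             weights = NULL) {
  sp <- if (inherits(curve, "sensitivity_curve")) curve$spectrum else curve
  stopifnot(inherits(sp, "spectrum"))
  if (any(diff(init$lambda_max_nm) <= 0))
    stop("initial lambda_max must be ordered S < M < L", call. = FALSE)
  grid <- sp$wavelength_nm
  obs <- sp$value
  if (is.null(weights)) {
    se <- if (inherits(curve, "sensitivity_curve")) curve$se else NULL
    if (!is.null(se) && !anyNA(se) && any(se > 0)) {
      se <- pmax(se, 0.05 * stats::median(se[se > 0]))  # floor runaway weights
      weights <- 1 / se
    } else {
      weights <- rep(1, length(obs))
    }
  }
  weights <- weights / mean(weights)
  stopifnot(length(weights) == length(obs), all(weights >= 0))

  a0 <- init$amplitudes / init$amplitudes[1L]
  par0 <- c(init$lambda_max_nm, a0[2L], a0[3L], 1)
  fit <- minpack.lm::nls.lm(
    par = par0,
    fn = .receptor_residuals,
    lower = c(lower, 0, 0, 1e-6),
    upper = c(upper, Inf, Inf, Inf),
    grid = grid, obs = obs, w = weights, family = family,
    beta_band = beta_band,
    control = minpack.lm::nls.lm.control(maxiter = 400))
  if (fit$info < 1 || fit$info > 4)
    stop("receptor-set fit did not converge: ", fit$message, call. = FALSE)
  par <- fit$par
  if (any(diff(par[1:3]) <= 0))
    stop("fitted lambda_max not ordered S < M < L", call. = FALSE)

  rs <- receptor_set(lambda_max_nm = par[1:3],
                     amplitudes = c(1, par[4L], par[5L]),
                     weber_fractions = weber_fractions,
                     family = family, beta_band = beta_band)
  fitted_v <- par[6L] * composite_sensitivity(rs, grid)$value
  resid <- obs - fitted_v
  rss <- sum(fit$fvec^2)   # weighted RSS, the minimized objective
  dof <- max(length(obs) - length(par), 1L)
  sigma2 <- rss / dof
  ## covariance from the LM-scaled Jacobian; guard singular hessians
  vc <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, 6L) else sqrt(pmax(diag(vc), 0))
  tcrit <- stats::qt(0.975, dof)
  coefs <- data.frame(
    parameter = c("lambda_max_S", "lambda_max_M", "lambda_max_L",
                  "amplitude_M", "amplitude_L", "scale"),
    estimate = par,
    se = se,
    ci_lower = par - tcrit * se,
    ci_upper = par + tcrit * se)

  structure(list(receptor_set = rs,
                 coefficients = coefs,
                 residuals = resid,
                 fitted = fitted_v,
                 weights = weights,
                 grid = grid,
                 observed = obs,
                 rss = rss,
                 convergence = fit$info,
                 message = fit$message,
                 niter = fit$niter,
                 metadata = list(family = family, beta_band = beta_band,
                                 amplitude_reference = "S fixed at 1")),
            class = "receptor_fit")
}

#' @export
print.receptor_fit <- function(x, ...) {
  l <- x$receptor_set$lambda_max_nm
  a <- x$receptor_set$amplitudes
  cat("Trichromatic receptor-set fit\n")
  cat(sprintf("  lambda_max (S,M,L): %.1f, %.1f, %.1f nm\n", l[1L], l[2L], l[3L]))
  cat(sprintf("  amplitude ratio   : 1 : %.3g : %.3g\n", a[2L], a[3L]))
  cat(sprintf("  RSS = %.4g on %d wavelengths\n", x$rss, length(x$grid)))
  invisible(x)
}

#' @export
summary.receptor_fit <- function(object, ...) {
  structure(list(coefficients = object$coefficients,
                 rss = object$rss,
                 n = length(object$grid),
                 convergence = object$convergence,
                 message = object$message,
                 metadata = object$metadata),
            class = "summary.receptor_fit")
}

#' @export
print.summary.receptor_fit <- function(x, ...) {
  cat("Trichromatic receptor-set fit\n\n")
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("\nRSS %.4g on %d wavelengths; LM status %d (%s)\n",
              x$rss, x$n, x$convergence, x$message))
  invisible(x)
}

#' @export
coef.receptor_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$parameter)
}

#' @export
fitted.receptor_fit <- function(object, ...) object$fitted

#' @export
residuals.receptor_fit <- function(object, ...) object$residuals

#' @export
predict.receptor_fit <- function(object, grid = NULL, ...) {
  if (is.null(grid)) grid <- object$grid
  composite_sensitivity(object$receptor_set, grid)
}

#' @export
plot.receptor_fit <- function(x, ...) {
  graphics::plot(x$grid, x$observed, xlab = "wavelength (nm)",
                 ylab = "relative sensitivity", ...)
  graphics::lines(x$grid, x$fitted)
  invisible(x)
}
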