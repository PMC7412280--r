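## Visual-pigment nomogram templates.
##
## Constants are taken verbatim from the cited template literature:
##  - Stavenga, Smits & Hoenders (1993, Vision Res 33) modified-lognormal
##    bands: alpha a = 380, b = 6.09, c = 3 b^2 / 8; beta band at 340 nm with
##    amplitude 0.29, a = 247, b = 3.59, c = 3 b^2 / 8.
##  - Govardovskii et al. (2000, Vis Neurosci 17) A1 alpha band
##    (A = 69.7, B = 28, C = -14.9, D = 0.674, b = 0.922, c = 1.104,
##    a = 0.8795 + 0.0459 exp(-(lmax - 300)^2 / 11940)) and beta band
##    (A_beta = 0.26, lmax_beta = 189 + 0.315 lmax, width = -40.5 + 0.195 lmax).
## Alpha bands are renormalized so the template equals exactly 1 at lmax.

.stavenga_band <- function(lambda, lmax, a, b) {
  x <- log10(lambda / lmax)
  cc <- 3 * b^2 / 8
  exp(-a * x^2 * (1 + b * x + cc * x^2))
}

.stavenga_alpha <- function(lambda, lmax) .stavenga_band(lambda, lmax, 380, 6.09)

.stavenga_beta <- function(lambda) 0.29 * .stavenga_band(lambda, 340, 247, 3.59)

.govardovskii_alpha <- function(lambda, lmax) {
  x <- lmax / lambda
  a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
  1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
         exp(-14.9 * (1.104 - x)) + 0.674)
}

.govardovskii_beta <- function(lambda, lmax) {
  lmb <- 189 + 0.315 * lmax
  bw <- -40.5 + 0.195 * lmax
  0.26 * exp(-((lambda - lmb) / bw)^2)
}

resolve_family <- function(family, lambda_max) {
  if (family == "auto") {
    if (lambda_max < 400) "stavenga" else "govardovskii"
  } else family
}

#' Visual pigment defined by a nomogram template
#'
#' A pigment is a peak wavelength plus a template family. With
#' `family = "auto"` the Stavenga (1993) formulae are used below 400 nm and
#' the Govardovskii (2000) A1 nomogram above, following the physiological
#' convention for UV versus blue/green pigments.
#'
#' @param lambda_max_nm Peak wavelength of the alpha band, strictly inside
#'   (300, 700) nm.
#' @param family `"auto"`, `"stavenga"` or `"govardovskii"`.
#' @param beta_band Logical; add the template's UV-shoulder beta band.
#' @return Object of class `pigment`.
#' @export
pigment <- function(lambda_max_nm,
                    family = c("auto", "stavenga", "govardovskii"),
                    beta_band = FALSE) {
  family <- match.arg(family)
  stopifnot(is.numeric(lambda_max_nm), length(lambda_max_nm) == 1L)
  if (lambda_max_nm <= 300 || lambda_max_nm >= 700)
    stop("lambda_max must lie strictly inside (300, 700) nm", call. = FALSE)
  structure(list(lambda_max_nm = lambda_max_nm,
                 family = family,
                 resolved_family = resolve_family(family, lambda_max_nm),
                 beta_band = isTRUE(beta_band)),
            class = "pigment")
}

#' @export
print.pigment <- function(x, ...) {
  cat(sprintf("<pigment: lambda_max %g nm, %s template%s>\n",
              x$lambda_max_nm, x$resolved_family,
              if (x$beta_band) " + beta band" else ""))
  invisible(x)
}

#' Evaluate a pigment template
#'
#' Returns the unitless absorbance of the pigment's nomogram template at the
#' given wavelengths. The alpha band is normalized to exactly 1 at
#' `lambda_max`; the optional beta band is added on top, so values may exceed
#' 1 in the UV for long-wavelength pigments.
#'
#' @param p A [pigment].
#' @param lambda_nm Wavelengths in \[300, 700\] nm (vectorized).
#' @return Numeric vector of non-negative template values.
#' @export
template_value <- function(p, lambda_nm) {
  stopifnot(inherits(p, "pigment"))
  if (any(lambda_nm < 300 | lambda_nm > 700))
    stop("template evaluated outside [300, 700] nm", call. = FALSE)
  lmax <- p$lambda_max_nm
  if (p$resolved_family == "stavenga") {
    v <- .stavenga_alpha(lambda_nm, lmax)       # exactly 1 at lmax
    if (p$beta_band) v <- v + .stavenga_beta(lambda_nm)
  } else {
    v <- .govardovskii_alpha(lambda_nm, lmax) / .govardovskii_alpha(lmax, lmax)
    if (p$beta_band) v <- v + .govardovskii_beta(lambda_nm, lmax)
  }
  pmax(v, 0)
}

#' Pigment template as a spectrum
#'
#' @param p A [pigment].
#' @param grid Wavelength grid (default [canonical_grid()]).
#' @return A [spectrum] of kind `sensitivity`.
#' @export
pigment_spectrum <- function(p, grid = canonical_grid()) {
  spectrum(grid, template_value(p, grid), "sensitivity")
}

#' A trichromatic receptor set
#'
#' Bundles the three photoreceptor pigments (UV/S, blue/M, green/L), their
#' relative amplitudes in the composite eye response, and the Weber fractions
#' that weight each channel in the receptor-noise-limited model. Defaults are
#' the fitted leafhopper set: peaks at 356/435/542 nm with amplitude ratio
#' 1:0.6:6.4, and the standard honeybee Weber fractions (0.13, 0.06, 0.12),
#' since the study organism's own channel noise has not been measured.
#'
#' @param lambda_max_nm Length-3 numeric, strictly increasing (S < M < L).
#' @param amplitudes Length-3 non-negative weights, not all zero.
#' @param weber_fractions Length-3 positive Weber fractions (omega_S, omega_M,
#'   omega_L).
#' @param family Template family tag passed to [pigment()].
#' @param beta_band Length-3 logical; by default only the L pigment carries a
#'   beta band (the UV shoulder that gives green receptors residual
#'   long-wavelength-complementary sensitivity).
#' @return Object of class `receptor_set`.
#' @export
receptor_set <- function(lambda_max_nm = c(356, 435, 542),
                         amplitudes = c(1, 0.6, 6.4),
                         weber_fractions = c(0.13, 0.06, 0.12),
                         family = "auto",
                         beta_band = c(FALSE, FALSE, TRUE)) {
  stopifnot(length(lambda_max_nm) == 3L, length(amplitudes) == 3L,
            length(weber_fractions) == 3L, length(beta_band) == 3L)
  if (any(diff(lambda_max_nm) <= 0))
    stop("pigment lambda_max must be strictly increasing (S < M < L); ",
         "coincident peaks are not identifiable", call. = FALSE)
  if (any(amplitudes < 0) || all(amplitudes == 0))
    stop("amplitudes must be non-negative and not all zero", call. = FALSE)
  if (any(weber_fractions <= 0))
    stop("Weber fractions must be positive", call. = FALSE)
  pigs <- mapply(function(l, b) pigment(l, family, b),
                 lambda_max_nm, beta_band, SIMPLIFY = FALSE)
  names(pigs) <- c("S", "M", "L")
  structure(list(pigments = pigs,
                 lambda_max_nm = as.numeric(lambda_max_nm),
                 amplitudes = as.numeric(amplitudes),
                 weber_fractions = as.numeric(weber_fractions)),
            class = "receptor_set")
}

#' @export
print.receptor_set <- function(x, ...) {
  cat("<receptor_set>\n")
  cat(sprintf("  lambda_max (S,M,L): %g, %g, %g nm\n",
              x$lambda_max_nm[1L], x$lambda_max_nm[2L], x$lambda_max_nm[3L]))
  a <- x$amplitudes
  cat(sprintf("  amplitude ratio   : %.3g : %.3g : %.3g\n",
              1, a[2L] / a[1L], a[3L] / a[1L]))
  cat(sprintf("  Weber fractions   : %.3g, %.3g, %.3g\n",
              x$weber_fractions[1L], x$weber_fractions[2L],
              x$weber_fractions[3L]))
  invisible(x)
}

#' Composite spectral sensitivity of a receptor set
#'
#' Amplitude-weighted sum of the three pigment templates, renormalized so the
#' curve equals 1 at the longest-wavelength pigment's peak. Because of that
#' renormalization the composite depends only on amplitude ratios, not on
#' their absolute scale.
#'
#' @param rs A [receptor_set].
#' @param grid Wavelength grid (default [canonical_grid()]).
#' @return A [spectrum] of kind `sensitivity`.
#' @export
composite_sensitivity <- function(rs, grid = canonical_grid()) {
  stopifnot(inherits(rs, "receptor_set"))
  v <- numeric(length(grid))
  at_peak <- 0
  lmax_L <- rs$lambda_max_nm[3L]
  for (j in 1:3) {
    tv <- template_value(rs$pigments[[j]], grid)
    v <- v + rs$amplitudes[j] * tv
    at_peak <- at_peak + rs$amplitudes[j] *
      template_value(rs$pigments[[j]], lmax_L)
  }
  spectrum(grid, v / at_peak, "sensitivity")
}
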