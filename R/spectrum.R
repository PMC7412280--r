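#' Spectral data objects
#'
#' A `spectrum` is the unit of all optical computation in leafvision: a set of
#' values tabulated on a strictly ascending wavelength grid inside 300--700 nm.
#' The `kind` tag records what the values mean; most operations check it.
#'
#' @param wavelength_nm Numeric vector, strictly ascending, within
#'   \[300, 700\] nm.
#' @param value Numeric vector of the same length. Negative entries (raw
#'   instrument noise) are clipped to zero with a warning.
#' @param kind One of `"raw"`, `"white_standard"`, `"normalized_reflectance"`,
#'   `"sensitivity"`, `"illuminant"`. Normalized reflectance is expressed in
#'   percent.
#'
#' @return An object of class `spectrum`: a list with elements
#'   `wavelength_nm`, `value` and `kind`.
#' @examples
#' s <- spectrum(300:700, rep(50, 401), "normalized_reflectance")
#' reflectance_intensity(s)
#' @export
spectrum <- function(wavelength_nm, value,
                     kind = c("raw", "white_standard", "normalized_reflectance",
                              "sensitivity", "illuminant")) {
  kind <- match.arg(kind)
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  if (length(wavelength_nm) < 2L)
    stop("a spectrum needs at least two wavelengths", call. = FALSE)
  if (length(wavelength_nm) != length(value))
    stop("wavelength and value lengths differ", call. = FALSE)
  if (anyNA(wavelength_nm) || anyNA(value))
    stop("NA in spectrum data", call. = FALSE)
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly ascending", call. = FALSE)
  if (wavelength_nm[1L] < 300 || wavelength_nm[length(wavelength_nm)] > 700)
    stop("wavelength grid must lie within [300, 700] nm", call. = FALSE)
  if (any(value < 0)) {
    warning(sprintf("%d negative value(s) clipped to 0", sum(value < 0)),
            call. = FALSE)
    value[value < 0] <- 0
  }
  structure(list(wavelength_nm = wavelength_nm, value = value, kind = kind),
            class = "spectrum")
}

#' Canonical wavelength grid
#'
#' All cross-spectrum operations happen on this grid: 300 to 700 nm inclusive
#' in 1-nm steps. The source instrumentation reports only the range; the 1-nm
#' step is the package's tabulation choice.
#'
#' @return Integer-valued numeric vector `300:700`.
#' @export
canonical_grid <- function() as.numeric(300:700)

#' @export
print.spectrum <- function(x, ...) {
  wl <- x$wavelength_nm
  cat(sprintf("<spectrum: %s, %d points, %g-%g nm, values %.4g-%.4g>\n",
              x$kind, length(wl), wl[1L], wl[length(wl)],
              min(x$value), max(x$value)))
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ...,
                          xlab = "wavelength (nm)", ylab = x$kind,
                          type = "l") {
  graphics::plot(x$wavelength_nm, x$value,
                 xlab = xlab, ylab = ylab, type = type, ...)
  invisible(x)
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; the target grid must lie within the span of the
#' source grid (no extrapolation).
#'
#' @param s A [spectrum].
#' @param grid Target wavelength grid (strictly ascending numeric).
#' @return A [spectrum] on `grid` with the same `kind`.
#' @export
resample <- function(s, grid = canonical_grid()) {
  stopifnot(inherits(s, "spectrum"))
  grid <- as.numeric(grid)
  src <- s$wavelength_nm
  if (min(grid) < src[1L] || max(grid) > src[length(src)])
    stop(sprintf("target grid [%g, %g] outside source span [%g, %g]",
                 min(grid), max(grid), src[1L], src[length(src)]),
         call. = FALSE)
  v <- stats::approx(src, s$value, xout = grid, method = "linear")$y
  spectrum(grid, v, s$kind)
}

#' White-standard normalization of a reflectance spectrum
#'
#' Converts raw sample counts `S(lambda)` to normalized reflectance in percent
#' against a white standard `L(lambda)`:
#' `R(lambda) = S(lambda) / L(lambda) * 100`.
#'
#' @param sample_spec Raw sample [spectrum].
#' @param white White-standard [spectrum] on the same grid; must be strictly
#'   positive everywhere.
#' @return A [spectrum] with `kind = "normalized_reflectance"`.
#' @export
normalize_reflectance <- function(sample_spec, white) {
  stopifnot(inherits(sample_spec, "spectrum"), inherits(white, "spectrum"))
  if (!isTRUE(all.equal(sample_spec$wavelength_nm, white$wavelength_nm)))
    stop("sample and white standard must share one wavelength grid",
         call. = FALSE)
  bad <- which(white$value <= 0)
  if (length(bad))
    stop(sprintf("white standard non-positive at %g nm",
                 white$wavelength_nm[bad[1L]]), call. = FALSE)
  spectrum(sample_spec$wavelength_nm,
           sample_spec$value / white$value * 100,
           "normalized_reflectance")
}

## trapezoidal integral of a spectrum over its full grid
trapz_spectrum <- function(s) {
  pracma::trapz(s$wavelength_nm, s$value)
}

#' Normalized reflectance intensity
#'
#' The integral of normalized reflectance over the 300--700 nm range,
#' approximated by the trapezoidal rule on the spectrum's grid. Units are
#' percent x nm.
#'
#' @param r A [spectrum] of kind `normalized_reflectance` whose grid spans
#'   300--700 nm.
#' @return Scalar intensity.
#' @export
reflectance_intensity <- function(r) {
  stopifnot(inherits(r, "spectrum"))
  if (r$kind != "normalized_reflectance")
    stop("reflectance_intensity expects a normalized reflectance spectrum",
         call. = FALSE)
  wl <- r$wavelength_nm
  if (wl[1L] > 300 || wl[length(wl)] < 700)
    stop("grid does not span 300-700 nm", call. = FALSE)
  trapz_spectrum(r)
}

#' Replicate series of spectra for one leaf
#'
#' Groups replicate measurements of one leaf (numbered `i` from the top of the
#' shoot downward) and stores their pointwise arithmetic mean. Replicates must
#' share one wavelength grid; averaging happens after normalization, since the
#' white-standard conversion is defined per measurement.
#'
#' @param leaf_index Integer leaf number (1 = first leaf below the bud).
#' @param replicates List of [spectrum] objects on one shared grid.
#' @return Object of class `leaf_series` with elements `leaf_index`,
#'   `replicates` and `mean_spectrum`.
#' @export
leaf_series <- function(leaf_index, replicates) {
  leaf_index <- as.integer(leaf_index)
  stopifnot(length(leaf_index) == 1L, leaf_index >= 1L,
            is.list(replicates), length(replicates) >= 1L)
  grid <- replicates[[1L]]$wavelength_nm
  for (r in replicates) {
    stopifnot(inherits(r, "spectrum"))
    if (!isTRUE(all.equal(r$wavelength_nm, grid)))
      stop("all replicates must share one wavelength grid", call. = FALSE)
  }
  vals <- vapply(replicates, function(r) r$value, numeric(length(grid)))
  m <- if (is.matrix(vals)) rowMeans(vals) else vals
  structure(list(leaf_index = leaf_index,
                 replicates = replicates,
                 mean_spectrum = spectrum(grid, m, replicates[[1L]]$kind)),
            class = "leaf_series")
}

#' @export
print.leaf_series <- function(x, ...) {
  cat(sprintf("<leaf_series: leaf %d, %d replicate(s)>\n",
              x$leaf_index, length(x$replicates)))
  invisible(x)
}

#' Flat (equal-energy) illuminant on a grid
#'
#' @param grid Wavelength grid.
#' @param value Constant spectral value (default 1).
#' @return A [spectrum] with `kind = "illuminant"`.
#' @export
flat_illuminant <- function(grid = canonical_grid(), value = 1) {
  spectrum(grid, rep(value, length(grid)), "illuminant")
}
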