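#' Photoreceptor quantum catch
#'
#' The effective photon capture of one receptor channel viewing a surface:
#' the integral over 300--700 nm of receptor sensitivity x surface reflectance
#' x illuminant, by the trapezoidal rule on the shared grid.
#'
#' @param q Receptor sensitivity [spectrum].
#' @param r Reflectance [spectrum].
#' @param illum Illuminant [spectrum] (default flat equal-energy).
#' @return Scalar catch (unitless, illuminant-scaled).
#' @export
quantum_catch <- function(q, r, illum = flat_illuminant(q$wavelength_nm)) {
  stopifnot(inherits(q, "spectrum"), inherits(r, "spectrum"),
            inherits(illum, "spectrum"))
  if (!isTRUE(all.equal(q$wavelength_nm, r$wavelength_nm)) ||
      !isTRUE(all.equal(q$wavelength_nm, illum$wavelength_nm)))
    stop("sensitivity, reflectance and illuminant must share one grid",
         call. = FALSE)
  pracma::trapz(q$wavelength_nm, q$value * r$value * illum$value)
}

#' Log-ratio receptor contrast between two stimuli
#'
#' The signed per-channel contrast `ln(Q_a / Q_b)` between the quantum
#' catches of the same receptor viewing two surfaces.
#'
#' @param q_a,q_b Strictly positive catches (vectorized).
#' @return Signed log-ratio contrast.
#' @export
receptor_contrast <- function(q_a, q_b) {
  if (any(q_a <= 0) || any(q_b <= 0))
    stop("quantum catches must be strictly positive", call. = FALSE)
  log(q_a) - log(q_b)
}

#' Receptor-noise-limited chromatic contrast
#'
#' Combines the three per-channel contrasts into a single chromatic distance
#' in just-noticeable-difference units, weighted by the channel Weber
#' fractions:
#' \deqn{\Delta S = \sqrt{\frac{\omega_S^2(\Delta f_L-\Delta f_M)^2 +
#'   \omega_M^2(\Delta f_L-\Delta f_S)^2 + \omega_L^2(\Delta f_M-\Delta f_S)^2}
#'  {(\omega_S\omega_M)^2 + (\omega_S\omega_L)^2 + (\omega_M\omega_L)^2}}}
#' Only pairwise differences of the channel contrasts enter, so a uniform
#' intensity change (which shifts all channels equally) contributes nothing.
#'
#' @param df Length-3 numeric of channel contrasts `(df_S, df_M, df_L)`.
#' @param weber_fractions Length-3 positive Weber fractions
#'   `(omega_S, omega_M, omega_L)`.
#' @return Non-negative `delta_S` in JND units.
#' @export
chromatic_contrast <- function(df, weber_fractions = c(0.13, 0.06, 0.12)) {
  stopifnot(length(df) == 3L, length(weber_fractions) == 3L)
  w <- weber_fractions
  if (any(w <= 0)) stop("Weber fractions must be positive", call. = FALSE)
  num <- w[1L]^2 * (df[3L] - df[2L])^2 +
         w[2L]^2 * (df[3L] - df[1L])^2 +
         w[3L]^2 * (df[2L] - df[1L])^2
  den <- (w[1L] * w[2L])^2 + (w[1L] * w[3L])^2 + (w[2L] * w[3L])^2
  sqrt(num / den)
}

#' Michelson achromatic contrast
#'
#' `C = (Q_max - Q_min) / (Q_max + Q_min)` between the achromatic-channel
#' catches of two surfaces; bounded in \[0, 1\] and invariant to joint
#' rescaling.
#'
#' @param q_a,q_b Non-negative catches, not both zero.
#' @return Contrast in \[0, 1\].
#' @export
michelson_contrast <- function(q_a, q_b) {
  if (q_a < 0 || q_b < 0) stop("catches must be non-negative", call. = FALSE)
  if (q_a == 0 && q_b == 0)
    stop("both catches zero: contrast undefined", call. = FALSE)
  (max(q_a, q_b) - min(q_a, q_b)) / (q_a + q_b)
}

#' Default discrimination thresholds
#'
#' The honeybee-derived criteria used throughout: chromatic discrimination is
#' considered impossible below 2.3 JND, intensity discrimination below a
#' Michelson contrast of 0.08.
#'
#' @return Named numeric `c(delta_s = 2.3, michelson = 0.08)`.
#' @export
default_thresholds <- function() c(delta_s = 2.3, michelson = 0.08)

.mean_spectrum <- function(x) {
  if (inherits(x, "leaf_series")) x$mean_spectrum
  else if (inherits(x, "spectrum")) x
  else stop("expected a spectrum or leaf_series", call. = FALSE)
}

## catches of the three channels for one reflectance spectrum
.catch_triple <- function(r, rs, illum) {
  grid <- r$wavelength_nm
  vapply(1:3, function(j) {
    quantum_catch(pigment_spectrum(rs$pigments[[j]], grid), r,
                  resample(illum, grid))
  }, numeric(1L))
}

## achromatic-channel catch under the configured convention
.achromatic_catch <- function(r, rs, illum, channel) {
  switch(channel,
         L = .catch_triple(r, rs, illum)[3L],
         composite = quantum_catch(composite_sensitivity(rs, r$wavelength_nm),
                                   r, resample(illum, r$wavelength_nm)),
         intensity = trapz_spectrum(r),
         stop("unknown achromatic channel: ", channel, call. = FALSE))
}

#' Chromatic and achromatic discriminability of a leaf pair
#'
#' Runs the full receptor-noise-limited comparison of two reflectance spectra:
#' quantum catches per channel, log-ratio contrasts, chromatic `delta_S`,
#' Michelson `C` on the achromatic channel, and threshold calls.
#'
#' @param leaf_a,leaf_b [leaf_series] objects (their mean spectra are used) or
#'   plain reflectance [spectrum] objects.
#' @param rs A [receptor_set].
#' @param illum Illuminant [spectrum]; default flat equal-energy.
#' @param thresholds Named numeric with `delta_s` and `michelson` entries.
#' @param achromatic_channel `"L"` (green-receptor catch, the default, as
#'   long-wavelength receptors dominate achromatic vision in the honeybee
#'   framework), `"composite"` (catch through the composite sensitivity) or
#'   `"intensity"` (integrated reflectance itself).
#' @return Object of class `discrimination`: pair indices, `delta_s`,
#'   `michelson_c`, `chromatic_call` (`delta_s >=` threshold),
#'   `achromatic_call` (`C >=` threshold), catches and settings.
#' @export
discriminate_pair <- function(leaf_a, leaf_b, rs = receptor_set(),
                              illum = flat_illuminant(),
                              thresholds = default_thresholds(),
                              achromatic_channel = c("L", "composite",
                                                     "intensity")) {
  achromatic_channel <- match.arg(achromatic_channel)
  ra <- .mean_spectrum(leaf_a); rb <- .mean_spectrum(leaf_b)
  if (!isTRUE(all.equal(ra$wavelength_nm, rb$wavelength_nm)))
    stop("the two spectra must share one grid", call. = FALSE)
  qa <- .catch_triple(ra, rs, illum)
  qb <- .catch_triple(rb, rs, illum)
  df <- receptor_contrast(qa, qb)
  ds <- chromatic_contrast(df, rs$weber_fractions)
  ca <- .achromatic_catch(ra, rs, illum, achromatic_channel)
  cb <- .achromatic_catch(rb, rs, illum, achromatic_channel)
  cm <- michelson_contrast(ca, cb)
  structure(list(
    pair = c(a = if (inherits(leaf_a, "leaf_series")) leaf_a$leaf_index else NA,
             b = if (inherits(leaf_b, "leaf_series")) leaf_b$leaf_index else NA),
    delta_s = ds,
    michelson_c = cm,
    chromatic_call = ds >= thresholds[["delta_s"]],
    achromatic_call = cm >= thresholds[["michelson"]],
    catches = rbind(a = qa, b = qb),
    achromatic_catches = c(a = ca, b = cb),
    thresholds = thresholds,
    achromatic_channel = achromatic_channel),
    class = "discrimination")
}

#' @export
print.discrimination <- function(x, ...) {
  cat(sprintf(
    "<discrimination: delta_S = %.3f (%s), C = %.3f (%s)>\n",
    x$delta_s, if (x$chromatic_call) "chromatic" else "below threshold",
    x$michelson_c, if (x$achromatic_call) "achromatic" else "below threshold"))
  invisible(x)
}

#' Pairwise discrimination matrices over a leaf series
#'
#' Computes symmetric `delta_S` and Michelson-`C` matrices (and the
#' corresponding threshold-call matrices) over every pair of leaves.
#'
#' @param series List of [leaf_series] (or reflectance [spectrum]) objects.
#' @inheritParams discriminate_pair
#' @return Object of class `discrimination_matrix` with matrices `delta_s`,
#'   `michelson_c`, `chromatic_call`, `achromatic_call`, plus settings.
#'   Use [vs_reference()] for the row against one reference leaf.
#' @export
discrimination_matrix <- function(series, rs = receptor_set(),
                                  illum = flat_illuminant(),
                                  thresholds = default_thresholds(),
                                  achromatic_channel = c("L", "composite",
                                                         "intensity")) {
  achromatic_channel <- match.arg(achromatic_channel)
  n <- length(series)
  if (n < 2L) stop("need at least two leaves", call. = FALSE)
  idx <- vapply(seq_along(series), function(i) {
    if (inherits(series[[i]], "leaf_series")) series[[i]]$leaf_index else i
  }, integer(1L))
  ds <- cm <- matrix(0, n, n, dimnames = list(idx, idx))
  for (i in seq_len(n - 1L)) {
    for (k in (i + 1L):n) {
      d <- discriminate_pair(series[[i]], series[[k]], rs, illum, thresholds,
                             achromatic_channel)
      ds[i, k] <- ds[k, i] <- d$delta_s
      cm[i, k] <- cm[k, i] <- d$michelson_c
    }
  }
  chrom <- ds >= thresholds[["delta_s"]]
  achrom <- cm >= thresholds[["michelson"]]
  diag(chrom) <- diag(achrom) <- FALSE
  structure(list(delta_s = ds, michelson_c = cm,
                 chromatic_call = chrom, achromatic_call = achrom,
                 leaf_index = idx, thresholds = thresholds,
                 achromatic_channel = achromatic_channel,
                 weber_fractions = rs$weber_fractions),
            class = "discrimination_matrix")
}

#' @export
print.discrimination_matrix <- function(x, ...) {
  cat(sprintf("<discrimination_matrix: %d leaves, thresholds delta_S >= %g, C >= %g>\n",
              length(x$leaf_index), x$thresholds[["delta_s"]],
              x$thresholds[["michelson"]]))
  cat("delta_S:\n"); print(round(x$delta_s, 3))
  cat("Michelson C:\n"); print(round(x$michelson_c, 3))
  invisible(x)
}

#' Contrasts against one reference leaf
#'
#' @param dm A [discrimination_matrix()] result.
#' @param reference Leaf index used as the contrast object (default 1, the
#'   first leaf below the bud; 4 reproduces the mid-shoot comparison).
#' @return Data frame with one row per other leaf: `delta_s`, `michelson_c`
#'   and both calls.
#' @export
vs_reference <- function(dm, reference = 1L) {
  stopifnot(inherits(dm, "discrimination_matrix"))
  pos <- match(reference, dm$leaf_index)
  if (is.na(pos)) stop("reference leaf not in matrix", call. = FALSE)
  others <- setdiff(seq_along(dm$leaf_index), pos)
  data.frame(leaf = dm$leaf_index[others],
             delta_s = dm$delta_s[pos, others],
             michelson_c = dm$michelson_c[pos, others],
             chromatic_call = dm$chromatic_call[pos, others],
             achromatic_call = dm$achromatic_call[pos, others],
             row.names = NULL)
}

#' Classify shoot zones from achromatic discriminability
#'
#' Partitions the leaf series into `top` (the reference leaf), `middle`
#' (leaves whose Michelson contrast against the reference stays below the
#' achromatic threshold) and `bottom` (leaves achromatically discriminable
#' from the reference).
#'
#' @param dm A [discrimination_matrix()] result.
#' @param reference Reference leaf index (default 1).
#' @param c_threshold Michelson threshold; defaults to the matrix's own.
#' @return Named character vector (names = leaf indices) with values in
#'   `c("top", "middle", "bottom")`.
#' @export
classify_zones <- function(dm, reference = 1L,
                           c_threshold = dm$thresholds[["michelson"]]) {
  stopifnot(inherits(dm, "discrimination_matrix"))
  pos <- match(reference, dm$leaf_index)
  if (is.na(pos)) stop("reference leaf not in matrix", call. = FALSE)
  zone <- ifelse(dm$michelson_c[pos, ] >= c_threshold, "bottom", "middle")
  zone[pos] <- "top"
  stats::setNames(zone, dm$leaf_index)
}
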