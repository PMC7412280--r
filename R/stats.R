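## Regression and correlation summaries in the row shape used throughout:
## slope a, intercept b, Pearson R, p-value (t transform of R), n.

.regression_record <- function(slope, intercept, r, n, extra = NULL) {
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  rec <- data.frame(slope = slope, intercept = intercept, pearson_r = r,
                    p_value = p, n = n)
  if (!is.null(extra)) rec <- cbind(extra, rec)
  rec
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor()] that enforces the degenerate-input
#' contract used by the spectral analyses (at least three pairs, nonzero
#' variance on both sides).
#'
#' @param x,y Paired numeric series.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: zero variance", call. = FALSE)
  stats::cor(x, y)
}

#' Ordinary least squares of y on x
#'
#' Fits `y = a x + b` with [stats::lm()] and reports it as a one-row record
#' (`slope`, `intercept`, `pearson_r`, `p_value`, `n`), the shape of the
#' package's regression tables.
#'
#' @param x Predictor; @param y response.
#' @return One-row data frame record.
#' @export
ols_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate input: constant predictor",
                              call. = FALSE)
  if (stats::sd(y) == 0) stop("degenerate input: constant response",
                              call. = FALSE)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  .regression_record(unname(co[2L]), unname(co[1L]), pearson_r(x, y),
                     length(x))
}

#' Inter-leaf spectral regressions (hue-change table)
#'
#' Regresses each leaf's normalized reflectance spectrum on the reference
#' leaf's, pairing values across the wavelength grid. A proportional spectral
#' change (pure intensity shift) gives intercept `b = 0`; a nonzero intercept
#' is the operational signature of a hue change.
#'
#' @param series List of [leaf_series] (or reflectance [spectrum]) objects on
#'   one grid.
#' @param reference Leaf index of the reference spectrum (default 1).
#' @param hue_tol Absolute intercept below which the change counts as pure
#'   intensity scaling (default 1e-8, i.e. only an exactly proportional
#'   family is flagged as hue-stable).
#' @return Data frame, one row per non-reference leaf: `leaf`, `slope`,
#'   `intercept`, `pearson_r`, `p_value`, `n`, `hue_change`.
#' @export
hue_regression_table <- function(series, reference = 1L, hue_tol = 1e-8) {
  specs <- lapply(series, .mean_spectrum)
  idx <- vapply(seq_along(series), function(i) {
    if (inherits(series[[i]], "leaf_series")) series[[i]]$leaf_index else i
  }, integer(1L))
  pos <- match(reference, idx)
  if (is.na(pos)) stop("reference leaf not present", call. = FALSE)
  ref <- specs[[pos]]
  out <- lapply(setdiff(seq_along(specs), pos), function(i) {
    if (!isTRUE(all.equal(specs[[i]]$wavelength_nm, ref$wavelength_nm)))
      stop("all spectra must share one grid", call. = FALSE)
    rec <- ols_fit(ref$value, specs[[i]]$value)
    cbind(data.frame(leaf = idx[i]), rec,
          data.frame(hue_change = abs(rec$intercept) > hue_tol))
  })
  do.call(rbind, out)
}

#' Regression of integrated reflectance intensity on leaf age
#'
#' Integrates each leaf's normalized reflectance and regresses the intensity
#' `I_i` on the leaf number `i`. On foliage-like data the slope is negative:
#' reflected intensity declines as leaves age down the shoot.
#'
#' @param series List of [leaf_series] objects (>= 3 leaves).
#' @return One-row record plus the per-leaf intensities as attribute
#'   `"intensities"`.
#' @export
intensity_age_regression <- function(series) {
  if (length(series) < 3L) stop("need at least 3 leaves", call. = FALSE)
  idx <- vapply(seq_along(series), function(i) {
    if (inherits(series[[i]], "leaf_series")) series[[i]]$leaf_index else i
  }, integer(1L))
  ii <- vapply(series, function(s) reflectance_intensity(.mean_spectrum(s)),
               numeric(1L))
  rec <- ols_fit(as.numeric(idx), ii)
  attr(rec, "intensities") <- stats::setNames(ii, idx)
  rec
}

#' Trap-count correlations against colour predictors
#'
#' Regresses, separately per sex, the mean number of leafhoppers trapped by
#' each simulated foliage colour on each colour predictor (integrated
#' reflectance intensity, saturation, brightness) and reports the slope,
#' intercept and Pearson R rows.
#'
#' @param counts Data frame with columns `sex`, `replicate`, `choice_index`,
#'   `count` (choice indices beyond the number of predictor rows — control and
#'   no-choice — are ignored).
#' @param predictors Data frame with column `leaf_index` plus one column per
#'   predictor (e.g. `I`, `S`, `B`), aligned to choice indices 1..n.
#' @return Data frame with one row per sex x predictor.
#' @export
trap_count_correlations <- function(counts, predictors) {
  stopifnot(all(c("sex", "replicate", "choice_index", "count") %in%
                  names(counts)),
            "leaf_index" %in% names(predictors))
  pred_cols <- setdiff(names(predictors), "leaf_index")
  out <- list()
  for (sx in unique(counts$sex)) {
    di <- counts[counts$sex == sx &
                   counts$choice_index %in% predictors$leaf_index, ]
    mean_n <- tapply(di$count, di$choice_index, mean)
    ord <- match(predictors$leaf_index, as.integer(names(mean_n)))
    nvec <- as.numeric(mean_n[ord])
    for (pc in pred_cols) {
      rec <- ols_fit(predictors[[pc]], nvec)
      out[[length(out) + 1L]] <-
        cbind(data.frame(sex = sx, predictor = pc), rec)
    }
  }
  do.call(rbind, out)
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = (C * 1e6) / (N * L / 1e3)` for `C` reads uniquely aligned to a
#' transcript of length `L` bases out of `N` total mapped fragments.
#'
#' @param reads Reads aligned to the transcript (vectorized).
#' @param total_mapped Total mapped fragments `N > 0`.
#' @param length_bp Transcript length in bases, `L > 0`.
#' @return RPKM value(s).
#' @export
rpkm <- function(reads, total_mapped, length_bp) {
  if (any(total_mapped <= 0)) stop("total mapped reads must be > 0",
                                   call. = FALSE)
  if (any(length_bp <= 0)) stop("transcript length must be > 0",
                                call. = FALSE)
  if (any(reads < 0)) stop("read counts must be >= 0", call. = FALSE)
  (reads * 1e6) / (total_mapped * (length_bp / 1e3))
}
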