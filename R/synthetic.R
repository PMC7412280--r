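## Seeded generators that emulate every measured input of the study design:
## leaf reflectance series with affine inter-leaf structure, ERG spectral
## scans driven by a known receptor set, and behavioural choice counts linear
## in a colour predictor. All generators are pure functions of
## (config, seed): the same pair reproduces bitwise-identical output.

#' Default inter-leaf affine constants
#'
#' Per-leaf affine parameters `(a_i, b_i)` such that leaf `i`'s normalized
#' reflectance is `a_i * R_1 + b_i`. The defaults follow the linear trends of
#' the published inter-leaf regression constants for an 11-leaf tea shoot
#' (`a` rising from ~1.21 to ~1.37, `b` falling from ~-10.7 to ~-24.4), which
#' reproduce both the intensity decline with leaf age and the hue drift
#' (nonzero intercepts). Leaf 1 is the identity.
#'
#' @param n_leaves Number of leaves (default 11).
#' @return Data frame with columns `i`, `a`, `b`.
#' @export
default_affine_constants <- function(n_leaves = 11L) {
  i <- seq_len(n_leaves)
  a <- ifelse(i == 1L, 1, 1.17433 + 0.01767 * i)
  b <- ifelse(i == 1L, 0, -7.61008 - 1.52425 * i)
  data.frame(i = i, a = a, b = b)
}

#' Reference young-leaf reflectance spectrum
#'
#' The generator's base curve for the first leaf below the bud: a broad
#' background with a green reflectance peak near 545 nm and chlorophyll
#' absorption troughs near 475 and 665 nm, expressed in normalized
#' reflectance percent. The shape follows the qualitative description of tea
#' foliage (green band highest, blue and red bands low); the exact curve is
#' generator-defined and returned with every truth record.
#'
#' @param grid Wavelength grid (default [canonical_grid()]).
#' @return A [spectrum] of kind `normalized_reflectance`.
#' @export
base_leaf_reflectance <- function(grid = canonical_grid()) {
  v <- 29 -
    3 * exp(-((grid - 330) / 60)^2) +
    21 * exp(-((grid - 545) / 58)^2) -
    9 * exp(-((grid - 475) / 18)^2) -
    9 * exp(-((grid - 665) / 18)^2)
  spectrum(grid, pmax(v, 0), "normalized_reflectance")
}

#' Configuration for the leaf-series generator
#'
#' @param n_leaves Number of leaves down the shoot (default 11).
#' @param affine Data frame `i, a, b` of per-leaf affine constants
#'   (default [default_affine_constants()]); `a_i` must be positive.
#' @param base Base reflectance [spectrum] for leaf 1.
#' @param noise_sd Additive Gaussian measurement noise per replicate, in
#'   reflectance percent (default 0.8; generated values are truncated at 0).
#' @param replicates Replicate spectra per leaf (default 24, matching four
#'   sampling points on each of six shoots).
#' @return Object of class `leaf_generator_config`.
#' @export
leaf_generator_config <- function(n_leaves = 11L,
                                  affine = default_affine_constants(n_leaves),
                                  base = base_leaf_reflectance(),
                                  noise_sd = 0.8,
                                  replicates = 24L) {
  n_leaves <- as.integer(n_leaves)
  stopifnot(n_leaves >= 2L, nrow(affine) >= n_leaves,
            all(c("i", "a", "b") %in% names(affine)),
            inherits(base, "spectrum"), noise_sd >= 0, replicates >= 1L)
  if (any(affine$a <= 0))
    stop("affine slopes a_i must be positive", call. = FALSE)
  structure(list(n_leaves = n_leaves, affine = affine[seq_len(n_leaves), ],
                 base = base, noise_sd = noise_sd,
                 replicates = as.integer(replicates)),
            class = "leaf_generator_config")
}

#' Generate a synthetic leaf reflectance series
#'
#' Leaf 1 is the base spectrum; leaf `i` is `a_i * base + b_i` plus additive
#' Gaussian noise per replicate, truncated at zero. Replicates are averaged
#' into each leaf's mean spectrum. The returned truth record carries the
#' generating constants and noiseless intensities.
#'
#' @param cfg A [leaf_generator_config()].
#' @param seed Integer seed; the generator is a pure function of
#'   `(cfg, seed)`.
#' @return List with `series` (list of [leaf_series]) and `truth`
#'   (`affine`, `intensity` of the noiseless leaves, `base`).
#' @export
generate_leaf_series <- function(cfg = leaf_generator_config(), seed = 1L) {
  stopifnot(inherits(cfg, "leaf_generator_config"))
  set.seed(as.integer(seed))
  grid <- cfg$base$wavelength_nm
  series <- vector("list", cfg$n_leaves)
  truth_int <- numeric(cfg$n_leaves)
  for (i in seq_len(cfg$n_leaves)) {
    clean <- pmax(cfg$affine$a[i] * cfg$base$value + cfg$affine$b[i], 0)
    truth_int[i] <- pracma::trapz(grid, clean)
    reps <- lapply(seq_len(cfg$replicates), function(r) {
      v <- pmax(clean + stats::rnorm(length(grid), 0, cfg$noise_sd), 0)
      spectrum(grid, v, "normalized_reflectance")
    })
    series[[i]] <- leaf_series(i, reps)
  }
  list(series = series,
       truth = list(affine = cfg$affine, intensity = truth_int,
                    base = cfg$base))
}

#' Configuration for the ERG-recording generator
#'
#' @param receptors True [receptor_set] driving the synthetic eye.
#' @param v_max,k,n True Naka-Rushton parameters (defaults 10 mV, 5e10
#'   photons cm^-2 s^-1, 1). The default half-saturation constant places the
#'   peak-wavelength response at about two thirds of `v_max` under the
#'   delivered flux — a mid-dynamic-range operating point, since the
#'   criterion-response conversion assumes responses clear of saturation.
#' @param flux Quantum flux delivered at every wavelength (default 1e11,
#'   the equal-quantum calibration level).
#' @param noise_sd Amplitude noise SD as a fraction of `v_max` (default 0.02).
#' @param scans Number of spectral scans (default 10).
#' @param step Wavelength step in nm (default 10, i.e. 300, 310, ..., 700).
#' @return Object of class `erg_generator_config`.
#' @export
erg_generator_config <- function(receptors = receptor_set(),
                                 v_max = 10, k = 5e10, n = 1,
                                 flux = 1e11, noise_sd = 0.02,
                                 scans = 10L, step = 10) {
  stopifnot(inherits(receptors, "receptor_set"),
            v_max > 0, k > 0, n > 0, flux > 0, noise_sd >= 0, scans >= 1L)
  structure(list(receptors = receptors, v_max = v_max, k = k, n = n,
                 flux = flux, noise_sd = noise_sd,
                 scans = as.integer(scans), step = step),
            class = "erg_generator_config")
}

#' Generate a synthetic ERG dataset
#'
#' Computes the composite spectral sensitivity of the true receptor set,
#' scales the delivered flux by it, pushes the effective intensity through
#' the Naka-Rushton function and adds truncated Gaussian amplitude noise,
#' for each of `scans` spectral sweeps.
#'
#' @param cfg An [erg_generator_config()].
#' @param seed Integer seed.
#' @return List with `dataset` (an [erg_dataset]) and `truth` (the receptor
#'   set, Naka-Rushton parameters and noiseless sensitivity [spectrum]).
#' @export
generate_erg_dataset <- function(cfg = erg_generator_config(), seed = 1L) {
  stopifnot(inherits(cfg, "erg_generator_config"))
  set.seed(as.integer(seed))
  wl <- seq(300, 700, by = cfg$step)
  sens <- composite_sensitivity(cfg$receptors, wl)
  clean_v <- naka_rushton(sens$value * cfg$flux, cfg$v_max, cfg$k, cfg$n)
  rows <- lapply(seq_len(cfg$scans), function(sc) {
    amp <- pmax(clean_v + stats::rnorm(length(wl), 0, cfg$noise_sd * cfg$v_max),
                0)
    data.frame(wavelength_nm = wl, scan = sc, amplitude = amp,
               flux = cfg$flux)
  })
  d <- do.call(rbind, rows)
  list(dataset = erg_dataset(d$wavelength_nm, d$scan, d$amplitude, d$flux),
       truth = list(receptors = cfg$receptors,
                    naka_rushton = c(v_max = cfg$v_max, k = cfg$k, n = cfg$n),
                    sensitivity = sens))
}

#' Default HSB colour table for the simulated foliage colours
#'
#' Eleven hue/saturation/brightness triples sliding from a bright
#' yellow-green (young top leaf) to a darker, less saturated green (old
#' bottom leaf), used both as behavioural stimuli descriptors and as
#' predictors for choice counts. Chosen so that expected counts under the
#' default saturation coefficients stay positive and sum below the released
#' total of 60.
#'
#' @param n_leaves Number of colours (default 11).
#' @return Data frame with columns `leaf_index`, `H`, `S`, `B`.
#' @export
default_hsb_table <- function(n_leaves = 11L) {
  i <- seq_len(n_leaves)
  data.frame(leaf_index = i,
             H = 65 + 5.5 * (i - 1),
             S = 50 - 2.2 * (i - 1),
             B = 55 - 2.0 * (i - 1))
}

#' Generate behavioural choice counts
#'
#' Expected counts for each simulated colour follow the linear model
#' `N_i = a x_i + b` (clipped at zero) in the chosen predictor column. In
#' `"deterministic"` mode those expectations are returned as-is (useful for
#' exact regression-recovery checks); in `"multinomial"` mode each replicate
#' allocates the released total (default 60 insects) by a multinomial draw
#' with the remaining probability mass going to the no-choice category.
#'
#' @param hsb Predictor table from [default_hsb_table()] (or with an extra
#'   `I` column).
#' @param coefficients Named numeric `c(a = , b = )`.
#' @param predictor Column of `hsb` used as `x` (default `"S"`).
#' @param total Insects released per replicate (default 60).
#' @param replicates Number of replicates per sex (default 5).
#' @param sexes Character vector of sexes to simulate.
#' @param mode `"multinomial"` or `"deterministic"`.
#' @param seed Integer seed.
#' @return Data frame with columns `sex`, `replicate`, `choice_index`,
#'   `count`; choice indices `n+1` (control) and `n+2` (no choice) complete
#'   each replicate to `total` in multinomial mode.
#' @export
generate_choice_counts <- function(hsb = default_hsb_table(),
                                   coefficients = c(a = 0.411, b = -11.12),
                                   predictor = "S",
                                   total = 60L, replicates = 5L,
                                   sexes = c("male", "female"),
                                   mode = c("multinomial", "deterministic"),
                                   seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(predictor %in% names(hsb), is.finite(coefficients[["a"]]),
            is.finite(coefficients[["b"]]))
  set.seed(as.integer(seed))
  x <- hsb[[predictor]]
  expected <- pmax(coefficients[["a"]] * x + coefficients[["b"]], 0)
  if (all(expected == 0))
    stop("config error: all expected counts are zero", call. = FALSE)
  if (sum(expected) > total)
    stop("config error: expected counts exceed the released total",
         call. = FALSE)
  n_col <- nrow(hsb)
  out <- list()
  for (sx in sexes) {
    for (rep_i in seq_len(replicates)) {
      if (mode == "deterministic") {
        cnt <- c(expected, 0, max(total - sum(expected), 0))
      } else {
        p <- c(expected, 0, total - sum(expected)) / total
        cnt <- as.numeric(stats::rmultinom(1L, total, p))
      }
      out[[length(out) + 1L]] <-
        data.frame(sex = sx, replicate = rep_i,
                   choice_index = seq_len(n_col + 2L), count = cnt)
    }
  }
  do.call(rbind, out)
}
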