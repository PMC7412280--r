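## CSV readers and writers for the package's exchange formats. All files are
## plain comma-separated text with a header row.

#' Read a spectrum from CSV
#'
#' Expects columns `wavelength_nm,value`, one file per measurement.
#'
#' @param path File path.
#' @param kind Spectrum kind tag (see [spectrum()]).
#' @return A [spectrum].
#' @export
read_spectrum_csv <- function(path, kind = "raw") {
  d <- utils::read.csv(path)
  stopifnot(all(c("wavelength_nm", "value") %in% names(d)))
  spectrum(d$wavelength_nm, d$value, kind)
}

#' Write a spectrum to CSV
#'
#' @param s A [spectrum]; @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  utils::write.csv(data.frame(wavelength_nm = s$wavelength_nm,
                              value = s$value),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a leaf-series manifest
#'
#' The manifest CSV has columns `leaf_index,replicate,path`; each referenced
#' file is a spectrum CSV. Relative paths resolve against the manifest's
#' directory.
#'
#' @param path Manifest file.
#' @param kind Kind tag applied to each replicate spectrum.
#' @return List of [leaf_series], ordered by leaf index.
#' @export
read_spectra_manifest <- function(path, kind = "normalized_reflectance") {
  m <- utils::read.csv(path)
  stopifnot(all(c("leaf_index", "replicate", "path") %in% names(m)))
  base_dir <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  lapply(sort(unique(m$leaf_index)), function(i) {
    rows <- m[m$leaf_index == i, ]
    rows <- rows[order(rows$replicate), ]
    leaf_series(i, lapply(rows$path,
                          function(p) read_spectrum_csv(resolve(p), kind)))
  })
}

#' Read an ERG recording CSV
#'
#' Expects columns `wavelength_nm,scan_id,amplitude,flux`.
#'
#' @param path File path.
#' @return An [erg_dataset].
#' @export
read_erg_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("wavelength_nm", "scan_id", "amplitude", "flux") %in%
                  names(d)))
  erg_dataset(d$wavelength_nm, d$scan_id, d$amplitude, d$flux)
}

#' Read behavioural choice counts
#'
#' Expects columns `sex,replicate,choice_index,count`.
#'
#' @param path File path.
#' @return Data frame in the shape consumed by [trap_count_correlations()].
#' @export
read_choice_counts_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("sex", "replicate", "choice_index", "count") %in% names(d)))
  d
}

#' Read an HSB colour table
#'
#' Expects columns `leaf_index,H,S,B`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_hsb_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("leaf_index", "H", "S", "B") %in% names(d)))
  d
}

#' Write a discrimination matrix as long-format CSV
#'
#' One row per unordered leaf pair: `leaf_i,leaf_k,delta_s,michelson_c,
#' chromatic_call,achromatic_call`.
#'
#' @param dm A [discrimination_matrix()] result; @param path output file.
#' @return `path`, invisibly.
#' @export
write_discrimination_csv <- function(dm, path) {
  stopifnot(inherits(dm, "discrimination_matrix"))
  n <- length(dm$leaf_index)
  rows <- list()
  for (i in seq_len(n - 1L)) for (k in (i + 1L):n) {
    rows[[length(rows) + 1L]] <- data.frame(
      leaf_i = dm$leaf_index[i], leaf_k = dm$leaf_index[k],
      delta_s = dm$delta_s[i, k], michelson_c = dm$michelson_c[i, k],
      chromatic_call = dm$chromatic_call[i, k],
      achromatic_call = dm$achromatic_call[i, k])
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
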