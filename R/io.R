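#' Read and write spectral data sets
#'
#' The on-disk format is delimited text with one row per subject: a
#' `subject_id` column, a `label` column, then one numeric column per bin,
#' named by its axis position (e.g. ppm center). `read_spectra()` validates
#' the file and returns a [spectral_dataset()]; `write_spectra()` writes one
#' back, with full double precision so a write/read round trip reproduces
#' the intensities bit for bit. The provenance log can be stored alongside
#' as JSON with `write_provenance()`.
#'
#' @param path File to read or write.
#' @param delim Field delimiter (default comma).
#' @param label_aliases Optional named character vector mapping study-specific
#'   label spellings to the canonical vocabulary, e.g.
#'   `c(healthy = "control", patient = "disease")`.
#' @param bin_width Optional bin width recorded as metadata.
#'
#' @return `read_spectra()` returns a [spectral_dataset()]; `write_spectra()`
#'   invisibly returns `path`.
#' @export
read_spectra <- function(path, delim = ",", label_aliases = NULL,
                         bin_width = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    subject_id = readr::col_character(),
    label = readr::col_character(),
    .default = readr::col_character()
  ), progress = FALSE)
  if (!all(c("subject_id", "label") %in% names(df))) {
    stop("file must have 'subject_id' and 'label' columns", call. = FALSE)
  }
  labels <- df$label
  if (!is.null(label_aliases)) {
    hit <- labels %in% names(label_aliases)
    labels[hit] <- unname(label_aliases[labels[hit]])
  }
  bin_cols <- setdiff(names(df), c("subject_id", "label"))
  if (length(bin_cols) == 0) stop("no bin columns found", call. = FALSE)
  axis <- suppressWarnings(as.numeric(bin_cols))
  if (anyNA(axis)) {
    stop("bin column names must be numeric axis positions; offending: ",
         paste(bin_cols[is.na(axis)][1:min(3, sum(is.na(axis)))], collapse = ", "),
         call. = FALSE)
  }
  raw <- as.matrix(df[, bin_cols])
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric intensity for subject '", df$subject_id[bad[1]],
         "' in bin column '", bin_cols[bad[2]], "'", call. = FALSE)
  }
  out <- spectral_dataset(num, df$subject_id, labels, bin_axis = axis,
                          bin_width = bin_width)
  add_provenance(out, sprintf("loaded %d subjects x %d bins from %s",
                              nrow(out), length(axis), path))
}

#' @rdname read_spectra
#' @param data A [spectral_dataset()].
#' @export
write_spectra <- function(data, path, delim = ",") {
  check_spectra(data)
  df <- tibble::as_tibble(data)
  readr::write_delim(df, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' @rdname read_spectra
#' @export
write_provenance <- function(data, path) {
  check_spectra(data)
  jsonlite::write_json(
    list(provenance = provenance(data),
         bin_width = attr(data, "bin_width"),
         n_subjects = nrow(data),
         n_bins = length(bin_axis(data))),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
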