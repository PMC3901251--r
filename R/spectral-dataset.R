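#' Spectral data sets
#'
#' A `spectral_dataset` is a tibble with one row per subject and one column
#' per spectral bin, plus two identifying columns: `subject_id` and `label`
#' (one of `"control"`, `"disease"`, `"unlabeled"`). The numeric position of
#' each bin along the spectral axis (ppm for NMR, cm^-1 for Raman; units are
#' opaque metadata) is stored in the `bin_axis` attribute, aligned with the
#' bin columns, and every processing step appends a line to the `provenance`
#' attribute.
#'
#' @param intensities Numeric matrix, subjects in rows and bins in columns.
#'   No missing values are allowed.
#' @param subject_ids Character vector of unique subject identifiers, one per
#'   row of `intensities`.
#' @param labels Character or factor vector of class labels, one per subject,
#'   each one of `"control"`, `"disease"`, `"unlabeled"`.
#' @param bin_axis Numeric vector of bin center positions, strictly monotone,
#'   one per column of `intensities`. Defaults to the column index.
#' @param bin_width Width of a bin on the axis, or `NA` if unknown/irregular.
#' @param provenance Character vector logging how the data were produced.
#'
#' @return A tibble of class `spectral_dataset` with columns `subject_id`,
#'   `label`, and one numeric column per bin (named by its axis position).
#' @export
#' @examples
#' x <- matrix(rnorm(12), nrow = 3, ncol = 4)
#' spectral_dataset(x, c("s1", "s2", "s3"), c("control", "disease", "unlabeled"))
spectral_dataset <- function(intensities, subject_ids, labels,
                             bin_axis = NULL, bin_width = NA_real_,
                             provenance = character()) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (is.null(bin_axis)) bin_axis <- seq_len(ncol(intensities))
  bin_axis <- as.numeric(bin_axis)
  validate_spectra_parts(intensities, subject_ids, labels, bin_axis)
  colnames(intensities) <- format_axis(bin_axis)
  out <- tibble::tibble(
    subject_id = as.character(subject_ids),
    label = as.character(labels)
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(intensities))
  new_spectral_dataset(out, bin_axis, bin_width, provenance)
}

new_spectral_dataset <- function(df, bin_axis, bin_width, provenance) {
  structure(
    df,
    bin_axis = as.numeric(bin_axis),
    bin_width = as.numeric(bin_width)[1],
    provenance = as.character(provenance),
    class = c("spectral_dataset", class(tibble::tibble()))
  )
}

spectra_labels <- c("control", "disease", "unlabeled")

validate_spectra_parts <- function(intensities, subject_ids, labels, bin_axis) {
  if (anyNA(intensities) || any(!is.finite(intensities))) {
    bad <- which(!is.finite(intensities), arr.ind = TRUE)[1, ]
    stop("non-finite intensity at row ", bad[1], ", column ", bad[2],
         "; impute or drop explicitly before constructing the dataset",
         call. = FALSE)
  }
  if (length(subject_ids) != nrow(intensities)) {
    stop("need exactly one subject_id per row of intensities", call. = FALSE)
  }
  if (anyDuplicated(subject_ids)) {
    stop("subject_ids must be unique", call. = FALSE)
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(intensities)) {
    stop("need exactly one label per subject", call. = FALSE)
  }
  bad_lab <- setdiff(unique(labels), spectra_labels)
  if (length(bad_lab) > 0) {
    stop("unknown label(s) ", paste0("'", bad_lab, "'", collapse = ", "),
         "; allowed labels are: ", paste(spectra_labels, collapse = ", "),
         call. = FALSE)
  }
  if (length(bin_axis) != ncol(intensities)) {
    stop("bin_axis must have one entry per intensity column", call. = FALSE)
  }
  d <- diff(bin_axis)
  if (length(d) > 0 && !(all(d > 0) || all(d < 0))) {
    stop("bin_axis must be strictly monotone", call. = FALSE)
  }
  invisible(TRUE)
}

format_axis <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)

#' @export
print.spectral_dataset <- function(x, ...) {
  ax <- bin_axis(x)
  cat(sprintf("<spectral_dataset: %d subjects x %d bins>\n", nrow(x), length(ax)))
  lab <- table(factor(x$label, levels = spectra_labels))
  cat(sprintf("  labels: %d control, %d disease, %d unlabeled\n",
              lab[["control"]], lab[["disease"]], lab[["unlabeled"]]))
  if (length(ax) > 0) {
    cat(sprintf("  axis: [%g, %g]%s\n", min(ax), max(ax),
                if (is.na(attr(x, "bin_width"))) "" else
                  sprintf(", bin width %g", attr(x, "bin_width"))))
  }
  NextMethod()
}

#' Accessors for spectral datasets
#'
#' `bin_axis()` returns the numeric bin positions, `intensity_matrix()` the
#' subjects-by-bins numeric matrix (row names are subject ids), and
#' `provenance()` the processing log.
#'
#' @param data A [spectral_dataset()].
#' @return A numeric vector, a numeric matrix, or a character vector.
#' @export
bin_axis <- function(data) {
  check_spectra(data)
  attr(data, "bin_axis")
}

#' @rdname bin_axis
#' @export
intensity_matrix <- function(data) {
  check_spectra(data)
  m <- as.matrix(data[, -(1:2)])
  storage.mode(m) <- "double"
  rownames(m) <- data$subject_id
  m
}

#' @rdname bin_axis
#' @export
provenance <- function(data) {
  check_spectra(data)
  attr(data, "provenance")
}

check_spectra <- function(data) {
  if (!inherits(data, "spectral_dataset")) {
    stop("expected a spectral_dataset; see ?spectral_dataset", call. = FALSE)
  }
  invisible(data)
}

add_provenance <- function(data, msg) {
  attr(data, "provenance") <- c(attr(data, "provenance"), msg)
  data
}

# rebuild a dataset around a transformed intensity matrix
rewrap_spectra <- function(data, intensities, bin_axis, bin_width = attr(data, "bin_width")) {
  spectral_dataset(intensities, data$subject_id, data$label,
                   bin_axis = bin_axis, bin_width = bin_width,
                   provenance = provenance(data))
}
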