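#' Aggregate spectral measurements into bins
#'
#' Groups consecutive raw measurements into bins, either `bin_size` columns
#' at a time or by a fixed `bin_width` along the axis. Each output bin is the
#' mean of its member columns by default (the mean keeps the intensity scale
#' comparable across bin sizes, which matters because the pairwise linear
#' fits are scale-sensitive); summation is available via `aggregate = "sum"`.
#' A trailing partial bin is kept (and noted in the provenance) rather than
#' silently dropped. Bin centers become the new axis positions.
#'
#' @param data A [spectral_dataset()].
#' @param bin_size Positive integer: number of consecutive columns per bin.
#' @param bin_width Positive real: width of each bin in axis units
#'   (alternative to `bin_size`).
#' @param aggregate `"mean"` (default) or `"sum"`.
#' @return A [spectral_dataset()] with fewer (aggregated) bins.
#' @export
#' @examples
#' d <- spectral_dataset(matrix(1:20, 2, 10, byrow = TRUE),
#'                       c("a", "b"), c("control", "disease"))
#' bin_spectrum(d, bin_size = 5)
bin_spectrum <- function(data, bin_size = NULL, bin_width = NULL,
                         aggregate = c("mean", "sum")) {
  check_spectra(data)
  aggregate <- match.arg(aggregate)
  axis <- bin_axis(data)
  n_raw <- length(axis)
  if (is.null(bin_size) == is.null(bin_width)) {
    stop("supply exactly one of bin_size or bin_width", call. = FALSE)
  }
  if (!is.null(bin_size)) {
    bin_size <- as.integer(bin_size)
    if (length(bin_size) != 1 || is.na(bin_size) || bin_size < 1) {
      stop("bin_size must be a positive integer", call. = FALSE)
    }
    if (bin_size > n_raw) {
      stop("bin_size (", bin_size, ") exceeds the number of raw columns (",
           n_raw, ")", call. = FALSE)
    }
    groups <- (seq_len(n_raw) - 1L) %/% bin_size + 1L
  } else {
    if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
    res <- min(abs(diff(axis)))
    if (bin_width < res) {
      stop("bin_width (", bin_width, ") is below the axis resolution (",
           res, ")", call. = FALSE)
    }
    groups <- as.integer(floor((axis - min(axis)) / bin_width)) + 1L
    groups <- match(groups, unique(groups))  # consecutive group ids
  }
  x <- intensity_matrix(data)
  idx <- split(seq_len(n_raw), groups)
  agg_fun <- if (aggregate == "mean") rowMeans else rowSums
  binned <- vapply(idx, function(j) agg_fun(x[, j, drop = FALSE]),
                   numeric(nrow(x)))
  if (nrow(x) == 1) binned <- matrix(binned, nrow = 1)
  centers <- vapply(idx, function(j) mean(axis[j]), numeric(1))
  sizes <- lengths(idx)
  partial <- sizes[length(sizes)] != sizes[1]
  new_width <- if (!is.null(bin_width)) bin_width else {
    if (n_raw > 1) abs(axis[2] - axis[1]) * bin_size else attr(data, "bin_width")
  }
  out <- rewrap_spectra(data, binned, centers, bin_width = new_width)
  msg <- sprintf("binned %d raw columns into %d bins (%s aggregation)%s",
                 n_raw, length(idx), aggregate,
                 if (partial) sprintf("; trailing partial bin of %d column(s) kept",
                                      sizes[length(sizes)]) else "")
  add_provenance(out, msg)
}

#' Remove bins falling in excluded spectral regions
#'
#' Drops every bin whose center lies inside any of the given closed axis
#' intervals, e.g. water regions or drug peaks that should not inform the
#' disease model. The intervals are user-supplied: which regions to exclude
#' is a property of the study, not of the method.
#'
#' @param data A [spectral_dataset()].
#' @param regions A list of length-2 numeric vectors `c(lo, hi)`, or a
#'   two-column matrix/data frame of interval bounds. Overlapping intervals
#'   behave as their union. An empty list leaves the data unchanged.
#' @return A [spectral_dataset()] without the masked bins.
#' @export
mask_bins <- function(data, regions) {
  check_spectra(data)
  if (is.matrix(regions) || is.data.frame(regions)) {
    regions <- lapply(seq_len(nrow(regions)), function(i) as.numeric(regions[i, 1:2]))
  }
  if (length(regions) == 0) return(data)
  axis <- bin_axis(data)
  drop <- rep(FALSE, length(axis))
  for (r in regions) {
    r <- sort(as.numeric(r[1:2]))
    if (anyNA(r)) stop("mask regions must be finite intervals", call. = FALSE)
    drop <- drop | (axis >= r[1] & axis <= r[2])
  }
  if (all(drop)) stop("masking removed every bin", call. = FALSE)
  if (!any(drop)) return(data)
  x <- intensity_matrix(data)[, !drop, drop = FALSE]
  out <- rewrap_spectra(data, x, axis[!drop])
  add_provenance(out, sprintf("masked %d of %d bins in %d region(s)",
                              sum(drop), length(axis), length(regions)))
}

#' Pollute intensities with additive Gaussian noise
#'
#' Adds an independent zero-mean Gaussian perturbation of standard deviation
#' `sigma` (absolute intensity units) to every measurement; used by the
#' noise-robustness experiment. Deterministic given `seed`.
#'
#' @param data A [spectral_dataset()].
#' @param sigma Non-negative noise standard deviation.
#' @param seed Integer seed.
#' @return A [spectral_dataset()] with perturbed intensities.
#' @export
add_noise <- function(data, sigma, seed) {
  check_spectra(data)
  if (!is.numeric(sigma) || length(sigma) != 1 || is.na(sigma) || sigma < 0) {
    stop("sigma must be a single non-negative number", call. = FALSE)
  }
  if (sigma == 0) return(data)
  x <- intensity_matrix(data)
  noise <- withr::with_seed(as.integer(seed),
                            matrix(stats::rnorm(length(x), 0, sigma), nrow(x)))
  out <- rewrap_spectra(data, x + noise, bin_axis(data))
  add_provenance(out, sprintf("added N(0, %g^2) noise (seed %d)", sigma,
                              as.integer(seed)))
}
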