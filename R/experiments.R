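#' Noise-robustness sweep
#'
#' Creates an ensemble of noise-polluted copies of the data (additive
#' zero-mean Gaussian noise of standard deviation `sigma`, in absolute
#' intensity units) and scores each classification method on each copy with
#' leave-one-out validation. The `"network"` method runs the full pipeline
#' of [loo_classify()]; every other method is an off-the-shelf baseline
#' trained directly on the raw bin intensities, standardized per training
#' fold — the contrast is between the network representation and classifiers
#' fed the data itself.
#'
#' @param data A labeled [spectral_dataset()].
#' @param sigmas Noise standard deviations to sweep.
#' @param n_replicates Polluted copies per sigma (the full experiment uses
#'   100; reduce for quick runs).
#' @param methods Methods to score: `"network"` plus any of
#'   `"naive_bayes"`, `"decision_tree"`, `"mlp"`, `"svm_linear"`.
#' @param seed Integer seed driving the noise draws and classifier seeds.
#' @param threshold,features,refit_models,sigma_relative Options for the
#'   network method; `sigma_relative = TRUE` rescales each sigma by the mean
#'   per-bin standard deviation of the clean data.
#' @return A `sweep_result` tibble: one row per (sigma, method, replicate)
#'   with the LOO `score` in percent. Use [glance()] for per-condition means
#'   and [ggplot2::autoplot()] for the score-vs-noise figure.
#' @export
noise_sweep <- function(data, sigmas, n_replicates = 100,
                        methods = c("network", "naive_bayes",
                                    "decision_tree", "mlp"),
                        seed = 1L, threshold = 0.65,
                        features = c("density", "efficiency"),
                        refit_models = TRUE, sigma_relative = FALSE) {
  check_spectra(data)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  labeled <- data[data$label %in% c("control", "disease"), ]
  y <- factor(labeled$label, levels = c("control", "disease"))
  scale_unit <- if (sigma_relative) mean(apply(intensity_matrix(labeled), 2,
                                               stats::sd)) else 1
  grid <- tidyr::expand_grid(sigma = as.numeric(sigmas),
                             replicate = seq_len(n_replicates))
  rows <- purrr::pmap(grid, function(sigma, replicate) {
    noise_seed <- as.integer((as.integer(seed) * 7919 +
                              match(sigma, sigmas) * 1009 + replicate) %%
                             .Machine$integer.max)
    polluted <- add_noise(labeled, sigma * scale_unit, noise_seed)
    purrr::map(methods, function(method) {
      sc <- if (method == "network") {
        loo_classify(polluted, features = features, threshold = threshold,
                     refit_models = refit_models, seed = noise_seed)$score
      } else {
        loo_table_score(intensity_matrix(polluted), y, method, noise_seed)
      }
      tibble::tibble(sigma = sigma, replicate = replicate,
                     method = method, score = sc)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  new_sweep_result(rows, axis = "sigma", seed = seed,
                   n_replicates = n_replicates)
}

#' Bin-size sweep
#'
#' Re-runs the network classification pipeline after aggregating the raw
#' measurements at each bin size: bin, refit the pairwise models,
#' leave-one-out classify. A bin size that leaves fewer than 2 bins cannot
#' form any pair; its score is recorded as `NA` (flagged in the result)
#' rather than an error, so a full sweep up to `n_raw` is representable.
#'
#' @param data A labeled [spectral_dataset()].
#' @param bin_sizes Integer bin sizes to sweep (each at most the number of
#'   raw columns).
#' @param seed Integer seed.
#' @inheritParams noise_sweep
#' @return A `sweep_result` tibble with one row per bin size.
#' @export
binning_sweep <- function(data, bin_sizes, seed = 1L, threshold = 0.65,
                          features = c("density", "efficiency"),
                          refit_models = TRUE) {
  check_spectra(data)
  n_raw <- length(bin_axis(data))
  if (any(bin_sizes > n_raw)) {
    stop("bin sizes exceed the number of raw columns (", n_raw, ")",
         call. = FALSE)
  }
  rows <- purrr::map(as.integer(bin_sizes), function(bs) {
    binned <- bin_spectrum(data, bin_size = bs)
    n_bins <- length(bin_axis(binned))
    sc <- if (n_bins < 2) NA_real_ else {
      loo_classify(binned, features = features, threshold = threshold,
                   refit_models = refit_models, seed = seed)$score
    }
    tibble::tibble(bin_size = bs, n_bins = n_bins, replicate = 1L,
                   method = "network", score = sc,
                   degenerate = n_bins < 2)
  }) |> dplyr::bind_rows()
  new_sweep_result(rows, axis = "bin_size", seed = seed, n_replicates = 1L)
}

new_sweep_result <- function(rows, axis, seed, n_replicates) {
  structure(rows,
            axis = axis, seed = as.integer(seed),
            n_replicates = as.integer(n_replicates),
            class = c("sweep_result", class(tibble::tibble())))
}

#' @export
glance.sweep_result <- function(x, ...) {
  axis <- attr(x, "axis")
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x),
                    dplyr::across(dplyr::all_of(c(axis, "method")))),
    mean_score = mean(score, na.rm = FALSE),
    sd_score = stats::sd(score),
    n = dplyr::n(), .groups = "drop")
}

#' Track network structure through time
#'
#' Reconstructs one network per timepoint from a longitudinal series of
#' spectra of the same subject, under a fixed reference model, and records
#' the link density of each thresholded network — the quantity whose fall
#' and rebound tracks treatment response.
#'
#' @param model A `dual_class_model` trained on the reference cohorts.
#' @param series A tibble with columns `timepoint` and `values` (list column
#'   of bin-intensity vectors), as produced by [generate_trajectory()]; or a
#'   list of intensity vectors.
#' @param threshold Binarization threshold (default 0.65).
#' @return A `trajectory_result` tibble: `timepoint`, `density`, in input
#'   order, with the threshold as an attribute.
#' @export
track_evolution <- function(model, series, threshold = 0.65) {
  stopifnot(inherits(model, "dual_class_model"))
  if (is.data.frame(series)) {
    timepoints <- series$timepoint
    values <- series$values
  } else {
    values <- series
    timepoints <- seq_along(values)
  }
  if (length(values) == 0) stop("series must be non-empty", call. = FALSE)
  dens <- vapply(values, function(x) {
    net <- reconstruct(as.numeric(x), model)
    link_density(binarize(net, threshold))
  }, numeric(1))
  structure(tibble::tibble(timepoint = timepoints, density = dens),
            threshold_used = threshold,
            class = c("trajectory_result", class(tibble::tibble())))
}
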