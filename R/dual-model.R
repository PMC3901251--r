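#' Fit class-conditional pairwise linear models
#'
#' For every ordered pair of bins (i, j), fits by ordinary least squares two
#' linear models of bin j on bin i — one on the control cohort and one on the
#' disease cohort — and records slope, intercept and residual standard
#' deviation for each class. These dual models are the training stage of the
#' network representation: a new subject's link weight for the pair is the
#' normalized probability that its (i, j) values sit closer to the disease
#' regression line than to the control one (see [disease_probability()]).
#'
#' Residual standard deviations use the unbiased denominator (m - 2) and are
#' floored at `1e-9` times the response bin's intensity range within the
#' class, so that an exact fit does not collapse the Gaussian residual model
#' to a point mass. Pairs in which either bin has zero variance in either
#' class are flagged degenerate; their weight is fixed at the neutral 0.5 so
#' the node set stays constant across subjects.
#'
#' @param data A [spectral_dataset()] containing at least 3 control and
#'   3 disease subjects; unlabeled rows are ignored. Alternatively pass the
#'   two class matrices via `controls` and `patients`.
#' @param controls,patients Optional numeric matrices (subjects x bins) used
#'   instead of `data`.
#' @return A `dual_class_model` object; see [tidy.dual_class_model()] for a
#'   tabular view of the fitted coefficients.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_bins = 12, seed = 1))
#' fit <- fit_pair_models(cohort)
#' fit
fit_pair_models <- function(data = NULL, controls = NULL, patients = NULL) {
  if (!is.null(data)) {
    check_spectra(data)
    x <- intensity_matrix(data)
    controls <- x[data$label == "control", , drop = FALSE]
    patients <- x[data$label == "disease", , drop = FALSE]
    bin_labels <- format_axis(bin_axis(data))
  } else {
    controls <- as.matrix(controls)
    patients <- as.matrix(patients)
    bin_labels <- colnames(controls)
    if (is.null(bin_labels)) bin_labels <- as.character(seq_len(ncol(controls)))
  }
  if (ncol(controls) != ncol(patients)) {
    stop("control and disease matrices must have the same number of bins",
         call. = FALSE)
  }
  if (ncol(controls) < 2) stop("need at least 2 bins to form pairs", call. = FALSE)
  if (nrow(controls) < 3 || nrow(patients) < 3) {
    stop("each class needs at least 3 subjects (", nrow(controls),
         " control, ", nrow(patients), " disease given)", call. = FALSE)
  }
  fit_from_stats(class_stats(controls), class_stats(patients), bin_labels,
                 control_ids = rownames(controls), disease_ids = rownames(patients))
}

# Sufficient statistics of one class matrix: subject count, column sums,
# cross-product matrix, and column ranges. Everything the pairwise OLS
# needs, and cheap to downdate for leave-one-out refits.
class_stats <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  list(m = nrow(x), s = colSums(x), P = crossprod(x),
       lo = apply(x, 2, min), hi = apply(x, 2, max))
}

# Remove one subject (row vector x) from the statistics. Ranges cannot be
# downdated exactly without the data, so callers that need exact ranges
# recompute them; for the residual floor an upper bound on the range is
# harmless, so the stored ranges are kept as-is.
drop_subject_stats <- function(st, x) {
  list(m = st$m - 1L, s = st$s - x, P = st$P - tcrossprod(x),
       lo = st$lo, hi = st$hi)
}

# OLS of every column j on every column i within one class, from sufficient
# statistics. Returns matrices indexed [predictor i, response j].
class_fit <- function(st) {
  m <- st$m
  mu <- st$s / m
  S <- st$P - tcrossprod(st$s) / m     # centered cross-products
  Sii <- diag(S)
  # numerically-zero variance: constant bin within the class
  scale2 <- pmax(mu^2, (st$hi - st$lo)^2, 1)
  zero_var <- Sii <= m * scale2 * (.Machine$double.eps * 64)^2 | Sii <= 0
  Sii_safe <- ifelse(zero_var, 1, Sii)
  slope <- S / Sii_safe                 # rows: predictor i
  intercept <- matrix(mu, nrow(S), ncol(S), byrow = TRUE) - slope * mu
  rss <- pmax(sweep(-slope * S, 2, diag(S), "+"), 0)  # S_jj - S_ij^2/S_ii
  sd <- sqrt(rss / (m - 2))
  floor_sd <- matrix(1e-9 * (st$hi - st$lo), nrow(S), ncol(S), byrow = TRUE)
  sd <- pmax(sd, floor_sd)
  list(slope = slope, intercept = intercept, sd = sd, zero_var = zero_var,
       m = m)
}

fit_from_stats <- function(st_c, st_d, bin_labels,
                           control_ids = NULL, disease_ids = NULL) {
  fc <- class_fit(st_c)
  fd <- class_fit(st_d)
  n <- length(st_c$s)
  zero_bin <- fc$zero_var | fd$zero_var
  degenerate <- outer(zero_bin, zero_bin, "|")
  diag(degenerate) <- TRUE  # self-pairs are never evaluated
  # a zero sd can survive flooring only when the response range is zero,
  # which zero_bin already covers; guard against log(0) anyway
  sd_c <- pmax(fc$sd, .Machine$double.xmin)
  sd_d <- pmax(fd$sd, .Machine$double.xmin)
  structure(
    list(
      n_bins = n,
      bin_labels = bin_labels,
      slope_c = fc$slope, intercept_c = fc$intercept, sd_c = sd_c,
      slope_d = fd$slope, intercept_d = fd$intercept, sd_d = sd_d,
      log_sd_c = log(sd_c), log_sd_d = log(sd_d),
      degenerate = degenerate,
      n_control = st_c$m, n_disease = st_d$m,
      control_ids = control_ids, disease_ids = disease_ids,
      stats = list(control = st_c, disease = st_d)
    ),
    class = "dual_class_model"
  )
}

#' @export
print.dual_class_model <- function(x, ...) {
  cat(sprintf("<dual_class_model: %d bins, %d ordered pairs>\n", x$n_bins,
              x$n_bins * (x$n_bins - 1)))
  cat(sprintf("  trained on %d control and %d disease subjects\n",
              x$n_control, x$n_disease))
  ndeg <- sum(x$degenerate) - x$n_bins  # diagonal never used
  if (ndeg > 0) cat(sprintf("  %d degenerate ordered pair(s) (neutral weight)\n", ndeg))
  invisible(x)
}

#' Disease probability of one bin pair
#'
#' Given a subject's intensities at a predictor bin i and a response bin j,
#' evaluates the two fitted regression lines at x_i to get the expected
#' response under each class, places a Gaussian of width equal to the class
#' residual standard deviation on each expectation, and returns the
#' normalized disease weight
#' \deqn{w = \frac{\phi_d(x_j)}{\phi_c(x_j) + \phi_d(x_j)}}{w = phi_d / (phi_c + phi_d)}
#' computed as a logistic of the log-density difference, which is stable
#' even when both densities underflow. Degenerate pairs return the neutral
#' weight 0.5.
#'
#' @param x_i,x_j Finite numeric intensities at the predictor and response bin.
#' @param model A `dual_class_model` from [fit_pair_models()].
#' @param i,j Bin indices of the ordered pair (predictor, response).
#' @return A weight in `[0, 1]`.
#' @export
disease_probability <- function(x_i, x_j, model, i, j) {
  stopifnot(inherits(model, "dual_class_model"))
  if (!all(is.finite(c(x_i, x_j)))) stop("inputs must be finite", call. = FALSE)
  if (i == j) stop("predictor and response bin must differ", call. = FALSE)
  if (model$degenerate[i, j]) return(0.5)
  pair_weight(x_i, x_j,
              model$slope_c[i, j], model$intercept_c[i, j], model$sd_c[i, j],
              model$slope_d[i, j], model$intercept_d[i, j], model$sd_d[i, j])
}

#' @rdname disease_probability
#' @param control,disease Numeric vectors `c(slope, intercept, resid_std)`
#'   specifying one pair's two class models directly, for
#'   `pairwise_weight()` — the same computation as [disease_probability()]
#'   without needing a fitted model object.
#' @export
pairwise_weight <- function(x_i, x_j, control, disease) {
  control <- as.numeric(control); disease <- as.numeric(disease)
  if (length(control) != 3 || length(disease) != 3) {
    stop("control and disease must be c(slope, intercept, resid_std)",
         call. = FALSE)
  }
  if (control[3] <= 0 || disease[3] <= 0) {
    stop("residual stds must be positive", call. = FALSE)
  }
  if (!all(is.finite(c(x_i, x_j)))) stop("inputs must be finite", call. = FALSE)
  pair_weight(x_i, x_j, control[1], control[2], control[3],
              disease[1], disease[2], disease[3])
}

# scalar/vector core of the weight: logistic of log-density difference
pair_weight <- function(x_i, x_j, a_c, b_c, s_c, a_d, b_d, s_d) {
  z_c <- (x_j - (a_c * x_i + b_c)) / s_c
  z_d <- (x_j - (a_d * x_i + b_d)) / s_d
  stats::plogis(log(s_c) - log(s_d) + 0.5 * (z_c^2 - z_d^2))
}

# full n x n matrix of ordered-pair weights for one subject (row vector x);
# entry [i, j] is the weight of the ordered pair predictor i -> response j
ordered_weights <- function(model, x) {
  n <- model$n_bins
  if (length(x) != n) {
    stop("subject has ", length(x), " bins but the model expects ", n,
         call. = FALSE)
  }
  if (!all(is.finite(x))) stop("subject intensities must be finite", call. = FALSE)
  xj <- matrix(x, n, n, byrow = TRUE)
  z_c <- (xj - (model$slope_c * x + model$intercept_c)) / model$sd_c
  z_d <- (xj - (model$slope_d * x + model$intercept_d)) / model$sd_d
  w <- stats::plogis(model$log_sd_c - model$log_sd_d + 0.5 * (z_c^2 - z_d^2))
  w[model$degenerate] <- 0.5
  diag(w) <- 0
  dimnames(w) <- NULL
  w
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fitted pairwise models
#'
#' @param x A `dual_class_model`.
#' @param ... Unused.
#' @return One row per ordered bin pair with the six fitted coefficients,
#'   the class sizes, and the degeneracy flag.
#' @export
tidy.dual_class_model <- function(x, ...) {
  n <- x$n_bins
  idx <- which(diag(n) == 0, arr.ind = TRUE)  # all off-diagonal (i, j)
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  lin <- cbind(idx[, 1], idx[, 2])
  tibble::tibble(
    predictor_bin = idx[, 1],
    response_bin = idx[, 2],
    predictor = x$bin_labels[idx[, 1]],
    response = x$bin_labels[idx[, 2]],
    control_slope = x$slope_c[lin],
    control_intercept = x$intercept_c[lin],
    control_resid_std = x$sd_c[lin],
    disease_slope = x$slope_d[lin],
    disease_intercept = x$intercept_d[lin],
    disease_resid_std = x$sd_d[lin],
    degenerate = x$degenerate[lin],
    n_control = x$n_control,
    n_disease = x$n_disease
  )
}

#' @rdname tidy.dual_class_model
#' @export
glance.dual_class_model <- function(x, ...) {
  tibble::tibble(
    n_bins = x$n_bins,
    n_pairs = x$n_bins * (x$n_bins - 1),
    n_control = x$n_control,
    n_disease = x$n_disease,
    n_degenerate = sum(x$degenerate) - x$n_bins
  )
}

#' Serialize a fitted dual-class model to JSON
#'
#' Writes the full coefficient table plus metadata; [read_pair_models()]
#' restores an equivalent model (without the training sufficient statistics,
#' so leave-one-out refitting needs the original data).
#'
#' @param model A `dual_class_model`.
#' @param path Output file.
#' @export
write_pair_models <- function(model, path) {
  stopifnot(inherits(model, "dual_class_model"))
  jsonlite::write_json(
    list(format = "specnet_dual_model", version = 1L,
         n_bins = model$n_bins, bin_labels = model$bin_labels,
         n_control = model$n_control, n_disease = model$n_disease,
         pairs = tidy(model)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pair_models
#' @export
read_pair_models <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "specnet_dual_model")) {
    stop("not a specnet dual-model file: ", path, call. = FALSE)
  }
  n <- obj$n_bins
  p <- obj$pairs
  mk <- function(v, fill = NA_real_) {
    m <- matrix(fill, n, n)
    m[cbind(p$predictor_bin, p$response_bin)] <- v
    m
  }
  sd_c <- mk(p$control_resid_std, 1)
  sd_d <- mk(p$disease_resid_std, 1)
  deg <- mk(as.numeric(p$degenerate), 1) > 0
  structure(
    list(n_bins = n, bin_labels = obj$bin_labels,
         slope_c = mk(p$control_slope, 0), intercept_c = mk(p$control_intercept, 0),
         sd_c = sd_c,
         slope_d = mk(p$disease_slope, 0), intercept_d = mk(p$disease_intercept, 0),
         sd_d = sd_d,
         log_sd_c = log(sd_c), log_sd_d = log(sd_d),
         degenerate = deg,
         n_control = obj$n_control, n_disease = obj$n_disease,
         control_ids = NULL, disease_ids = NULL, stats = NULL),
    class = "dual_class_model")
}
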