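#' Leave-one-out classification on network features
#'
#' Evaluates the full pipeline with leave-one-out validation over the
#' labeled subjects. With `refit_models = TRUE` (the default, leakage-free)
#' each held-out subject is excluded from *everything*: the dual pairwise
#' models are refitted on the remaining subjects, all networks are
#' reconstructed under that refitted model, features are extracted, the
#' classifier is trained on the other subjects' features, and the held-out
#' subject is predicted. `refit_models = FALSE` fits the pairwise models
#' once on all labeled subjects (the in-sample variant) and leaves only the
#' classifier out-of-sample.
#'
#' Features are standardized by the training fold's mean and standard
#' deviation before the classifier sees them.
#'
#' @param data A [spectral_dataset()] with at least 3 subjects per class.
#' @param features Network feature names (see [feature_table()]); default
#'   link density and efficiency.
#' @param classifier One of `"svm_linear"` (default: linear-kernel SVM with
#'   unit cost), `"svm_rbf"`, `"naive_bayes"`, `"decision_tree"`, `"mlp"`.
#' @param threshold Binarization threshold (default 0.65).
#' @param refit_models Refit the pairwise models for every fold (default
#'   `TRUE`).
#' @param seed Integer seed for classifiers with internal randomness.
#' @param symmetrization Passed to the reconstruction step.
#' @return A `classification_result`: list with `score` (percent correct,
#'   0-100), `per_subject` tibble (id, label, prediction, features), and
#'   `config`.
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(n_bins = 30, m_control = 8,
#'                                         m_disease = 8, hub_bins = 5,
#'                                         partners_per_hub = 4, seed = 2))
#' res <- loo_classify(cohort)
#' res$score
#' }
loo_classify <- function(data,
                         features = c("density", "efficiency"),
                         classifier = c("svm_linear", "svm_rbf", "naive_bayes",
                                        "decision_tree", "mlp"),
                         threshold = 0.65, refit_models = TRUE, seed = 1L,
                         symmetrization = "mean") {
  check_spectra(data)
  classifier <- match.arg(classifier)
  if (length(features) == 0) stop("features must be non-empty", call. = FALSE)
  labeled <- data[data$label %in% c("control", "disease"), ]
  x <- intensity_matrix(labeled)
  y <- factor(labeled$label, levels = c("control", "disease"))
  m <- nrow(x)
  if (m == 0 || min(table(y)) < 3) {
    stop("each class needs at least 3 labeled subjects", call. = FALSE)
  }
  is_c <- y == "control"
  bin_labels <- format_axis(bin_axis(labeled))

  if (refit_models) {
    # Each subject's features are computed out-of-sample: the pairwise
    # models are refitted without the subject (cheap, by downdating the
    # class sufficient statistics) and only its own network is
    # reconstructed under that refit. The classifier is then leave-one-out
    # validated on this table of held-out features, so neither stage of the
    # pipeline ever sees the subject it is evaluated on.
    st_c <- class_stats(x[is_c, , drop = FALSE])
    st_d <- class_stats(x[!is_c, , drop = FALSE])
    if (st_c$m < 4 || st_d$m < 4) {
      stop("leave-one-out refitting needs at least 4 subjects per class",
           call. = FALSE)
    }
    fm <- matrix(NA_real_, m, length(features),
                 dimnames = list(labeled$subject_id, features))
    for (k in seq_len(m)) {
      st_c_k <- if (is_c[k]) drop_subject_stats(st_c, x[k, ]) else st_c
      st_d_k <- if (!is_c[k]) drop_subject_stats(st_d, x[k, ]) else st_d
      model_k <- fit_from_stats(st_c_k, st_d_k, bin_labels,
                                control_ids = labeled$subject_id[is_c & seq_len(m) != k],
                                disease_ids = labeled$subject_id[!is_c & seq_len(m) != k])
      stopifnot(!labeled$subject_id[k] %in% c(model_k$control_ids,
                                              model_k$disease_ids))
      fm[k, ] <- compute_feature_matrix(model_k, x[k, , drop = FALSE],
                                        threshold, features, symmetrization)
    }
  } else {
    model <- fit_pair_models(labeled)
    fm <- compute_feature_matrix(model, x, threshold, features, symmetrization)
  }
  preds <- loo_table_predictions(fm, y, classifier, seed)
  per_subject <- tibble::tibble(subject_id = labeled$subject_id,
                                label = as.character(y), predicted = preds)
  per_subject <- dplyr::bind_cols(per_subject, tibble::as_tibble(fm))
  score <- 100 * mean(per_subject$predicted == per_subject$label)
  structure(
    list(score = score, per_subject = per_subject,
         config = list(features = features, classifier = classifier,
                       threshold = threshold, refit_models = refit_models,
                       symmetrization = symmetrization, seed = seed)),
    class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result: %.1f%% correct (%d/%d subjects)>\n",
              x$score, round(x$score / 100 * nrow(x$per_subject)),
              nrow(x$per_subject)))
  cat(sprintf("  classifier %s on [%s], threshold %g, refit_models %s\n",
              x$config$classifier, paste(x$config$features, collapse = ", "),
              x$config$threshold, x$config$refit_models))
  invisible(x)
}

#' @rdname loo_classify
#' @param x A `classification_result`.
#' @param ... Unused.
#' @export
tidy.classification_result <- function(x, ...) x$per_subject

#' @rdname loo_classify
#' @export
glance.classification_result <- function(x, ...) {
  tibble::tibble(score = x$score,
                 n = nrow(x$per_subject),
                 classifier = x$config$classifier,
                 features = paste(x$config$features, collapse = "+"),
                 threshold = x$config$threshold,
                 refit_models = x$config$refit_models)
}

# ---- classifier wrappers ---------------------------------------------------

# standardize by training statistics; constant columns are left centered only
standardize_train_test <- function(train, test) {
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sd, "/"),
       test = sweep(sweep(test, 2, mu), 2, sd, "/"))
}

# inverse-frequency class weights: keeps the SVM from degenerating into a
# majority vote under class imbalance (including the 1-subject imbalance
# every leave-one-out fold introduces on a balanced cohort)
balanced_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * tab)
  stats::setNames(as.numeric(w), names(tab))
}

# train one classifier on (train, y) and predict the test rows
fit_predict <- function(train, y, test, classifier, seed) {
  std <- standardize_train_test(train, test)
  train <- std$train
  test <- std$test
  colnames(train) <- colnames(test) <- paste0("f", seq_len(ncol(train)))
  df_train <- as.data.frame(train)
  df_train$.y <- y
  df_test <- as.data.frame(test)
  pred <- withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    switch(classifier,
      svm_linear = {
        fit <- e1071::svm(.y ~ ., data = df_train, kernel = "linear",
                          cost = 1, scale = FALSE,
                          class.weights = balanced_weights(y))
        stats::predict(fit, df_test)
      },
      svm_rbf = {
        fit <- e1071::svm(.y ~ ., data = df_train, kernel = "radial",
                          cost = 1, scale = FALSE,
                          class.weights = balanced_weights(y))
        stats::predict(fit, df_test)
      },
      naive_bayes = {
        fit <- e1071::naiveBayes(.y ~ ., data = df_train)
        stats::predict(fit, df_test, threshold = 1e-6)
      },
      decision_tree = {
        fit <- rpart::rpart(.y ~ ., data = df_train, method = "class",
                            control = rpart::rpart.control(minsplit = 5, cp = 0.01))
        pr <- stats::predict(fit, df_test, type = "class")
        pr
      },
      mlp = {
        fit <- nnet::nnet(.y ~ ., data = df_train, size = 3, decay = 0.01,
                          maxit = 100, trace = FALSE, MaxNWts = 5000)
        factor(stats::predict(fit, df_test, type = "class"),
               levels = levels(y))
      })
  })
  pred <- as.character(pred)
  # a degenerate fit may abstain (e.g. single-class prediction NA); fall back
  # to the training majority class rather than failing the whole experiment
  pred[is.na(pred)] <- names(which.max(table(y)))
  pred
}

# plain leave-one-out over a fixed feature table (no model refitting);
# used for raw-bin baselines, feature selection, and refit_models = FALSE
loo_table_predictions <- function(fm, y, classifier, seed) {
  m <- nrow(fm)
  preds <- character(m)
  for (k in seq_len(m)) {
    preds[k] <- fit_predict(fm[-k, , drop = FALSE], y[-k],
                            fm[k, , drop = FALSE], classifier, seed + k)
  }
  preds
}

loo_table_score <- function(fm, y, classifier, seed) {
  100 * mean(loo_table_predictions(fm, y, classifier, seed) == as.character(y))
}

#' Exhaustive feature-subset selection
#'
#' Scores every subset of up to `max_subset` candidate features by the
#' leave-one-out accuracy of `classifier` on the given feature table and
#' returns the best subset. Ties are broken in favor of the smaller subset,
#' then lexicographically by the sorted feature names, so the result is
#' deterministic.
#'
#' @param feature_tbl A tibble with a `label` column and one numeric column
#'   per candidate feature (e.g. from [feature_table()]); `subject_id` and
#'   `threshold` columns are ignored.
#' @param max_subset Largest subset size to consider (default 2).
#' @param classifier As in [loo_classify()].
#' @param seed Integer seed.
#' @return Character vector of selected feature names, with the winning LOO
#'   score attached as attribute `score`.
#' @export
select_features <- function(feature_tbl, max_subset = 2,
                            classifier = "svm_linear", seed = 1L) {
  if (nrow(feature_tbl) == 0) stop("empty feature table", call. = FALSE)
  y <- factor(feature_tbl$label, levels = c("control", "disease"))
  cand <- setdiff(names(feature_tbl)[vapply(feature_tbl, is.numeric, TRUE)],
                  c("threshold"))
  if (length(cand) < 2) stop("need at least 2 candidate features", call. = FALSE)
  fm_all <- as.matrix(feature_tbl[, cand])
  best <- NULL
  best_score <- -Inf
  for (size in seq_len(min(max_subset, length(cand)))) {
    for (subset in utils::combn(sort(cand), size, simplify = FALSE)) {
      sc <- loo_table_score(fm_all[, subset, drop = FALSE], y, classifier, seed)
      if (sc > best_score) {          # strict: earlier (smaller, lexicographic
        best_score <- sc              # first) subsets win ties
        best <- subset
      }
    }
  }
  structure(best, score = best_score)
}
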