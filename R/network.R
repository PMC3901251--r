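#' Reconstruct a subject's weighted network
#'
#' Builds the complex-network representation of one subject: every bin is a
#' node, and the weight of the link between bins i and j is the normalized
#' probability that the subject's (i, j) intensities follow the disease
#' model rather than the control model. Both ordered pairs (i -> j and
#' j -> i) are evaluated with [disease_probability()] and combined by the
#' `symmetrization` rule (arithmetic mean by default; `"max"` and
#' `"directed"` are available — metrics always operate on the symmetrized
#' form).
#'
#' @param subject Either a numeric vector of bin intensities, or a
#'   single-row [spectral_dataset()], or a full dataset plus `subject_id`.
#' @param model A `dual_class_model` from [fit_pair_models()].
#' @param symmetrization `"mean"` (default), `"max"`, or `"directed"`.
#' @param subject_id When `subject` is a multi-row dataset, which subject to
#'   reconstruct.
#' @return A `subject_network`: a list with the symmetric `weights` matrix
#'   (zero diagonal, entries in `[0, 1]`), node labels, the degenerate-pair
#'   mask, and (for `"directed"`) the raw ordered weights.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_bins = 10, seed = 1))
#' fit <- fit_pair_models(cohort)
#' net <- reconstruct(cohort, fit, subject_id = cohort$subject_id[1])
#' net
reconstruct <- function(subject, model, symmetrization = c("mean", "max", "directed"),
                        subject_id = NULL) {
  stopifnot(inherits(model, "dual_class_model"))
  symmetrization <- match.arg(symmetrization)
  if (inherits(subject, "spectral_dataset")) {
    x <- intensity_matrix(subject)
    if (!is.null(subject_id)) {
      if (!subject_id %in% rownames(x)) {
        stop("no subject '", subject_id, "' in the dataset", call. = FALSE)
      }
      x <- x[subject_id, ]
      sid <- subject_id
    } else {
      if (nrow(x) != 1) {
        stop("dataset has ", nrow(x),
             " subjects; pick one with subject_id=", call. = FALSE)
      }
      sid <- rownames(x)[1]
      x <- x[1, ]
    }
  } else {
    x <- as.numeric(subject)
    sid <- if (is.null(subject_id)) "subject" else subject_id
  }
  w_ord <- ordered_weights(model, x)
  w <- switch(symmetrization,
              mean = (w_ord + t(w_ord)) / 2,
              max = pmax(w_ord, t(w_ord)),
              directed = (w_ord + t(w_ord)) / 2)
  diag(w) <- 0
  structure(
    list(subject_id = sid,
         weights = w,
         ordered_weights = if (symmetrization == "directed") w_ord else NULL,
         node_labels = model$bin_labels,
         degenerate_mask = model$degenerate,
         symmetrization = symmetrization),
    class = "subject_network")
}

#' @export
print.subject_network <- function(x, ...) {
  n <- nrow(x$weights)
  ut <- x$weights[upper.tri(x$weights)]
  cat(sprintf("<subject_network '%s': %d nodes, %d undirected weights>\n",
              x$subject_id, n, length(ut)))
  cat(sprintf("  weight range [%.3f, %.3f], mean %.3f (symmetrization: %s)\n",
              min(ut), max(ut), mean(ut), x$symmetrization))
  invisible(x)
}

#' Threshold a weighted network into a binary one
#'
#' Keeps a link exactly when its weight is strictly greater than `threshold`
#' (the strict inequality mirrors "weight higher than" the cut). The default
#' analysis threshold elsewhere in the package is 0.65.
#'
#' @param network A `subject_network` from [reconstruct()], or a bare
#'   symmetric weight matrix.
#' @param threshold Real in `[0, 1]`.
#' @return A `binary_network`: symmetric hollow 0/1 `adjacency` matrix plus
#'   node labels and the threshold used.
#' @export
binarize <- function(network, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must be a single number in [0, 1]", call. = FALSE)
  }
  if (inherits(network, "subject_network")) {
    w <- network$weights
    labels <- network$node_labels
    sid <- network$subject_id
  } else {
    w <- as.matrix(network)
    labels <- colnames(w)
    if (is.null(labels)) labels <- as.character(seq_len(ncol(w)))
    sid <- NA_character_
  }
  a <- (w > threshold) * 1L
  diag(a) <- 0L
  structure(
    list(subject_id = sid, adjacency = a, node_labels = labels,
         threshold_used = threshold),
    class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  n <- nrow(x$adjacency)
  e <- sum(x$adjacency) / 2
  cat(sprintf("<binary_network '%s': %d nodes, %d edges (threshold %g)>\n",
              x$subject_id, n, e, x$threshold_used))
  invisible(x)
}

# coerce user input to a 0/1 adjacency matrix
as_adjacency <- function(g) {
  a <- if (inherits(g, "binary_network")) g$adjacency else as.matrix(g)
  if (nrow(a) != ncol(a)) stop("adjacency must be square", call. = FALSE)
  if (any(a != t(a))) stop("adjacency must be symmetric", call. = FALSE)
  if (!all(a %in% c(0, 1))) stop("adjacency must be binary", call. = FALSE)
  diag(a) <- 0
  a
}

#' Tidy edge list of a network
#'
#' @param x A `subject_network` or `binary_network`.
#' @param ... Unused.
#' @return A tibble with one row per unordered node pair (`from`, `to`,
#'   axis positions, and `weight` or `edge`).
#' @export
tidy.subject_network <- function(x, ...) {
  n <- nrow(x$weights)
  ut <- which(upper.tri(x$weights), arr.ind = TRUE)
  tibble::tibble(
    from = ut[, 1], to = ut[, 2],
    from_label = x$node_labels[ut[, 1]],
    to_label = x$node_labels[ut[, 2]],
    weight = x$weights[ut],
    degenerate = x$degenerate_mask[ut]
  )
}

#' @rdname tidy.subject_network
#' @export
tidy.binary_network <- function(x, ...) {
  ut <- which(upper.tri(x$adjacency) & x$adjacency == 1, arr.ind = TRUE)
  tibble::tibble(
    from = ut[, 1], to = ut[, 2],
    from_label = x$node_labels[ut[, 1]],
    to_label = x$node_labels[ut[, 2]]
  )
}

#' Export a network
#'
#' `write_edge_list()` writes a TSV of (i, j, weight); `write_graphml()`
#' writes GraphML via igraph; `write_adjacency()` writes the dense weight or
#' adjacency matrix as CSV. Node labels carry the bin axis positions.
#'
#' @param network A `subject_network` or `binary_network`.
#' @param path Output file.
#' @export
write_edge_list <- function(network, path) {
  readr::write_tsv(tidy(network), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(network, path) {
  g <- as_igraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_adjacency <- function(network, path) {
  m <- if (inherits(network, "subject_network")) network$weights else
    as_adjacency(network)
  labels <- if (inherits(network, "subject_network")) network$node_labels else
    network$node_labels
  df <- tibble::as_tibble(as.data.frame(m, col.names = labels))
  names(df) <- labels
  readr::write_csv(dplyr::bind_cols(tibble::tibble(node = labels), df),
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
as_igraph <- function(network) {
  if (inherits(network, "subject_network")) {
    g <- igraph::graph_from_adjacency_matrix(network$weights, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    igraph::V(g)$name <- network$node_labels
  } else {
    a <- as_adjacency(network)
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected", diag = FALSE)
    igraph::V(g)$name <- if (inherits(network, "binary_network"))
      network$node_labels else as.character(seq_len(nrow(a)))
  }
  g
}
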