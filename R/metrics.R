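#' Structural descriptors of a binary network
#'
#' The four metrics used to summarize a subject's thresholded network:
#'
#' * `link_density()` — number of expressed undirected links divided by the
#'   number that may be present, `n(n-1)/2`.
#' * `clustering_coefficient()` — global transitivity, three times the
#'   number of triangles divided by the number of connected triples
#'   (0 when no triples exist).
#' * `efficiency()` — mean over unordered node pairs of the inverse
#'   shortest-path length; disconnected pairs contribute 0.
#' * `eigenvector_centrality()` — principal-eigenvector scores of the
#'   adjacency matrix of the largest connected component, zero elsewhere,
#'   normalized to unit maximum; computed by power iteration on `A + I`
#'   (the shift removes bipartite oscillation) to relative tolerance 1e-10.
#'
#' All four are in `[0, 1]` (centrality per node).
#'
#' @param g A `binary_network` from [binarize()], or a symmetric 0/1 matrix.
#' @return A scalar, or for `eigenvector_centrality()` a numeric vector with
#'   one entry per node.
#' @export
#' @examples
#' star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
#' link_density(star)          # 0.4
#' efficiency(star)            # 0.7
#' clustering_coefficient(star) # 0 (a star has no triangles)
link_density <- function(g) {
  a <- as_adjacency(g)
  n <- nrow(a)
  if (n < 2) stop("link density needs at least 2 nodes", call. = FALSE)
  sum(a) / (n * (n - 1))  # sum counts each undirected edge twice
}

#' @rdname link_density
#' @export
clustering_coefficient <- function(g) {
  a <- as_adjacency(g)
  n <- nrow(a)
  if (n < 3) stop("clustering needs at least 3 nodes", call. = FALSE)
  deg <- colSums(a)
  n3_twice <- sum(deg * (deg - 1))        # 2 * number of connected triples
  if (n3_twice == 0) return(0)
  a2 <- a %*% a
  tr_a3 <- sum(a * a2)                    # = 6 * number of triangles
  # 3 * N_triangles / N_triples = (tr_a3 / 2) / (n3_twice / 2)
  tr_a3 / 2 / (n3_twice / 2)
}

#' @rdname link_density
#' @export
efficiency <- function(g) {
  a <- as_adjacency(g)
  n <- nrow(a)
  if (n < 2) stop("efficiency needs at least 2 nodes", call. = FALSE)
  if (sum(a) == 0) return(0)
  d <- igraph::distances(igraph::graph_from_adjacency_matrix(a, "undirected"))
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0   # disconnected pairs contribute 0; kills diagonal too
  sum(inv) / (n * (n - 1))
}

#' @rdname link_density
#' @param tol Relative convergence tolerance of the power iteration.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @export
eigenvector_centrality <- function(g, tol = 1e-10, max_iter = 1e5) {
  a <- as_adjacency(g)
  n <- nrow(a)
  if (n < 2) stop("centrality needs at least 2 nodes", call. = FALSE)
  if (sum(a) == 0) return(rep(0, n))
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(a, "undirected"))
  keep <- comp$membership == which.max(comp$csize)
  sub <- a[keep, keep, drop = FALSE]
  v <- rep(1 / sqrt(sum(keep)), sum(keep))
  for (it in seq_len(max_iter)) {
    # power iteration on A + I: same eigenvectors, strictly dominant
    # eigenvalue on a connected component, no bipartite flip-flop
    w <- as.vector(sub %*% v) + v
    w <- w / sqrt(sum(w^2))
    if (max(abs(w - v)) <= tol * max(abs(w))) {
      v <- w
      break
    }
    v <- w
    if (it == max_iter) {
      stop("eigenvector centrality did not converge within ", max_iter,
           " iterations", call. = FALSE)
    }
  }
  out <- rep(0, n)
  out[keep] <- v / max(v)
  out
}

#' Extract the network-feature vector of one subject
#'
#' Binarizes a weighted subject network at `threshold` and computes the
#' structural descriptors used for classification: link density, clustering
#' coefficient (transitivity), global efficiency, and eigenvector-centrality
#' summaries (maximum is 1 by construction whenever an edge exists, so the
#' summaries reported are the max/median ratio proxy via the Gini spread and
#' the raw per-node vector as a list column).
#'
#' @param network A `subject_network` from [reconstruct()].
#' @param threshold Binarization threshold in `[0, 1]` (default 0.65).
#' @return A one-row tibble of class `network_features`: `subject_id`,
#'   `threshold`, `density`, `clustering`, `efficiency`, `centrality_max`,
#'   `centrality_gini`, and a `centrality` list column with the per-node
#'   vector.
#' @export
extract_features <- function(network, threshold = 0.65) {
  stopifnot(inherits(network, "subject_network"))
  b <- binarize(network, threshold)
  a <- b$adjacency
  cent <- eigenvector_centrality(a)
  out <- tibble::tibble(
    subject_id = network$subject_id,
    threshold = threshold,
    density = link_density(a),
    clustering = clustering_coefficient(a),
    efficiency = efficiency(a),
    centrality_max = max(cent),
    centrality_gini = gini(cent),
    centrality = list(stats::setNames(cent, network$node_labels))
  )
  class(out) <- c("network_features", class(out))
  out
}

# Gini coefficient of a non-negative vector; 0 for a constant (or all-zero)
# vector, -> 1 as mass concentrates on one entry. Used as the spread summary
# of the centrality distribution (star-like disease networks score high).
gini <- function(x) {
  x <- sort(x)
  n <- length(x)
  s <- sum(x)
  if (n < 2 || s == 0) return(0)
  sum((2 * seq_len(n) - n - 1) * x) / (n * s)
}

#' Per-subject network feature table
#'
#' Reconstructs the network of every subject in `data` under `model`,
#' binarizes at `threshold`, and tabulates the scalar features — the input
#' expected by the classification stage and by [write_feature_table()].
#'
#' @param data A [spectral_dataset()].
#' @param model A `dual_class_model` from [fit_pair_models()].
#' @param threshold Binarization threshold (default 0.65).
#' @param features Which scalar features to compute; any of `"density"`,
#'   `"clustering"`, `"efficiency"`, `"centrality_max"`, `"centrality_gini"`.
#' @param symmetrization Passed to [reconstruct()].
#' @return A tibble with one row per subject: `subject_id`, `label`,
#'   `threshold`, and one column per requested feature.
#' @export
feature_table <- function(data, model, threshold = 0.65,
                          features = c("density", "clustering", "efficiency",
                                       "centrality_max", "centrality_gini"),
                          symmetrization = "mean") {
  check_spectra(data)
  features <- match.arg(features, several.ok = TRUE)
  x <- intensity_matrix(data)
  rows <- compute_feature_matrix(model, x, threshold, features, symmetrization)
  dplyr::bind_cols(
    tibble::tibble(subject_id = data$subject_id, label = data$label,
                   threshold = threshold),
    tibble::as_tibble(rows))
}

# fast path shared by feature_table() and the leave-one-out pipeline:
# subjects-by-features numeric matrix, no object overhead per subject
compute_feature_matrix <- function(model, x, threshold, features,
                                   symmetrization = "mean") {
  m <- nrow(x)
  out <- matrix(NA_real_, m, length(features),
                dimnames = list(rownames(x), features))
  need_cent <- any(c("centrality_max", "centrality_gini") %in% features)
  for (k in seq_len(m)) {
    w <- ordered_weights(model, x[k, ])
    w <- if (symmetrization == "max") pmax(w, t(w)) else (w + t(w)) / 2
    a <- (w > threshold) * 1
    diag(a) <- 0
    if ("density" %in% features) out[k, "density"] <- link_density(a)
    if ("clustering" %in% features) out[k, "clustering"] <- clustering_coefficient(a)
    if ("efficiency" %in% features) out[k, "efficiency"] <- efficiency(a)
    if (need_cent) {
      cent <- eigenvector_centrality(a)
      if ("centrality_max" %in% features) out[k, "centrality_max"] <- max(cent)
      if ("centrality_gini" %in% features) out[k, "centrality_gini"] <- gini(cent)
    }
  }
  out
}

#' Write a per-subject feature table to CSV
#'
#' @param features A tibble from [feature_table()].
#' @param path Output file.
#' @export
write_feature_table <- function(features, path) {
  df <- dplyr::select(features, -dplyr::any_of("centrality"))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
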