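test_that("metrics reproduce hand-computed reference graphs", {
  s5 <- star_graph(5)
  expect_equal(link_density(s5), 4 / 10)
  expect_equal(clustering_coefficient(s5), 0)
  expect_equal(efficiency(s5), (4 * 1 + 6 * 0.5) / 10)
  k4 <- complete_graph(4)
  expect_equal(link_density(k4), 1)
  expect_equal(clustering_coefficient(k4), 1)
  expect_equal(efficiency(k4), 1)
  empty <- matrix(0L, 3, 3)
  expect_equal(link_density(empty), 0)
  expect_equal(efficiency(empty), 0)
  expect_equal(clustering_coefficient(empty), 0)
  # two isolated nodes: the disconnected pair contributes zero
  expect_equal(efficiency(matrix(0L, 2, 2)), 0)
  # triangle plus a pendant: 1 triangle; triples: 3 in the triangle plus
  # 2 through the attachment vertex
  tri_p <- matrix(0L, 4, 4)
  tri_p[1, 2] <- tri_p[2, 1] <- 1L
  tri_p[1, 3] <- tri_p[3, 1] <- 1L
  tri_p[2, 3] <- tri_p[3, 2] <- 1L
  tri_p[3, 4] <- tri_p[4, 3] <- 1L
  expect_equal(clustering_coefficient(tri_p), oracle_clustering(tri_p))
  expect_equal(clustering_coefficient(tri_p), 3 / 5)
})

test_that("size preconditions are enforced", {
  expect_error(link_density(matrix(0, 1, 1)), "at least 2")
  expect_error(clustering_coefficient(matrix(0, 2, 2)), "at least 3")
  expect_error(efficiency(matrix(0, 1, 1)), "at least 2")
})

test_that("eigenvector centrality matches symmetry expectations", {
  s6 <- star_graph(6)
  cent <- eigenvector_centrality(s6)
  expect_equal(cent[1], 1)
  expect_true(all(cent[-1] < 1))
  expect_equal(length(unique(round(cent[-1], 12))), 1)
  c7 <- eigenvector_centrality(cycle_graph(7))
  expect_equal(max(c7) - min(c7), 0, tolerance = 1e-9)
  expect_equal(eigenvector_centrality(matrix(0L, 4, 4)), rep(0, 4))
})

test_that("all four metrics agree with brute-force oracles on random graphs", {
  set.seed(99)
  for (rep in 1:500) {
    n <- sample(3:7, 1)
    a <- random_adjacency(n, p = runif(1, 0.1, 0.9))
    expect_identical(link_density(a), oracle_density(a))
    expect_identical(clustering_coefficient(a), oracle_clustering(a))
    expect_equal(efficiency(a), oracle_efficiency(a), tolerance = 1e-12)
    expect_equal(eigenvector_centrality(a), oracle_centrality(a),
                 tolerance = 1e-8)
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(4:7, 1)
    a <- random_adjacency(n)
    p <- sample(n)
    ap <- a[p, p]
    expect_equal(link_density(ap), link_density(a))
    expect_equal(clustering_coefficient(ap), clustering_coefficient(a))
    expect_equal(efficiency(ap), efficiency(a), tolerance = 1e-12)
    # centrality is defined on the largest component; with tied component
    # sizes the reference component itself is permutation-dependent, so
    # compare only when the largest component is unique
    d <- oracle_distances(a)
    sizes <- table(apply(is.finite(d), 1, function(r) min(which(r))))
    if (sum(sizes == max(sizes)) == 1) {
      expect_equal(eigenvector_centrality(ap),
                   eigenvector_centrality(a)[p], tolerance = 1e-7)
    }
  }
})

test_that("deleting an edge never increases efficiency", {
  set.seed(23)
  for (rep in 1:25) {
    a <- random_adjacency(6, p = 0.6)
    if (sum(a) == 0) next
    e0 <- efficiency(a)
    edges <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
    k <- sample(nrow(edges), 1)
    a2 <- a
    a2[edges[k, 1], edges[k, 2]] <- a2[edges[k, 2], edges[k, 1]] <- 0L
    expect_lte(efficiency(a2), e0 + 1e-12)
  }
})

test_that("extract_features cascades from the thresholded graph", {
  fake_net <- function(w_val, n = 6) {
    w <- matrix(w_val, n, n); diag(w) <- 0
    structure(list(subject_id = "s", weights = w, ordered_weights = NULL,
                   node_labels = as.character(1:n),
                   degenerate_mask = matrix(FALSE, n, n),
                   symmetrization = "mean"),
              class = "subject_network")
  }
  lo <- extract_features(fake_net(0.5), threshold = 0.65)
  expect_equal(lo$density, 0)
  expect_equal(lo$clustering, 0)
  expect_equal(lo$efficiency, 0)
  hi <- extract_features(fake_net(0.9), threshold = 0.65)
  expect_equal(hi$density, 1)
  expect_equal(hi$clustering, 1)
  expect_equal(hi$efficiency, 1)
  expect_equal(hi$centrality_max, 1)
  expect_length(hi$centrality[[1]], 6)
})

test_that("disease networks are denser, more efficient, and pattern-centred", {
  cfg <- cohort_config(seed = 21)
  cohort <- generate_cohort(cfg)
  fit <- fit_pair_models(cohort)
  ft <- feature_table(cohort, fit, features = c("density", "efficiency"))
  by_class <- dplyr::summarise(
    dplyr::group_by(ft, label),
    density = mean(density), efficiency = mean(efficiency))
  ctl <- by_class[by_class$label == "control", ]
  dis <- by_class[by_class$label == "disease", ]
  expect_gt(dis$density, ctl$density)
  expect_gt(dis$efficiency, ctl$efficiency)
  # in patient networks the links gather around the disease-pattern bins:
  # pattern bins out-rank the rest in eigenvector centrality
  pattern <- c(cfg$hub_bins, unlist(lapply(cfg$hub_bins,
                                           function(h) h + 1:cfg$partners_per_hub)))
  net <- reconstruct(cohort, fit, subject_id = "disease_003")
  cent <- eigenvector_centrality(binarize(net, 0.65)$adjacency)
  expect_gt(mean(cent[pattern]), 1.2 * mean(cent[-pattern]))
})
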