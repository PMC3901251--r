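test_that("exact linear training data is recovered exactly", {
  set.seed(1)
  x <- rnorm(10, 5, 2)
  controls <- cbind(x, 2 * x + 1)           # y = 2x + 1, no residual
  patients <- cbind(rnorm(10), rnorm(10))
  fit <- fit_pair_models(controls = controls, patients = patients)
  expect_equal(fit$slope_c[1, 2], 2)
  expect_equal(fit$intercept_c[1, 2], 1)
  # residual std is floored, not zero: the Gaussian must stay proper
  expect_gt(fit$sd_c[1, 2], 0)
  expect_lt(fit$sd_c[1, 2], 1e-6)
})

test_that("a model over n bins holds exactly n(n-1) ordered pairs", {
  cohort <- generate_cohort(cohort_config(n_bins = 4, m_control = 5,
                                          m_disease = 5, hub_bins = 1,
                                          partners_per_hub = 1, seed = 2))
  fit <- fit_pair_models(cohort)
  tid <- tidy(fit)
  expect_equal(nrow(tid), 4 * 3)
  expect_equal(glance(fit)$n_pairs, 12)
  expect_false(any(tid$predictor_bin == tid$response_bin))
})

test_that("coefficients are recovered within 3 SE on a large cohort", {
  m <- 1000
  slope <- 1.5; intercept <- 0.5; resid_sd <- 0.1
  set.seed(42)
  xc <- rnorm(m, 2, 1)
  controls <- cbind(xc, slope * xc + intercept + rnorm(m, 0, resid_sd))
  xd <- rnorm(m, 2, 1)
  patients <- cbind(xd, 2.5 * xd - 1 + rnorm(m, 0, resid_sd))
  fit <- fit_pair_models(controls = controls, patients = patients)
  se_slope <- resid_sd / (sd(xc) * sqrt(m))
  se_int <- resid_sd * sqrt(1 / m + mean(xc)^2 / (m * var(xc)))
  se_sd <- resid_sd / sqrt(2 * m)
  expect_lt(abs(fit$slope_c[1, 2] - slope), 3 * se_slope)
  expect_lt(abs(fit$intercept_c[1, 2] - intercept), 3 * se_int)
  expect_lt(abs(fit$sd_c[1, 2] - resid_sd), 3 * se_sd)
  expect_lt(abs(fit$slope_d[1, 2] - 2.5), 3 * se_slope)
})

test_that("classes below the minimum fit size are rejected", {
  expect_error(
    fit_pair_models(controls = matrix(rnorm(4), 2, 2),
                    patients = matrix(rnorm(10), 5, 2)),
    "at least 3 subjects")
})

test_that("zero-variance bins flag their pairs degenerate, not an error", {
  controls <- cbind(rep(1, 5), rnorm(5), rnorm(5))
  patients <- matrix(rnorm(15), 5, 3)
  fit <- fit_pair_models(controls = controls, patients = patients)
  expect_true(fit$degenerate[1, 2])
  expect_true(fit$degenerate[2, 1])
  expect_false(fit$degenerate[2, 3])
  expect_equal(disease_probability(0.3, 0.7, fit, 1, 2), 0.5)
})

test_that("the weight matches direct Gaussian density evaluation", {
  # expected responses 1 (control) and 3 (disease), unit sds, observed 3:
  # closed form gives 1 / (1 + exp(-2))
  w <- pairwise_weight(0, 3, control = c(0, 1, 1), disease = c(0, 3, 1))
  expect_equal(w, 1 / (1 + exp(-2)), tolerance = 1e-12)
  direct <- dnorm(3, 3, 1) / (dnorm(3, 1, 1) + dnorm(3, 3, 1))
  expect_equal(w, direct, tolerance = 1e-12)
  # observed point equidistant from both expectations with equal sds
  expect_identical(pairwise_weight(0, 2, c(0, 1, 1), c(0, 3, 1)), 0.5)
  # indistinguishable class models
  expect_identical(pairwise_weight(1.3, -0.4, c(2, 1, 0.5), c(2, 1, 0.5)), 0.5)
})

test_that("weights normalize: swapping classes maps w to 1 - w", {
  set.seed(5)
  for (rep in 1:50) {
    ctl <- c(rnorm(2), rexp(1) + 0.01)
    dis <- c(rnorm(2), rexp(1) + 0.01)
    xi <- rnorm(1, 0, 3); xj <- rnorm(1, 0, 3)
    w <- pairwise_weight(xi, xj, ctl, dis)
    expect_gte(w, 0); expect_lte(w, 1)
    # the two class probabilities sum to one (absolute tolerance: weights
    # saturate near 0/1 where relative comparison is meaningless)
    expect_lt(abs(pairwise_weight(xi, xj, dis, ctl) - (1 - w)), 1e-12)
  }
})

test_that("label swap at the model level flips every weight", {
  cohort <- generate_cohort(small_config(seed = 8))
  x <- intensity_matrix(cohort)
  ctl <- x[cohort$label == "control", ]
  dis <- x[cohort$label == "disease", ]
  fit <- fit_pair_models(controls = ctl, patients = dis)
  swapped <- fit_pair_models(controls = dis, patients = ctl)
  subj <- x[1, ]
  w1 <- reconstruct(subj, fit)$weights
  w2 <- reconstruct(subj, swapped)$weights
  off <- upper.tri(w1)
  expect_equal(w2[off], 1 - w1[off], tolerance = 1e-12)
})

test_that("with equal sds the weight exceeds 0.5 iff the point is closer to the disease line", {
  set.seed(6)
  for (rep in 1:100) {
    ctl <- c(rnorm(2), 0.7)
    dis <- c(rnorm(2), 0.7)
    xi <- rnorm(1); xj <- rnorm(1, 0, 2)
    yc <- ctl[1] * xi + ctl[2]
    yd <- dis[1] * xi + dis[2]
    w <- pairwise_weight(xi, xj, ctl, dis)
    if (abs(xj - yd) < abs(xj - yc)) expect_gt(w, 0.5)
    if (abs(xj - yd) > abs(xj - yc)) expect_lt(w, 0.5)
  }
})

test_that("weights are invariant to a common affine rescaling of the bins", {
  cohort <- generate_cohort(small_config(seed = 9))
  x <- intensity_matrix(cohort)
  ctl <- x[cohort$label == "control", ]
  dis <- x[cohort$label == "disease", ]
  fit <- fit_pair_models(controls = ctl, patients = dis)
  w0 <- reconstruct(x[3, ], fit)$weights
  a <- 2.5; b <- -7
  fit2 <- fit_pair_models(controls = a * ctl + b, patients = a * dis + b)
  w1 <- reconstruct(a * x[3, ] + b, fit2)$weights
  expect_equal(w1, w0, tolerance = 1e-8)
})

test_that("extreme points keep the weight finite (log-space computation)", {
  # observations hundreds of sds from both lines: naive density ratio is 0/0
  w_far <- pairwise_weight(0, 500, c(0, 0, 1), c(0, 1, 1))
  expect_true(is.finite(w_far))
  expect_equal(w_far, 1, tolerance = 1e-10)   # far side of the disease line
  w_other <- pairwise_weight(0, -500, c(0, 0, 1), c(0, 1, 1))
  expect_equal(w_other, 0, tolerance = 1e-10)
  expect_error(pairwise_weight(Inf, 0, c(0, 0, 1), c(0, 1, 1)), "finite")
})

test_that("model serialization round-trips coefficients and weights", {
  cohort <- generate_cohort(small_config(seed = 10))
  fit <- fit_pair_models(cohort)
  path <- withr::local_tempfile(fileext = ".json")
  write_pair_models(fit, path)
  back <- read_pair_models(path)
  x <- intensity_matrix(cohort)[2, ]
  expect_equal(reconstruct(x, back)$weights, reconstruct(x, fit)$weights,
               tolerance = 1e-12)
  expect_equal(back$n_bins, fit$n_bins)
})
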