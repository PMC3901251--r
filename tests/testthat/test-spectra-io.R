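test_that("loader reads a small cohort and validates labels", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "subject_id,label,1.0,2.0,3.0,4.0",
    "s1,control,1,2,3,4",
    "s2,disease,5,6,7,8",
    "s3,unlabeled,9,10,11,12"), path)
  d <- read_spectra(path)
  expect_s3_class(d, "spectral_dataset")
  expect_equal(nrow(d), 3)
  expect_equal(bin_axis(d), c(1, 2, 3, 4))
  expect_equal(unname(intensity_matrix(d)[2, ]), c(5, 6, 7, 8))
  expect_equal(d$label, c("control", "disease", "unlabeled"))
})

test_that("loader rejects unknown labels, naming the allowed set", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,label,1,2", "s1,patient,1,2"), path)
  expect_error(read_spectra(path), "control, disease, unlabeled")
  # alias table maps study-specific names onto the canonical vocabulary
  d <- read_spectra(path, label_aliases = c(patient = "disease"))
  expect_equal(d$label, "disease")
})

test_that("loader rejects non-numeric intensities naming row and column", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,label,1,2", "s1,control,1,oops"), path)
  expect_error(read_spectra(path), "s1.*'2'")
})

test_that("write/read round trip preserves everything bit for bit", {
  cohort <- generate_cohort(small_config(seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(cohort, path)
  back <- read_spectra(path)
  expect_identical(intensity_matrix(back), intensity_matrix(cohort))
  expect_identical(back$subject_id, cohort$subject_id)
  expect_identical(back$label, cohort$label)
  expect_identical(bin_axis(back), bin_axis(cohort))
})

test_that("binning groups consecutive columns by their mean", {
  x <- matrix(rnorm(2 * 200), 2, 200)
  d <- spectral_dataset(x, c("a", "b"), c("control", "disease"))
  b <- bin_spectrum(d, bin_size = 10)
  expect_equal(length(bin_axis(b)), 20)
  expect_equal(unname(intensity_matrix(b)[, 1]), rowMeans(x[, 1:10]))
  expect_equal(unname(intensity_matrix(b)[, 20]), rowMeans(x[, 191:200]))
  # sum aggregation behind the flag
  bs <- bin_spectrum(d, bin_size = 10, aggregate = "sum")
  expect_equal(unname(intensity_matrix(bs)[, 1]), rowSums(x[, 1:10]))
})

test_that("binning identity, constants, partial bins and errors", {
  x <- matrix(rnorm(3 * 7), 3, 7)
  d <- spectral_dataset(x, c("a", "b", "c"),
                        c("control", "disease", "unlabeled"))
  expect_equal(intensity_matrix(bin_spectrum(d, bin_size = 1)),
               intensity_matrix(d))
  const <- spectral_dataset(matrix(5, 3, 9), c("a", "b", "c"),
                            rep("control", 3))
  expect_true(all(intensity_matrix(bin_spectrum(const, bin_size = 4)) == 5))
  # 7 columns at size 3: trailing partial bin of 1 column kept
  b <- bin_spectrum(d, bin_size = 3)
  expect_equal(length(bin_axis(b)), 3)
  expect_equal(unname(intensity_matrix(b)[, 3]), x[, 7])
  expect_match(tail(provenance(b), 1), "partial")
  expect_error(bin_spectrum(d, bin_size = 8), "exceeds")
})

test_that("masking removes exactly the covered bin centers", {
  axis <- seq(0.02, 8, by = 0.04)  # 200 bins of width 0.04 spanning 0-8
  d <- spectral_dataset(matrix(rnorm(3 * 200), 3, 200),
                        c("a", "b", "c"), rep("control", 3),
                        bin_axis = axis, bin_width = 0.04)
  m <- mask_bins(d, list(c(4.5, 5.0)))
  expected_removed <- sum(axis >= 4.5 & axis <= 5.0)
  expect_equal(length(bin_axis(m)), 200 - expected_removed)
  expect_false(any(bin_axis(m) >= 4.5 & bin_axis(m) <= 5.0))
  # empty region list: identity
  expect_identical(intensity_matrix(mask_bins(d, list())), intensity_matrix(d))
  # overlapping intervals behave as their union
  m2 <- mask_bins(d, list(c(4.5, 4.8), c(4.7, 5.0)))
  expect_identical(bin_axis(m2), bin_axis(m))
  expect_error(mask_bins(d, list(c(-1, 9))), "every bin")
})

test_that("binning then masking equals masking then binning when bins nest", {
  # axis 1..20, bins of 4 -> groups 1-4, 5-8, ...; region covering columns
  # 5..12 is exactly two whole bins, so the operations commute
  x <- matrix(rnorm(4 * 20), 4, 20)
  d <- spectral_dataset(x, paste0("s", 1:4), rep(c("control", "disease"), 2))
  a <- mask_bins(bin_spectrum(d, bin_size = 4), list(c(4.5, 12.5)))
  b <- bin_spectrum(mask_bins(d, list(c(4.5, 12.5))), bin_size = 4)
  expect_equal(intensity_matrix(a), intensity_matrix(b))
  expect_equal(bin_axis(a), bin_axis(b))
})

test_that("additive noise has the configured moments and is seeded", {
  d <- spectral_dataset(matrix(rnorm(100 * 100), 100, 100),
                        sprintf("s%03d", 1:100), rep("control", 100))
  expect_identical(intensity_matrix(add_noise(d, 0, 1)), intensity_matrix(d))
  n1 <- add_noise(d, 1, seed = 7)
  n2 <- add_noise(d, 1, seed = 7)
  expect_identical(intensity_matrix(n1), intensity_matrix(n2))
  delta <- intensity_matrix(n1) - intensity_matrix(d)
  n_cells <- length(delta)
  expect_lt(abs(mean(delta)), 3 / sqrt(n_cells))           # 3 SE of the mean
  expect_lt(abs(sd(delta) - 1), 3 / sqrt(2 * n_cells))     # 3 SE of the sd
  expect_error(add_noise(d, -1, 1), "non-negative")
})

test_that("stacked noise variances add", {
  d <- spectral_dataset(matrix(0, 120, 120), sprintf("s%03d", 1:120),
                        rep("control", 120))
  noisy <- add_noise(add_noise(d, 0.6, seed = 1), 0.8, seed = 2)
  delta <- intensity_matrix(noisy)
  expect_lt(abs(sd(delta) - 1), 3 / sqrt(2 * length(delta)))  # sqrt(.36+.64)
})
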