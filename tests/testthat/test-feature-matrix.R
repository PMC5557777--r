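test_that("distribution statistics match hand computation", {
  # constant vector: all spread/shape statistics vanish
  s <- summarize_distributed(c(1, 1, 1))
  expect_equal(s$mean, 1)
  expect_equal(s$median, 1)
  expect_equal(s$sdev, 0)
  expect_equal(s$cv, 0)
  expect_equal(s$skew, 0)

  # symmetric vector: zero skewness
  expect_equal(summarize_distributed(c(1, 2, 3))$skew, 0)

  # textbook moment formulas evaluated directly on an asymmetric vector
  x <- c(1, 2, 3, 10)
  n <- length(x)
  m <- sum(x) / n
  s2 <- sum((x - m)^2) / (n - 1)
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m4 <- sum((x - m)^4) / n
  got <- summarize_distributed(x)
  expect_equal(got$mean, m)
  expect_equal(got$median, median(x))
  expect_equal(got$sdev, sqrt(s2))
  expect_equal(got$cv, sqrt(s2) / m)
  expect_equal(got$ci95, qt(0.975, n - 1) * sqrt(s2 / n))
  expect_equal(got$skew, m3 / m2^1.5)
  expect_equal(got$kurt, m4 / m2^2 - 3)
})

test_that("length-1 vectors are flagged with zero spread by convention", {
  s <- summarize_distributed(5)
  expect_true(s$degenerate)
  expect_equal(s$sdev, 0)
  expect_equal(s$ci95, 0)
  expect_error(summarize_distributed(numeric(0)), "empty")
})

test_that("mode uses the KDE peak for continuous, top count for integers", {
  # bimodal with heavier left mode
  set.seed(2)
  x <- c(rnorm(300, 0, 0.2), rnorm(100, 3, 0.2))
  expect_lt(abs(summarize_distributed(x)$mode), 0.3)
  # integer data: most frequent value, lowest-value tie-break
  expect_equal(summarize_distributed(c(1, 1, 2, 2, 3))$mode, 1)
})

test_that("the default catalog expands to 110 columns", {
  fm <- build_feature_matrix(default_sim())
  expect_length(feature_names(fm), 110)
  dict <- feature_dictionary(fm)
  expect_equal(sum(dict$statistic == "none"), 14)
  expect_equal(sum(dict$statistic != "none"), 96)
})

test_that("expansion count is n_scalar + 8 * n_distributed for any catalog", {
  sim <- default_sim()
  full <- morphology_catalog()
  for (pick in list(c(1, 0), c(0, 1), c(3, 2), c(5, 7))) {
    cat_i <- dplyr::bind_rows(
      dplyr::slice_head(full[!full$distributed, ], n = pick[1]),
      dplyr::slice_head(full[full$distributed, ], n = pick[2]))
    fm <- build_feature_matrix(sim, cat_i)
    expect_length(feature_names(fm), pick[1] + 8 * pick[2])
  }
})

test_that("unknown features in the data are reported by name", {
  sim <- default_sim()
  bad <- sim
  bad$processes <- dplyr::bind_rows(
    sim$processes,
    tibble::tibble(cell_id = "c001", feature = "Mystery metric", value = 1))
  expect_error(build_feature_matrix(bad), "Mystery metric")
})

test_that("zscoring gives exact column means 0 and sdev 1, idempotently", {
  # two-point column: sample-sd convention
  fm <- toy_features(cbind(a = c(0, 2), b = c(5, 9)))
  z <- zscore_features(fm)
  expect_equal(z$a, c(-1, 1) / sqrt(2))
  m <- as.matrix(z[, feature_names(z)])
  expect_true(max(abs(colMeans(m))) < 1e-12)
  expect_true(max(abs(apply(m, 2, sd) - 1)) < 1e-12)
  # idempotence
  z2 <- zscore_features(z)
  expect_equal(as.matrix(z2[, feature_names(z2)]), m, tolerance = 1e-10)
})

test_that("constant columns are dropped with a warning; all-constant errors", {
  fm <- toy_features(cbind(a = c(1, 1, 1, 1), b = 1:4))
  expect_warning(z <- zscore_features(fm), "constant")
  expect_equal(feature_names(z), "b")
  allc <- toy_features(cbind(a = rep(2, 4), b = rep(3, 4)))
  expect_error(suppressWarnings(zscore_features(allc)), "constant")
})

test_that("feature selection honours both branches and neither", {
  loadings <- tibble::tibble(
    feature = c("loading_only", "p_only", "neither"),
    PC1 = c(0.25, 0.10, 0.10), PC2 = c(0, 0.10, 0),
    PC3 = c(0, 0.10, 0), PC4 = c(0, 0.10, 0))
  odp <- tibble::tibble(feature = loadings$feature, p = c(0.9, 0.01, 0.5))
  sel <- select_features(loadings, odp, magnitude = "max")
  expect_equal(sel$selected, c(TRUE, TRUE, FALSE))
  expect_error(select_features(loadings[, 1:4], odp), "4 components")
})

test_that("loosening a selection threshold never removes a feature", {
  set.seed(9)
  loadings <- tibble::tibble(feature = paste0("f", 1:50))
  for (pc in paste0("PC", 1:4)) loadings[[pc]] <- runif(50, -0.4, 0.4)
  odp <- tibble::tibble(feature = loadings$feature, p = runif(50))
  for (mag in c("max", "l2")) {
    tight <- select_features(loadings, odp, 0.25, 0.02, magnitude = mag)
    loose <- select_features(loadings, odp, 0.15, 0.10, magnitude = mag)
    expect_true(all(loose$selected[tight$selected]))
  }
})

test_that("non-negative shift zeroes each feature's minimum, always", {
  fm <- toy_features(cbind(a = c(-1, 0, 1, 2), b = c(2, 3, 4, 5)))
  d <- shift_nonnegative(fm)
  expect_equal(d$a, c(0, 1, 2, 3))
  expect_equal(d$b, c(0, 1, 2, 3))  # positive minimum is subtracted too
  set.seed(3)
  r <- toy_features(matrix(rnorm(80), 8, dimnames = list(NULL, paste0("f", 1:10))))
  dr <- as.matrix(shift_nonnegative(r)[, paste0("f", 1:10)])
  expect_true(all(dr >= 0))
  expect_true(all(abs(apply(dr, 2, min)) < 1e-14))
})
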