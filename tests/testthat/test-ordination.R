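test_that("principal components satisfy their defining identities", {
  set.seed(14)
  m <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("f", 1:10)))
  fm <- toy_features(m)
  pca <- morph_pca(fm)
  L <- as.matrix(pca$loadings[, -1])
  # orthonormal loadings
  expect_equal(max(abs(crossprod(L) - diag(ncol(L)))), 0, tolerance = 1e-10)
  # variance fractions sum to 1
  expect_equal(sum(pca$variance$variance_fraction), 1)
  # scores equal centered data projected on the loadings (independent oracle)
  centered <- scale(m, center = TRUE, scale = FALSE)
  expect_equal(as.matrix(pca$scores[, -1]), centered %*% L,
               tolerance = 1e-10, ignore_attr = TRUE)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(L))) {
    expect_gt(L[which.max(abs(L[, j])), j], 0)
  }
})

test_that("two perfectly correlated features collapse onto one component", {
  x <- rnorm(30)
  fm <- toy_features(cbind(a = x, b = 2 * x + 1))
  pca <- morph_pca(fm)
  expect_equal(pca$variance$variance_fraction[1], 1, tolerance = 1e-12)
})

test_that("rank-correlation distance matches a rank-then-Pearson oracle", {
  set.seed(15)
  m <- matrix(rnorm(60), 4, 15, dimnames = list(NULL, paste0("f", 1:15)))
  m[2, ] <- -m[1, ] * 3 + 100       # anti-monotone with cell 1
  fm <- toy_features(m)
  d <- spearman_distance(fm)
  expect_equal(diag(d), rep(0, 4), ignore_attr = TRUE)
  expect_equal(d, t(d))
  expect_equal(d[1, 2], 2)
  r_oracle <- cor(rank(m[3, ]), rank(m[4, ]))
  expect_equal(d[3, 4], 1 - r_oracle)
  expect_true(all(d >= 0 & d <= 2))
  # constant profile errors with the cell named
  m2 <- m
  m2[2, ] <- 7
  expect_error(spearman_distance(toy_features(m2)), "c02")
})

test_that("an exactly embeddable configuration reaches near-zero stress", {
  set.seed(16)
  pts <- matrix(rnorm(36), 12, 3)
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- sprintf("c%02d", 1:12)
  fit <- suppressWarnings(morph_nmds(d, k = 3, seed = 1, n_restarts = 10))
  expect_lt(fit$stress, 0.01)
  expect_equal(nrow(fit$coords), 12)
})

test_that("stress does not increase with embedding dimension", {
  z <- default_selected()
  sub <- z[seq(1, nrow(z), by = 4), ]   # 55 cells keep this quick
  d <- spearman_distance(sub)
  s2 <- suppressWarnings(morph_nmds(d, k = 2, seed = 1, n_restarts = 8)$stress)
  s3 <- suppressWarnings(morph_nmds(d, k = 3, seed = 1, n_restarts = 8)$stress)
  expect_lte(s3, s2 + 1e-8)
})

test_that("planted clusters are compact in the embedding", {
  z <- default_selected()
  fitn <- default_nmf()
  sub_idx <- seq(1, nrow(z), by = 2)
  sub <- z[sub_idx, ]
  d <- spearman_distance(sub)
  fit <- suppressWarnings(morph_nmds(d, k = 3, seed = 1, n_restarts = 10))
  cl <- fitn$clusters$cluster[sub_idx]
  co <- as.matrix(fit$coords[, -1])
  ed <- as.matrix(dist(co))
  same <- outer(cl, cl, "==") & upper.tri(ed)
  diff_ <- outer(cl, cl, "!=") & upper.tri(ed)
  expect_lt(mean(ed[same]), mean(ed[diff_]))
})

test_that("hypergeometric enrichment equals exhaustive enumeration", {
  cl <- tibble::tibble(cell_id = as.character(1:20),
                       cluster = rep(c(1, 2), c(5, 15)))
  g <- tibble::tibble(cell_id = as.character(1:20),
                      genotype = rep(c("KO", "WT"), each = 10))
  enr <- cluster_enrichment(cl, g)
  # all 5 draws KO out of 10 KO / 20 cells: C(10,5)/C(20,5)
  expect_equal(enr$p[enr$cluster == 1], choose(10, 5) / choose(20, 5))
  expect_equal(enr$p[enr$cluster == 1], 0.016253, tolerance = 1e-4)
  # whole population as one cluster: certain to contain all KO cells
  one <- cluster_enrichment(
    tibble::tibble(cell_id = as.character(1:20), cluster = 1), g)
  expect_equal(one$p, 1)
})
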