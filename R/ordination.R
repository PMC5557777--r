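#' Principal component analysis of a feature matrix
#'
#' Projects cells onto orthonormal directions of maximal feature variance.
#' The input is centered internally (Z-scored input is unchanged by this);
#' no re-scaling is applied. Signs follow the convention that each
#' component's largest-magnitude loading is positive.
#'
#' @param fm A `morph_features` tibble.
#' @param n_comp Number of components to retain (default: all).
#' @return A `morph_pca` object with tibbles `scores` (`cell_id`, `PC1`,
#'   ...), `loadings` (`feature`, `PC1`, ...), and `variance` (`component`,
#'   `variance_fraction`); fractions sum to 1 over all components.
#' @export
morph_pca <- function(fm, n_comp = NULL) {
  m <- feature_values(fm)
  pr <- prcomp(m, center = TRUE, scale. = FALSE)
  k_full <- length(pr$sdev)
  k <- min(n_comp %||% k_full, k_full)
  flip <- vapply(seq_len(k), function(j) {
    v <- pr$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  load <- sweep(pr$rotation[, seq_len(k), drop = FALSE], 2, flip, `*`)
  scores <- sweep(pr$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  out <- list(
    scores = dplyr::bind_cols(tibble(cell_id = fm$cell_id),
                              as_tibble(scores)),
    loadings = dplyr::bind_cols(tibble(feature = colnames(m)),
                                as_tibble(load)),
    variance = tibble(component = seq_len(k_full),
                      variance_fraction = pr$sdev^2 / sum(pr$sdev^2))
  )
  class(out) <- "morph_pca"
  out
}

#' @export
print.morph_pca <- function(x, ...) {
  vf <- x$variance$variance_fraction
  cat(sprintf("<morph_pca> %d cells, %d features; PC1-4 variance: %s\n",
              nrow(x$scores), nrow(x$loadings),
              paste(sprintf("%.1f%%", 100 * vf[1:min(4, length(vf))]),
                    collapse = ", ")))
  invisible(x)
}

#' @method tidy morph_pca
#' @export
tidy.morph_pca <- function(x, matrix = c("loadings", "scores", "variance"),
                           ...) {
  matrix <- match.arg(matrix)
  as_tibble(x[[matrix]])
}

#' Spearman rank-correlation distance between cells
#'
#' `d_ij = 1 - rho_ij`, where `rho` is the Spearman rank correlation of two
#' cells' feature profiles across all features; values lie in `[0, 2]` and
#' the diagonal is 0. A cell with a constant profile has no defined rank
#' correlation and raises an error naming the cell.
#'
#' @param fm A `morph_features` tibble with >= 2 features.
#' @return A symmetric cells-by-cells matrix with cell ids as dimnames.
#' @export
spearman_distance <- function(fm) {
  m <- feature_values(fm)
  if (ncol(m) < 2) abort("need at least 2 features per cell")
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    abort(paste0("constant feature profile for cell(s): ",
                 paste(rownames(m)[sds == 0], collapse = ", ")))
  }
  d <- 1 - cor(t(m), method = "spearman")
  dimnames(d) <- list(fm$cell_id, fm$cell_id)
  diag(d) <- 0
  d
}

#' Nonmetric multidimensional scaling of a cell distance matrix
#'
#' Embeds cells in `k` dimensions by minimising Kruskal stress-1 over
#' monotone transformations of the input dissimilarities (isotonic
#' regression iterations with random restarts, via \pkg{vegan}).
#'
#' @param d Symmetric dissimilarity matrix, e.g. from
#'   [spearman_distance()].
#' @param k Embedding dimension (default 3).
#' @param seed Seed for the restarts.
#' @param n_restarts Random restarts; the best configuration is returned.
#' @return A `morph_nmds` object: `coords` tibble (`cell_id`, `MDS1..k`),
#'   `stress` (in `[0, 1]`), `converged`.
#' @export
morph_nmds <- function(d, k = 3, seed = 1L, n_restarts = 20) {
  fit <- withr::with_seed(seed, {
    vegan::metaMDS(as.dist(d), k = k, trymax = n_restarts,
                   autotransform = FALSE, trace = 0, wascores = FALSE)
  })
  if (!fit$converged) {
    warn("nonmetric MDS did not converge; returning best configuration found")
  }
  coords <- as_tibble(fit$points, .name_repair = "minimal")
  names(coords) <- paste0("MDS", seq_len(k))
  out <- list(coords = dplyr::bind_cols(
                tibble(cell_id = rownames(d) %||%
                         as.character(seq_len(nrow(d)))), coords),
              stress = fit$stress, converged = isTRUE(fit$converged))
  class(out) <- "morph_nmds"
  out
}

#' @export
print.morph_nmds <- function(x, ...) {
  cat(sprintf("<morph_nmds> %d cells in %d dimensions, stress %.4f\n",
              nrow(x$coords), ncol(x$coords) - 1, x$stress))
  invisible(x)
}

#' @method glance morph_nmds
#' @export
glance.morph_nmds <- function(x, ...) {
  tibble(stress = x$stress, converged = x$converged,
         n_cells = nrow(x$coords))
}

#' Genotype enrichment of cell clusters
#'
#' Upper-tail hypergeometric probability that a cluster contains at least
#' its observed number of knockout cells, given the population composition
#' (sampling without replacement). Empty clusters get `p = 1` and are
#' flagged.
#'
#' @param clusters Tibble with `cell_id` and `cluster` (e.g.
#'   `fit$clusters`).
#' @param genotypes Tibble with `cell_id` and `genotype`, or a vector
#'   aligned with `clusters`.
#' @param enriched_for Genotype whose overrepresentation is tested
#'   (default `"KO"`).
#' @return Tibble: `cluster`, `n_cells`, `n_enriched`, `p`, `empty`.
#' @examples
#' cl <- tibble::tibble(cell_id = as.character(1:20),
#'                      cluster = rep(c(1, 2), c(5, 15)))
#' g <- tibble::tibble(cell_id = as.character(1:20),
#'                     genotype = rep(c("KO", "WT"), each = 10))
#' cluster_enrichment(cl, g)  # cluster 1: all-KO, p ~ 0.0163
#' @export
cluster_enrichment <- function(clusters, genotypes, enriched_for = "KO") {
  if (!is.data.frame(genotypes)) {
    genotypes <- tibble(cell_id = clusters$cell_id, genotype = genotypes)
  }
  df <- dplyr::left_join(clusters, genotypes, by = "cell_id")
  if (dplyr::n_distinct(df$genotype) != 2) {
    abort("exactly two genotype labels required")
  }
  n_total <- nrow(df)
  n_ko <- sum(df$genotype == enriched_for)
  df |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     n_enriched = sum(.data$genotype == enriched_for),
                     .groups = "drop") |>
    dplyr::mutate(
      empty = .data$n_cells == 0,
      p = ifelse(.data$empty, 1,
                 phyper(.data$n_enriched - 1, n_ko, n_total - n_ko,
                        .data$n_cells, lower.tail = FALSE)))
}
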