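#' Offset non-negative matrix factorization of a feature matrix
#'
#' Decomposes the non-negative features-by-cells data matrix `D` as
#' `D ~ W H + c 1'`, where `W` (features x rank) holds meta-feature basis
#' vectors, `H` (rank x cells) holds per-cell coefficients, and the
#' per-feature offset column `c` absorbs features expressed at constant
#' levels across cells. Factors are initialised by non-negative double SVD
#' (negative parts zeroed, zeros filled with the matrix mean so
#' multiplicative updates cannot lock at zero) and refined by
#' multiplicative updates for `W`, `H` and `c` that minimise squared
#' reconstruction error; the error sequence is non-increasing. Cells are
#' assigned to the meta-feature with the largest coefficient relative to
#' that meta-feature's population average (row-mean-normalised argmax over
#' each cell's coefficient column; lowest index wins ties).
#'
#' @param x A `morph_features` tibble (cells x features; transposed
#'   internally) or a non-negative numeric matrix already oriented
#'   features x cells.
#' @param rank Factorization rank (number of meta-features / cell states).
#' @param seed Seed for the random jitter applied after SVD initialisation.
#' @param max_iter,tol Stopping rule: relative error change below `tol` or
#'   `max_iter` updates.
#' @return A `morph_nmf` object: `W`, `H`, `offset`, `rank`,
#'   `error_trace`, `reconstruction_error` (relative Frobenius),
#'   `clusters` (tibble `cell_id`, `cluster`), `converged`, `iterations`.
#' @examples
#' D <- matrix(runif(60), 6, 10)
#' fit <- morph_nmf(D, rank = 2, seed = 1)
#' fit$reconstruction_error
#' @export
morph_nmf <- function(x, rank = 6, seed = 1L, max_iter = 2000, tol = 1e-7) {
  D <- if (inherits(x, "morph_features")) t(feature_values(x)) else as.matrix(x)
  if (any(D < 0)) abort("data matrix must be non-negative")
  if (rank < 1 || rank > min(dim(D))) {
    abort(sprintf("rank must be in 1..%d", min(dim(D))))
  }

  init <- withr::with_seed(seed, nndsvd_init(D, rank))
  W <- init$W
  H <- init$H
  offset <- pmax(rowMeans(D) * 0.1, 1e-6)
  eps <- 1e-12
  dnorm <- sqrt(sum(D^2))

  err <- numeric(0)
  prev <- Inf
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    R <- W %*% H + offset        # recycled column-wise: offset per feature
    H <- H * (crossprod(W, D) / (crossprod(W, R) + eps))
    R <- W %*% H + offset
    W <- W * (D %*% t(H)) / (R %*% t(H) + eps)
    R <- W %*% H + offset
    offset <- offset * rowSums(D) / (rowSums(R) + eps)
    e <- sqrt(sum((D - W %*% H - offset)^2)) / dnorm
    err <- c(err, e)
    if (is.finite(prev) && abs(prev - e) < tol * max(prev, eps)) {
      converged <- TRUE
      break
    }
    prev <- e
  }

  # resolve the W/H scale ambiguity before argmax clustering: unit-sum
  # basis columns, compensating scale moved into the coefficients; cells
  # are then assigned to the meta-feature most enriched relative to its
  # population average (row-mean-normalised argmax), which is invariant
  # to the residual per-component scale
  s <- pmax(colSums(W), eps)
  W <- sweep(W, 2, s, `/`)
  H <- H * s
  cl <- apply(H / pmax(rowMeans(H), eps), 2, which.max)
  cell_ids <- colnames(D) %||% as.character(seq_len(ncol(D)))
  out <- list(W = W, H = H, offset = as.numeric(offset), rank = rank,
              error_trace = err, reconstruction_error = err[length(err)],
              clusters = tibble(cell_id = cell_ids, cluster = as.integer(cl)),
              converged = converged, iterations = iter,
              features = rownames(D) %||% as.character(seq_len(nrow(D))))
  class(out) <- "morph_nmf"
  out
}

# non-negative double SVD initialisation, mean-based zero fill
nndsvd_init <- function(D, rank) {
  sv <- svd(D, nu = rank, nv = rank)
  W <- matrix(0, nrow(D), rank)
  H <- matrix(0, rank, ncol(D))
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (rank > 1) {
    for (j in 2:rank) {
      u <- sv$u[, j]
      v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      n_p <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
      n_n <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
      if (n_p >= n_n && n_p > 0) {
        W[, j] <- sqrt(sv$d[j] * n_p) * up / sqrt(sum(up^2))
        H[j, ] <- sqrt(sv$d[j] * n_p) * vp / sqrt(sum(vp^2))
      } else if (n_n > 0) {
        W[, j] <- sqrt(sv$d[j] * n_n) * un / sqrt(sum(un^2))
        H[j, ] <- sqrt(sv$d[j] * n_n) * vn / sqrt(sum(vn^2))
      }
    }
  }
  fill <- mean(D)
  W[W <= 0] <- fill * (1 + 0.01 * runif(sum(W <= 0)))
  H[H <= 0] <- fill * (1 + 0.01 * runif(sum(H <= 0)))
  rownames(W) <- rownames(D)
  colnames(H) <- colnames(D)
  list(W = W, H = H)
}

#' Group features into feature sets from the basis matrix
#'
#' Rows of `W` are normalised to unit sum (all-zero rows are labelled
#' `"unassigned"`), hierarchically clustered on correlation distance with
#' average linkage, and the tree is cut at the number of clusters (2 to
#' `rank`) with the largest mean silhouette width. Labels are ordered by
#' cluster size (`fs1` the largest).
#'
#' @param fit A `morph_nmf` object.
#' @param k Optional fixed number of feature sets; by default chosen by
#'   silhouette.
#' @return Tibble: `feature`, `feature_set`.
#' @export
assign_feature_sets <- function(fit, k = NULL) {
  W <- fit$W
  rs <- rowSums(W)
  ok <- rs > 0
  Wn <- W[ok, , drop = FALSE] / rs[ok]
  dmat <- 1 - cor(t(Wn))
  d <- as.dist(dmat)
  hc <- hclust(d, method = "average")
  if (is.null(k)) {
    ks <- 2:min(fit$rank, nrow(Wn) - 1)
    sil <- vapply(ks, function(kk) {
      cl <- cutree(hc, kk)
      mean(cluster::silhouette(cl, d)[, "sil_width"])
    }, numeric(1))
    k <- ks[which.max(sil)]
  }
  cl <- cutree(hc, k)
  sizes <- sort(table(cl), decreasing = TRUE)
  relabel <- setNames(paste0("fs", seq_along(sizes)), names(sizes))
  out <- tibble(feature = fit$features,
                feature_set = "unassigned")
  out$feature_set[ok] <- unname(relabel[as.character(cl)])
  out
}

#' Survey factorization ranks
#'
#' Runs the factorization over a range of ranks and several seeds and
#' summarises, per rank: the best relative reconstruction error, factor
#' sparsity (fraction of near-zero entries of the normalised `W`), and
#' cluster stability (mean pairwise adjusted Rand index of the cell
#' clusterings across seeds; defined as 1 at rank 1).
#'
#' @param x Input as in [morph_nmf()].
#' @param ranks Integer vector of ranks to survey.
#' @param seeds At least two seeds for the stability estimate.
#' @param ... Passed to [morph_nmf()].
#' @return Tibble: `rank`, `error`, `sparsity`, `stability`.
#' @export
nmf_rank_survey <- function(x, ranks = 1:12, seeds = 1:3, ...) {
  if (length(seeds) < 2) abort("need >= 2 seeds for the stability estimate")
  purrr::map(ranks, function(r) {
    fits <- purrr::map(seeds, function(s) morph_nmf(x, rank = r, seed = s, ...))
    errs <- purrr::map_dbl(fits, "reconstruction_error")
    best <- fits[[which.min(errs)]]
    Wn <- best$W / pmax(rowSums(best$W), 1e-12)
    pairs <- utils::combn(length(fits), 2)
    ari <- if (r == 1) 1 else mean(apply(pairs, 2, function(ij) {
      mclust::adjustedRandIndex(fits[[ij[1]]]$clusters$cluster,
                                fits[[ij[2]]]$clusters$cluster)
    }))
    tibble(rank = r, error = min(errs),
           sparsity = mean(Wn < 0.01 / r), stability = ari)
  }) |> dplyr::bind_rows()
}

#' @export
print.morph_nmf <- function(x, ...) {
  cat(sprintf("<morph_nmf> rank %d, %d features x %d cells, rel. error %.4f (%d iterations%s)\n",
              x$rank, nrow(x$W), ncol(x$H), x$reconstruction_error,
              x$iterations, if (x$converged) ", converged" else ""))
  invisible(x)
}

#' @method glance morph_nmf
#' @export
glance.morph_nmf <- function(x, ...) {
  tibble(rank = x$rank, reconstruction_error = x$reconstruction_error,
         iterations = x$iterations, converged = x$converged,
         n_clusters = dplyr::n_distinct(x$clusters$cluster))
}

#' Tidy a factorization
#'
#' @param x A `morph_nmf` object.
#' @param matrix Which component to tidy: the basis (`"W"`), coefficients
#'   (`"H"`), or per-feature offset (`"offset"`).
#' @param ... Unused.
#' @return A long tibble of the requested component.
#' @method tidy morph_nmf
#' @export
tidy.morph_nmf <- function(x, matrix = c("W", "H", "offset"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    W = tibble(feature = rep(x$features, x$rank),
               meta_feature = rep(seq_len(x$rank), each = nrow(x$W)),
               loading = as.vector(x$W)),
    H = tibble(cell_id = rep(x$clusters$cell_id, each = x$rank),
               meta_feature = rep(seq_len(x$rank), ncol(x$H)),
               coefficient = as.vector(x$H)),
    offset = tibble(feature = x$features, offset = x$offset))
}
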