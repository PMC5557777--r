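#' Sum of squared error of a natural-cubic-spline time-course fit
#'
#' Least-squares fit of a natural cubic spline (intercept plus `df` basis
#' columns) to values over time. With group labels, one curve is fitted per
#' group and the residual sums are added; this is the alternative model of
#' the time-course test.
#'
#' @param values Numeric response vector.
#' @param times Observation times (same length); at least `df + 1` distinct
#'   values are required.
#' @param groups Optional group labels (e.g. genotype) for group-specific
#'   curves.
#' @param df Spline degrees of freedom (basis columns), default 3.
#' @return The residual sum of squares (single number).
#' @examples
#' t <- rep(c(0, 1, 3, 5), each = 4)
#' fit_spline_sse(2 * t + 1, t)  # straight line is interpolated: ~0
#' @export
fit_spline_sse <- function(values, times, groups = NULL, df = 3) {
  X <- spline_basis(times, df)
  if (!is.null(groups)) {
    g <- as.factor(groups)
    X <- do.call(cbind, lapply(levels(g), function(l) X * (g == l)))
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    abort(sprintf("singular spline design (rank %d < %d columns)",
                  qr_x$rank, ncol(X)))
  }
  sum(qr.resid(qr_x, values)^2)
}

spline_basis <- function(times, df) {
  n_distinct <- length(unique(times))
  if (n_distinct < 2) abort("need at least 2 distinct time values")
  if (df + 1 > n_distinct) {
    abort(sprintf("spline df = %d too large for %d distinct times",
                  df, n_distinct))
  }
  cbind(1, splines::ns(times, df = df))
}

#' Time-course test statistic from pooled and group-specific fits
#'
#' `F = (SS0 - SSA) / SSA`: the relative gain in goodness of fit when the
#' temporal profile is allowed to differ by group.
#'
#' @param ss0 Residual sum of squares of the pooled (null) fit.
#' @param ssa Residual sum of squares of the group-specific (alternative)
#'   fit.
#' @return The statistic; `Inf` with a warning when `ssa` is 0.
#' @examples
#' odp_statistic(2, 1)
#' @export
odp_statistic <- function(ss0, ssa) {
  out <- (ss0 - ssa) / ssa
  if (any(ssa == 0)) {
    warn("alternative fit is exact (SSA = 0); statistic reported as Inf")
    out[ssa == 0] <- Inf
  }
  out
}

#' Genotype-specific temporal-profile test over all features
#'
#' For every feature, fits a pooled natural cubic spline over time and
#' genotype-specific splines, forms `F = (SS0 - SSA)/SSA`, and estimates
#' p-values from a residual bootstrap under the pooled (null) fit:
#' residual rows are resampled with replacement, added back to the pooled
#' fitted values with genotype labels held fixed, and the null statistic
#' recomputed. `p = (1 + #{F_null >= F_obs}) / (1 + n_boot)`, followed by
#' FDR adjustment.
#'
#' @param fm A `morph_features` tibble (Z-scored or raw) with `genotype`
#'   and `time_days` metadata.
#' @param n_boot Bootstrap replicates (>= 100).
#' @param seed Seed for the bootstrap resampling.
#' @param df Spline degrees of freedom.
#' @param fdr FDR method passed to [adjust_fdr()].
#' @return An `odp_fit` tibble: `feature`, `ss0`, `ssa`, `statistic`, `p`,
#'   `q`, sorted as the input columns.
#' @export
odp_test <- function(fm, n_boot = 500, seed = 1L, df = 3,
                     fdr = c("bh", "storey")) {
  fdr <- match.arg(fdr)
  if (n_boot < 100) abort("n_boot must be >= 100")
  Y <- feature_values(fm)
  times <- fm$time_days
  geno <- as.factor(fm$genotype)

  X0 <- spline_basis(times, df)
  XA <- do.call(cbind, lapply(levels(geno), function(l) X0 * (geno == l)))
  qr0 <- qr(X0)
  qrA <- qr(XA)
  if (qrA$rank < ncol(XA)) abort("singular genotype-specific spline design")

  E0 <- qr.resid(qr0, Y)
  ss0 <- colSums(E0^2)
  ssa <- colSums(qr.resid(qrA, Y)^2)
  f_obs <- odp_statistic(ss0, ssa)

  fitted0 <- Y - E0
  n <- nrow(Y)
  exceed <- numeric(ncol(Y))
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      Yb <- fitted0 + E0[sample.int(n, n, replace = TRUE), , drop = FALSE]
      ss0_b <- colSums(qr.resid(qr0, Yb)^2)
      ssa_b <- colSums(qr.resid(qrA, Yb)^2)
      f_b <- (ss0_b - ssa_b) / ssa_b
      exceed <- exceed + (f_b >= f_obs)
    }
  })
  p <- unname((1 + exceed) / (1 + n_boot))
  out <- tibble(feature = colnames(Y), ss0 = unname(ss0),
                ssa = unname(ssa), statistic = unname(f_obs), p = p,
                q = adjust_fdr(p, fdr))
  class(out) <- c("odp_fit", class(out))
  out
}

#' False-discovery-rate adjustment
#'
#' Benjamini-Hochberg step-up by default; the Storey variant rescales the
#' BH values by a conservative null-proportion estimate
#' `pi0 = min(1, mean(p > 0.5) / 0.5)`.
#'
#' @param p P-values in `[0, 1]`.
#' @param method `"bh"` or `"storey"`.
#' @return Adjusted values (q-values), monotone in `p`.
#' @examples
#' adjust_fdr(c(0.01, 0.02, 0.03))
#' @export
adjust_fdr <- function(p, method = c("bh", "storey")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must be in [0, 1]")
  q <- p.adjust(p, method = "BH")
  if (method == "storey") {
    pi0 <- min(1, mean(p > 0.5, na.rm = TRUE) / 0.5)
    q <- pmin(1, pi0 * q)
  }
  q
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Maximum ECDF difference between two samples with the asymptotic p-value;
#' ties are handled by the standard ECDF convention (a warning from the
#' underlying test is suppressed since morphometric exports routinely
#' contain tied values).
#'
#' @param dist_a,dist_b Non-empty numeric vectors.
#' @return Tibble: `statistic` (D), `p`.
#' @examples
#' ks_compare(rnorm(50), rnorm(50, 2))
#' @export
ks_compare <- function(dist_a, dist_b) {
  if (length(dist_a) == 0 || length(dist_b) == 0) {
    abort("both samples must be non-empty")
  }
  kt <- suppressWarnings(ks.test(dist_a, dist_b))
  tibble(statistic = unname(kt$statistic), p = unname(kt$p.value))
}

#' @method glance odp_fit
#' @export
glance.odp_fit <- function(x, ...) {
  tibble(n_features = nrow(x),
         n_sig_p05 = sum(x$p < 0.05),
         n_sig_q05 = sum(x$q < 0.05))
}

#' @method tidy odp_fit
#' @export
tidy.odp_fit <- function(x, ...) as_tibble(x)
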