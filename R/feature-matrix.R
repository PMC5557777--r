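#' Distribution statistics of a per-process measurement vector
#'
#' Summarises one cell's distributed feature by the eight statistics used
#' throughout the analysis: mean, median, mode (Gaussian-KDE peak with
#' Silverman bandwidth for continuous values, most frequent value with
#' lowest-value tie-break for integer-valued vectors), sample standard
#' deviation (n - 1), coefficient of variation, half-width of the t-based
#' 95% confidence interval of the mean, moment skewness and excess
#' kurtosis. For a length-1 vector the spread and shape statistics are 0 by
#' convention and the record is flagged.
#'
#' @param values Numeric vector, length >= 1.
#' @return One-row tibble: the eight statistics plus `n` and `degenerate`.
#' @examples
#' summarize_distributed(c(1, 2, 3, 10))
#' @export
summarize_distributed <- function(values) {
  if (length(values) == 0 || all(is.na(values))) {
    abort("empty measurement vector")
  }
  values <- values[!is.na(values)]
  n <- length(values)
  m <- mean(values)
  if (n == 1) {
    return(tibble(mean = m, median = m, mode = m, sdev = 0, cv = 0,
                  ci95 = 0, skew = 0, kurt = 0, n = 1L, degenerate = TRUE))
  }
  s <- sd(values)
  cm <- values - m
  m2 <- mean(cm^2)
  skew <- if (m2 > 0) mean(cm^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean(cm^4) / m2^2 - 3 else 0
  tibble(
    mean = m,
    median = median(values),
    mode = estimate_mode(values),
    sdev = s,
    cv = if (m != 0) s / m else 0,
    ci95 = qt(0.975, n - 1) * s / sqrt(n),
    skew = skew,
    kurt = kurt,
    n = n,
    degenerate = FALSE
  )
}

# KDE-peak mode for continuous data; most frequent value (lowest wins ties)
# for integer-valued data
estimate_mode <- function(values) {
  if (length(unique(values)) == 1) return(values[1])
  if (all(values == round(values))) {
    tab <- table(values)
    return(as.numeric(names(tab)[which.max(tab)]))
  }
  d <- density(values, bw = "nrd0")
  d$x[which.max(d$y)]
}

#' Assemble the cells-by-features analysis matrix
#'
#' Scalar features are carried over as-is; every distributed feature is
#' expanded into the eight distribution statistics (suffixes `_mean`,
#' `_median`, `_mode`, `_sdev`, `_cv`, `_ci95`, `_skew`, `_kurt`), so a
#' catalog of 14 scalar and 12 distributed features yields 110 columns.
#'
#' @param sim A `microglia_sim` (or a list with `cells` and `processes`
#'   tibbles in the same layout).
#' @param catalog Feature catalog; unknown features in the data raise an
#'   error naming the offenders.
#' @return A `morph_features` tibble: metadata columns (`cell_id`,
#'   `mouse_id`, `genotype`, `time_days`, and `state` if present) followed
#'   by one numeric column per expanded feature. The feature dictionary
#'   (feature, base feature, statistic, compartment, feature set) is
#'   attached as attribute `"dictionary"` and retrievable with
#'   [feature_dictionary()].
#' @examples
#' sim <- simulate_microglia(study_design(seed = 7))
#' fm <- build_feature_matrix(sim)
#' ncol(fm) - sum(c("cell_id", "mouse_id", "genotype", "time_days",
#'                  "state") %in% names(fm))  # 110
#' @export
build_feature_matrix <- function(sim, catalog = morphology_catalog()) {
  cells <- sim$cells
  processes <- sim$processes
  scalar_cat <- catalog[!catalog$distributed, ]
  dist_cat <- catalog[catalog$distributed, ]

  known <- c(scalar_cat$feature, dist_cat$feature)
  data_feats <- c(intersect(names(cells), morphology_catalog(FALSE)$feature),
                  unique(processes$feature))
  unknown <- setdiff(unique(processes$feature), catalog$feature)
  unknown <- setdiff(unknown, morphology_catalog(FALSE)$feature)
  if (length(unknown) > 0) {
    abort(paste0("unknown features in data: ", paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(known, data_feats)
  if (length(missing) > 0) {
    abort(paste0("catalog features absent from data: ",
                 paste(missing, collapse = ", ")))
  }

  meta_cols <- intersect(c("cell_id", "mouse_id", "genotype", "time_days",
                           "state"), names(cells))
  out <- cells[, c(meta_cols, scalar_cat$feature)]

  stats_set <- distribution_statistics()
  if (nrow(dist_cat) > 0) {
    summ <- processes |>
      dplyr::filter(.data$feature %in% dist_cat$feature) |>
      dplyr::group_by(.data$cell_id, .data$feature) |>
      dplyr::summarise(stats = list(summarize_distributed(.data$value)),
                       .groups = "drop") |>
      tidyr::unnest("stats") |>
      dplyr::select(-"n", -"degenerate") |>
      tidyr::pivot_longer(dplyr::all_of(stats_set), names_to = "statistic") |>
      dplyr::mutate(column = paste0(.data$feature, "_", .data$statistic)) |>
      dplyr::select("cell_id", "column", "value") |>
      tidyr::pivot_wider(names_from = "column", values_from = "value")
    ordered_cols <- as.vector(t(outer(dist_cat$feature, stats_set, paste,
                                      sep = "_")))
    out <- dplyr::left_join(out, summ[, c("cell_id", ordered_cols)],
                            by = "cell_id")
  }

  keep <- complete.cases(out)
  if (!all(keep)) {
    warn(sprintf("dropping %d cells with incomplete feature records",
                 sum(!keep)))
    out <- out[keep, ]
  }

  dict <- dplyr::bind_rows(
    tibble(feature = scalar_cat$feature, base_feature = scalar_cat$feature,
           statistic = "none", compartment = scalar_cat$compartment,
           distributed = FALSE, feature_set = scalar_cat$feature_set),
    if (nrow(dist_cat) > 0) {
      tidyr::expand_grid(base_feature = dist_cat$feature,
                         statistic = stats_set) |>
        dplyr::left_join(dist_cat[, c("feature", "compartment", "feature_set")],
                         by = c(base_feature = "feature")) |>
        dplyr::mutate(feature = paste0(.data$base_feature, "_",
                                       .data$statistic),
                      distributed = TRUE) |>
        dplyr::select("feature", "base_feature", "statistic", "compartment",
                      "distributed", "feature_set")
    }
  )
  attr(out, "dictionary") <- dict
  class(out) <- c("morph_features", class(out))
  out
}

#' @rdname build_feature_matrix
#' @param fm A `morph_features` tibble.
#' @export
feature_dictionary <- function(fm) {
  dict <- attr(fm, "dictionary")
  if (is.null(dict)) abort("not a morph_features object (no dictionary)")
  dict[dict$feature %in% names(fm), ]
}

#' @rdname build_feature_matrix
#' @export
feature_names <- function(fm) feature_dictionary(fm)$feature

# numeric cells x features matrix view
feature_values <- function(fm) {
  m <- as.matrix(fm[, feature_names(fm)])
  rownames(m) <- fm$cell_id
  m
}

# rebuild a morph_features tibble from metadata + matrix
set_feature_values <- function(fm, m) {
  meta <- fm[, setdiff(names(fm), feature_names(fm))]
  dict <- attr(fm, "dictionary")
  out <- dplyr::bind_cols(meta, as_tibble(m))
  attr(out, "dictionary") <- dict[dict$feature %in% colnames(m), ]
  class(out) <- c("morph_features", class(out))
  out
}

#' Z-score the feature columns
#'
#' Centers and scales every feature column to mean 0 and sample standard
#' deviation 1 across all cells (genotypes and times pooled). Constant
#' columns cannot be scaled and are dropped with a warning; an all-constant
#' matrix is an error. The operation is idempotent.
#'
#' @param fm A `morph_features` tibble.
#' @return The Z-scored `morph_features` tibble.
#' @export
zscore_features <- function(fm) {
  m <- feature_values(fm)
  if (nrow(m) < 2) abort("need at least 2 cells to Z-score")
  sds <- apply(m, 2, sd)
  constant <- sds == 0 | !is.finite(sds)
  if (all(constant)) abort("all feature columns are constant")
  if (any(constant)) {
    warn(paste0("dropping constant features: ",
                paste(colnames(m)[constant], collapse = ", ")))
    m <- m[, !constant, drop = FALSE]
    sds <- sds[!constant]
  }
  m <- scale(m, center = TRUE, scale = sds)
  attr(m, "scaled:center") <- NULL
  attr(m, "scaled:scale") <- NULL
  set_feature_values(fm, m)
}

#' Select informative features for factorization
#'
#' A feature is retained when its temporal-profile test is significant
#' (`p < p_cutoff`) or its principal-component loading magnitude across the
#' first four components exceeds `loading_cutoff`. The magnitude is the
#' maximum absolute loading over components 1-4 by default (an L2-norm
#' alternative is available).
#'
#' @param loadings Tibble with a `feature` column and one column per
#'   component (`PC1`, `PC2`, ...), as from [morph_pca()]; at least four
#'   components are required.
#' @param odp Tibble with `feature` and `p` columns, as from [odp_test()].
#' @param loading_cutoff,p_cutoff Selection thresholds.
#' @param magnitude `"l2"` (default) or `"max"` loading magnitude over the
#'   first four components; the L2 norm pools evidence across components
#'   and keeps every correlated feature block represented.
#' @return Tibble: `feature`, `loading_magnitude`, `p`, `selected`.
#' @export
select_features <- function(loadings, odp, loading_cutoff = 0.2,
                            p_cutoff = 0.05,
                            magnitude = c("l2", "max")) {
  magnitude <- match.arg(magnitude)
  pc_cols <- grep("^PC[0-9]+$", names(loadings), value = TRUE)
  if (length(pc_cols) < 4) abort("need loadings for at least 4 components")
  L <- as.matrix(loadings[, paste0("PC", 1:4)])
  mag <- switch(magnitude,
                l2 = sqrt(rowSums(L^2)),
                max = apply(abs(L), 1, max))
  out <- tibble(feature = loadings$feature, loading_magnitude = mag) |>
    dplyr::left_join(odp[, c("feature", "p")], by = "feature") |>
    dplyr::mutate(selected = .data$loading_magnitude > loading_cutoff |
                    (!is.na(.data$p) & .data$p < p_cutoff))
  out
}

#' Restrict a feature matrix to a feature subset
#'
#' @param fm A `morph_features` tibble.
#' @param features Character vector of feature columns to keep.
#' @return The restricted `morph_features` tibble.
#' @export
filter_features <- function(fm, features) {
  missing <- setdiff(features, feature_names(fm))
  if (length(missing) > 0) {
    abort(paste0("features not in matrix: ", paste(missing, collapse = ", ")))
  }
  set_feature_values(fm, feature_values(fm)[, features, drop = FALSE])
}

#' Shift features to non-negative range
#'
#' Subtracts each feature's minimum so every feature's minimum becomes
#' exactly 0 (the minimum is always subtracted, also when it is already
#' positive), producing the non-negative matrix required by the
#' factorization stage.
#'
#' @param fm A `morph_features` tibble (typically Z-scored).
#' @return The shifted `morph_features` tibble.
#' @export
shift_nonnegative <- function(fm) {
  m <- feature_values(fm)
  if (any(!is.finite(m))) abort("non-finite values in feature matrix")
  m <- sweep(m, 2, apply(m, 2, min))
  set_feature_values(fm, m)
}
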