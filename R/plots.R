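#' Plot a simulated cytokine trajectory
#'
#' Concentration time courses per species, with the stimulus window
#' shaded.
#'
#' @param object A `cytokine_trajectory`.
#' @param microglial_only Drop the cascade stages except the output.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cytokine_trajectory
#' @export
autoplot.cytokine_trajectory <- function(object, microglial_only = TRUE, ...) {
  df <- object
  if (microglial_only) {
    stages <- grep("^TGFb_env_", unique(df$species), value = TRUE)
    keep_stage <- stages[length(stages)]
    df <- df[!(df$species %in% setdiff(stages, keep_stage)), ]
  }
  stim <- attr(object, "stimulus")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_days, .data$conc,
                                        colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = "concentration (a.u.)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(stim) && stim$magnitude > 0) {
    p <- p + ggplot2::annotate("rect", xmin = stim$onset / 24,
                               xmax = (stim$onset + stim$duration) / 24,
                               ymin = -Inf, ymax = Inf, alpha = 0.1)
  }
  p
}

#' Heatmap of the factorised Z-score matrix
#'
#' Cells ordered by their cluster assignment (coefficient matrix) and
#' features by their feature set (basis matrix), the standard display of
#' an offset-NMF decomposition.
#'
#' @param object A `morph_nmf` fit.
#' @param fm The (Z-scored) `morph_features` tibble the fit was computed
#'   from; when omitted the reconstruction `W H + c` is shown.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot morph_nmf
#' @export
autoplot.morph_nmf <- function(object, fm = NULL, ...) {
  fsets <- assign_feature_sets(object)
  cell_ord <- object$clusters$cell_id[order(object$clusters$cluster)]
  feat_ord <- fsets$feature[order(fsets$feature_set)]
  if (is.null(fm)) {
    m <- object$W %*% object$H + object$offset
    rownames(m) <- object$features
    colnames(m) <- object$clusters$cell_id
    df <- as_tibble(as.data.frame.table(m, stringsAsFactors = FALSE),
                    .name_repair = ~c("feature", "cell_id", "value"))
  } else {
    df <- fm |>
      dplyr::select("cell_id", dplyr::all_of(object$features)) |>
      tidyr::pivot_longer(-"cell_id", names_to = "feature")
  }
  df$cell_id <- factor(df$cell_id, levels = cell_ord)
  df$feature <- factor(df$feature, levels = feat_ord)
  ggplot2::ggplot(df, ggplot2::aes(.data$cell_id, .data$feature,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = "cells (by cluster)", y = "features (by feature set)",
                  fill = "Z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Adaptation indices with confidence intervals
#'
#' Bar chart of per-feature adaptation indices by genotype with the
#' t-based 95% confidence intervals.
#'
#' @param object Tibble from [estimate_adaptation()].
#' @param features Optional subset of features to display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_adaptation <- function(object, features = NULL, ...) {
  df <- object
  if (!is.null(features)) df <- df[df$feature %in% features, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$feature, .data$A,
                                   fill = .data$genotype)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi),
                           position = ggplot2::position_dodge(0.9),
                           width = 0.3) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "adaptation index A") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Dose-response curves of peak and adaptation
#'
#' @param object Tibble from [dose_response()].
#' @param what `"adaptation"` or `"peak"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_dose_response <- function(object, what = c("adaptation", "peak"), ...) {
  what <- match.arg(what)
  ggplot2::ggplot(object, ggplot2::aes(.data$dose, .data[[what]],
                                       colour = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "LPS magnitude (a.u.)", y = what, colour = NULL) +
    ggplot2::theme_minimal()
}

#' NMDS embedding coloured by cluster
#'
#' @param object A `morph_nmds` result.
#' @param clusters Optional tibble `cell_id`, `cluster` to colour by.
#' @param ... Unused.
#' @return A ggplot of the first two embedding dimensions.
#' @method autoplot morph_nmds
#' @export
autoplot.morph_nmds <- function(object, clusters = NULL, ...) {
  df <- object$coords
  if (!is.null(clusters)) {
    df <- dplyr::left_join(df, clusters, by = "cell_id")
    df$cluster <- factor(df$cluster)
  }
  aes <- if (!is.null(clusters)) {
    ggplot2::aes(.data$MDS1, .data$MDS2, colour = .data$cluster)
  } else {
    ggplot2::aes(.data$MDS1, .data$MDS2)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(caption = sprintf("stress = %.3f", object$stress)) +
    ggplot2::theme_minimal()
}
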