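#' Scaled, orientation-corrected temporal profiles
#'
#' For each feature, per-genotype time-point means of the Z-scored values
#' are min-max scaled to `[0, 1]` using one scaling (min and max over the
#' pooled wild-type and knockout means) so the two genotypes share a scale.
#' A genotype's profile is flipped (`z -> 1 - z`) when its maximal
#' deviation from baseline is downward (`|min - t0| > |max - t0|`),
#' labelling the response direction; per-time standard errors are
#' transformed with the same scaling factor. Features whose pooled profile
#' is flat (max = min) are flagged and excluded from adaptation indexing.
#'
#' The standard error convention follows the error-propagation framework
#' this analysis derives from, which defines SEM as standard deviation
#' divided by n; the conventional `sd/sqrt(n)` is available via
#' `sem_method = "sd_sqrt_n"`.
#'
#' @param fm A Z-scored `morph_features` tibble.
#' @param features Features to profile (default: all).
#' @param sem_method `"sd_n"` (default) or `"sd_sqrt_n"`.
#' @return A `scaled_profiles` tibble: `feature`, `genotype`, `time_days`,
#'   `zbar` (scaled mean), `sem` (scaled), `n`, `direction`
#'   (`"increase"`/`"decrease"`), `flat`.
#' @export
scale_profiles <- function(fm, features = NULL,
                           sem_method = c("sd_n", "sd_sqrt_n")) {
  sem_method <- match.arg(sem_method)
  features <- features %||% feature_names(fm)
  long <- fm |>
    dplyr::select("cell_id", "genotype", "time_days",
                  dplyr::all_of(features)) |>
    tidyr::pivot_longer(dplyr::all_of(features), names_to = "feature")
  t0 <- min(fm$time_days)

  prof <- long |>
    dplyr::group_by(.data$feature, .data$genotype, .data$time_days) |>
    dplyr::summarise(zbar = mean(.data$value),
                     zsd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(sem_raw = .data$zsd / ifelse(sem_method == "sd_n",
                                               .data$n, sqrt(.data$n)))

  prof |>
    dplyr::group_by(.data$feature) |>
    dplyr::group_modify(function(df, key) {
      zmin <- min(df$zbar)
      zmax <- max(df$zbar)
      if (zmax - zmin < 1e-12) {
        return(dplyr::mutate(df, zbar = NA_real_, sem = NA_real_,
                             direction = NA_character_, flat = TRUE) |>
                 dplyr::select(-"zsd", -"sem_raw"))
      }
      df$zbar <- (df$zbar - zmin) / (zmax - zmin)
      df$sem <- df$sem_raw / (zmax - zmin)
      df |>
        dplyr::group_by(.data$genotype) |>
        dplyr::group_modify(function(g, k) {
          z0 <- g$zbar[g$time_days == t0]
          d_max <- abs(max(g$zbar) - z0)
          d_min <- abs(min(g$zbar) - z0)
          if (d_min > d_max) {
            g$zbar <- 1 - g$zbar
            g$direction <- "decrease"
          } else {
            g$direction <- "increase"
          }
          g
        }) |>
        dplyr::ungroup() |>
        dplyr::mutate(flat = FALSE) |>
        dplyr::select(-"zsd", -"sem_raw")
    }) |>
    dplyr::ungroup() |>
    structure(class = c("scaled_profiles", class(prof)))
}

#' Adaptation index of a scaled profile
#'
#' `A = 1 - (z_final - z_t0) / (z_peak - z_t0)`, where the peak is the
#' post-baseline extreme of the orientation-corrected profile and the
#' final value is the last time point. `A = 1` is complete recovery to
#' baseline, `A = 0` no recovery, values above 1 indicate overshoot below
#' baseline.
#'
#' @param zbar Scaled profile means ordered by time.
#' @param times Corresponding times; the first entry is baseline.
#' @return The adaptation index.
#' @examples
#' adaptation_index(c(0, 1, 0.5, 0.25), c(0, 1, 3, 5))
#' @export
adaptation_index <- function(zbar, times) {
  stopifnot(length(zbar) == length(times), length(zbar) >= 2)
  ord <- order(times)
  zbar <- zbar[ord]
  z0 <- zbar[1]
  z_final <- zbar[length(zbar)]
  post <- zbar[-1]
  z_peak <- post[which.max(abs(post - z0))]
  if (abs(z_peak - z0) < 1e-12) abort("peak equals baseline; no excursion")
  1 - (z_final - z0) / (z_peak - z0)
}

#' Propagated variance of the adaptation index
#'
#' First-order (delta-method) error propagation of the index through its
#' peak and final means, treating the baseline as a constant:
#' `var(A) = sem_final^2 (dA/dz_final)^2 + sem_peak^2 (dA/dz_peak)^2` with
#' `dA/dz_final = -1/(z_peak - z_t0)` and
#' `dA/dz_peak = (z_final - z_t0)/(z_peak - z_t0)^2`.
#'
#' @param z0,z_peak,z_final Baseline, peak and final scaled means.
#' @param sem_peak,sem_final Their standard errors on the scaled scale.
#' @return The propagated variance.
#' @examples
#' adaptation_variance(0, 1, 0.5, sem_peak = 0, sem_final = 0.1)  # 0.01
#' @export
adaptation_variance <- function(z0, z_peak, z_final, sem_peak, sem_final) {
  denom <- z_peak - z0
  if (abs(denom) < 1e-12) abort("peak equals baseline; variance undefined")
  dA_dfinal <- -1 / denom
  dA_dpeak <- (z_final - z0) / denom^2
  sem_final^2 * dA_dfinal^2 + sem_peak^2 * dA_dpeak^2
}

#' Per-feature, per-genotype adaptation estimates
#'
#' Applies [adaptation_index()] and [adaptation_variance()] to every
#' non-flat profile, with a t-based 95% confidence interval
#' `A +/- t(df) * sd(A) / sqrt(n_min)` where `n_min` is the smallest
#' per-time-point sample size across both genotypes for the feature and
#' `df = 2 n_min - 2`.
#'
#' @param profiles A `scaled_profiles` tibble.
#' @return Tibble: `feature`, `genotype`, `direction`, `A`, `var_A`,
#'   `n_min`, `df`, `ci_lo`, `ci_hi`.
#' @export
estimate_adaptation <- function(profiles) {
  nmin <- profiles |>
    dplyr::filter(!.data$flat) |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(n_min = min(.data$n), .groups = "drop")

  profiles |>
    dplyr::filter(!.data$flat) |>
    dplyr::group_by(.data$feature, .data$genotype) |>
    dplyr::arrange(.data$time_days, .by_group = TRUE) |>
    dplyr::summarise(
      direction = dplyr::first(.data$direction),
      A = adaptation_index(.data$zbar, .data$time_days),
      var_A = {
        z0 <- dplyr::first(.data$zbar)
        post <- .data$zbar[-1]
        ip <- which.max(abs(post - z0))
        adaptation_variance(z0, post[ip], dplyr::last(.data$zbar),
                            sem_peak = .data$sem[-1][ip],
                            sem_final = dplyr::last(.data$sem))
      },
      .groups = "drop") |>
    dplyr::left_join(nmin, by = "feature") |>
    dplyr::mutate(df = 2 * .data$n_min - 2,
                  half = ifelse(.data$df >= 1,
                                suppressWarnings(qt(0.975, .data$df)) *
                                  sqrt(.data$var_A) / sqrt(.data$n_min),
                                NA_real_),
                  ci_lo = .data$A - .data$half,
                  ci_hi = .data$A + .data$half) |>
    dplyr::select(-"half")
}

#' Eligibility of a feature for genotype comparison of adaptation
#'
#' A feature is compared between genotypes only when both indices show
#' meaningful, same-direction adaptation:
#' `min(A_wt, A_ko) > 0.5`, both indices within `(-0.2, 1.2)`, and both
#' genotypes responding in the same direction.
#'
#' @param a_wt,a_ko Adaptation indices (vectorised).
#' @param dir_wt,dir_ko Response directions.
#' @param min_a Lower bound on the smaller index (default 0.5).
#' @param window Allowed index range (default `c(-0.2, 1.2)`).
#' @return Logical vector.
#' @export
eligible_for_comparison <- function(a_wt, a_ko, dir_wt, dir_ko,
                                    min_a = 0.5, window = c(-0.2, 1.2)) {
  pmin(a_wt, a_ko) > min_a &
    a_wt > window[1] & a_wt < window[2] &
    a_ko > window[1] & a_ko < window[2] &
    dir_wt == dir_ko
}

#' Compare adaptation between genotypes
#'
#' For each eligible feature, forms the statistic
#' `T = (A_ko - A_wt) / sqrt(2 S^2 / n_min)` with pooled spread
#' `S^2 = (n_min - 1)/df * (var_wt + var_ko)` and `df = 2 n_min - 2`,
#' two-tailed p-values from the t distribution, and
#' Benjamini-Hochberg-adjusted q-values (within feature set when a
#' `feature_set` column is present, otherwise across all compared
#' features).
#'
#' @param estimates Tibble from [estimate_adaptation()], optionally with a
#'   `feature_set` column joined on.
#' @param wt,ko Genotype labels (defaults `"WT"`, `"KO"`).
#' @param ... Passed to [eligible_for_comparison()].
#' @return An `adaptation_comparison` tibble: `feature`, `A_WT`, `A_KO`,
#'   `var_WT`, `var_KO`, `n_min`, `eligible`, `statistic`, `df`, `p`, `q`
#'   (the test columns are `NA` for ineligible features).
#' @export
compare_adaptation <- function(estimates, wt = "WT", ko = "KO", ...) {
  fs <- if ("feature_set" %in% names(estimates)) {
    dplyr::distinct(estimates, .data$feature, .data$feature_set)
  }
  wide <- estimates |>
    dplyr::select("feature", "genotype", "A", "var_A", "direction",
                  "n_min") |>
    tidyr::pivot_wider(names_from = "genotype",
                       values_from = c("A", "var_A", "direction"))
  need <- paste0(c("A_", "var_A_", "direction_"), rep(c(wt, ko), 3))
  if (!all(need %in% names(wide))) {
    abort("estimates must contain both genotypes for comparison")
  }
  if (any(wide$n_min < 2)) abort("n_min must be >= 2 for comparison")
  out <- wide |>
    dplyr::rename(A_WT = paste0("A_", wt), A_KO = paste0("A_", ko),
                  var_WT = paste0("var_A_", wt),
                  var_KO = paste0("var_A_", ko)) |>
    dplyr::mutate(
      eligible = eligible_for_comparison(
        .data$A_WT, .data$A_KO,
        .data[[paste0("direction_", wt)]],
        .data[[paste0("direction_", ko)]], ...),
      df = 2 * .data$n_min - 2,
      s2 = (.data$n_min - 1) / .data$df * (.data$var_WT + .data$var_KO),
      statistic = ifelse(.data$eligible,
                         (.data$A_KO - .data$A_WT) /
                           sqrt(pmax(2 * .data$s2 / .data$n_min, 1e-300)),
                         NA_real_),
      p = 2 * pt(-abs(.data$statistic), .data$df)) |>
    dplyr::select("feature", "A_WT", "A_KO", "var_WT", "var_KO",
                  "n_min", "eligible", "statistic", "df", "p")
  if (!is.null(fs)) out <- dplyr::left_join(out, fs, by = "feature")
  grp <- if (!is.null(fs)) "feature_set" else character(0)
  out <- out |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(q = ifelse(.data$eligible,
                             adjust_fdr(.data$p[.data$eligible])[
                               pmax(cumsum(.data$eligible), 1)], NA_real_)) |>
    dplyr::ungroup()
  class(out) <- c("adaptation_comparison", class(out))
  out
}

#' Feature-set dynamics with two-way analysis of variance
#'
#' Computes each cell's mean Z-score over the features of each feature
#' set, then per set: a genotype-by-time two-way ANOVA (with interaction)
#' on the per-cell means, and Sidak-corrected Fisher-LSD-style post-hoc
#' comparisons of the within-genotype means against baseline and of the
#' genotypes against each other at every time point.
#'
#' @param fm A Z-scored `morph_features` tibble.
#' @param feature_sets Tibble `feature`, `feature_set` (e.g. from
#'   [assign_feature_sets()] or the feature dictionary).
#' @return A list with tibbles `means` (per set/genotype/time mean and
#'   SEM), `anova` (per set: term, df, F, p), and `posthoc` (per set:
#'   comparison label, estimate, p adjusted within the set's family).
#' @export
featureset_dynamics <- function(fm, feature_sets) {
  feats <- intersect(feature_sets$feature, feature_names(fm))
  if (length(feats) == 0) abort("no overlapping features")
  long <- fm |>
    dplyr::select("cell_id", "genotype", "time_days",
                  dplyr::all_of(feats)) |>
    tidyr::pivot_longer(dplyr::all_of(feats), names_to = "feature") |>
    dplyr::left_join(feature_sets, by = "feature") |>
    dplyr::group_by(.data$cell_id, .data$genotype, .data$time_days,
                    .data$feature_set) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")

  counts <- long |>
    dplyr::count(.data$feature_set, .data$genotype, .data$time_days)
  n_expected <- dplyr::n_distinct(long$feature_set) *
    dplyr::n_distinct(long$genotype) * dplyr::n_distinct(long$time_days)
  if (nrow(counts) < n_expected) abort("empty design cell")
  if (dplyr::n_distinct(long$genotype) < 2 ||
      dplyr::n_distinct(long$time_days) < 2) {
    abort("need >= 2 levels of genotype and time")
  }

  means <- long |>
    dplyr::group_by(.data$feature_set, .data$genotype, .data$time_days) |>
    dplyr::summarise(mean = mean(.data$value),
                     sem = sd(.data$value) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")

  per_set <- long |>
    dplyr::group_by(.data$feature_set) |>
    dplyr::group_map(function(df, key) {
      df$time_f <- factor(df$time_days)
      fit <- aov(value ~ genotype * time_f, data = df)
      an <- as.data.frame(anova(fit))
      anova_tbl <- tibble(feature_set = key$feature_set,
                          term = sub("time_f", "time", rownames(an)),
                          df = an$Df, statistic = an$`F value`,
                          p = an$`Pr(>F)`)
      em <- emmeans::emmeans(fit, ~ genotype * time_f)
      t0 <- levels(df$time_f)[1]
      cells <- as.data.frame(em)[, c("genotype", "time_f")]
      idx <- function(g, t) which(cells$genotype == g & cells$time_f == t)
      contrasts <- list()
      for (g in unique(df$genotype)) {
        for (tl in setdiff(levels(df$time_f), t0)) {
          v <- numeric(nrow(cells))
          v[idx(g, tl)] <- 1
          v[idx(g, t0)] <- -1
          contrasts[[paste0(g, ": day ", tl, " vs day ", t0)]] <- v
        }
      }
      gl <- unique(df$genotype)
      for (tl in levels(df$time_f)) {
        v <- numeric(nrow(cells))
        v[idx(gl[2], tl)] <- 1
        v[idx(gl[1], tl)] <- -1
        contrasts[[paste0(gl[2], " vs ", gl[1], ": day ", tl)]] <- v
      }
      ct <- as.data.frame(emmeans::contrast(em, contrasts, adjust = "sidak"))
      posthoc_tbl <- tibble(feature_set = key$feature_set,
                            comparison = as.character(ct$contrast),
                            estimate = ct$estimate, p = ct$p.value)
      list(anova = anova_tbl, posthoc = posthoc_tbl)
    })

  list(means = means,
       anova = dplyr::bind_rows(purrr::map(per_set, "anova")),
       posthoc = dplyr::bind_rows(purrr::map(per_set, "posthoc")))
}
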