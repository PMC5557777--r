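#' Relative expression fold change from qPCR Ct values
#'
#' Standard relative quantification against a reference gene and a baseline
#' condition: `2^-((Ct_t - Ct_ref) - (Ct_t0 - Ct_ref0))`.
#'
#' @param ct_target,ct_reference Ct values of the target and reference gene
#'   in the condition of interest.
#' @param ct_target_baseline,ct_reference_baseline Ct values at baseline.
#' @return Numeric fold change(s).
#' @examples
#' fold_change(24, 20, 25, 20)  # one cycle earlier than baseline: 2-fold
#' @export
fold_change <- function(ct_target, ct_reference,
                        ct_target_baseline, ct_reference_baseline) {
  ddct <- (ct_target - ct_reference) -
    (ct_target_baseline - ct_reference_baseline)
  2^(-ddct)
}

#' Default cytokine qPCR kinetic templates
#'
#' Fold-change trajectories (relative to baseline, reference-gene
#' normalised) for the four profiled cytokine genes: a sharp Tnf peak at
#' day 1 with recovery by day 3 and a larger peak in the knockout, a
#' similar but smaller Il6 response, a modest Il1b response decaying toward
#' baseline, and sustained Tgfb1 upregulation through day 5.
#'
#' @param timepoints_days Times at which templates are evaluated.
#' @return Tibble: `gene`, `genotype`, `time_days`, `fold`.
#' @export
qpcr_templates <- function(timepoints_days = c(0, 1, 3, 5)) {
  shapes <- list(
    Tnf   = list(WT = c(1, 8, 1.2, 1),   KO = c(1, 20, 1.2, 1)),
    Il6   = list(WT = c(1, 5, 1.1, 1),   KO = c(1, 10, 1.1, 1)),
    Il1b  = list(WT = c(1, 2.5, 1.3, 1), KO = c(1, 4, 1.3, 1)),
    Tgfb1 = list(WT = c(1, 2, 3, 2.5),   KO = c(1, 2, 3, 2.5))
  )
  ref_times <- c(0, 1, 3, 5)
  purrr::imap(shapes, function(gt, gene) {
    purrr::imap(gt, function(folds, g) {
      tibble(gene = gene, genotype = g, time_days = timepoints_days,
             fold = stats::approx(ref_times, folds, xout = timepoints_days,
                                  rule = 2)$y)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Simulate a qPCR Ct table
#'
#' Emits per-mouse target and reference Ct values whose relative
#' quantification reproduces the template fold changes up to measurement
#' noise: `Ct_target = Ct_ref + dCt0 - log2(fold) + noise`.
#'
#' @param design A [study_design()]; mice per group and genotypes are reused.
#' @param templates Template tibble as from [qpcr_templates()].
#' @param ct_reference_mean Mean reference-gene Ct.
#' @param dct_baseline Baseline delta-Ct (target minus reference) per gene;
#'   recycled across genes.
#' @param noise_sd Ct measurement noise (cycles).
#' @return Tibble: `gene`, `genotype`, `time_days`, `mouse`, `ct_target`,
#'   `ct_reference`.
#' @examples
#' q <- simulate_qpcr(study_design(seed = 2))
#' head(q)
#' @export
simulate_qpcr <- function(design = study_design(),
                          templates = qpcr_templates(design$timepoints_days),
                          ct_reference_mean = 20, dct_baseline = 6,
                          noise_sd = 0.15) {
  withr::with_seed(design$seed + 1L, {
    grid <- templates |>
      dplyr::left_join(tibble(time_days = design$timepoints_days,
                              n_mice = design$mice_per_group),
                       by = "time_days")
    grid <- grid[rep(seq_len(nrow(grid)), grid$n_mice), ]
    grid |>
      dplyr::group_by(.data$gene, .data$genotype, .data$time_days) |>
      dplyr::mutate(mouse = dplyr::row_number()) |>
      dplyr::ungroup() |>
      dplyr::mutate(
        ct_reference = rnorm(dplyr::n(), ct_reference_mean, 0.3),
        ct_target = .data$ct_reference + dct_baseline - log2(.data$fold) +
          rnorm(dplyr::n(), 0, noise_sd)
      ) |>
      dplyr::select("gene", "genotype", "time_days", "mouse",
                    "ct_target", "ct_reference")
  })
}

#' Recover fold changes from a simulated Ct table
#'
#' Applies [fold_change()] per gene and genotype against the mean baseline
#' (day 0) Ct values, mirroring how bench data would be analysed.
#'
#' @param qpcr Tibble as returned by [simulate_qpcr()].
#' @return Tibble: `gene`, `genotype`, `time_days`, `fold` (mean over mice).
#' @export
qpcr_fold_changes <- function(qpcr) {
  base <- qpcr |>
    dplyr::filter(.data$time_days == min(.data$time_days)) |>
    dplyr::group_by(.data$gene, .data$genotype) |>
    dplyr::summarise(ct_t0 = mean(.data$ct_target),
                     ct_ref0 = mean(.data$ct_reference), .groups = "drop")
  qpcr |>
    dplyr::left_join(base, by = c("gene", "genotype")) |>
    dplyr::mutate(fold = fold_change(.data$ct_target, .data$ct_reference,
                                     .data$ct_t0, .data$ct_ref0)) |>
    dplyr::group_by(.data$gene, .data$genotype, .data$time_days) |>
    dplyr::summarise(fold = mean(.data$fold), .groups = "drop")
}
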