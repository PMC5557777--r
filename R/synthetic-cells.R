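#' Study design for the synthetic inflammation time course
#'
#' Describes the sampling frame the generator emulates: two genotypes
#' (wild type and IL-10 knockout), an LPS challenge at day 0, microglia
#' reconstructed at four post-challenge time points, a fixed number of mice
#' per genotype-by-time group and a per-mouse cell yield. The defaults
#' reproduce the reference design of 218 cells from 28 mice.
#'
#' @param genotypes Genotype labels; the first is treated as wild type.
#' @param timepoints_days Strictly increasing sampling times in days.
#' @param mice_per_group Mice per genotype x time group (scalar or one value
#'   per time point). The default `c(4, 3, 4, 3)` gives 14 mice per genotype.
#' @param cells_per_mouse Inclusive range of cells reconstructed per mouse.
#' @param n_cells_total If non-`NULL`, total cells are allocated
#'   deterministically across mice (evenly, remainder to the first mice)
#'   instead of drawn from `cells_per_mouse`.
#' @param seed Integer seed; every draw the generator makes is reproducible
#'   given the seed.
#' @return A `study_design` list.
#' @examples
#' d <- study_design()
#' sum(d$mice_per_group) * length(d$genotypes)  # 28 mice
#' @export
study_design <- function(genotypes = c("WT", "KO"),
                         timepoints_days = c(0, 1, 3, 5),
                         mice_per_group = c(4, 3, 4, 3),
                         cells_per_mouse = c(7, 8),
                         n_cells_total = 218,
                         seed = 1L) {
  if (length(genotypes) != 2) abort("exactly two genotype labels required")
  if (is.unsorted(timepoints_days, strictly = TRUE)) {
    abort("timepoints_days must be strictly increasing")
  }
  mice_per_group <- rep_len(mice_per_group, length(timepoints_days))
  if (any(mice_per_group < 1)) abort("mice_per_group must be >= 1")
  if (length(cells_per_mouse) != 2 || cells_per_mouse[1] > cells_per_mouse[2] ||
      cells_per_mouse[1] < 1) {
    abort("cells_per_mouse must be a valid range c(min, max), min >= 1")
  }
  if (!is.null(n_cells_total) && n_cells_total < 1) {
    abort("n_cells_total must be positive")
  }
  structure(list(genotypes = genotypes,
                 timepoints_days = timepoints_days,
                 mice_per_group = mice_per_group,
                 cells_per_mouse = cells_per_mouse,
                 n_cells_total = n_cells_total,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Per-block LPS response profiles
#'
#' Deflections of the four latent feature-set intensities over time, per
#' genotype, parameterised by peak time, peak amplitude and the fraction of
#' the peak recovered by the final time point. Ramification (fs1) falls
#' after LPS while soma size (fs2), process shape (fs3) and process size
#' (fs4) rise; knockout recovery is at least as complete as wild type for
#' fs2 and fs3, and the fs2 peak is earlier in the knockout.
#'
#' @return Tibble with columns `block`, `genotype`, `amplitude`,
#'   `peak_time`, `recovery`.
#' @export
default_effect_profiles <- function() {
  tibble::tribble(
    ~block, ~genotype, ~amplitude, ~peak_time, ~recovery,
    "fs1",  "WT",      -1.00,      1,          0.55,
    "fs1",  "KO",      -1.20,      1,          0.90,
    "fs2",  "WT",       1.60,      3,          0.70,
    "fs2",  "KO",       2.00,      1,          0.95,
    "fs3",  "WT",       1.30,      1,          0.60,
    "fs3",  "KO",       1.30,      1,          0.95,
    "fs4",  "WT",       0.70,      1,          0.70,
    "fs4",  "KO",       0.70,      1,          0.75
  )
}

# deflection of a block's latent intensity at time t: linear rise to the
# peak, then linear relaxation losing `recovery` of the peak by t_final
effect_deflection <- function(t, amplitude, peak_time, recovery, t_final) {
  ifelse(t <= peak_time,
         amplitude * t / peak_time,
         amplitude * (1 - recovery * (t - peak_time) / (t_final - peak_time)))
}

#' Configuration of the synthetic morphology generator
#'
#' The generator plants two kinds of structure on top of long-tailed
#' per-feature noise: six latent cell states, each a profile of intensities
#' over the four feature-set blocks (mimicking discrete morphological
#' classes), and genotype-specific LPS deflection curves of the block
#' intensities over time. Knockout cells are enriched for the
#' large-soma state (state 2), making genotype-by-cluster enrichment
#' testable.
#'
#' @param catalog Feature catalog (see [morphology_catalog()]); its
#'   feature-set column is the block map and must assign every feature to
#'   exactly one block.
#' @param state_intensity 6 x 4 matrix of per-state block intensities
#'   (rows: states; columns: fs1..fs4).
#' @param state_freq_wt,state_freq_ko State frequencies per genotype
#'   (length 6, summing to 1).
#' @param effects Effect-profile tibble as in [default_effect_profiles()].
#' @param effect_scale Multiplier on all effect amplitudes; `0` removes the
#'   LPS perturbation entirely.
#' @param state_shift Multiplier interpolating knockout state frequencies
#'   between the wild-type vector (`0`) and `state_freq_ko` (`1`); `0`
#'   removes all genotype-linked structure.
#' @param state_dispersion Per-state multiplier on the within-cell spread
#'   of distributed features: the pure large-process state (4) has
#'   heterogeneous processes, the blended soma/process state (5) has
#'   uniform, tightly controlled ones, and the moderate state (6) is the
#'   most heterogeneous, giving each state a distinctive signature in the
#'   spread/shape statistic columns.
#' @param occupancy_gain Strength of the occupancy response: state
#'   frequencies at each time are reweighted by
#'   `exp(gain * affinity %*% deflection)`, moving cells into activation
#'   states whose block profile matches the LPS deflection.
#' @param within_state_share Fraction of the block deflection applied as a
#'   within-state intensity shift (the remainder acts through occupancy).
#' @param mouse_sd Standard deviation of the per-mouse random intercept on
#'   each block intensity.
#' @param cell_sd Standard deviation of the per-cell intensity jitter.
#' @param process_mean Typical process-segment count per cell.
#' @param process_range Inclusive bounds on the per-cell process count.
#' @param spread_effect Scaling of within-cell spread with block intensity
#'   (the distribution-expansion effect of LPS on distributed features).
#' @param within_sdlog Within-cell log-scale spread of distributed features.
#' @return A `morph_sim_config` list.
#' @export
morph_sim_config <- function(catalog = morphology_catalog(),
                             state_intensity = default_state_intensity(),
                             state_freq_wt = c(0.30, 0.06, 0.16, 0.14, 0.12, 0.22),
                             state_freq_ko = c(0.20, 0.22, 0.16, 0.14, 0.12, 0.16),
                             effects = default_effect_profiles(),
                             effect_scale = 1,
                             state_shift = 1,
                             state_dispersion = c(1, 1, 1, 1.5, 0.45, 2),
                             occupancy_gain = 1.6,
                             within_state_share = 0.35,
                             mouse_sd = 0.10,
                             cell_sd = 0.10,
                             process_mean = 18,
                             process_range = c(5, 60),
                             spread_effect = 0.25,
                             within_sdlog = 0.45) {
  validate_block_map(catalog)
  if (!all(dim(state_intensity) == c(6, 4))) {
    abort("state_intensity must be a 6 x 4 matrix (states x blocks fs1..fs4)")
  }
  stopifnot(length(state_freq_wt) == 6, length(state_freq_ko) == 6,
            length(state_dispersion) == 6, all(state_dispersion > 0))
  if (abs(sum(state_freq_wt) - 1) > 1e-8 || abs(sum(state_freq_ko) - 1) > 1e-8) {
    abort("state frequencies must sum to 1")
  }
  if (mouse_sd < 0 || cell_sd < 0 || within_sdlog <= 0 || process_mean <= 0) {
    abort("scale parameters must be positive")
  }
  # planted contract: knockout recovery at least wild type for fs2 and fs3
  ef <- tidyr::pivot_wider(effects[, c("block", "genotype", "recovery")],
                           names_from = "genotype", values_from = "recovery")
  bad <- ef$block[ef$block %in% c("fs2", "fs3") & ef$KO < ef$WT]
  if (length(bad) > 0) {
    abort(paste0("knockout recovery must be >= wild type for: ",
                 paste(bad, collapse = ", ")))
  }
  structure(list(catalog = catalog, state_intensity = state_intensity,
                 state_freq_wt = state_freq_wt, state_freq_ko = state_freq_ko,
                 effects = effects, effect_scale = effect_scale,
                 state_shift = state_shift,
                 state_dispersion = state_dispersion,
                 occupancy_gain = occupancy_gain,
                 within_state_share = within_state_share, mouse_sd = mouse_sd,
                 cell_sd = cell_sd, process_mean = process_mean,
                 process_range = process_range, spread_effect = spread_effect,
                 within_sdlog = within_sdlog),
            class = "morph_sim_config")
}

#' Default latent-state block intensities
#'
#' Six morphological states expressed as intensities over the four
#' feature-set blocks: a ramified state (high fs1), a large-soma state
#' (high fs2), a complex-branch-shape state (high fs3), two large-process
#' states (high fs4, one with elevated soma features), and a state with
#' moderate expression of every block.
#'
#' @return 6 x 4 numeric matrix.
#' @export
default_state_intensity <- function() {
  m <- rbind(c(2.75, 0.00, 0.00, 0.00),
             c(0.00, 2.75, 0.00, 0.00),
             c(0.00, 0.00, 2.75, 0.00),
             c(0.00, 0.00, 0.00, 3.00),
             c(0.00, 1.50, 0.00, 2.50),
             c(1.25, 1.25, 1.25, 1.25))
  dimnames(m) <- list(paste0("state", 1:6), paste0("fs", 1:4))
  m
}

#' Simulate per-cell microglial morphometry
#'
#' Draws a complete synthetic reconstruction export: per-cell scalar
#' features and per-process distributed features, with long-tailed noise
#' families per feature (lognormal sizes, Poisson-lognormal counts,
#' scaled-beta bounded shape parameters), six latent cell states, mouse-level
#' random effects, and genotype-specific LPS deflections of the feature-set
#' block intensities.
#'
#' @param design A [study_design()].
#' @param config A [morph_sim_config()].
#' @return A list of class `microglia_sim` with elements
#'   \describe{
#'     \item{cells}{tibble, one row per cell: `cell_id`, `mouse_id`,
#'       `genotype`, `time_days`, `state` (planted latent state),
#'       `n_processes`, `degenerate` (fewer than 2 processes), then one
#'       column per scalar feature.}
#'     \item{processes}{long tibble of distributed measurements:
#'       `cell_id`, `feature`, `value` (one row per process per feature).}
#'   }
#' @examples
#' sim <- simulate_microglia(study_design(seed = 7), morph_sim_config())
#' nrow(sim$cells)
#' @export
simulate_microglia <- function(design = study_design(),
                               config = morph_sim_config()) {
  stopifnot(inherits(design, "study_design"),
            inherits(config, "morph_sim_config"))
  withr::with_seed(design$seed, simulate_microglia_impl(design, config))
}

simulate_microglia_impl <- function(design, config) {
  cat <- config$catalog
  times <- design$timepoints_days
  t_final <- max(times)
  blocks <- paste0("fs", 1:4)

  mice <- tidyr::expand_grid(genotype = design$genotypes,
                             tp = seq_along(times)) |>
    dplyr::mutate(time_days = times[.data$tp],
                  n_mice = design$mice_per_group[.data$tp])
  mice <- mice[rep(seq_len(nrow(mice)), mice$n_mice), ] |>
    dplyr::mutate(mouse_id = sprintf("m%02d", dplyr::row_number())) |>
    dplyr::select("mouse_id", "genotype", "time_days")

  n_mice <- nrow(mice)
  # cells per mouse: deterministic allocation to hit the design total,
  # otherwise uniform in the configured range
  rng <- design$cells_per_mouse
  if (!is.null(design$n_cells_total)) {
    base <- design$n_cells_total %/% n_mice
    extra <- design$n_cells_total %% n_mice
    n_cells <- rep(base, n_mice) + c(rep(1, extra), rep(0, n_mice - extra))
    if (any(n_cells < rng[1]) || any(n_cells > rng[2])) {
      warn("deterministic cell allocation falls outside cells_per_mouse range")
    }
  } else {
    n_cells <- sample(seq(rng[1], rng[2]), n_mice, replace = TRUE)
  }

  # mouse random effects on each block intensity
  mouse_re <- matrix(rnorm(n_mice * 4, 0, config$mouse_sd), n_mice, 4,
                     dimnames = list(mice$mouse_id, blocks))

  # genotype x time x block deflections
  eff <- config$effects
  defl <- array(0, dim = c(2, length(times), 4),
                dimnames = list(design$genotypes, NULL, blocks))
  for (g in design$genotypes) {
    for (b in blocks) {
      row <- eff[eff$genotype == g & eff$block == b, ]
      if (nrow(row) == 1) {
        defl[g, , b] <- config$effect_scale *
          effect_deflection(times, row$amplitude, row$peak_time,
                            row$recovery, t_final)
      }
    }
  }

  freq_ko <- config$state_freq_wt +
    config$state_shift * (config$state_freq_ko - config$state_freq_wt)
  base_freq <- rbind(config$state_freq_wt, freq_ko)
  rownames(base_freq) <- design$genotypes

  cells <- mice[rep(seq_len(n_mice), n_cells), ] |>
    dplyr::mutate(cell_id = sprintf("c%03d", dplyr::row_number()))
  nc <- nrow(cells)
  tp_idx <- match(cells$time_days, times)
  g_idx <- match(cells$genotype, design$genotypes)

  # the LPS response acts mostly through state occupancy: cells shift
  # into states whose block profile matches the deflection (activation
  # states), with a smaller within-state intensity shift on top
  affinity <- config$state_intensity / max(config$state_intensity)
  state_freq <- array(0, dim = c(2, length(times), 6))
  for (g in 1:2) {
    for (tp in seq_along(times)) {
      w <- base_freq[g, ] *
        exp(config$occupancy_gain * as.vector(affinity %*% defl[g, tp, ]))
      state_freq[g, tp, ] <- w / sum(w)
    }
  }
  cells$state <- vapply(seq_len(nc), function(i) {
    sample.int(6, 1, prob = state_freq[g_idx[i], tp_idx[i], ])
  }, integer(1))

  lambda <- config$state_intensity[cells$state, , drop = FALSE] +
    mouse_re[cells$mouse_id, , drop = FALSE] +
    matrix(rnorm(nc * 4, 0, config$cell_sd), nc, 4)
  for (b in seq_along(blocks)) {
    lambda[, b] <- lambda[, b] +
      config$within_state_share * defl[cbind(g_idx, tp_idx, b)]
  }
  colnames(lambda) <- blocks

  # process counts track ramification (fs1) intensity
  pr <- config$process_range
  n_proc <- rpois(nc, exp(log(config$process_mean) + 0.35 * lambda[, "fs1"] +
                            rnorm(nc, 0, 0.2)))
  n_proc <- pmin(pmax(n_proc, pr[1]), pr[2])
  cells$n_processes <- n_proc
  cells$degenerate <- n_proc < 2

  scalar_cat <- cat[!cat$distributed, ]
  for (i in seq_len(nrow(scalar_cat))) {
    f <- scalar_cat[i, ]
    lam <- f$effect * lambda[, f$feature_set]
    cells[[f$feature]] <- draw_feature(f, lam, rnorm(nc, 0, f$sigma))
  }

  dist_cat <- cat[cat$distributed, ]
  cell_rep <- rep(seq_len(nc), n_proc)
  proc_list <- vector("list", nrow(dist_cat))
  for (i in seq_len(nrow(dist_cat))) {
    f <- dist_cat[i, ]
    lam_b <- lambda[, f$feature_set]
    shift <- f$effect * lam_b + rnorm(nc, 0, f$sigma)
    # LPS-style expansion: within-cell spread grows with block intensity;
    # states additionally carry their own dispersion signature
    sdl <- config$within_sdlog *
      config$state_dispersion[cells$state] *
      exp(config$spread_effect * pmax(lam_b, 0))
    vals <- draw_feature(f, shift[cell_rep],
                         rnorm(length(cell_rep), 0, sdl[cell_rep]))
    proc_list[[i]] <- tibble(cell_id = cells$cell_id[cell_rep],
                             feature = f$feature, value = vals)
  }

  structure(list(cells = dplyr::relocate(cells, "cell_id"),
                 processes = dplyr::bind_rows(proc_list)),
            class = "microglia_sim")
}

# draw from a feature's noise family given a latent shift and extra noise
# on the latent scale; counts via Poisson-lognormal, bounded features via
# scaled beta with logit-shifted mean
draw_feature <- function(f, shift, noise) {
  eta <- shift + noise
  switch(f$family,
    lognormal = exp(log(f$base) + eta),
    poislog   = rpois(length(eta), exp(log(f$base) + eta)),
    beta      = {
      m <- stats::plogis(stats::qlogis(f$base / f$upper) + eta)
      phi <- 12
      f$upper * rbeta(length(m), m * phi, (1 - m) * phi)
    },
    abort(paste0("unknown noise family: ", f$family))
  )
}

#' @export
print.microglia_sim <- function(x, ...) {
  cat(sprintf("<microglia_sim> %d cells / %d mice, %d scalar + %d distributed features\n",
              nrow(x$cells), dplyr::n_distinct(x$cells$mouse_id),
              sum(!attr_catalog(x)$distributed), sum(attr_catalog(x)$distributed)))
  invisible(x)
}

attr_catalog <- function(sim) {
  feats <- setdiff(names(sim$cells),
                   c("cell_id", "mouse_id", "genotype", "time_days", "state",
                     "n_processes", "degenerate"))
  cat <- morphology_catalog(default_only = FALSE)
  dplyr::bind_rows(cat[cat$feature %in% feats, ],
                   cat[cat$feature %in% unique(sim$processes$feature), ])
}

#' Simulate a null feature matrix
#'
#' Generates standard-normal features over the cells of a study design with
#' no genotype- or time-linked structure at all; used for type-I error
#' calibration of the time-course tests.
#'
#' @param design A [study_design()].
#' @param n_features Number of features to draw.
#' @param seed Seed (defaults to the design seed).
#' @return A wide tibble: `cell_id`, `mouse_id`, `genotype`, `time_days`,
#'   then `f1..fN` feature columns, carrying a feature dictionary attribute
#'   so it can flow into the same analyses as a real feature matrix.
#' @export
simulate_null_features <- function(design = study_design(), n_features = 200,
                                   seed = design$seed) {
  skeleton <- withr::with_seed(design$seed, {
    sim_design_cells(design)
  })
  vals <- withr::with_seed(seed, {
    matrix(rnorm(nrow(skeleton) * n_features), nrow(skeleton), n_features)
  })
  colnames(vals) <- paste0("f", seq_len(n_features))
  out <- dplyr::bind_cols(skeleton, as_tibble(vals))
  dict <- tibble(feature = colnames(vals), base_feature = colnames(vals),
                 statistic = "none", compartment = NA_character_,
                 distributed = FALSE, feature_set = NA_character_)
  attr(out, "dictionary") <- dict
  class(out) <- c("morph_features", class(out))
  out
}

# metadata skeleton (cells x design labels) without feature draws
sim_design_cells <- function(design) {
  times <- design$timepoints_days
  mice <- tidyr::expand_grid(genotype = design$genotypes,
                             tp = seq_along(times)) |>
    dplyr::mutate(time_days = times[.data$tp],
                  n_mice = design$mice_per_group[.data$tp])
  mice <- mice[rep(seq_len(nrow(mice)), mice$n_mice), ] |>
    dplyr::mutate(mouse_id = sprintf("m%02d", dplyr::row_number())) |>
    dplyr::select("mouse_id", "genotype", "time_days")
  n_mice <- nrow(mice)
  if (!is.null(design$n_cells_total)) {
    base <- design$n_cells_total %/% n_mice
    extra <- design$n_cells_total %% n_mice
    n_cells <- rep(base, n_mice) + c(rep(1, extra), rep(0, n_mice - extra))
  } else {
    rng <- design$cells_per_mouse
    n_cells <- sample(seq(rng[1], rng[2]), n_mice, replace = TRUE)
  }
  mice[rep(seq_len(n_mice), n_cells), ] |>
    dplyr::mutate(cell_id = sprintf("c%03d", dplyr::row_number())) |>
    dplyr::relocate("cell_id")
}
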