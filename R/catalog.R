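#' Morphometric feature catalog for IMARIS-style microglia exports
#'
#' The catalog enumerates the base morphological features produced by
#' filament-tracing reconstruction of Iba1-labeled microglia: scalar
#' soma/whole-filament descriptors (one value per cell) and distributed
#' per-process descriptors (one value per process segment). Each feature
#' carries a compartment, measurement units, a distributional noise family
#' used by the synthetic generator, and a feature-set annotation grouping
#' correlated features (fs1 ramification, fs2 soma size/shape, fs3 process
#' shape, fs4 process size).
#'
#' Two soma shape descriptors (oblate ellipticity and sphericity) carry no
#' feature-set annotation and are excluded from the default analysis catalog;
#' with the remaining 14 scalar features and 12 distributed features expanded
#' into 8 distribution statistics each, the analysis matrix has
#' 14 + 12 * 8 = 110 columns.
#'
#' @param default_only Drop the unannotated features (the default analysis
#'   catalog). Set to `FALSE` to see the full reconstruction export.
#' @return A tibble with one row per base feature: `feature`, `compartment`
#'   (`"soma"` or `"process"`), `units`, `distributed` (logical),
#'   `feature_set` (`"fs1"`--`"fs4"` or `NA`), `family` (noise family:
#'   `"lognormal"`, `"poislog"`, or `"beta"`), `base` (typical magnitude in
#'   `units`), `upper` (upper bound for bounded features, `NA` otherwise),
#'   `effect` (loading of the feature on its feature-set's latent intensity),
#'   and `sigma` (between-cell noise scale on the latent log/logit scale).
#' @examples
#' morphology_catalog()
#' @export
morphology_catalog <- function(default_only = TRUE) {
  cat <- tibble::tribble(
    ~feature,                    ~compartment, ~units,   ~distributed, ~feature_set, ~family,     ~base, ~upper, ~effect, ~sigma,
    "Soma area",                 "soma",       "um2",    FALSE,        "fs2",        "lognormal", 120,   NA,     0.70,    0.35,
    "Soma ellipsoid length A",   "soma",       "um",     FALSE,        "fs2",        "lognormal", 8,     NA,     0.45,    0.30,
    "Soma ellipsoid length B",   "soma",       "um",     FALSE,        "fs2",        "lognormal", 6,     NA,     0.45,    0.30,
    "Soma ellipsoid length C",   "soma",       "um",     FALSE,        "fs2",        "lognormal", 4,     NA,     0.55,    0.30,
    "Ellipticity oblate",        "soma",       NA,       FALSE,        NA,           "beta",      0.4,   1,      0.30,    0.35,
    "Ellipticity prolate",       "soma",       NA,       FALSE,        "fs2",        "beta",      0.5,   1,      0.40,    0.35,
    "Number triangles",          "soma",       "count",  FALSE,        "fs2",        "poislog",   700,   NA,     0.70,    0.30,
    "Number vertices",           "soma",       "count",  FALSE,        "fs2",        "poislog",   350,   NA,     0.70,    0.30,
    "Number voxels",             "soma",       "count",  FALSE,        "fs2",        "poislog",   1500,  NA,     0.75,    0.30,
    "Soma sphericity",           "soma",       NA,       FALSE,        NA,           "beta",      0.8,   1,      0.25,    0.35,
    "Soma volume",               "soma",       "um3",    FALSE,        "fs2",        "lognormal", 180,   NA,     0.80,    0.35,
    "Process branches",          "process",    "count",  FALSE,        "fs1",        "poislog",   12,    NA,     0.95,    0.30,
    "Process segments",          "process",    "count",  FALSE,        "fs1",        "poislog",   25,    NA,     0.95,    0.30,
    "Process terminals",         "process",    "count",  FALSE,        "fs1",        "poislog",   14,    NA,     0.90,    0.30,
    "Filament edges",            "process",    "count",  FALSE,        "fs1",        "poislog",   300,   NA,     0.85,    0.30,
    "Filament volume",           "process",    "um3",    FALSE,        "fs1",        "lognormal", 250,   NA,     0.85,    0.35,
    "Process area",              "process",    "um2",    TRUE,         "fs4",        "lognormal", 15,    NA,     0.65,    0.30,
    "Branch depth",              "process",    "count",  TRUE,         "fs1",        "poislog",   4,     NA,     0.80,    0.25,
    "Branch level",              "process",    NA,       TRUE,         "fs1",        "lognormal", 3,     NA,     0.75,    0.25,
    "Branch angle",              "process",    "deg",    TRUE,         "fs3",        "beta",      80,    180,    0.55,    0.30,
    "Branch angle B",            "process",    "deg",    TRUE,         "fs3",        "beta",      60,    180,    0.55,    0.30,
    "Process length",            "process",    "um",     TRUE,         "fs4",        "lognormal", 12,    NA,     0.70,    0.30,
    "Process diameter",          "process",    "um",     TRUE,         "fs3",        "lognormal", 1.2,   NA,     0.60,    0.25,
    "Process orientation angle", "process",    "deg",    TRUE,         "fs3",        "beta",      45,    180,    0.45,    0.30,
    "Process position",          "process",    "um",     TRUE,         "fs1",        "lognormal", 20,    NA,     0.70,    0.30,
    "Process resistance",        "process",    "um-1",   TRUE,         "fs4",        "lognormal", 8,     NA,     0.60,    0.30,
    "Process straightness",      "process",    NA,       TRUE,         "fs3",        "beta",      0.75,  1,      0.45,    0.30,
    "Process volume",            "process",    "um3",    TRUE,         "fs4",        "lognormal", 6,     NA,     0.70,    0.35
  )
  if (default_only) cat <- dplyr::filter(cat, !is.na(.data$feature_set))
  cat
}

#' Distribution statistics used to expand distributed features
#'
#' Each distributed (per-process) feature is summarised per cell by these
#' eight statistics: three of center (mean, median, mode), three of spread
#' (standard deviation, coefficient of variation, half-width of the t-based
#' 95% confidence interval of the mean) and two of shape (skewness, excess
#' kurtosis).
#'
#' @return Character vector of statistic suffixes.
#' @export
distribution_statistics <- function() {
  c("mean", "median", "mode", "sdev", "cv", "ci95", "skew", "kurt")
}

# validate a catalog's feature-set (block) map: every analysed feature
# assigned exactly one block
validate_block_map <- function(catalog) {
  if (anyDuplicated(catalog$feature)) {
    abort(paste0("duplicated features in catalog: ",
                 paste(unique(catalog$feature[duplicated(catalog$feature)]),
                       collapse = ", ")))
  }
  bad <- catalog$feature[is.na(catalog$feature_set)]
  if (length(bad) > 0) {
    abort(paste0("features with no feature-set (block) assignment: ",
                 paste(bad, collapse = ", ")))
  }
  if (!all(catalog$feature_set %in% paste0("fs", 1:4))) {
    abort("feature_set labels must be fs1..fs4")
  }
  invisible(catalog)
}
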