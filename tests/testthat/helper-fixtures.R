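# lazily computed shared fixtures so expensive objects are built once per run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

default_sim <- function() {
  fixture("sim", function() simulate_microglia(study_design(seed = 1)))
}

default_zscores <- function() {
  fixture("z", function() zscore_features(build_feature_matrix(default_sim())))
}

default_odp <- function() {
  fixture("odp", function() odp_test(default_zscores(), n_boot = 500, seed = 1))
}

default_selected <- function() {
  fixture("selected", function() {
    z <- default_zscores()
    sel <- select_features(morph_pca(z, n_comp = 10)$loadings, default_odp())
    filter_features(z, sel$feature[sel$selected])
  })
}

default_nmf <- function() {
  fixture("nmf", function() {
    morph_nmf(shift_nonnegative(default_selected()), rank = 6, seed = 1)
  })
}

# tiny morph_features object built by hand for unit tests
toy_features <- function(values, genotype = NULL, time = NULL) {
  n <- nrow(values)
  out <- dplyr::bind_cols(
    tibble::tibble(
      cell_id = sprintf("c%02d", seq_len(n)),
      mouse_id = rep("m01", n),
      genotype = genotype %||% rep(c("WT", "KO"), length.out = n),
      time_days = time %||% rep(c(0, 1, 3, 5), length.out = n)
    ),
    tibble::as_tibble(values)
  )
  attr(out, "dictionary") <- tibble::tibble(
    feature = colnames(values), base_feature = colnames(values),
    statistic = "none", compartment = NA_character_,
    distributed = FALSE, feature_set = NA_character_)
  class(out) <- c("morph_features", class(out))
  out
}

`%||%` <- rlang::`%||%`
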