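#' End-to-end analysis pipeline on synthetic data
#'
#' Runs the full workflow: simulate the morphometry and qPCR datasets,
#' assemble and Z-score the feature matrix, test temporal profiles and run
#' PCA, select features, factorise at the configured rank, validate with
#' rank-distance MDS, quantify adaptation, and simulate the cytokine
#' model. Every table is written as TSV with a provenance header
#' (`# morphodyn <version>; seed=<seed>; config=<hash>`), so a rerun with
#' the same configuration is byte-identical.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Seed driving every stochastic stage.
#' @param design,sim_config Study design and generator configuration.
#' @param n_boot Bootstrap replicates of the temporal-profile test.
#' @param rank Factorization rank.
#' @param loading_cutoff,p_cutoff Feature-selection thresholds.
#' @param network Cytokine network for the simulation stage.
#' @param run_nmds Compute the (slow) MDS validation stage.
#' @return Invisibly, a named list of the in-memory stage results.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         design = study_design(seed = seed),
                         sim_config = morph_sim_config(),
                         n_boot = 500, rank = 6,
                         loading_cutoff = 0.2, p_cutoff = 0.05,
                         network = cytokine_network(),
                         run_nmds = TRUE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg <- list(design = design, sim_config = sim_config, n_boot = n_boot,
              rank = rank, loading_cutoff = loading_cutoff,
              p_cutoff = p_cutoff, network = network)
  hash <- rlang::hash(cfg)
  write_stage <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    header <- sprintf("# morphodyn %s; seed=%d; config=%s",
                      as.character(utils::packageVersion("morphodyn")),
                      as.integer(seed), hash)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }

  inform("generating synthetic morphometry and qPCR data")
  sim <- simulate_microglia(design, sim_config)
  qpcr <- simulate_qpcr(design)
  write_stage(sim$cells, "cells")
  write_stage(sim$processes, "processes")
  write_stage(qpcr, "qpcr")

  inform("building and scaling the feature matrix")
  fm <- build_feature_matrix(sim, sim_config$catalog)
  z <- zscore_features(fm)
  write_stage(feature_dictionary(z), "feature_dictionary")

  inform("temporal-profile testing and PCA")
  odp <- odp_test(z, n_boot = n_boot, seed = seed)
  write_stage(odp, "odp_results")
  pca <- morph_pca(z, n_comp = 10)
  write_stage(pca$loadings, "pca_loadings")

  sel <- select_features(pca$loadings, odp,
                         loading_cutoff = loading_cutoff,
                         p_cutoff = p_cutoff)
  write_stage(sel, "feature_selection")
  z_sel <- filter_features(z, sel$feature[sel$selected])
  d_sel <- shift_nonnegative(z_sel)

  inform(sprintf("factorising %d selected features at rank %d",
                 sum(sel$selected), rank))
  nmf <- morph_nmf(d_sel, rank = rank, seed = seed)
  fsets <- assign_feature_sets(nmf)
  write_stage(tidy(nmf, "W"), "nmf_W")
  write_stage(tidy(nmf, "H"), "nmf_H")
  write_stage(nmf$clusters, "cell_clusters")
  write_stage(fsets, "feature_sets")
  enr <- cluster_enrichment(nmf$clusters,
                            z[, c("cell_id", "genotype")])
  write_stage(enr, "cluster_enrichment")

  nmds <- NULL
  if (run_nmds) {
    inform("nonmetric MDS validation")
    nmds <- morph_nmds(spearman_distance(z_sel), seed = seed)
    write_stage(nmds$coords, "mds_coords")
  }

  inform("adaptation analysis")
  profiles <- scale_profiles(z)
  est <- estimate_adaptation(profiles) |>
    dplyr::left_join(feature_dictionary(z)[, c("feature", "feature_set")],
                     by = "feature")
  cmp <- compare_adaptation(est)
  write_stage(est, "adaptation_indices")
  write_stage(cmp, "adaptation_comparisons")

  inform("cytokine network simulation")
  traj <- simulate_cytokines(network, lps_stimulus(1), t_end = 120)
  dr <- dose_response(network, doses = 10^seq(-2, 2, length.out = 8))
  write_stage(traj, "cytokine_trajectory")
  write_stage(dr, "dose_response")

  invisible(list(sim = sim, qpcr = qpcr, features = fm, zscores = z,
                 odp = odp, pca = pca, selection = sel, nmf = nmf,
                 feature_sets = fsets, enrichment = enr, nmds = nmds,
                 adaptation = est, comparisons = cmp, trajectory = traj,
                 dose_response = dr, config_hash = hash))
}

#' Read a pipeline stage table
#'
#' Reads a TSV written by [run_pipeline()], returning the provenance
#' header as attributes `seed` and `config_hash`.
#'
#' @param path Path to the stage TSV.
#' @return Tibble with provenance attributes.
#' @export
read_stage <- function(path) {
  header <- readLines(path, n = 1)
  df <- as_tibble(utils::read.delim(path, comment.char = "#",
                                    check.names = FALSE))
  m <- regmatches(header,
                  regexec("seed=([0-9]+); config=([0-9a-f]+)", header))[[1]]
  if (length(m) == 3) {
    attr(df, "seed") <- as.integer(m[2])
    attr(df, "config_hash") <- m[3]
  }
  df
}
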