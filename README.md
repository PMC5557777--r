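# morphodyn

Microglia — the resident immune cells of the central nervous system —
change shape when the CNS is inflamed: somata swell, processes retract,
branch geometry reorganises. Those changes track the cytokine environment,
and in particular the balance between pro-inflammatory TNFα and
anti-inflammatory IL-10. `morphodyn` is an R package for quantifying both
sides of that relationship:

* **multivariate morphometry** — turning per-cell reconstruction exports
  (scalar soma descriptors plus per-process distributed measurements) into
  a cells × features matrix of distribution statistics, testing which
  features' temporal profiles differ between genotypes, discovering
  morphological cell states by offset non-negative matrix factorization,
  and validating the states by nonmetric multidimensional scaling;
* **adaptation analysis** — scoring how completely a perturbed feature (or
  a simulated cytokine) returns to baseline, with closed-form error
  propagation and genotype comparisons;
* **a two-compartment cytokine network model** — Hill-kinetic ordinary
  differential equations for six microglial cytokines coupled to a delayed
  TGFβ feedback from the CNS environment, with knockout simulation and
  LPS dose–response analysis.

No public per-cell morphometry data accompany the study design this
package emulates, so it ships a seed-reproducible synthetic-data generator
(`simulate_microglia()`, `simulate_qpcr()`) that plants the structure the
analyses assume — six latent cell states built from four correlated
feature blocks, long-tailed noise families, and genotype-specific
LPS-response kinetics — so every downstream method can be exercised and
checked against known ground truth.

## The statistics in brief

* **Temporal-profile test.** For feature *i*, natural cubic splines are
  fitted to the time course pooled over genotypes (error *SS⁰*) and per
  genotype (error *SSᴬ*); the statistic *Fᵢ = (SSᵢ⁰ − SSᵢᴬ)/SSᵢᴬ* measures
  the gain from genotype-specific curves, with p-values from a residual
  bootstrap under the pooled fit and Benjamini–Hochberg FDR control.
* **Offset NMF.** The non-negative feature matrix **D** is factorised as
  **D ≈ WH + c·1ᵀ** (basis **W**, coefficients **H**, per-feature offset
  *c*), initialised by non-negative double SVD and refined by
  multiplicative updates; cells are classified by their most-enriched
  meta-feature, features are grouped into feature sets by clustering rows
  of **W**.
* **Adaptation index.** After min–max scaling of time-point means to
  [0, 1] and orientation correction,
  *A = 1 − (Z̄_final − Z̄_t0)/(Z̄_peak − Z̄_t0)*; *A = 1* is complete
  recovery. Var(*A*) follows by the delta method, and genotypes are
  compared with *T = (A_KO − A_WT)/√(2S²/n_min)*, *df = 2n_min − 2*.
* **Cytokine model.** Each species follows
  *dC/dt = (1 + k·LPS/(LPS+K_LPS))·∏(activation)·∏(inhibition) − γC −
  γ_ss·C_ss*, with the constant degradation *γ_ss* derived so the resting
  state *C_ss = 0.1* is an exact fixed point; microglial IL-10 drives a
  first-order cascade producing delayed CNS TGFβ.

## Worked example

```r
library(morphodyn)

design  <- study_design(seed = 42)            # 218 cells / 28 mice / 4 time points
sim     <- simulate_microglia(design, morph_sim_config())
features <- build_feature_matrix(sim)         # 110 expanded feature columns
zscores  <- zscore_features(features)

odp <- odp_test(zscores, n_boot = 500, seed = 42)
glance(odp)
#>   n_features n_sig_p05 n_sig_q05
#> 1        110        61        48

pca <- morph_pca(zscores, n_comp = 10)
sel <- select_features(pca$loadings, odp)     # ODP p < 0.05 or loading > 0.2
sum(sel$selected)
#> [1] 76

fit <- zscores |>
  filter_features(sel$feature[sel$selected]) |>
  shift_nonnegative() |>
  morph_nmf(rank = 6, seed = 42)
fit
#> <morph_nmf> rank 6, 76 features x 218 cells, rel. error 0.3111 (1396 iterations, converged)

cluster_enrichment(fit$clusters, zscores[, c("cell_id", "genotype")])
#>   cluster n_cells n_enriched empty          p
#> 1       1      22          9 FALSE 0.838
#> 4       4      47         37 FALSE 0.00000225   <- knockout-enriched state
#> ...
```

Cluster 4 is the planted large-soma activation state: it is heavily
over-represented in IL-10-knockout cells (hypergeometric p ≈ 2.3 × 10⁻⁶),
the pattern the enrichment test is designed to detect.

```r
est <- zscores |>
  scale_profiles() |>
  estimate_adaptation() |>
  dplyr::left_join(feature_dictionary(zscores)[, c("feature", "feature_set")],
                   by = "feature")
cmp <- compare_adaptation(est)
dplyr::filter(cmp, eligible, feature_set == "fs2")
#>   feature                  A_WT  A_KO statistic        q
#> 1 Soma ellipsoid length A 0.610 0.848      16.9 1.63e-19
#> 2 Soma ellipsoid length B 0.834 1.07       13.7 1.04e-16
```

Eligible soma-size features recover more completely in the knockout
(A_KO > A_WT), mirroring the planted kinetics. The same index applied to
the simulated TNFα trajectory shows the model's counter-intuitive
behaviour — removing the IL-10 node *increases* both the peak response and
the completeness of recovery, most visibly at low stimulus doses:

```r
net <- cytokine_network()
dose_response(net, doses = 10^seq(-2, 2, length.out = 6))
#>     dose peak_wt peak_ko adaptation_wt adaptation_ko
#> 1 0.0100   0.147   0.159         0.973          1.00
#> 2 0.0631   0.305   0.344         0.993          1.00
#> 3 0.398    0.656   0.765         0.997          1.00
#> ...
```

`autoplot()` methods exist for trajectories, factorizations and
embeddings; `run_pipeline(out_dir, seed)` executes the whole workflow and
writes every stage as TSV with provenance headers.

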