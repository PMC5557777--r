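---
title: "Methods: morphology dynamics, adaptation, and the cytokine network model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphology dynamics, adaptation, and the cytokine network model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphodyn)
```

`morphodyn` analyses how microglial morphology and CNS cytokine networks
respond to, and recover from, an inflammatory (LPS) challenge, comparing
wild-type mice with IL-10 knockouts. This vignette is the package's own
account of its methods: the models and their assumptions, the parameters
that matter and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical and design choices made where more
than one convention was defensible.

## 1. From reconstruction exports to the feature matrix

Filament-tracing reconstruction of Iba1-labelled microglia yields two
kinds of measurements per cell: *scalar* descriptors (one value per cell;
soma geometry and whole-filament totals) and *distributed* descriptors
(one value per process segment; lengths, areas, angles, and so on). The
catalog of features, their compartments, units and noise families is in
`morphology_catalog()`.

Each distributed feature is summarised per cell by eight distribution
statistics — mean, median, mode, standard deviation, coefficient of
variation, the half-width of the t-based 95% confidence interval of the
mean, skewness, and excess kurtosis (`distribution_statistics()`).
Conventions:

* **Mode.** For continuous measurements, the peak of a Gaussian kernel
  density estimate with Silverman's bandwidth; for integer-valued
  measurements, the most frequent value with the lowest value winning
  ties.
* **Spread/shape estimators.** The standard deviation uses the sample
  (n − 1) form; skewness and kurtosis are the moment estimators
  (`m3/m2^1.5` and `m4/m2² − 3`). A single-process cell has all spread and
  shape statistics set to 0 by convention and is flagged.
* **Column count.** The default analysis catalog holds 14 scalar features
  (two unannotated soma-shape descriptors, oblate ellipticity and
  sphericity, are excluded because they belong to no feature set) and 12
  distributed features, so the matrix has 14 + 12 × 8 = 110 columns. The
  variance is deliberately not part of the statistic set — it is redundant
  with the standard deviation, and the confidence-interval half-width
  takes its place.

Columns are Z-scored over all cells (both genotypes, all time points
pooled); constant columns are dropped with a warning. For factorization
the Z-matrix is made non-negative by subtracting each feature's minimum
(`shift_nonnegative()`), so every feature's minimum is exactly zero — the
per-feature offset of the factorization then absorbs whatever baseline
level remains.

## 2. Temporal-profile testing

Whether a feature's time course differs between genotypes is tested on
whole profiles, not individual time points. A natural cubic spline with
`df = 3` basis columns (plus intercept) is fitted to the pooled data
(error $SS^0$) and per genotype (error $SS^A$); with four distinct time
points this basis is saturated, so the fits interpolate the pooled and
genotype-specific time-point means. The statistic

$$F_i = \frac{SS_i^0 - SS_i^A}{SS_i^A}$$

measures the relative gain of genotype-specific curves. Its null
distribution is estimated by a residual bootstrap under the pooled fit:
residual rows are resampled with replacement jointly across features
(preserving feature correlation), added back to the pooled fitted values
with genotype labels held fixed, and the statistic recomputed;
$p = (1 + \#\{F^{null} \ge F^{obs}\})/(1 + B)$. Cells are the resampling
unit; mouse-level dependence is part of the generator's realism rather
than the test's error model, a deliberate simplification (a mixed-model
treatment is out of scope). FDR control is Benjamini–Hochberg by default,
with a conservative Storey-style variant
(`pi0 = min(1, mean(p > 0.5)/0.5)`) available.

On null data (200 standard-normal features over the default design,
`simulate_null_features()`), the bootstrap p-values are uniform within
Kolmogorov–Smirnov distance 0.1 and the fraction of q < 0.05 calls stays
within Monte-Carlo error of the nominal rate — the calibration property
the test suite asserts.

## 3. Feature selection

A feature enters the factorization when its profile test is significant
(p < 0.05) **or** its principal-component loading magnitude across the
first four components exceeds 0.2. The loading magnitude is, by default,
the **L2 norm** of the feature's loadings on components 1–4; the maximum
absolute loading is available via `magnitude = "max"`. The L2 default is a
considered choice: with blocks of strongly correlated features, a
component's unit-norm loading vector spreads over every member of a large
block, so the per-component maximum hovers near the cutoff and whole
blocks drop in or out of the selection from one draw to the next. Pooling
evidence across four components keeps each correlated block represented
and makes the selected set (typically 50–75 of 110 columns here) stable.

## 4. Offset non-negative matrix factorization

The features × cells matrix is decomposed as
$D \approx WH + c\,\mathbf{1}^\top$, with all factors non-negative and a
per-feature offset $c$ that accommodates features expressed at constant
levels across cells. Numerical choices:

* **Initialisation.** Non-negative double SVD: the leading singular
  triplets are split into their positive/negative parts and the larger
  side retained; zero entries are filled with the matrix mean (perturbed
  by ~1%) so multiplicative updates cannot lock at zero. This makes the
  fit deterministic up to the seed of the small jitter.
* **Updates.** The classical multiplicative rules for $W$ and $H$ under
  squared error, extended with
  $c \leftarrow c \cdot \text{rowSums}(D)/\text{rowSums}(WH + c)$ — the
  offset behaves as an extra basis column whose coefficient row is fixed
  at one, so the objective is non-increasing at every step (asserted by
  the tests). Iteration stops when the relative error change falls below
  `tol` (default 1e-7) or at `max_iter` (default 2000).
* **Cluster assignment.** Factorizations are scale-ambiguous
  ($WH = (W\Lambda)(\Lambda^{-1}H)$), so basis columns are first
  normalised to unit sum with the scale moved into $H$. Cells are then
  assigned to the meta-feature with the largest coefficient *relative to
  that meta-feature's population mean* (row-mean-normalised argmax,
  lowest index winning ties). The relative form matters: raw argmax
  favours components with large overall coefficient rows, and blended
  cell states — which load moderately on several components — would be
  absorbed by the dominant ones. On the default synthetic cohort the
  relative convention recovers the planted states with adjusted Rand
  index typically 0.7–0.9, where raw argmax loses 0.1–0.2.
* **Feature sets.** Rows of $W$ are normalised to unit sum, clustered
  hierarchically on correlation distance with average linkage, and the
  tree cut at the silhouette-optimal number of clusters between 2 and the
  rank (or a caller-specified `k`); labels are ordered by cluster size.
  All-zero rows are labelled `"unassigned"`.
* **Rank.** The default rank 6 reflects the number of morphological cell
  states the workflow is designed around; `nmf_rank_survey()` reports
  reconstruction error, sparsity, and cross-seed cluster stability
  (mean pairwise adjusted Rand index) over a rank range as a diagnostic.

## 5. Validation by ordination

Cell-to-cell dissimilarity is one minus the Spearman rank correlation of
the two cells' feature profiles, $d_{ij} = 1 - \rho_{ij} \in [0, 2]$.
Nonmetric MDS (Kruskal stress-1, isotonic-regression iterations with
random restarts, via **vegan**) embeds the cells in three dimensions;
cells of one factorization cluster should sit closer to each other than
to other clusters', which the test suite asserts on the default cohort.
A configuration that is exactly Euclidean in 3-D embeds with stress
below 0.01.

## 6. Adaptation analysis

For each feature, per-genotype time-point means of the Z-scores are
min–max scaled to $[0, 1]$ and orientation-corrected: if a genotype's
maximal deviation from baseline is downward
($|\bar Z_{min} - \bar Z_{t0}| > |\bar Z_{max} - \bar Z_{t0}|$) the
profile is flipped ($\bar Z \to 1 - \bar Z$) and the response labelled a
decrease. The adaptation index is

$$A = 1 - \frac{\bar Z_{final} - \bar Z_{t0}}{\bar Z_{peak} - \bar Z_{t0}},$$

with the *peak* defined as the post-baseline extreme of the oriented
profile (not the global extreme) and *final* the last time point. $A = 1$
is complete recovery, $A = 0$ none, $A > 1$ an overshoot below baseline.
The variance follows by first-order error propagation through
$\bar Z_{peak}$ and $\bar Z_{final}$ with the baseline treated as a
constant; the tests verify it against 10⁵-draw Monte-Carlo propagation to
within 5%.

Documented conventions, made where more than one reading was defensible:

* **Scaling scope.** The min and max are taken over the *pooled*
  wild-type and knockout time-point means of a feature, so both genotypes
  share one scale and their indices are directly comparable. (Per-genotype
  scaling is the main alternative; pooling preserves comparability and is
  what the genotype comparison below assumes.)
* **Standard error.** The SEM of a time-point mean is computed as
  standard deviation divided by *n* — the convention of the
  error-propagation framework this analysis follows, kept as the default
  deliberately even though it is smaller than the conventional
  `sd/sqrt(n)`; that form is available via `sem_method = "sd_sqrt_n"`.
  With the default, propagated variances (and hence the T statistics
  below) are on the framework's own scale; switching conventions rescales
  both genotypes alike and leaves orderings intact.
* **Eligibility.** Genotypes are compared only when both indices show
  meaningful, same-direction adaptation: $\min(A_{WT}, A_{KO}) > 0.5$,
  both within $(-0.2, 1.2)$, and matching response directions.
* **Comparison.** $T = (A_{KO} - A_{WT})/\sqrt{2S^2/n_{min}}$ with
  $S^2 = \frac{n_{min}-1}{df}(\hat\sigma^2_{A,WT} + \hat\sigma^2_{A,KO})$,
  $df = 2n_{min} - 2$, where $n_{min}$ is the smallest per-time-point
  sample size across both genotypes — a deliberately conservative choice.
  Two-tailed p-values come from the t distribution and are BH-adjusted
  within each feature set when feature-set labels are supplied, otherwise
  across all compared features. The 95% confidence interval of a single
  index is $A \pm t_{0.025}(df)\,\hat\sigma_A/\sqrt{n_{min}}$.

Feature-set dynamics (`featureset_dynamics()`) average each cell's
Z-scores within a feature set and fit a genotype × time two-way ANOVA,
with Fisher-LSD-style post-hoc contrasts (within-genotype versus baseline
and between-genotype per time point) under a Sidak correction, computed
with **emmeans**.

## 7. The synthetic-data generator

The generator replaces unavailable raw data and defines the study
conditions every property above is tested under: 2 genotypes × 4 time
points (0, 1, 3, 5 days), 28 mice (4/3/4/3 per genotype per time point),
218 cells allocated evenly with the remainder to the first mice.

**What is planted.**

* **Six latent cell states** over the four feature-set blocks
  (ramification fs1, soma size/shape fs2, process shape fs3, process size
  fs4): four nearly pure block states, a blended soma/process state, and
  a moderate-everything state. Intensities sit at 2.75–3.0 so states are
  separated by roughly 1.5–2 within-population standard deviations after
  Z-scoring.
* **Dispersion signatures.** States 4–6 additionally differ in
  within-cell process heterogeneity (multipliers 1.5, 0.45, 2.0 on the
  within-cell spread). This is not decoration: with non-negative
  factors, any state whose block profile lies inside the non-negative
  cone of the pure block states can never earn a dedicated basis
  component, so a six-state geometry built from four blocks alone is
  unrecoverable by design. The dispersion axes live in the spread/shape
  statistic columns and make each state conically extreme. A corollary,
  stated openly: spread-statistic columns carry *state-level* signal
  rather than block-level signal, so feature-set recovery is evaluated on
  the location-statistic columns, where the planted block structure
  genuinely resides.
* **The LPS response** acts mainly through *state occupancy*: at each
  time point, state frequencies are reweighted by
  $\exp(\text{gain} \cdot \text{affinity} \cdot d_{g,b}(t))$, moving
  cells into activation states whose block profile matches the deflection
  $d$ (gain 1.6), plus a smaller within-state intensity shift (35% of
  $d$). This mirrors how activation is understood biologically — cells
  transition between discrete states — and decouples statistical power
  (driven by occupancy shifts) from cluster separability (driven by state
  geometry), which global mean shifts would degrade.
* **Genotype kinetics.** Deflections rise linearly to a peak and relax
  linearly, parameterised by amplitude, peak day and the fraction
  recovered by day 5. Knockout recovery is at least wild-type for every
  block (0.90–0.95 versus 0.55–0.70; enforced for fs2/fs3 by the config
  validator); the soma-size peak is at day 1 in the knockout but day 3 in
  the wild type; and knockout cells are statically enriched for the
  large-soma state (frequency 0.22 versus 0.06). Wild-type recoveries are
  placed inside the adaptation-eligibility window so the genotype
  comparison has a non-trivial eligible set.
* **Noise families** follow each feature's physical nature: lognormal for
  sizes, lengths and volumes; Poisson-lognormal for counts; scaled beta
  for bounded angles, straightness and shape indices. Within-cell spread
  expands with block intensity (the distribution-expansion effect of
  LPS), mice carry small random intercepts (sd 0.10), and process counts
  (5–60, mean ≈ 18) track ramification intensity.

**What is not emulated:** reconstruction/segmentation error, spatial
position effects, between-batch staining variation, missing or truncated
cells, and any correlation between a cell's state and its mouse beyond
the shared random intercept. Passing tests therefore demonstrate that the
pipeline recovers structure of the planted kind at realistic noise — not
that real exports satisfy these distributional assumptions.

The qPCR generator emits reference/target Ct pairs whose
$2^{-\Delta\Delta Ct}$ fold changes reproduce kinetic templates (sharp
day-1 TNF peak, larger in the knockout; recovery by day 3; sustained
TGFβ elevation) up to 0.15-cycle measurement noise.

## 8. The two-compartment cytokine model

Six microglial species (TNFα, IL-1β, IL-6, TGFβ, IL-10, CCL5) follow

$$\frac{dC_x}{dt} = \Big(1 + \frac{k_x\,\text{LPS}}{\text{LPS} + K_{LPS}}\Big)
\prod_i \frac{C_i^{n}}{C_i^{n}+K^{n}}
\prod_j \frac{K^{n}}{C_j^{n}+K^{n}}
\; - \; \gamma_x C_x \; - \; \gamma_{ss,x} C_{ss,x},$$

with the constant degradation $\gamma_{ss,x} = P_{ss,x}/C_{ss,x} -
\gamma_x$ derived so the resting state $C_{ss} = 0.1$ is an exact fixed
point with no stimulus ($P_{ss}$ is the production product at rest). LPS
drives every microglial species except TGFβ for a 16-hour window.
Microglial IL-10 feeds a chain of first-order stages
($\tau_A \dot A_1 = k_A M_{IL10} - \gamma_A A_1$, and likewise down the
chain) whose output — CNS-environment TGFβ, attributed biologically to
astrocytes — inhibits microglial IL-1β and IL-6 with a delay that grows
with the number of stages (three by default, $\tau_A$ = 6 h).

**Topology and parameters** (all data, not code; see
`default_edges()`): LPS → all but TGFβ; TNFα activates IL-1β, IL-6,
IL-10, CCL5 (K = 0.5, n = 1.5); IL-10 inhibits TNFα, IL-1β, IL-6;
microglial TGFβ inhibits TNFα; **IL-6 inhibits TNFα**; environment TGFβ
inhibits IL-1β and IL-6. Gains $k_x = 4$, $K_{LPS} = 1$, $\gamma = 0.1$/h.
Two choices deserve explanation:

* **The IL-6 → TNFα brake.** IL-6 has a classical anti-inflammatory
  action suppressing TNF production. Structurally this edge is what lets
  the IL-10 knockout *enhance* TNFα recovery: in the knockout, IL-6 is
  doubly disinhibited (no IL-10, and a dead TGFβ cascade), its larger
  excursion trims the TNFα response, and TNFα returns to baseline faster
  than in the wild type. Without a second negative-feedback path onto
  TNFα, the knockout could only ever recover more slowly than the wild
  type, since IL-10 would be TNFα's sole dynamic regulator.
* **Weak-near-baseline inhibition of TNFα** (K = 1, n = 2 on all three
  TNFα-inhibiting edges). At resting levels these kernels are nearly
  silent, so feedback engages only when the inhibitors are themselves
  stimulated; this prevents the post-stimulus undershoot below baseline
  that sharper kernels produce, keeping the adaptation index
  interpretable.

These parameter values are the package's own, chosen to give the model
its documented qualitative behaviour (resting-state invariance, knockout
peak amplification at every dose, knockout adaptation at least wild-type
with the gap widest at low doses — the "left-shifted" adaptation curve);
they are not fitted to data, and quantitative trajectory reproduction is
explicitly out of scope.

**Numerics.** Stiff-capable integration (lsoda) with the time axis split
at the stimulus on/off switches so the discontinuous input is handled
exactly; relative/absolute tolerances 1e-8/1e-10; concentrations are kept
non-negative by smoothly attenuating negative derivatives near zero
(factor $C/(C + 10^{-4})$), a guard needed because the constant
degradation term keeps draining a species whose production has collapsed.
Knockout removes a node and its incident edges; the remaining
$\gamma_{ss}$ are re-derived, so the reduced network rests exactly at its
own steady state (a knocked-out cascade source leaves the cascade at
zero). Simulated time is hours internally, reported also in days.

## 9. Problem sizes and runtime

The default analyses are desk-scale by design: 218 cells × 110 features,
500 bootstrap replicates (vectorised through precomputed QR
factorizations, under a second), rank-6 factorization of ~50–75 selected
features (a few seconds), 12-dose × 2-variant model sweeps (a few
seconds), and a 30-day steady-state run well under a second. The full
test suite, including the end-to-end property checks, runs in a few
minutes on one core.

## 10. Known limitations

* Mouse nesting is emulated but not modelled: the profile test and the
  adaptation comparison treat cells as exchangeable. With strong mouse
  effects both would be anticonservative on real data.
* The silhouette-based cut for feature sets can return more than four
  sets when dispersion-driven columns form their own cluster; pass `k`
  explicitly when the block count is known.
* With four time points the spline basis is saturated; the `df` argument
  matters only for designs with more sampling times.
* The factorization's state recovery is typically ARI 0.7–0.9 across
  seeds but not guaranteed; blended states are intrinsically harder for
  parts-based decompositions, and an occasional seed confuses the
  blended state with a neighbouring pure state.
* The cytokine model is a two-compartment abstraction with a restricted
  species list and hand-set parameters; it supports qualitative
  reasoning about feedback structure, not quantitative prediction.
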