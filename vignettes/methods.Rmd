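---
title: "Models and methods behind dediffquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dediffquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dediffquant)
```

# The scientific problem

Lung adenocarcinomas arising from alveolar type 2 (AT2) pneumocytes can
lose the expression of their cell-of-origin marker genes — surfactant
proteins, lysozyme — while retaining the lineage transcription factor
NKX2-1. In mouse models this de-differentiation is driven cell-autonomously
by cooperating oncogenic signaling and appears *variegated*: within one
tumor, marker-negative cells are spatially interspersed among
marker-positive neighbours. Quantifying it requires (i) single-cell
measurements of immunofluorescence images with a defensible positivity
rule, and (ii) transcriptome-level evidence that an identity program, and
candidate regulators embedded in it, move together.

`dediffquant` implements both arms as reusable, tested components and
couples them to synthetic-data generators with known ground truth, so that
every stage's statistical behaviour (calibration, power, recovery) can be
demonstrated rather than assumed.

# The image arm

## Generative model for tumor images

`generate_tumor_image()` renders one field of view per tumor:

* **Geometry.** Nuclei are disks with radius $\sim N(6, 1)$ px truncated
  at 2 px, placed by rejection sampling so that center distances exceed
  the sum of radii (bounded retries; an explicit placement error
  otherwise). Each cell is its nucleus dilated by a 5 px cytoplasmic rim,
  clipped against neighbours by nearest-seed assignment.
* **Intensities.** Each channel has a log-normal intensity model per cell
  state. Nuclear channels (DNA stain, nuclear TF) are identical in both
  states; the marker channel has a high "retained" mode (median ≈ 3000)
  and a lower, wider "lost" mode (median ≈ 600, the paperless default for
  an uncharacterized partial-loss distribution, exposed in the
  configuration). A cell is "lost" with probability
  `marker_loss_fraction`, independently per cell — that is what makes the
  loss variegated rather than regional.
* **Association.** Per-cell levels are coupled across channels by a
  Gaussian copula. The configured value is a *Spearman* target; the latent
  Pearson correlation is $2\sin(\pi\rho/6)$, the exact inversion, so
  simulation studies can dial rank correlations directly. Default 0.25,
  in the range observed for nuclear-TF/marker association in
  well-differentiated tumors.
* **Acquisition.** A constant background (100), a left-to-right linear
  ramp (amplitude 50) standing in for uneven illumination, Gaussian read
  noise (SD 30), quantization to the 16-bit range. Saturation is avoided
  by construction, matching how quantitative acquisitions are set up.

What the generator deliberately does **not** emulate: point-spread
blurring, 3D sectioning artifacts, touching or multinucleated cells,
stromal contamination, autofluorescence structure. Passing tests therefore
certify the pipeline's logic and statistics on clean tissue-like scenes,
not robustness to every real-world artifact.

## Segmentation and measurement

`detect_nuclei()` concretizes primary-object identification as Gaussian
smoothing (σ = 1 px) → global Otsu threshold → hole filling →
distance-transform watershed declumping → area filter (20–5000 px) →
border-object removal. These settings are recorded in `params_used`
because the upstream convention (a CellProfiler pipeline) names modules,
not algorithmic constants.

`propagate_cells()` grows cells from nuclei in two modes: *propagation*
(nearest-seed Euclidean growth capped at `max_distance_px`, default 10;
with no membrane channel in these assays, intensity-guided propagation has
nothing to guide on, so geometric growth is the honest equivalent) and
*ring* (a 3 px dilation, the convention for diffuse tumors where
propagation performs poorly). Contested pixels go to the nearest nucleus,
ties to the lower label. The pipeline-level default caps propagation at
the generator's cytoplasm width (5 px); a looser cap floods the measured
cytoplasm with background in sparse scenes.

Cytoplasm is cell minus nucleus per label, which gives the exact
pixel-count conservation invariant |cell| = |nucleus| + |cytoplasm| used
throughout the tests. Medians use the lower middle value for even pixel
counts so every reported median is an attained pixel value, reproducible
across numeric backends.

## The statistics layer

Tumors, not cells, are the independent units: `aggregate_tumors()` reports
the mean of per-cell medians per tumor, and two-genotype comparisons run a
two-sided Wilcoxon rank-sum on tumor summaries (exact null for combined
n ≤ 12 without ties; tie-corrected normal approximation otherwise).
Three or more groups use one-way ANOVA with Tukey's HSD.

The positivity rule is fit on the reference genotype, whose tumors stain
relatively uniformly: a cell is *negative* when its compartment median
falls strictly below mean − 1·SD of the pooled reference cells (sample SD,
n − 1). Pooling is over all reference cells at the matching time point;
per-time-point fitting is the default because staining batches differ
between harvests, and both pooled-cell and per-tumor variants remain one
`subset` away in the records table. Under a Normal reference this rule
calls Φ(−1) ≈ 15.9% of the reference's own cells negative — a property
the acceptance checks verify empirically.

Quadrant classification crosses nuclear-TF positivity (nucleus
compartment) with marker positivity (cytoplasm compartment); genotype ×
class tables are compared by Pearson chi-squared without continuity
correction, and per-cell association by Spearman correlation pooled within
genotype (a tumor-stratified variant is available). The sample-size helper
solves the noncentral-t power equation for the two-sided two-sample
t-test by root-finding on continuous n, using the conventional upper-tail
two-sided power.

Cells within a tumor share acquisition conditions, so treating cells as
exchangeable within genotype (as the chi-squared and Spearman layers do)
is a simplification; the tumor-level tests are the inferential anchor.
Hierarchical cell-within-tumor models are out of scope.

# The expression arm

## Generative model for count matrices

`generate_expression_matrix()` draws negative-binomial counts (constant
dispersion 0.05; Poisson when 0) around means
$\text{scale} \cdot b_g \cdot s_j \cdot \exp(\lambda_{m(g),j} +
\varepsilon_{gj}) \cdot 2^{\delta_g}$: a log-normal gene base level
(median 300 for expressed genes, 5 for a 30% low-expressed block), a
log-normal sample depth factor (SD 0.15), a per-module latent factor
shared by all genes of a module (SD 0.4), independent gene noise
(SD 0.15), and a group-B fold change $\delta_g$ equal to the configured
effect for every gene of the affected module (default −2, i.e. four-fold
down). Module latents are mean-centered within each group: without
centering, the random difference of latent means would leak into every
gene's realized fold change and the truth table could not promise the
exact planted log2FC. Eight samples per group reflect the deposited
study's scale (two genotypes, a handful of sorted-tumor libraries per
arm).

The gene layout is deterministic given the configuration: the affected
module carries all AT2-type reference markers, three quarters of the
AT1-type markers, the planted regulator (a transcription factor), and
fillers; club and ciliated markers sit in unaffected modules; decoy TFs
are planted in unaffected modules and among unassigned genes.

## Reference marker sets

`generate_celltype_markers()` emits a gene × 4 cell-type table of
reference means, and `build_marker_sets()` scores specificity as
$\log_2(\mu_{t}+1) - \log_2(\max_{t'\ne t}\mu_{t'}+1)$, taking the top
100 with ties broken by gene id. Exclusive markers score positive in
exactly one type. Designed pairwise overlaps (default 6 genes per pair of
types, within the empirically reported 2–12 range for distal lung
epithelium marker compendia) are realized by pair-shared genes that tie
the within-type maximum in two types: they score zero in both, and their
deliberately low-sorting gene ids win the tie-break into both top-100
sets. A strict reading — 100 genes per type each strictly exceeding all
other types — is incompatible with any overlap under this score, so
"most specific" here means *attaining* the within-type maximum.

## Differential expression

`nb_wald_test()` is a deliberately small two-group test, not a GLM
framework: median-of-ratios size factors (geometric-mean-1 rescaled),
per-gene total dispersion as the squared CV of normalized counts by
method of moments (floored at 1e-8), delta-method standard error for the
log2 fold change, standard-normal two-sided p values, BH correction.

Two numerical choices deserve note. First, the statistic depends on the
data only through normalized counts, so pure depth rescalings cancel
exactly (doubling one sample's counts changes its size factor and nothing
else). The shot-noise component of the variance is therefore not an
explicit depth term; in the optional trend-shrinkage mode it appears as
the $1/\mu$ term of the fitted trend $\exp(a_0 + a_1/\mu)$. Second, raw
gene-wise dispersion is the default: in data with co-expression
structure, genes of equal mean have genuinely different dispersions
(latent-driven module genes versus independent genes), and shrinking
toward a single mean-dispersion trend makes the test conservative (null
type-I ≈ 0.03 versus ≈ 0.05 for the gene-wise estimate at 8 samples per
group, measured on the generator's null). Shrinkage remains available via
`dispersion = "shrunk"` for small-sample settings without that
heterogeneity.

Median-of-ratios normalization carries the usual composition effect:
when a large fraction of the transcriptome moves one way, the reference
median shifts and estimated fold changes are biased toward zero (about
−0.08 log2 units with 12.5% of genes down four-fold). This is a property
of the normalization, shared with standard implementations, and is why
the fold-change recovery checks use a small affected fraction.

## Preranked GSEA

`gsea_preranked()` is classic weighted-KS GSEA on a preranked list
(Wald statistic by default, log2FC optionally; the ranked list breaks
ties by gene id so results are deterministic). Hits increment the running
sum by $|r_i|^p / \sum_{hits}|r|^p$ (weight $p = 1$ by default; $p = 0$
retained for symmetry tests), misses decrement by $1/(N - N_h)$; the ES
is the extremum of larger magnitude, with exact magnitude ties resolved
to the positive extremum under a small relative tolerance so floating
error cannot flip the sign. The null is gene-permutation (random
same-size sets, sampled without replacement and seeded), matching the
preranked setting where sample labels are unavailable. NES divides ES by
the mean |null ES| of matching sign, and p values use the add-one
correction $(1 + \#\{|ES_{null}| \ge |ES|,\ \text{same sign}\}) /
(1 + \#\text{null same sign})$ — simple Monte-Carlo rather than an
adaptive multilevel approximation, exact in the limit and adequate at
$10^4$ permutations (tests and the acceptance script use a few hundred,
which bounds attainable p values at ~1/300 and is sufficient for
direction and calibration claims). BH runs across all sets of a
collection as one family.

## Module detection and the three-factor screen

`filter_expressed()` keeps genes with mean normalized count strictly
above 40 — the conventional low-expression floor, with the filter
statistic configurable because "normalized expression > 40" admits
mean/min/max readings. `coexpression_modules()` builds the unsigned
adjacency $|cor|^\beta$ with soft power β = 3 (where the scale-free fit
plateaus at these data sizes), optionally the topological overlap
similarity, then average-linkage clustering with a *static* cut (height
0.9 on the 1 − adjacency scale) and a minimum module size of 30, the
customary floor, below which clusters dissolve into module 0. A static
cut replaces dynamic tree cutting deliberately: it is deterministic,
single-parameter, and sufficient for planted-structure recovery, which is
what the package's claims are calibrated on; parity with dynamic cutting
on real transcriptomes is a non-goal.

`select_marker_module()` picks the module with the largest combined count
of AT1+AT2 marker-set members (ties to the lower id, flagged), and
`three_factor_screen()` intersects (1) membership in that module, (2) a
user-supplied transcription-factor list — annotation lookup is
intentionally external — and (3) differential expression at a
deliberately promiscuous adjP < 0.2, so that the intersection rather than
the DE threshold carries the specificity. On default synthetic
conditions the screen recovers the planted regulator in essentially all
seeded runs while excluding ≥ 99% of decoy TFs.

# Reproducibility machinery

Every generator and permutation consumes an explicit seed; the two arm
drivers (`run_image_arm()`, `run_expr_arm()`) fan a single configuration
seed out to per-stage seeds by fixed documented offsets, so stages are
independently reproducible and reruns are bit-identical. Artifacts are
plain text (CSV, GMT, JSON) plus TIFF rasters; plots are conveniences and
never inputs to any statistic.

Problem sizes used by the test-suite and the acceptance script — 384–512
px scenes with 120–200 cells, 2000–6000 genes × 16 samples, 2000-replicate
null calibrations, 20-seed recovery studies, a few hundred GSEA
permutations — were chosen as the smallest designs at which the binomial
or Monte-Carlo error of each checked quantity is comfortably inside its
acceptance band.

# Known limitations

* Segmentation is classical (threshold + watershed); scenes with heavy
  nucleus contact or intensity-graded boundaries will degrade before the
  generator's defaults do.
* The DE test has no outlier handling, no fold-change shrinkage, and a
  normal (not t) reference for the Wald statistic; it is calibrated at
  n ≥ 8 per group and should not be trusted at n = 2–3.
* GSEA p values are bounded below by the permutation count.
* The co-expression stage computes a full gene × gene correlation matrix;
  it is meant for filtered desk-scale matrices (≲ 10⁴ genes), not
  block-wise genome-scale runs.
* The synthetic generators define the conditions under which every
  quantitative claim here is verified; behaviour on real micrographs or
  transcriptomes inherits only the logic, not the measured rates.
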