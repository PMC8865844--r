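---
title: "Methods and design choices in plasmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in plasmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`plasmap` analyses the regional organisation of a plasmodial syncytium from
three data modalities: nuclei point patterns extracted from stained images,
gridded bulk transcriptomes that keep their 2-D coordinates, and
single-nucleus / single-cell UMI matrices. This vignette explains the models
behind each stage, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the choices made where the design
was genuinely open. It states no empirical result that the test suite does
not itself compute.

## 1. Nuclei point patterns

**Density model.** Nucleus centroids are treated as a planar point process
with intensity λ(x, y) (nuclei per µm²). The kernel estimate is an
isotropic Gaussian sum

    λ̂(x) = Σ_i (2πh²)^{-1} exp(−‖x − x_i‖² / 2h²),

evaluated on a regular grid of `cell_size` µm cells and normalised so the
map integrates to the point count. The bandwidth default is Scott's rule,
`h = mean(sd_x, sd_y) · n^{−1/6}`; a fixed bandwidth in µm can be given
instead. No boundary correction is applied, so mass near the domain edge
leaks outward; the mass-conservation guarantee (±2%) therefore holds for
patterns whose points sit at least ~3 bandwidths inside the domain, and the
fan/network density *ratio* estimated from the map is mildly attenuated
toward 1 near the region boundary (the recovery tests budget 15% for this).

**Fan/network split.** The map is averaged across x to a 1-D profile along
y, and an Otsu threshold — the histogram cut maximising the between-class
variance `w₀w₁(μ₀ − μ₁)²` over a 64-bin histogram — separates dense
(growth-front) from sparse (network) rows. 64 bins resolve profiles of tens
of rows without over-fragmenting the histogram; the threshold is verified
in the tests against an exhaustive scan over all cuts. The reported
boundary row is the step position minimising label mismatches against a
"network below, fan above" step, which is robust to isolated mislabelled
bins.

**Density test.** The region comparison uses Welch's unequal-variance
two-sided *t*-test (`density_ttest`). The calibration test feeds it counts
from non-overlapping quadrats: KDE cells are spatially correlated by the
kernel, and using them as "independent" samples would inflate the type-I
rate; quadrat counts are independent under the Poisson null.

**Detection scoring.** Predicted and true centroids are matched one-to-one
by minimum total distance subject to a cap (`match_radius`, default the
mean true diameter). The assignment problem is solved exactly with a
Jonker–Volgenant shortest-augmenting-path solver written in the package;
pairs beyond the radius carry a penalty larger than any achievable total
valid cost, which makes the optimisation lexicographic: maximise matches,
then minimise distance. Precision and accuracy follow the usual
TP/(TP+FP) and TP/(TP+FP+FN) identities.

## 2. Expression processing

Layers are explicit (`counts`, `TPM`, `log2TPM`, `lognorm`, `scaled`) and
every transform checks its input layer. Choices that were open:

* **"log-normalised" means natural log** with pseudo-depth 10⁴
  (`ln(1 + 10⁴·x/total)`), matching the convention of the standard
  single-cell toolchain; base 2 is used only for thresholded log₂ TPM
  (TPM ≤ 1 → 0, continuous at the threshold since log₂1 = 0).
* **Regression scaling** removes per-sample covariates (detected genes and
  total counts by default) by OLS with intercept, then z-scores each gene
  and clips at ±10. Genes whose residual spread is below 10⁻⁸ of their
  original spread (i.e. fully absorbed, or constant) scale to zeros rather
  than amplifying rounding noise. *Caveat*: in fixed-depth multinomial data
  the number of detected genes is itself a function of the expression
  program (program nuclei concentrate counts in fewer genes), so regressing
  `n_genes` can remove the biological signal; the clustering tests regress
  depth only, and real analyses should make this choice consciously.
* **Markers** use the one-vs-rest two-sided Wilcoxon rank-sum test. For two
  groups of ≤ 10 samples each (≤ 20,000 subsets) the p-value is an exact,
  tie-safe permutation enumeration of the rank-sum; otherwise a normal
  approximation with tie and continuity correction. The exact small-sample
  path mirrors `wilcox.test`'s own exact/approximate switch and is what
  makes agreement with a permutation oracle to 10⁻³ attainable. Adjustment
  is Bonferroni over all genes in the matrix (the stated toolchain's
  default), with Benjamini–Hochberg as an option. Pre-filters: detection
  fraction ≥ 0.1 in either group, |avg log FC| ≥ 0.25.
* **Clustering.** Graph clustering builds a shared-nearest-neighbour graph
  (Jaccard weights over kNN sets including self, links below 1/15 pruned)
  and runs Louvain at a user resolution under a fixed seed. Note that
  Louvain cannot merge disconnected graph components, so the
  "resolution → 0 gives one cluster" limit holds for connected graphs.
  Hierarchical clustering uses `1 − Pearson` distances with `hclust`'s
  `ward.D2` linkage ("Ward method"); the tree is cut at a user `k` or at
  the largest merge-height gap.
* **Module scores** follow the expression-matched control-bin construction:
  genes binned by average expression (24 bins), `n_ctrl` controls drawn per
  set gene from its bin with a seeded RNG, score = mean(set) − mean(controls).
  The construction is invariant to adding a constant to all values.
* **Quantiles** use R's default linear-interpolation definition (type 7)
  throughout, including the 10% detected-gene cutoff and the q10/q90
  display contrast limits.

## 3. Grid analyses

`distance_correlation` reproduces the documented sequence literally: top
200 genes by variance of the *scaled* layer, per-gene shift by |row
minimum| (a no-op for Pearson in exact arithmetic — kept for fidelity and
pinned by a rank-invariance test), Pearson between grid columns with the
diagonal excluded, Euclidean distance between grid centres, and an OLS line
of r on distance with a two-sided slope *t*-test. One statistical addition:
pairs sharing a grid are dependent, so the naive OLS confidence interval is
anticonservative (in position-shuffled null runs it covers zero in only
about 70% of runs). The reported `slope_ci` is therefore a leave-one-
grid-out jackknife interval, which restores honest coverage; `slope_p`
remains the naive OLS test, as in the original analysis.

## 4. Projection of nuclei onto space

Pseudobulks are arithmetic means of the log-normalised layer per cluster
(the layer named in the original description; the scaled layer would also
be defensible). The correlation map restricts both sides to the union of
the top 50 markers per spatial cluster ranked by adjusted then raw p,
computes Spearman correlations (average ranks for ties), and "scales" by
z-scoring columns first, then rows, clipping to [−1, 1] — z-scoring is the
interpretation of "scaled" under which clipping at ±1 is meaningful, and
the column-then-row order is pinned by a hand-computed 3 × 3 test. Nuclei
clusters are dendrogrammed by Ward on 1 − Pearson of the scaled rows.

## 5. Mitotic-wave pseudotime

The diffusion map uses a Gaussian kernel on Euclidean distances with either
a global σ or a local one (distance to the k-th neighbour,
k = max(5, ⌈√n⌉)); the kernel is density-normalised (α = 1:
`W = K/(q_i q_j)`) and the first nontrivial right eigenvectors of the
row-normalised operator are returned via the symmetrised eigenproblem, with
a deterministic sign convention. The adaptive bandwidth can wobble very
slightly at the ends of a 1-D manifold; the exact monotone-line limit holds
with a global bandwidth.

Ranking is block-wise: the user supplies the ordered group sequence (in the
original analysis, groups read off the embedding); within blocks samples
sort by the first diffusion component, whose global direction is chosen so
block medians increase along the sequence. Orderings are defined up to
global reversal, and reversing the sequence reverses the ranks exactly.

The LOESS "span = 10" of the original description is not a valid span
fraction; it is interpreted as a bandwidth of ~10 rank units converted to a
fraction, `span = max(0.3, 10/n)`, exposed as a parameter.

The grid-side "pseudospatial" ordering is an explicit reconstruction (the
original lacks a methods description): cluster grids on the phase markers,
order the blocks by mean expression of late-phase ("G2/M") markers, and
apply the same diffusion + block ranking. A linear ordering of a cyclic
process is only well-posed when the wave spans less than a full cycle
across the specimen, which motivates the generator default below.

## 6. The synthetic world

The generator encodes the stated conditions rather than tunable dials:

* **Point pattern**: Matérn II dependent thinning (propose Poisson, keep a
  point iff no proposal within the hard-core radius has a smaller mark).
  The proposal intensity is inverted analytically so the *realised*
  intensity equals the requested λ; λ ≥ 1/(πr²) is impossible and errors
  with the packing bound. Defaults: fan band = top 40% of the y-axis with
  λ = 0.01/µm², network λ = 0.005/µm² (ratio 2), hard core 3 µm, log-normal
  diameters with mean 5.65 µm and CV 0.15.
* **Grid counts**: expected expression = log-normal baseline × 2^(log2FC)
  for a region's program genes × a strictly positive wave factor
  `exp(a·cos(φ − peak))` for wave genes, with `a = log(2)·log2FC/2` so the
  peak-to-trough ratio equals 2^log2FC. Counts are negative binomial with
  per-grid means summing to `libsize_grid` (2×10⁵, SmartSeq2-like) and
  dispersion 2; dispersion ∞ switches to Poisson (tested by a moment
  check). The oat (food-contact) program occupies a 4 × 4 block. The wave
  advances π/12 per column — half a cycle across the 12-column specimen —
  because a single synchronized division wave traverses the organism
  without wrapping; a full-cycle wave would make grid columns 1 and 12
  transcriptionally identical and the linear ordering ill-posed.
* **Nuclei/amoeba counts**: each nucleus draws a program (region, or one of
  `n_phase_bins` wave-phase bins), a depth ~ Poisson(591), and a
  multinomial UMI vector from the program's relative profile; amoebae use
  continuous phases and depth ~ Poisson(14,525). Column sums equal the
  drawn library sizes by construction (the conservation invariant applies
  to these multinomial simulators; grid counts are negative binomial per
  their own model, so their totals fluctuate around the target).

What the generator does **not** emulate: transcript-length bias, batch and
plate effects, ambient RNA, doublets, zero inflation beyond the NB, 3-D
geometry, cytoplasmic flow, or any real gene identities. A green recovery
test therefore establishes that the pipeline inverts *this* stated world at
the configured effect sizes — not that it would do so on the real organism's
data, whose generative process is unknown (the source material is an
observational study; every distribution here is a stand-in, and the truth
files say so).

## 7. Numerical and degenerate-input conventions

* Coordinates are µm, origin at the domain's lower-left corner, y
  increasing toward the fan; images and masks are matrices with row 1 the
  bottom row.
* Identical `(config, seed)` reproduces every simulator output
  bit-for-bit; all stochastic analysis steps (module-score controls,
  Louvain) take explicit seeds and restore the caller's RNG state.
* Degenerate inputs error early and name the offender: zero-total samples
  in normalisation, zero-variance samples in correlation clustering,
  constant profiles in the Otsu split, disconnected kernel graphs in the
  diffusion map. Two constant equal groups in the *t*-test return p = 1 by
  convention; zero-variance pseudobulks or grids yield flagged `NA`
  correlations rather than failures.
* Ties: average ranks in Spearman and the Wilcoxon statistic; `which.max`
  tie-breaks (first maximum) make argmax assignments deterministic.

## 8. Known limitations

* The KDE has no edge correction; absolute densities near boundaries are
  biased low.
* The SNN/Louvain implementation targets the data sizes of this domain
  (10²–10⁴ samples); it builds a dense distance matrix.
* The pseudospatial grid ordering is a reconstruction, not a published
  procedure, and its recovery is the weakest of the wave criteria (median
  |Spearman ρ| across seeds is the tested statistic).
* `region_de` on a single-grid region runs but rests on one sample; the
  warning is not decorative.
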