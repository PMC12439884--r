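---
title: "Methods: stitching, spatial pattern consensus and factor transfer"
author: "spotMosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stitching, spatial pattern consensus and factor transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotMosaic)
```

spotMosaic implements the computational steps needed when a spatial
transcriptomics section spans several hexagonal capture arrays: stitch
the arrays into one coordinate frame, respot onto a section-level grid,
filter and normalize, discover spatially autocorrelated gene programs,
reconcile them across donors, register against external references, and
transfer factorization-based programs between single-nucleus and spatial
data. This vignette records the models, the tunable parameters, and the
design choices made where the methods literature leaves options open.

## Rigid stitching from landmark pairs

Each capture area is a hexagonal lattice with 100 µm spot pitch and
native array coordinates bounded by `array_row` ∈ [0, 77],
`array_col` ∈ [0, 127] (column parity equals row parity; the same-row
neighbor sits two columns away). Overlapping areas share manually
annotated landmark pairs. For a pair of areas, the rotation is estimated
from every unordered pair of landmarks: the segment joining the two
landmarks is formed in each area, the signed angle between the two
segments is taken from `atan2(cross, dot)`, and the estimate is the
weighted *circular* mean of these angles with weights
`sqrt(len_A * len_B)` (geometric mean of the segment lengths). The
circular mean avoids ±π wrap-around and reduces to the arithmetic mean
for small angles. The translation is estimated after de-rotation: the
B-side landmarks are rotated about their centroid and the mean
displacement to the A side is taken. The rotation pivot is a free
choice — it only redefines the translation component, which is solved
consistently afterwards — and is fixed at the B-side landmark centroid.

Multi-area sections are aligned by fixing the first area as the
reference and composing pairwise refinements along a breadth-first
spanning tree of the overlap graph, on top of any coarse (e.g. manual
image-alignment) affine transforms. Validation on noiseless planted
transforms recovers the map to below 1e-9 px; with 2 px landmark jitter
and 8 landmarks the estimates stay within 1° and 3 px of an independent
least-squares (SVD/Kabsch) rigid fit over 100 replicates.

After stitching, a section-level "artificial" hexagonal grid with the
same 100 µm pitch is laid over the bounding box of all spots, anchored
so the minimum pixel coordinates map to array index 0, with rows and
columns added as needed (typically far beyond 77 × 127). Every spot is
reassigned the array coordinates of its nearest lattice point; exact
ties break to the lexicographically smallest (row, column) for
determinism, and spots from overlapping areas may share coordinates.
The µm→px scale of the pitch is taken from the first area's median
nearest-neighbor distance in stitched pixels, since rigid transforms
preserve distances.

Overlapping spots are detected at 1.5 × that median nearest-neighbor
distance: a spot is overlapping when its nearest cross-area spot lies
within the threshold, and it pairs with that nearest spot (pairing with
*all* spots within the threshold would also capture first-ring lattice
neighbors, which sit below 1.5 × pitch by construction). Overlap pairs
are technical replicates; for each pair of areas, the side whose
overlapping spots have the *lower minimum* UMI count is flagged
`exclude_overlapping`, ties flagging the later-listed area.

## Spot QC and normalization

Low-quality spots are removed by the conjunction `sum_umi < 250` *and*
`edge_distance < 6` (array units to the native array rectangle): depth
and edge proximity must both indicate damage, because biologically
low-RNA regions (e.g. white matter) would otherwise be discarded by a
global depth cutoff. Nucleus-level filters: batch-wise MAD thresholds
(log scale for library size; lower tail only, since low depth is the
failure mode; MAD uses the 1.4826 consistency constant and zero-MAD
batches flag nothing), mitochondrial ratio strictly above 0.05, and
doublet score at or above 5. Normalization is either
`ln(count / libsize × 10⁴ + 1)` (scale-factor, used before NMF) or
`log2(count / sizefactor + 1)` with size factors relative to the mean
library size. Gene filters: nonzero total in every donor, or at least
3 counts in at least 0.5% of spots (both bounds inclusive). Ranked
spatially-variable-gene lists from several donors are aggregated by
first requiring adjusted p < 0.05 in *all* donors, then re-ranking by
mean rank (alphabetical tie-break) and keeping the top 2000.

## Spatial patterns: Moran statistics and grouping

The spatial graph is binary: `W_ij = 1` iff `0 < d(i, j) ≤ threshold`.
No row standardization is applied — statistics are normalized by
`S0 = Σ W_ij` — matching the binary-weight formulation; on a hexagonal
lattice a threshold of 1.5 × pitch gives exactly the six first-ring
neighbors (median degree 6). Global Moran's I is

$$I = \frac{n}{S_0} \frac{\sum_{ij} W_{ij}(x_i-\bar x)(x_j-\bar x)}
      {\sum_i (x_i-\bar x)^2},$$

with permutation inference available (the permutation expectation is
−1/(n−1), checked to within Monte-Carlo error in the tests). Gene
retention uses the local Moran (LISA) statistic
`I_i = (x_i − x̄)/m₂ · Σ_j W_ij (x_j − x̄)`: a gene is kept when at
least 5% of spots are significant at BH-FDR < 0.05. The default
p-values use the analytic moments of the conditional randomization null
(the spot's own value fixed; neighbor values drawn without replacement
from the rest) with a one-sided (greater) normal approximation — both
high-high and low-low cluster spots score positive, so "greater" is the
direction that means "contributes to the pattern". Monte-Carlo
conditional permutation is available (`method = "permutation"`), but
its p-value granularity of 1/(nPerm+1) interacts badly with BH at
hundreds of spots: with 999 permutations the smallest achievable
adjusted p can land exactly on the 0.05 boundary, dropping genuinely
strong genes; the analytic p-values agree closely with large-sample
permutation p-values and avoid the granularity artifact.

Similarity between retained genes is the spatial cross-correlation

$$\mathrm{SCC}(a,b) = \frac{n}{S_0}
  \frac{\sum_{ij} W_{ij}(a_i-\bar a)(b_j-\bar b)}
       {\sqrt{\sum_i (a_i-\bar a)^2 \sum_i (b_i-\bar b)^2}},$$

symmetrized as (M + Mᵀ)/2; the exact normalization is our documented
choice, validated by the identity SCC(a, a) = Moran's I(a). Genes are
grouped by hierarchical clustering on 1 − SCC (Ward or complete
linkage), and each pattern's per-spot score is the mean of the
z-scored expression of its member genes. Interpolation of scores into
spot-free regions is a visualization concern and is omitted.

## Cross-donor consensus patterns

Patterns discovered independently per donor are reconciled by combining
two similarities: the Jaccard index of pattern gene sets (0 on a pair
of empty sets), and the Pearson correlation of domain-averaged score
profiles (the mean pattern score within each shared spatial domain; at
least three shared domains make the correlation meaningful). The
consensus similarity is their plain mean — a [0, 1] and a [−1, 1]
quantity averaged as such, with an optional rescale of the correlation
to [0, 1] — with unit diagonal. Clustering is Ward (ward.D2) on the
dissimilarity 1 − s, with negative similarities floored to zero so the
distance caps at 1 (Ward needs a valid dissimilarity), and the tree is
cut at a configurable k (default 6). Clusters lacking multi-donor
support can be dropped downstream; all clusters are surfaced. Within
each consensus group, a donor contributing exactly one pattern has it
as its representative; donors contributing several get none by default,
or their highest-scoring pattern under the documented override. On five
synthetic donors sharing four planted island programs with 70%
cross-donor gene overlap, the k = 4 cut recovers the planted grouping
with Rand index 1.0.

## Registration and enrichment statistics

Pseudobulk profiles sum counts per (cluster, capture area), dropping
samples built from fewer than 50 spots (optionally samples with fewer
than 2000 detected genes, and groups with fewer than 10 samples). The
one-vs-all statistic for gene g and group c is implemented exactly as

$$t_{g,c} = \frac{\bar X_{g,c} - \bar X_{g,-c}}
  {\sqrt{(\sigma^2_{g,c} + \sigma^2_{g,-c}) / (2 n_c)}}.$$

This is *not* Welch's statistic — the pooled term divides by 2n_c
regardless of the complement's size; a Welch variant is available
behind a flag. The statistic's reference distribution is not dictated
by its downstream use (correlation-based registration), so p-values use
a t distribution with 2n_c − 2 degrees of freedom, BH-adjusted per
group; they matter only for the marker filter (FDR < 0.05, logFC > 0,
top 250 by logFC). Cross-dataset and cross-species registration is the
Pearson correlation of t-vectors over a shared gene universe — the
union of the reference's top markers (default 100 per group) — after
one-to-one ortholog mapping (any symbol participating in more than one
homology pair is dropped with all its pairs). Split-half registration
on synthetic nuclei places every true correspondence on the row-wise
arg-max.

Over-representation of external gene lists in group DEG sets uses a
2 × 2 table over the testable universe with a one-sided Fisher exact
p (enrichment direction) and the *sample* odds ratio ad/bc; lists
shorter than 25 genes after intersection are skipped. Heritability gene
sets take each group's top fraction of relative expression (CPM divided
by the group total; ceiling rule on the count) and emit ±100 kb
intervals around the gene span, strand-agnostically, clipped at zero,
excluding chrX/chrY/chrMT, as 0-based half-open BED.

## Factor models and transfer

NMF minimizes `0.5‖A − WH‖² + λ‖W‖₁` (λ = 0.1 on W only; tolerance
1e-6; maximum 1000 iterations; seeded uniform initialization) by
alternating exact coordinate-descent non-negative least squares, which
reaches the noiseless-reconstruction regime that multiplicative updates
approach only slowly; the objective trace is non-increasing and is
asserted in the tests. After convergence, a diagonal rescale makes each
W column sum to 1, absorbing the scale into H. The rank is chosen by
masked cross-validation: 20% of entries are withheld *from the
objective* (masking, not zero-filling, which would bias toward sparse
reconstructions) in each of three replicates, and the recommended rank
is the smallest within one standard error of the minimum held-out RMSE.

Projection onto spatial data is the literal transpose product
`H' = WᵀA'` over the shared genes (reported as a coverage fraction),
with a non-negative least-squares mode as an alternative, followed by
per-spot sum-to-1 normalization (all-zero spots exempt and flagged).
Factors are excluded when |r| with a binary sex indicator exceeds 0.3
or when nonzero in fewer than 200 spots. Domain summaries report
prevalence (fraction of a domain's spots with nonzero projection) and
the z-scaled (across domains) mean projection; a factor is
domain-associated when prevalence > 0.2 *and* scaled mean > 0.2 in at
least one domain — the scaling axis (across domains, within factor) is
our reading of "scaled average activity". Drug response is tested per
cell type by a two-sided Wilcoxon rank-sum on factor scores with the
rank-biserial effect size `2W/(n₁n₂) − 1` (+1 at complete separation);
a factor is drug-responsive at |effect| > 0.3 and BH-FDR < 0.05 in at
least one cell type.

## Ligand–receptor co-occurrence

Candidate pairs are prioritized by trait evidence ("no data" treated as
0; a gene is a risk gene when its maximum evidence score strictly
exceeds 0.1), exclusion of HLA-prefixed symbols, and an aggregate-rank
cutoff of 0.01. Spots are classified four ways by strict positivity of
the log-normalized ligand and receptor values. With W the spots ×
cell-types deconvolution weight matrix (rows renormalized to sum to 1
unless disabled) and S the co-expressing spot set,
`C_LR = W_Sᵀ W_S` and `C_ctrl` its complement analogue; the diagonal
and the *strict* upper triangle are zeroed, the lower triangle is
normalized to sum to 1, and the enrichment ratio is
`R = C_LR / (C_ctrl + 1e-6)` with the stabilizer on the control side
only, exactly as specified. QC-excluded spots enter neither set. Under
random spot classifications R concentrates at 1 (|R − 1| ≤ 0.1 at 1000
spots); a planted co-dominant cell-type pair attains the matrix maximum
above 1.

## Model-selection metrics

`BIC = −2·logLik + df·ln(n)` with natural log. The degrees-of-freedom
accounting of an external clustering model is generally not
recoverable, so `bic()` takes df as an argument and `modelDf()`
provides a documented default (`pq` loadings + `kq` means + covariance
terms by structure + an embedding-rank term). The Rand index is the
plain (unadjusted) fraction of agreeing pairs, and overlap concordance
is the fraction of overlapping (technical-replicate) spot pairs sharing
a cluster label.

## Synthetic data: what it emulates and what it does not

The generators are pure functions of (config, seed) and plant every
quantity the pipeline estimates: true rigid transforms and overlap
pairs, domain labels (lateral gradients with linear marker-mean
interpolation, compact island domains, or uniform), disjoint marker
sets at a configurable fold change (default 8), negative-binomial
counts parameterized by mean and dispersion θ (variance µ + µ²/θ;
defaults µ = 2, θ = 5), cell-type-labelled nuclei with optional planted
drug and sex programs, and Dirichlet deconvolution weights centered on
domain mixtures. Defaults — two 20 × 20 areas at 100 µm pitch with 20%
overlap, 200 genes, 3 domains — keep the full test-suite and the
end-to-end pipeline run in seconds on one CPU; these problem sizes are
stated here as the package's validation conditions.

Passing tests on these data establish algorithmic correctness
(formulas against brute-force oracles, planted-parameter recovery,
calibration of permutation nulls), not robustness to everything real
tissue does: the simulations have no segmentation errors, no spatial
bleed between spots, no gene-length or GC structure, no batch effects
beyond library size, and marker programs far cleaner than real
transcriptomes. Two practical lessons from the synthetic studies are
worth recording: per-spot LISA significance is conservative when a
pattern occupies a large fraction of the section (the global variance
inflates the conditional null), so compact programs are recovered more
completely than broad bands; and with small synthetic gene panels,
library-size normalization can cancel a planted fold change unless a
flat housekeeping block keeps libraries comparable — with realistic
panel sizes the planted programs are a small library share and the
effect vanishes.

## Numerical choices and degenerate inputs

Exact grid-assignment ties break to the smallest (row, column); equal
minimum-UMI overlaps flag the later-listed area; zero-variance genes
yield an error for global Moran's I, zero rows/columns (with warning)
in SCC, and r = 0 in correlation rankings; zero-length landmark
segments are skipped with a warning, all-degenerate input is an error;
zero library sizes drop the observation with a warning; empty
co-expressing spot sets flag the co-occurrence result undefined rather
than dividing by zero; all thresholds compare strictly or inclusively
exactly as documented in each function.
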