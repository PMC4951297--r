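---
title: "Models and methods behind lncsom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lncsom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lncsom` analyses cell-to-cell heterogeneity of long noncoding RNA (lncRNA)
expression in single-cell RNA-seq data quantified as TPM. This vignette
explains each model and procedure, the parameters that matter, the numerical
conventions chosen where the field leaves room, and what the bundled
synthetic-data generator does and does not emulate.

## Preprocessing

All analyses start from `log2(TPM + 1)`; the pseudocount of one makes zero
TPM map to exactly zero. Gene selection is a two-tier abundance filter: a
gene is kept when its mean `log2(TPM+1)` exceeds 2 across all single cells,
*or* exceeds 4 within at least one tumor/line of origin. The second branch
rescues genes expressed strongly but only in one tumor. Both comparisons are
strict (`>`), so a gene sitting exactly on a threshold is excluded. Cells
are then retained when they express — TPM strictly positive — at least half
of the selected genes; this bound is inclusive. Finally each gene is
z-scored: centred at its mean and divided by its standard deviation over the
included samples, yielding the "relative expression" scale used by the map,
the scores and the heatmap-style outputs.

Three conventions are deliberate choices:

* **Standard deviation.** The sample sd (n − 1 denominator) is used; with
  hundreds of cells the difference from the population sd is negligible,
  but the convention is fixed so results are bit-reproducible.
* **Constant genes.** A gene with zero variance has no defined z-score and
  carries no cell-to-cell information; it is dropped, and the dropped ids
  are recorded in the `dropped` attribute of the result.
* **Which samples define the statistics.** By default the retained single
  cells and any population samples (controls, GSC/DGC cultures) are z-scored
  jointly, so that population columns and single-cell columns share one
  relative-expression scale; `include_population = FALSE` restricts the
  statistics to single cells.

## Descriptive structure

`percent_expressed` reports, per cell, the fraction of a gene panel with
positive TPM. `pairwise_correlations` computes Pearson correlation over the
`log2(TPM+1)` gene vector for every unordered cell pair and flags pairs as
within- or between-group; a constant cell vector yields undefined
correlations, reported as `NA`. PCA (`run_pca`) is centred and unscaled,
computed with `prcomp` on a top-variance gene panel (default 500 genes, ties
broken by input order). "Most abundant" in `top_abundant_union` means the
highest `log2(TPM+1)` within that control sample; the per-control top-k
panels (default k = 50) are unioned in feature input order. Hierarchical
clustering defaults to average linkage on correlation distance (1 − r), both
configurable, and dendrograms export to Newick via `ape`.

## The self-organizing map

Gene vectors (z-scores across cells) are mapped onto a **toroidal hexagonal
lattice**. The number of units follows the heuristic `M = round(5 * sqrt(N))`
for `N` training genes, split into a near-square grid
(`xdim = round(sqrt(M))`, `ydim = round(M / xdim)`). Units sit at planar
coordinates `x = col + 0.5 * (row %% 2)`, `y = row * sqrt(3) / 2`; lattice
distances are the minimum planar distance over the nine torus images, which
is exact for even row counts and a very close approximation at the wrap seam
when `ydim` is odd (an intrinsic property of offset-row hexagonal tori; the
near-square heuristic frequently produces odd dimensions, so the seam
approximation is accepted rather than forcing even grids).

**Initialization** places codebooks in the affine span of the data mean and
the top 10 principal components: lattice columns sweep PC1 over ±2 sd of the
component scores, rows sweep PC2, and coordinates on components 3–10 are
drawn from a seeded normal with one tenth of each component's sd — enough to
break ties without disturbing the PC1/PC2 sheet.

**Training** is sequential (online): for each presented vector the
best-matching unit (BMU) is the codebook with the smallest Euclidean
distance (ties broken by lowest unit index), and every unit within the
current radius on the toroidal lattice moves by `w <- w + alpha * (x - w)`.
This is a *bubble* neighborhood — full learning rate inside the radius,
nothing outside — with a Gaussian alternative available. The learning rate
declines linearly from 0.05 to 0.01 and the radius from `d` to 2 over the
total number of updates (epochs × vectors), where `d` is the 2/3 quantile of
all pairwise unit-to-unit toroidal distances; both schedules are interpolated
per presentation, and the presentation order is reshuffled every epoch from
the seeded generator, making training fully deterministic given a seed. The
default of 200 epochs matches the intended operating scale of a few hundred
training genes. Note that the radius floor of 2 keeps the map smooth by
design; on very small grids (where radius 2 spans half the lattice) the
final quantization error can exceed the initial one even though the map is
topologically well organized — grids below roughly 6×6 are outside the
intended regime.

After training, *all* genes (not only the training panel) are mapped to
their BMUs. The **u-matrix** assigns each unit the mean Euclidean distance
from its codebook to its six lattice neighbors; valleys mark coherent gene
sets. **Clusters** are seeded at u-matrix local minima: units strictly below
all six neighbors, with a connected plateau of equal values that jointly
undercuts its surroundings contributing a single seed (its lowest-index
unit). Every other unit joins the seed with the nearest codebook, ties again
to the lowest seed index. The number of clusters is therefore emergent, not
fixed. A constant u-matrix yields a single cluster with a warning.
**Per-cell component portraits** assign each unit the mean z-score, in that
cell, of its mapped genes. Cluster gene lists are tested for
over-representation in user-supplied GMT gene sets with a one-sided
hypergeometric tail and Benjamini–Hochberg adjustment across sets.

## Splice-variant heterogeneity

Within a (gene, cell) where the gene has positive TPM, each transcript's
relative abundance is its TPM divided by the gene's summed transcript TPM;
variants with zero TPM are filtered out, and undetected (gene, cell) pairs
produce no records. Genes enter the analysis when their *annotated*
transcript count reaches the threshold (default 10, inclusive); using
annotation rather than detected counts keeps the gene universe independent
of sequencing depth. A variant **dominates** a (gene, cell) when its
relative abundance strictly exceeds 0.5 — the smallest threshold that
guarantees uniqueness, which is why the implementation rejects thresholds
below it. Detection frequency (cells per variant), variants per cell, and
pairwise variant association are computed from the same table. Association
uses the **phi coefficient of detection indicators** across cells expressing
the gene — positive for preferential co-expression, negative for mutual
exclusivity — because presence/absence patterns, not abundance correlation,
are the phenomenon of interest; pairs with a constant indicator are `NA`,
and genes expressed in fewer than three cells yield only `NA` with a warning.

## Stemness signature and score

The signature is derived from matched stem-like (GSC) and differentiated
(DGC) population cultures. For each gene, the per-pair difference
(GSC − DGC, `log2(TPM+1)`) is tested with **one paired t-test across the
tumor-derived pairs**; a per-pair test is impossible with one observation
per pair, so the set of pair differences forms the sample (an alternative
reading requiring a positive difference in every pair is available as
`method = "consistent_up"`). The signature keeps genes with p < 0.05 and a
positive mean difference. A gene with identical differences in all pairs has
an undefined t statistic; when that constant difference is positive the gene
is included with p recorded as 0 and flagged — a perfectly consistent effect
should not be discarded for being too consistent. No multiplicity correction
is applied to the selection (the raw threshold is the procedure), but BH
q-values are reported alongside.

The **stemness score** of a cell is the mean z-score of the signature genes
minus the mean z-score of the whole analysis universe; subtracting the
universe mean removes any per-cell shift. Significance of the per-tumor
stemness *gradient* compares the SD of per-cell scores against 100
size-matched random gene sets sampled without replacement from the universe,
with the empirical p-value `(1 + k) / (1 + n)` so that no p is exactly zero.

## Subtype scores, cutoffs and hybrid cells

Each of the four subtype classifier sets (proneural, neural, classical,
mesenchymal) is scored exactly like the stemness signature. The decision
threshold is empirical: for each subtype, 100 random sets of the same size
are scored in every cell, and the cutoff is the 99th percentile of the
**pooled** null scores (100 × cells values; a per-cell pool is available by
flag but with 100 draws per cell it is far noisier). A cell passes a subtype
when its score strictly exceeds the cutoff; cells may pass several subtypes
(hybrid states) or none (unclassified). Consistency between two
classifications counts cells whose *top-scoring passing* labels match, with
two unclassified calls also counting as agreement.

## The synthetic cohort generator

The generator produces TPM matrices with the statistical structure the
pipeline assumes, so every stage is testable without any download. Per gene
and cell the underlying log2 mean is

```
mu = baseline + group_shift + module_shift * activity +
     stemness_effect * latent   (signature genes) +
     subtype effect             (classifier genes of the cell's label)
```

with `TPM = max(2^(mu + noise) - 1, 0)` and Bernoulli detection with
probability `plogis(steepness * (mu - midpoint))`, so weak genes drop out
more often — a logistic dropout on the underlying mean, chosen over a
negative-binomial count model because the downstream analyses operate
entirely in TPM space. Latent stemness is uniform on [0, 1]; each cell gets
one primary subtype and, with probability `hybrid_frac` (default 0.2), a
secondary subtype at half effect, planting testable hybrid states.
Coexpression modules share a per-cell standard-normal activity scaled by
`module_shift`. Splice variants split gene TPM by a symmetric Dirichlet draw
per (gene, cell); proportions under `proportion_floor` (default 0.01) are
zeroed and the rest renormalized, so transcript TPMs always sum to the gene
TPM while "variants without expression" exist. Small concentrations
(e.g. 0.05) produce single-variant dominance, large ones near-uniform usage.

Defaults describe a desk-scale study: 5 tumors × 40 cells, 2,000 lncRNAs,
baseline `log2` mean 4 (sd 1.5), observation noise sd 1, dropout midpoint 1
and steepness 1 (≈95% detection at the baseline mean, ≈50% at mean 1),
group shift sd 0.5, 4 modules of 50 genes at shift 1, a 30-gene stemness
signature at effect 2, and four 30-gene classifier sets at effect 2. These
sizes keep every property check within seconds to a few minutes while
leaving all planted effects comfortably detectable; they were fixed once as
realistic for this kind of data and are not tuned per test. All randomness
flows from one seed through fixed per-component sub-streams, so changing,
say, the Dirichlet concentration does not perturb the expression draw.

What the generator does **not** emulate: empirical dropout/abundance
distributions of any real dataset (no public single-cell study characterizes
them for lncRNAs at TPM level), batch or plate effects, doublets,
cell-cycle structure, read-level artifacts, or correlated gene-gene
structure beyond the planted modules. Passing tests therefore demonstrate
that the procedures recover the structure they were designed to detect under
their own model assumptions — not that real tumors satisfy those
assumptions.

## Numerical conventions and degenerate inputs

* Strict inequalities at both gene-filter thresholds and the dominance and
  cutoff comparisons; the cell-retention bound is inclusive.
* "Expressed"/"detected" always means TPM strictly greater than zero.
* All tie-breaks (BMU search, seed assignment, top-variance and top-abundant
  panels) go to the lowest index / input order, making every output
  deterministic.
* Negative input values, NaNs in training vectors, transcripts mapped to two
  genes, single-sample z-scoring and sub-minimal GSC/DGC pair counts are
  rejected with errors naming the offence; empty filter results and
  constant-vector correlations degrade with warnings or `NA`, not errors.
* Empirical p-values use `(1 + k) / (1 + n)`, so 100 random sets bound p
  below at 1/101 ≈ 0.0099.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → preprocess → structure → SOM → splicing →
signatures from a single YAML config with one global seed, writes each
stage's tables under `outdir/<stage>/`, and records a JSON manifest with the
package version, parameters, per-stage status and MD5 checksums of every
output. Any stage failure halts the run and the manifest records which
stages completed. Because every stochastic step derives from the config
seed and all outputs are plain text written deterministically, two runs of
the same config produce byte-identical outputs — the property the test
suite checks on the bundled demo config.

## Known limitations

* The u-matrix seam approximation on odd-row toroidal grids (above).
* The paired t-test has few degrees of freedom when only 2–3 culture pairs
  exist; the degenerate sd = 0 inclusion rule is then load-bearing and
  flagged in the output.
* Signature scoring assumes the z-score universe is the analysis gene set;
  scores from different gene universes are not comparable.
* The classifier sets must be supplied (or planted by the simulator); the
  package does not reconstruct published subtype gene lists.
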