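---
title: "Statistics for matched tumor/normal single-cell cohorts: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistics for matched tumor/normal single-cell cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sccompare)
```

`sccompare` implements the comparison statistics used to contrast matched
tumor and adjacent-normal single-cell cohorts. This vignette is the package's
account of the underlying models: what each statistic assumes, which
parameters matter, how the synthetic-data generator is built, and where the
design was genuinely open.

## Data model and quality control

A cohort is a sparse gene × cell count matrix with per-cell metadata: sample
id, condition (exactly two labels, `tumor` and `normal`), cell-type label,
optional 2-D embedding coordinates and optional doublet score in [0, 1]. The
embedding and the doublet scores are *inputs*: graph integration, UMAP and
doublet detection are upstream tools, not reimplemented here.

QC retains cells with total UMI ≥ `min_umi` (default 700; "fewer than 700"
are excluded, so the boundary cell is kept) and doublet score ≤ `max_doublet`
(default 0.4; "above 0.4" removed, boundary kept). Counts removed per
criterion are logged per sample, mirroring the accounting a QC report needs.

Normalization divides each cell by its total UMI, multiplies by a common
scale (default 10⁴) and applies `log(x + pseudocount) − log(pseudocount)`
(natural log, pseudocount 1, i.e. `log1p` of counts-per-10k). The upstream
description of the scoring step pins down only "normalized for cell size";
scale and log base are therefore configurable, and every downstream statistic
here is mean- or rank-based, so the choice moves scores monotonically without
changing any test decision. All-zero cells map to all-zero columns.

## Signature scores

The score of cell *c* for gene set *G* is the arithmetic mean of its
normalized expression over the genes of *G* present in the matrix; the score
of sample *k* is the mean over its (optionally cell-type-restricted) cells.
Genes absent from the matrix are dropped rather than imputed as zero —
present-gene averaging is robust to annotation mismatches, and the
alternative (zero imputation) would make scores depend on how many aliases a
curator happened to include. The policy is configurable by editing the gene
set itself.

Two-group comparisons use the two-sided Wilcoxon rank-sum test with an
explicit policy: the exact distribution for pooled n ≤ 20 without ties,
otherwise the normal approximation with tie-corrected variance and continuity
correction. At n = 8 the exact path reproduces full enumeration to machine
precision; the continuity-corrected approximation stays within half a
discrete probability step (~0.03) of the exact answer on balanced splits,
which is the attainable accuracy for a continuous approximation to a
distribution whose atoms weigh 2/70.

## Differential cell density

Each sample's cells are smoothed on a shared `gridsize × gridsize` grid
(default 400 per axis — the natural reading of a "bin = 400" kernel-density
setting; tests and examples run at 30–100 for speed, a pure resolution
choice) covering the pooled embedding bounding box plus a 10 % margin.
Bandwidths follow the normal-reference (Scott-type) rule per sample and axis;
the upstream description names only the kernel-density tool, not a bandwidth
rule, and the plug-in family is its default behavior. Each grid is
renormalized so density × bin area sums to 1, removing edge-truncation loss.

Grids are quantile-normalized across samples (ties map to the mean of the
tied reference quantiles), which removes per-sample smoothness differences
while preserving within-sample ranks. Per bin, a Welch (unequal-variance)
two-sample t statistic across samples — "t-test" alone does not fix the
variance assumption, and Welch is the safer default with 2 × 5–13 samples —
is converted to a signed Z via its p-value (positive = denser in tumor).
Bins with fewer than `min_cells_per_bin` (default 1) cells across the cohort
are masked to avoid calling differences in empty space. On exchangeable
cohorts the fraction of masked-in bins with |Z| > 1.96 stays at the nominal
~5 % (measured 3–4 % over 100 cohorts in `calibrate_null()`).

## Compositional analysis

Per-sample cell-type fractions live on the simplex, so Euclidean statistics
on raw fractions confound every type with every other. Fractions (zeros
replaced multiplicatively by 0.5 / sample-cell-count before closure, the
standard replacement that keeps log-ratios finite) are mapped to isometric
log-ratio coordinates through a fixed orthonormal Helmert-type contrast
basis. A two-group canonical discriminant axis is fitted (for two groups this
is Fisher's LDA direction, computed with `MASS::lda`; a ridge-regularized
Fisher direction stands in on degenerate bootstrap draws), and its loadings
are mapped back through the basis into centered-log-ratio space. The
resulting per-type *separating coefficients* are basis-invariant (an ILR
basis change is an orthogonal rotation, and the back-mapped loadings are
unchanged — the unit tests verify invariance under cell-type permutation),
sum to zero, are scaled to unit norm, and are oriented so the tumor group
scores positive.

Robustness is assessed by resampling both levels of the hierarchy: each of
`n_boot` (default 1000) rounds resamples samples with replacement within each
condition, then draws `cells_per_boot` (default 1000) cells per condition
from the pooled resampled cells without replacement, and refits the axis. The
upstream wording ("resampling of samples and cells") leaves the exact scheme
open; this one preserves the sample hierarchy while equalizing the cell
budget between conditions. The reported `positive_fraction` per type is the
sign-stability of its coefficient across rounds.

## Expression distance

Pseudobulk ("mini-bulk") profiles sum all molecules of a (sample, cell-type)
group; profiles with fewer than `min_cells` = 10 cells are excluded. The
distance between two profiles is 1 − Pearson correlation of
`log1p(counts-per-million)` over genes expressed in at least one of the two
profiles (the pairwise gene filter avoids zero-variance degeneracies; CPM is
one concrete reading of "log-transformed values" and any common depth factor
cancels in the correlation).

Because profile noise depends on how many cells were summed, each cell type's
distance matrix is averaged over `n_rounds` (default 100) subsampling rounds
in which every contributing sample is subsampled without replacement to the
*minimum* cell count among them — a fixed target shared by all profiles of
the round, chosen over per-pair minima so that one distance matrix is
internally consistent. The **normalized distance** is
median(between-condition pairs) / median(within-condition pairs); it is ≈ 1
when condition labels carry no information (measured 0.8–1.25 on null
cohorts at 5 + 5 samples) and grows with condition-specific divergence.

Significance comes from permuting *sample* condition labels. A permutation
only re-partitions the already-averaged pairwise distances into between and
within sets, so the null statistics are recomputed from the stored matrix
rather than by re-subsampling — identical by construction, and ~100× cheaper.
Monte-Carlo p-values use the add-one estimator
p = (1 + #{perm ≥ obs}) / (1 + n_perm), which cannot return 0; with fewer
than 20 distinct label splits the full enumeration replaces Monte-Carlo.

The overall distance between two samples is the weighted mean of their
per-type pseudobulk distances over cell types passing the profile minimum in
both, with weight min(proportion in sample 1, proportion in sample 2) — a
type absent from either sample contributes nothing. Sample pairs sharing no
type receive the matrix maximum (logged) so that classical (Torgerson) MDS
stays defined.

## Markers, pseudobulk DE and signature selection

Marker calling is a one-vs-rest two-sided rank-sum test per gene per cluster,
reported as a signed Z (the normal quantile of p/2, signed by the mean
difference; continuity- and tie-corrected). Genes with Z > 3 are markers; on
exchangeable data ≤ 1 % of genes reach that bar (two-sided normal tail at 3
is 0.27 %).

Pseudobulk differential expression between conditions is a per-gene
negative-binomial GLM on the (sample, cell-type) sums with a condition factor
and a log-total offset, Wald p-values and BH adjustment. This is a deliberate
simplification of shrinkage-based DE machinery: downstream consumers here are
rank- and sign-based (top-N lists, log2FC > 0 filters), which shrinkage does
not reorder. A unit test confirms per-gene log2 fold changes correlate > 0.95
with an independent DESeq2 fit on the same profiles. One caveat is inherent
to total-count offsets: planting 10 % of the transcriptome at 2× shifts the
unplanted baseline by −log2(1.1) ≈ −0.14; the tests assert this arithmetic
rather than hiding it.

The metastatic-signature procedure runs two marker rounds: (1) the target
tumor subclone (C4) against the other subclones, tumor cells only; (2) the
target's cells against all non-tumor populations. Each round keeps the top
`top_n` (default 100) positive-Z genes ("highly expressed in C4" is
operationalized as positive one-vs-rest Z, the default of the two readings
the wording admits); the final signature is the intersection ordered by
round-1 rank, with ties broken by |log2FC| then symbol. An empty intersection
is a valid, warned outcome. The upstream study further curated its
four-gene signature against external bone-metastasis data; that manual step
is out of scope, and the full intersection is exposed for such review.

## Ligand-receptor inference

Candidate triples (pair, sender type, receiver type) must have the ligand
detected in strictly more than `min_frac` = 10 % of sender cells and the
receptor likewise in receiver cells. The score is the product of mean
normalized ligand expression over sender cells and mean receptor expression
over receiver cells. The null shuffles cell-type labels globally (composition
preserved, matching "shuffling cell identities in the aggregated data"
rather than within-sample shuffles) `n_perm` = 1000 times; each triple is
compared with its own permutation distribution (the literal reading of the
procedure), add-one estimator, BH across all triples. Two filters follow:
specificity (marker Z ≥ 3 for the ligand in the sender and the receptor in
the receiver, other types as background) and tumor upregulation (pseudobulk
log2FC > 0). The upstream phrase "both ligand or receptor are upregulated"
is grammatically ambiguous; `mode = "both"` (the stricter reading) is the
default, `"either"` is available. Multi-subunit complexes are not modeled:
the pair table is gene-to-gene.

## Survival stratification and reproducibility power

Per-sample scores are the mean log-scale expression of the signature genes in
a bulk cohort. The top ⌊0.25 n⌋ and bottom ⌊0.25 n⌋ samples form the high and
low groups (floor-sized tails with stable-order tie-breaking, so group sizes
are exact; the middle 50 % is excluded), compared with the standard two-sided
log-rank test. To separate "this gene list works" from "this exact gene list
works", the signature's genes are resampled *with replacement at the original
size* (the standard bootstrap; the upstream wording fixes only "resample the
signature genes") for 100 rounds, and the 0.95 quantile of the bootstrap
log-rank p-values is reported as the reproducibility-power p-value. By
construction it is ≥ the median bootstrap p and monotone in the quantile, so
it is conservative relative to the unresampled test: on null cohorts
(hazard log-HR 0, n = 300) it falls below 0.05 in 0 of 100 runs, while at
log-HR 0.7 per score SD with a 10-gene signature it does so in 50 of 50 runs
(`survival_power_study()`).

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the pipeline assumes:

- **Counts**: NB(μ, θ) with variance μ + μ²/θ (mean/dispersion
  parameterization, default θ = 2 per cell — overdispersed droplet-scale
  noise; chosen because pseudobulk sums of NB cells stay NB-like and all
  planted effects enter multiplicatively on μ).
- **Depth**: lognormal-mean gene baselines scaled so a depth-1 cell expects
  `target_umi` = 2000 total UMI — a typical droplet depth, and the reason the
  700-UMI QC filter behaves realistically at any simulated gene count — times
  a per-cell uniform multiplier on [0.7, 1.4].
- **Composition**: per-sample cell-type fractions are Dirichlet with
  concentration 50 around condition-specific targets (tumor targets are the
  baseline times the planted multiplicative shifts, re-closed). Concentration
  50 gives inter-sample compositional noise at which a doubled type is
  recoverable, but not trivially, at 10 samples per condition.
- **Identity**: each type carries a marker block (default 10 genes at fold 8)
  so marker calling, LR specificity and signature selection have ground
  truth; DE effects multiply μ in one (cell type, tumor) stratum;
  ligand-receptor plants co-elevate a ligand in the sender type and a
  receptor in the receiver type.
- **Embedding**: per-type Gaussian blobs on a circle of radius 4 (spread
  0.6) — enough geometry for density statistics, with no pretense of UMAP
  structure.
- **Doublets**: scores are a Beta(2, 30) baseline with a planted
  Beta(8, 2) fraction (default 5 %).
- **Determinism**: one global seed; every stage derives its stream via
  `child_seed(seed, tag)`, so identical configs are byte-identical.

What the generator does *not* emulate: ambient RNA, batch effects, realistic
manifold geometry, gene-gene correlation beyond the planted blocks, or
zero-inflation beyond NB sampling. Passing tests therefore demonstrate that
the statistics recover the effects they target under clean multi-sample NB
conditions with realistic compositional noise — not that they are robust to
every artifact of real tissue data.

`simulate_bulk_survival()` draws log-scale Gaussian expression, exponential
event times with log-hazard linear in the standardized signature score, and
independent exponential censoring tuned to the requested censoring fraction.

## Validation studies and problem sizes

`calibrate_null()`, `recover_planted()`, `signature_selection_study()` and
`survival_power_study()` are first-class exported studies; the acceptance
script reruns them from scratch. Study conditions: null calibration uses 200
cohorts of 5 + 5 samples × ~80 cells × 60 genes (densities on the first 100
cohorts at grid 40); planted recovery uses 10 + 10 samples for composition
(type at 20 % doubled), 5 + 5 × 200 genes for expression distance (30 genes
at log2FC 2 in one of two types), and 4 + 4 × 120 genes for LR (fold 4);
survival uses n = 300 cohorts. These sizes make every study rerunnable on a
laptop in minutes while leaving the planted effects comfortably inside each
test's power curve.

## Known limitations

- The per-bin density t-test treats bins independently; spatially correlated
  Z values are expected, and the maps are descriptive rather than
  FWER-controlled.
- The NB-GLM DE contract omits dispersion shrinkage and outlier handling;
  very low-replicate designs (2 + 2) inherit the instability of per-gene
  dispersion estimates.
- CoDA coefficients describe one linear discriminant axis; strongly nonlinear
  compositional responses are summarized, not captured.
- The permutation LR test conditions on the observed composition; it does not
  model sample-level pseudo-replication (cells within a sample are not
  independent), which is why the sample-level filters (specificity, DE) are
  applied downstream.
- The quartile survival stratification discards the middle 50 % by design;
  ties at the boundary are resolved by stable order and logged rather than
  randomized.
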