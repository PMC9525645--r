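# sccompare

Comparison statistics for matched tumor / adjacent-normal single-cell RNA-seq
cohorts, with a ground-truth synthetic-data generator.

## What problem this addresses

Matched tumor/normal single-cell studies (e.g. of clear cell renal cell
carcinoma and adjacent kidney) ask a recurring set of questions: *where* on a
shared embedding does cell abundance change, *which* cell types shift in
proportion, *how far* does each cell type's expression program move between
conditions, *which* ligand-receptor channels open up in the tumor
microenvironment, and *does* a tumor-derived gene signature stratify survival
in bulk cohorts. Each question needs a statistic that respects the sample (not
the cell) as the unit of replication. `sccompare` implements that toolkit for
analysts working with 10x-style count matrices and per-cell annotations:

- **QC and normalization** — total-UMI (default ≥ 700) and doublet-score
  (default ≤ 0.4) filters; per-cell depth normalization
  `log(1 + 10^4 · x / total)`.
- **Signature scoring** — per-cell score `s_c = mean_{g∈G} x̃_{gc}` over a
  gene set `G`, per-sample score `s̄_k = mean_{c∈k} s_c`, compared between
  conditions with a two-sided Wilcoxon rank-sum test (exact for pooled
  n ≤ 20 without ties).
- **Differential cell density** — per-sample Gaussian kernel density on a
  shared embedding grid (default 400 × 400), quantile-normalized across
  samples, then a per-bin Welch t statistic converted to a signed Z
  (positive = denser in tumor), masked to bins containing ≥ 1 cell.
- **Compositional analysis (CoDA)** — cell-type fractions → isometric
  log-ratio coordinates (Helmert basis) → two-group canonical discriminant
  axis → loadings mapped back to centered-log-ratio space, one *separating
  coefficient* per cell type (positive = enriched in tumor), with a
  sample-and-cell bootstrap (default 1000 rounds × 1000 cells per group).
- **Expression distance** — per-(sample, cell-type) pseudobulk ("mini-bulk",
  ≥ 10 cells), pairwise distance `d = 1 − cor(log1p CPM)`, cell-count-matched
  subsampling (100 rounds), and the **normalized distance**
  `median(between-condition pairs) / median(within-condition pairs)` with a
  sample-label permutation p-value; a proportion-weighted overall sample
  distance is projected to 2-D by classical MDS.
- **Markers and signature selection** — one-vs-rest Wilcoxon Z per gene
  (marker if Z > 3); pseudobulk tumor-vs-normal DE via an NB GLM with
  log-total offset; multi-round selection of a tumor-subclone (C4) signature:
  top-100 by Z against the other subclones, intersected with top-100 against
  all non-tumor populations.
- **Ligand-receptor inference** — candidate (ligand, sender, receptor,
  receiver) triples screened at > 10 % detection, scored as
  `mean(ligand | sender) × mean(receptor | receiver)`, tested against 1000
  global shuffles of cell identities (BH-adjusted), then filtered for
  specificity (marker Z ≥ 3) and tumor upregulation (log2FC > 0).
- **Survival stratification** — mean signature expression in bulk cohorts,
  top/bottom-25 % groups, two-sided log-rank test, and the **reproducibility
  power** p-value: the 0.95 quantile of log-rank p over 100 bootstrap
  resamples of the signature's genes.
- **Synthetic cohorts** — `simulate_cohort()` plants compositional shifts,
  cell-type/condition-specific DE, ligand-receptor co-elevation, Gaussian-blob
  embeddings and doublet scores in NB counts; `simulate_bulk_survival()`
  generates bulk cohorts whose hazard is log-linear in a signature score.
  Every statistic above is validated against these ground truths.

## Worked example

```r
library(sccompare)

cfg <- simulation_config(
  n_samples_per_condition = 5, cells_per_sample = 150, n_genes = 200,
  cell_types = c(Tcell = 0.4, Myeloid = 0.35, Stroma = 0.25),
  composition_effects = c(Myeloid = 2),                      # doubled in tumor
  de_effects = list(list(cell_type = "Tcell", genes = 101:130, log2fc = 2)),
  seed = 42)
sim <- simulate_cohort(cfg)
cm  <- filter_cells(sim$cm)          # UMI >= 700, doublet score <= 0.4
nm  <- normalize_cells(cm)

proportion_tests(cm)
#>   cell_type mean_tumor mean_normal statistic      p method  p_adj
#> 1   Myeloid      0.490       0.336        23 0.0317  exact 0.0833
#> 2    Stroma      0.183       0.212         6 0.2222  exact 0.2222
#> 3     Tcell      0.327       0.453         3 0.0556  exact 0.0833

dr <- celltype_distance(cm, n_rounds = 10, seed = 1)
distance_permutation_test(dr, n_perm = 1000, seed = 1)
#>   cell_type normalized_distance       p      method
#> 1   Myeloid               1.042 0.05295 monte-carlo
#> 2    Stroma               0.999 0.56244 monte-carlo
#> 3     Tcell               5.382 0.00599 monte-carlo

fr   <- cell_type_fractions(cm)
coda <- coda_coefficients(fr$counts, fr$condition,
                          n_boot = 1000, cells_per_boot = 1000, seed = 1)
round(coda$coefficients, 3)   # positive = enriched in tumor
#> Myeloid  Stroma   Tcell
#>   0.811  -0.322  -0.489
coda$positive_fraction
#> Myeloid  Stroma   Tcell
#>   1.000   0.070   0.299
```

The doubled myeloid compartment shows up as the one positive separating
coefficient (positive in 100 % of bootstrap draws) and the largest raw
fraction shift; the T-cell DE plant gives T cells a normalized expression
distance of 5.4 (permutation p ≈ 0.006) while unaffected types sit near the
null value of 1.

Survival stratification on a synthetic bulk cohort:

```r
sig <- gene_set("risk", sprintf("B%03d", 1:10))
coh <- simulate_bulk_survival(300, sprintf("B%03d", 1:50), sig,
                              hazard_log_hr = 0.7, censor_rate = 0.3, seed = 42)
st  <- reproducibility_power(coh, sig, n_boot = 100, seed = 42)
#> log-rank p = 7.88e-18, reproducibility power p (0.95 quantile) = 4.39e-08
```

A full config-driven run over all stages (`run_pipeline()`), including TSV
outputs and a JSON manifest, is shown in `?run_pipeline` and the vignette;
`inst/scripts/run_pipeline.R` wraps it for shell use.

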