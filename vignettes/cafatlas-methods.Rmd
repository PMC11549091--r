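---
title: "Methods: CAF subtype analysis from Smart-seq2 and in situ data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CAF subtype analysis from Smart-seq2 and in situ data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`cafatlas` re-implements, as a reusable and tested pipeline, the
computational core of a single-cell plus in situ study of cancer-associated
fibroblast (CAF) subtypes — immunomodulatory iCAFs, matrix mCAFs and
RGS5+ perivascular-like cells — in basal and squamous cell carcinoma and
melanoma. The upstream steps it deliberately does not cover are read
alignment and RPKM quantification, variable-gene/PCA/UMAP clustering
(cluster labels are *inputs*), trajectory inference, and all image
segmentation: the spatial stage consumes per-cell marker-positivity tables
and ROI areas, not images.

Because the patient-level data behind the original atlas are access
restricted, the package ships a synthetic-data generator whose planted
ground truth exercises every stage. All quantitative claims in this
vignette are computed by the test suite or the acceptance script; none are
imported from elsewhere.

# Quality control and normalization

Cells are kept when they express at least 400 genes (value strictly
positive) and their total expression lies between 150,000 and 8,000,000
RPKM, bounds inclusive. The thresholds follow plate-based Smart-seq2
practice where empty wells anchor the lower bound; "between" is read
inclusively so boundary cells are kept (permissive QC). A cell violating
several rules is reported under the first failing rule in the order
`low_genes`, `low_total`, `high_total` — the report covers every input
cell, so violation counts are auditable.

Normalization is the standard log-normal transform
`x = ln(1 + v / total * 1e4)`. Two exact invariants are tested: zeros map
to zeros, and after the transform every cell satisfies
`sum(exp(x) - 1) = 1e4` to 1e-9 relative tolerance.

# CNV-based malignancy calling

The caller is an inferCNV-style estimate on log-normalized data:

1. drop genes detected in fewer than `min_cells_per_gene = 3` cells;
2. order genes by (chromosome, start), ties broken by gene id;
3. subtract the healthy-stromal reference mean per gene and clip residuals
   to ±1 (the "cutoff = 1" convention, on natural-log scale);
4. smooth with a centered 101-gene moving average that never crosses a
   chromosome boundary (101 is the upstream tool's documented default; the
   window shrinks with a warning on smaller chromosome blocks);
5. subtract the reference-cell mean per position and recenter each cell at
   its median (this absorbs the library-size shift that large gains/losses
   themselves induce).

Each cell is scored by SoS, defined here as the **mean** of squared CNV
estimates across positions, not the raw sum. The published cutoffs (0.017
for keratinocytes, 0.026 for melanocytes) are only plausible for a
gene-count-invariant statistic — a raw sum over thousands of positions
would dwarf them — so the mean is the default and the raw sum stays
available behind `raw_sum = TRUE`. The correlation coordinate is the
Pearson r of a cell's profile to its sample's malignant reference profile,
built as the mean profile of the sample's top-decile SoS cells (the
upstream construction is described only by citation; the fraction is a
configurable argument, default 0.10, and is not asserted to be the
original authors' choice). Cells with a constant profile get r := 0 so
degenerate profiles can never be called malignant.

Calls are quadrants: CNV+ iff r ≥ r_cut **and** SoS ≥ s_cut, CNV− iff both
are below, `undefined` otherwise. Keratinocytes from BCC additionally get a
PTCH1/PTCH2 flag (expression above healthy mean + 2 SD), since
expression-based CNV inference only sees large chromosomal events and BCC
genomes can be CNV-quiet.

The HMM and random-trees subclustering of the upstream tool are out of
scope: the malignancy call consumes only (r, SoS), which do not depend on
HMM states.

# Marker signatures and module scores

Markers are two-sided Wilcoxon rank-sum tests of cluster vs rest with the
conventional gates: tested only when detected in ≥ 10% of one group and
|log2FC| ≥ 0.25 (log2FC on mean `expm1` expression with pseudocount 1);
Benjamini–Hochberg across tested genes; entries kept at adjusted p ≤ 0.01 —
the one threshold the source analysis states. Exact enumeration (tie-safe)
is used when both groups have ≤ 10 cells, the tie-corrected normal
approximation with continuity correction otherwise; both routes are tested
against `stats::wilcox.test` and full enumeration.

Module scores follow the bin-matched control design: genes are binned into
24 expression bins by dataset-wide average; each program gene contributes
100 control genes sampled with replacement from its bin; the score is mean
program expression minus mean pooled control expression, per cell. The
seed is a required argument. Program genes absent from the matrix or never
expressed are dropped and listed, mirroring the source's explicit
exclusions of never-expressed chemokines/cytokines. Note an inherent
property of the design (shared with the original): if the program is
shifted in a large fraction of cells, the shift leaks into the bin
averages and partially into the controls; the planted-recovery test
therefore shifts a small (5%) cluster, and recovers the planted 1.0 shift
within ±0.1.

# Ligand–receptor enrichment

Candidate interactions for a directed cluster pair are database pairs
whose ligand is in the source cluster's signature and whose receptor is in
the target's. The null model resamples, in each of 10,000 replicates,
pools of the same sizes from the database's ligand and receptor universes
(uniformly, without replacement) and counts database pairs formed. The
"equally sized pool" is resampled from the **database** universes — not
from all expressed genes — because the database is the only universe the
observed and null sets share; the alternative is not exposed since the
observed counts are database pairs by construction. The empirical p-value
uses the add-one estimator `(1 + #{count ≥ n_obs}) / (n_perm + 1)`, which
keeps p > 0 and BH well defined. BH spans all ordered cluster pairs that
pass the donor prerequisite, as one family (the source analysis does not
state its family; one global family is the conservative, simple choice).

A pair is testable only if some donor contributes ≥ 2.5% of the cells of
both clusters — the donor co-presence prerequisite that guards against
"interactions" between clusters never observed in the same person.
Failing pairs are reported with `donor_ok = FALSE` and no p.

Replicates are seeded individually from a counter-based stream, so results
are bit-identical regardless of how the replicate loop is chunked across
workers — the run-time/parallelism adjustments of the original are
honored as a determinism contract.

# Spatial quantification and T-cell exclusion

Phenotypes come from marker combinations: total CAF = COL1A1+, iCAF =
COL1A1+MMP1+, mCAF = COL1A1+COL11A1+MMP1−. Per-sample density is pooled
counts over pooled area across ≥ 5 ROIs (`Σc/Σa`, never a mean of per-ROI
ratios — the two differ and a test asserts the pooled form). Classes are
compared by two-sided Mann–Whitney (exact for ≤ 8 samples per class). The
exclusion analysis is OLS of `log10(CD3 density + 1)` on
`log10(CAF density + 1)` — base 10 and pseudocount 1 cell/mm² are choices
of this package, since the source plots log axes without stating either —
plus a high/low stratification at the published cutoffs (140 cells/mm² for
total CAFs, 40 for mCAFs/iCAFs, inclusive on the high side) with a Welch
t-test on log densities.

# The synthetic world

`generate_atlas()` draws per-gene log-normal baselines (meanlog log(100),
sdlog 1 — RPKM-like heavy-tailed positivity), adds Gaussian log-space
noise (sd 0.4) per cell, and applies all planted effects multiplicatively
in linear space: cluster markers, ligand/receptor shifts and CNV folds are
therefore exactly recoverable fold changes. Dropout is independent
Bernoulli zeroing at rate 0.3 (Smart-seq2 sparsity is moderate). CNVs are
applied to raw expression before QC, so the caller sees the realistic
coupling of signal with library-size shift. Default scale mirrors the
atlas design: 15 donors × 4 clusters × 96 cells = 5760 cells, and 4600
genes so that at 30% dropout the median genes detected per cell (~3220)
sits near the reported median. Donors contribute equally per cluster
unless a per-donor cell-count vector is given (the donor-skew knob used to
test the 2.5% rule).

Deliberate idealizations: no gene–gene correlation beyond planted
programs, no donor batch effects, no read- or UMI-level noise, no spatial
coordinates beyond ROI summaries. A green test on this world demonstrates
the *procedures* are correct and calibrated — not that the biological
conclusions of any particular dataset follow.

Two generator choices deserve explanation:

* **Synthetic LR database scale.** 300 ligands × 300 receptors with ~600
  wired pairs gives a pair density of ~0.7%, matching curated catalogues
  of the Ramilowski scale (~2500 pairs over ~700 × ~600). Density is what
  the permutation null is sensitive to; an early draft with a 4× denser
  toy database made planted circuits statistically invisible, which is a
  property of the database, not of the method.

* **CNV load.** The demo plants chromosome-level gains/losses (folds
  1.5/0.5) over 30% of the genome in one sample. Keratinocyte cancers
  typically carry aberrations of that order; at exactly 20% coverage the
  planted mean-square signal lands within ~1.5× of the published 0.017
  cutoff once dropout attenuates the log-fold shift, so 20% is a boundary
  regime rather than a representative tumor. The acceptance criterion's
  "≥ 20% of the genome" is instantiated at 30%.

`generate_roi_table()` draws Poisson phenotype counts at class-specific
planted densities over log-normal ROI areas, and CD3-in-nest counts from
`log10(cd3) = α + β·log10(mCAF density + 1) + ε` — the same pseudocounted
transform the regression fits, so β is exactly identifiable and
zero-count ROIs are well defined. CD3 counts are stored as expected
(possibly fractional) counts so that at ε = 0 the fitted slope is exactly
the planted one; phenotype counts stay integer.

# Numerical and degenerate-input conventions

* QC bounds inclusive; detection is value > 0 (strict).
* Wilcoxon: exact enumeration handles ties correctly; all-tied data gives
  p = 1; continuity correction matches `stats::wilcox.test`.
* BH: step-up with running-minimum monotonicity; p must lie in (0, 1].
* CNV: window shrinks to the chromosome block with a warning; zero-variance
  profiles get r = 0; empty reference sets error.
* Module score: required seed; empty effective gene set errors with the
  dropped genes listed.
* Regression: < 3 points or zero predictor variance error; constant
  response reports slope 0, R² = 0.
* All pipeline randomness flows from one config seed; rerunning a config
  byte-identically reproduces every output table.

# Known limitations

* The malignant-reference construction (top-decile SoS per sample) is a
  documented stand-in for the original's unreferenced construction; with
  very few malignant cells in a sample the reference degrades toward noise
  (a warning fires below 1/top_fraction cells).
* The permutation p-value is discrete (the null statistic is an integer
  count), so the achieved type-I level sits below nominal and fluctuates
  with the draw: calibration measurements over 200 null cluster pairs
  typically land around 0.03–0.05, and can fall slightly below 0.03 for
  some seeds. This is the estimator's true behaviour, shared by any
  count-based permutation test at these database densities.
* `rank_sum_de` loops genes in R; at atlas scale (tens of thousands of
  genes × thousands of cells) it is minutes, not seconds.
* The spatial stage trusts upstream marker thresholds; no image-derived
  uncertainty is propagated.
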