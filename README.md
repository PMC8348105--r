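# septraj

Cohort-trajectory analysis of circulating leukocyte transcriptomes in
surgical sepsis survivors.

Sepsis survivors split into two clinical trajectories: patients who rapidly
recover (RAP) and patients who develop chronic critical illness (CCI, an ICU
stay of 14+ days with persistent organ dysfunction). Both groups experience
an early "genomic storm" — a genome-wide shift in blood leukocyte
expression — but they return toward healthy baseline differently, and the
genes that stay aberrant late in sepsis differ by trajectory and by
discharge disposition. `septraj` implements the analysis pipeline for this
setting and a ground-truth-labelled synthetic cohort generator, so every
stage is testable end to end without access to patient microarray data
(which for studies of this kind is typically available only on request).

## What it computes

**Distance From Reference (DFR).** A per-sample scalar perturbation score
relative to healthy controls, over the variance-filtered gene set:

    DFR = ln Σ_i (e_i − M_i)² / V_i

where `e_i` is the sample's log2 expression of gene *i*, and `M_i`, `V_i`
are the mean and unbiased variance of the controls' expression of that
gene. Standardizing by the control variance keeps inherently variable or
highly expressed genes from dominating the sum. Group summaries use
Shapiro–Wilk-gated Welch *t* / Mann–Whitney comparisons.

**Variance filter with elbow cutoff.** Per-gene variances of the log2
values across all samples are sorted descending, min–max normalized, and
the knee (maximum perpendicular distance to the chord between the first and
last points) sets the cutoff; genes strictly above it feed the DFR and PCA.

**PCA cohort geometry.** Centered and scaled PCA (`prcomp`) with samples as
observations; group centroids and centroid-to-control Euclidean distances
quantify which trajectory sits closer to healthy controls at day 14.

**Multi-criteria differential expression.** Per-gene Welch tests with three
selection rules, all strict: fold change > |2| with Benjamini–Hochberg
FDR Q < 0.0001 (patient group vs controls), p < 0.001 (direct CCI vs RAP),
and FDR Q < 0.001 (good vs poor disposition); plus direction-concordance
analysis of common gene sets and day-1/day-14 signature overlap.

**Synthetic cohorts.** `generate_cohort()` plants a shared-direction storm
module, trajectory-specific day-1 modules, a disjoint CCI day-14 signature,
trajectory-dependent partial return at day 14 (70% of the day-1 effect
retained in CCI vs 20% in RAP by default), positive disposition effects in
poor-disposition CCI patients, and a two-tier baseline-variance structure
that produces the elbow. Every planted effect is recorded as ground truth.

## Worked example

```r
library(septraj)
report <- run_pipeline(pipeline_config(cohort = cohort_config()))
print(report)
```

On the default cohort (5000 genes; 40 controls; 20 patients per group and
timepoint; seed 1) this prints, among other things:

```
variance filter: cutoff 0.1281, 1685 genes retained
DFR group summary (ln expression units):
  control        n= 40  7.40 +/- 0.03
  CCI_day1       n= 20  10.37 +/- 0.01
  RAP_day1       n= 20  10.38 +/- 0.01
  CCI_day14      n= 20  10.32 +/- 0.10
  RAP_day14      n= 20  8.01 +/- 0.03
DE cci_day1_vs_control: 500 genes selected
DE rap_day14_vs_control: 0 genes selected
DE disposition_cci_day14: 63 genes selected
```

Read: both trajectories are far from health at day 1 (DFR ≈ 10.4 vs 7.4 in
controls, p < 0.001 for every patient group vs controls); by day 14 the
rapid-recovery group has moved most of the way back (8.01) while CCI
remains almost as perturbed as at day 1 (10.32). The day-1 selections
recover the planted storm + trajectory-specific modules (500 genes each),
their 400 common genes agree in direction in both groups (100%), and every
disposition-selected gene is higher in poor-disposition patients.
`report$pca$distances` shows the RAP day-14 centroid an order of magnitude
closer to controls (13.1) than the CCI day-14 centroid (49.9).

The `analysis/` directory holds the same workflow as numbered drivers
(`01_simulate.R` … `06_disposition.R`); run them in order from the
repository root to regenerate the tables under `results/` (the simulated
cohort itself is written under `scratch/`).

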