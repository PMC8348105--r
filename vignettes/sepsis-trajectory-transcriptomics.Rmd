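---
title: "Methods: trajectory analysis of sepsis survivor transcriptomes"
author: "septraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory analysis of sepsis survivor transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(septraj)
```

## The setting and the model

Surgical sepsis survivors follow one of two clinical trajectories: rapid
recovery (RAP) or chronic critical illness (CCI; 14+ ICU days with
persistent organ dysfunction). Blood leukocyte expression shifts massively
in both groups right after the septic insult — the "genomic storm" — and
then returns toward the healthy baseline only partially, at a
trajectory-dependent rate, with the genes that remain aberrant late in
sepsis differing between trajectories and between discharge dispositions.

`septraj` quantifies this with four connected analyses over a genes ×
samples log2 expression matrix and a cohort/timepoint/disposition metadata
table:

1. a **Distance From Reference (DFR)** score per sample,
   `DFR = ln Σ_i (e_i − M_i)² / V_i`, where `M_i` and `V_i` are the mean
   and unbiased variance of the healthy controls' expression of gene *i*.
   Dividing by `V_i` standardizes each gene's contribution so inherently
   variable or highly expressed genes do not dominate; the outer natural
   log compresses the sum to a scale on which cohort means are compared.
2. a **variance filter** selecting the high-variability genes on which both
   the DFR and the PCA operate,
3. **PCA geometry**: centered/scaled PCA with group centroids and
   centroid-to-control distances, and
4. **multi-criteria differential expression** with direction-concordance
   and signature-overlap set analysis.

All four stages are exercised against a synthetic cohort generator whose
planted structure is recorded as ground truth.

## Statistical choices, stage by stage

**Variance filter.** Per-gene variances are computed on the log2 values
across *all* samples, patients and controls pooled — the filter asks which
genes vary in the cohort at large, not within any one group. Variances use
the unbiased n − 1 denominator everywhere in the package. The cutoff is the
knee of the descending variance curve: ranks and variances are min–max
normalized to the unit square and the knee is the point with maximum
perpendicular distance to the chord joining the first and last points
(a kneedle-style rule; the normalization makes the location invariant to
uniform rescaling of the variances). Retention is *strictly* above the
cutoff; a gene exactly at the cutoff is excluded, and that boundary policy
is tested. `reference_variance_cutoff()` (0.4) is the cutoff reported for
the original microarray cohort this methodology comes from, exposed as a
fixed fallback for comparable data.

**DFR.** The reference is fit on the variance-filtered control matrix.
Genes with zero control variance cannot be standardized; they are dropped
with a recorded warning rather than floored with an epsilon, which would
have inflated their terms by an arbitrary factor. Control samples are
scored in-sample by default (reference fit on all controls, each control
scored against it); with the unbiased variance this pins
`Σ_samples Σ_i (e−M)²/V = G(n−1)` exactly, a useful self-check. A
leave-one-out mode (`dfr_control_scores(..., "leave_one_out")`) provides
the held-out alternative, under which the expected per-gene term inflates
by `(1 + 1/n)(n−1)/(n−3)`; both modes are provided because published group
summaries of this kind rarely state which protocol produced the control
scores. Group comparisons follow the normality-gated convention: Shapiro–
Wilk on each group at α = 0.05, Welch *t*-test if neither rejects,
Mann–Whitney otherwise (Welch rather than pooled-variance Student, as the
robust default when group variances are not assumed equal). Groups smaller
than 3 are summarized but not compared, since Shapiro–Wilk is undefined
there.

**PCA.** `stats::prcomp` with `center = TRUE, scale. = TRUE`; samples are
observations. All `min(n_samples, n_genes)` components are retained, and
centroid distances default to the full component space — restricting to a
subspace (e.g. PC2–PC3, where late-timepoint differences tend to be most
visible) is available but no quantitative claim is tied to specific
components. Results are deterministic up to component sign, and every
reported quantity (variance fractions, distances) is sign-invariant.

**Differential expression.** Per-gene two-sided Welch *t*-tests, vectorized
over the matrix rows and cross-checked against `stats::t.test` in the test
suite. Genes with zero variance in both groups get p = 1 when the means are
equal and p = 0 otherwise. Fold changes are differences of group means on
the log2 scale, reported both as `log2fc` (canonical) and as the signed
linear convention (+FC up, −FC down, so |signed FC| ≥ 1 always).
Benjamini–Hochberg adjustment is the standard step-up rule
(`stats::p.adjust`, verified in the tests against a brute-force
min-over-tails oracle), with the BH family being all genes of one two-group
comparison — q-values are never pooled across comparisons. The three
selection rules use strict inequalities (`> |2|`, `< 0.001`), which the
boundary tests pin down. DE runs on the *full* gene set: the variance
filter is a PCA/DFR concern, and filtering before testing would silently
change the BH family.

## The synthetic cohort generator

The generator emulates the features of the real cohort design that the
analyses depend on; its defaults are study conditions, not tuning knobs.

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 5000 | desk-scale stand-in for a filtered array's gene space |
| `n_controls` | 40 | matches the ~41 healthy controls of such cohorts |
| group sizes | 20 each | two trajectories × two timepoints, balanced |
| `n_shared_storm_genes` | 400 | large common day-1 module |
| `n_cci_specific_genes`, `n_rap_specific_genes` | 100 each | trajectory-unique day-1 signal |
| `n_d14_signature_genes` | 150 | late signature, disjoint from all day-1 modules |
| `effect_mean_log2`, `effect_sd_log2` | 2.5, 0.3 | well above the |FC| > 2 (|Δlog2| > 1) threshold, as storm effects are |
| `return_fraction_cci`, `return_fraction_rap` | 0.7, 0.2 | CCI stays perturbed at day 14; RAP returns most of the way |
| `baseline_mean_range` | 4–12 log2 units | typical microarray intensity range |
| `baseline_sd_low`, `baseline_sd_high`, `high_var_fraction` | 0.3, 0.9, 0.2 | two-tier noise creating the variance elbow |
| `disposition_split` (CCI), `disposition_split_rap` | 0.75, 0.33 | poor-disposition rates of such cohorts (~77% / ~33%) |
| `n_disposition_genes` | 100 | genes upregulated in poor-disposition CCI day-14 samples |

Expression is generated directly on the log2 scale with Gaussian per-gene
noise — the simplest model consistent with the t-test/fold-change machinery
downstream; no distributional description of real array intensities is
assumed beyond that. Design choices that were genuinely open:

- **Shared direction field.** One direction per gene, applied identically
  to both trajectories for storm genes, so genes common to the two day-1
  DE sets agree in direction by construction (the 100% concordance the
  pipeline should recover).
- **Multiplicative day-14 return.** Day-14 samples retain
  `return_fraction × day-1 effect` — one interpretable knob per trajectory
  that reproduces "partial return toward baseline". At the defaults, RAP
  residual effects (0.5 log2 units) fall below the |FC| > 2 selection
  threshold while CCI residuals (1.75) remain above it.
- **Day-14 signature planted in CCI day-14 samples only.** The late
  signature belongs to the CCI trajectory; planting it asymmetrically makes
  the declared truth set of the direct CCI-vs-RAP day-14 contrast exactly
  this module, and makes the day-1 and day-14 direct-contrast truth sets
  disjoint by construction. Residual day-1 effects that differ between
  trajectories through their unequal return fractions *are* genuinely
  differentially expressed at day 14 but are not part of the declared
  late signature, and the DE-selected direct sets are therefore not
  expected to be disjoint — only the planted signatures are.
- **Disposition effects strictly positive** in poor vs good, so
  good-disposition patients show decreased expression of every selected
  disposition gene. RAP day-14 samples receive disposition labels (for the
  all-survivors contrast) but no planted effect.

What the generator does *not* emulate: probe-set-level structure, array
normalization artefacts, batch effects, missing values, count-based noise,
or correlated gene modules (noise is independent across genes). Passing
tests therefore demonstrate that the pipeline recovers the planted
structure under clean Gaussian conditions — not that it is robust to the
full messiness of real microarray data.

## Numerical and degenerate-input policies

- File round trips serialize at 15 significant digits (lossless to 12).
- `elbow_cutoff` needs ≥ 3 genes and a non-constant profile; ties at the
  maximum distance resolve to the higher-variance point.
- A variance cutoff retaining zero genes, a reference with < 2 controls or
  all-flat genes, a sample identical to the reference means (DFR = ln 0),
  and comparisons whose groups resolve to no samples are all hard errors
  with stage-named messages rather than silent degradation.
- The pipeline validates every configured comparison's group labels
  immediately after loading data, before any computation.
- One seed governs a whole run (`pipeline_config(seed = )` overrides the
  embedded cohort seed); outputs are byte-identical across runs with equal
  seeds, and a config fingerprint (FNV-1a hash) is stamped into the run
  provenance.

## Scale of the shipped checks

The test suite runs the full pipeline at the default study scale
(5000 × 120) — a run takes well under a minute — plus 100-replicate
Monte-Carlo checks for the PCA-geometry and elbow-location properties and a
200-replicate simulation for the held-out control DFR limit at G = 1052
genes and 40 controls, where the mean score should match an independent
simulation oracle (and the analytic `ln(G · (1 + 1/n)(n−1)/(n−3))` regime)
within 2%. Smaller parameterized cohorts (600 genes) back the unit tests.

## Known limitations

- The per-gene Welch test stands in for whatever per-gene statistic a
  given array-analysis suite computes; the acceptance surface is recovery
  of planted structure, not test-for-test equivalence with any particular
  software.
- DFR control summaries depend on the in-sample vs held-out protocol
  (held-out scores run ~8% higher at n = 40 controls before the log);
  both modes are provided, in-sample being the default.
- One row per gene: probe-set-to-gene collapsing is out of scope, so gene
  counts from probe-level platforms are not directly comparable.
- The generator's independence across genes understates the correlation of
  real co-regulated modules; PCA variance fractions on synthetic cohorts
  are therefore flatter than on real data.
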