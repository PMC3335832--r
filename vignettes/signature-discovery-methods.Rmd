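---
title: "Methods: signature discovery and scoring in PBMC expression cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature discovery and scoring in PBMC expression cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`edsig` implements a complete bead-array analysis chain for discovering
correlated gene-expression signatures in peripheral blood mononuclear cell
(PBMC) cohorts of pulmonary hypertension (PH) patients, and a seeded
synthetic-cohort generator that reproduces the statistical structure such a
study assumes. This vignette documents the models, the tunable parameters,
the numerical conventions, and what the validation on synthetic cohorts does
and does not demonstrate.

## The statistical models

### Preprocessing

Raw probe intensities (no background correction) are scaled per sample so
the median intensity is 256 = 2^8, then log2-transformed. Intensities below
1 are floored to 1 first: without background correction small positive
values occur, and the floor avoids negative logs while preserving order.
Probes enter the analysis when their detection p-value is below 0.01 in at
least one sample and a gene symbol is available (`expressed_probe_filter()`).

Two z-transformations are used downstream. `zscore_within_sample()` centers
and scales each sample column over the working probe set; it feeds the
z-ratio metric and per-sample enrichment. `zscore_across_samples()`
standardizes each probe row; it is the heatmap/clustering normalization.
Both use the population (divide-by-N) standard deviation. The choice of SD
convention is not externally fixed; what matters is internal consistency,
because the PAGE denominator and the z-ratio standardization must use the
same convention as the transforms that produce their inputs. Constant probe
rows are emitted as zero rows with a warning (a display convention) and are
excluded from variance ranking and enrichment input, where they would be
undefined.

One numerical caveat: with an even number of probes the sample median is the
midpoint of the two middle values, so "median 256 before log" translates to
"median log2 = 8" exactly only for odd probe counts; for even counts the
discrepancy is below 10^-4 on realistic data.

### Differential expression

For a two-group contrast, a probe is *tested* only when, in the group with
the higher mean log2 expression, at least 80% of samples have detection
p < 0.01. When the group means tie exactly, the gate passes if either group
meets the detection requirement — the symmetric reading avoids an arbitrary
order dependence (ties have probability zero on continuous data). Gated
probes get a two-sided Welch unequal-variance t-test, Benjamini–Hochberg
q-values computed *within the gated universe of that contrast only* (the
gate deliberately shrinks the testing universe before the FDR step; pooling
contrasts would couple unrelated comparisons), and a geometric-mean fold
change 2^(mean A − mean B). Significance requires p ≤ 0.01, q ≤ 0.1 and
FC ≥ 1.5 or ≤ 1/1.5. The fold-change criterion is evaluated on gated probes
only, keeping a single testing universe for all three criteria. For gene
lists, a gene is significant if any of its probes is; lists deduplicate
symbols.

### Signature discovery

The `k = 500` most variant probes (across-sample variance, descending,
ties broken by probe id) are row-standardized and clustered with complete
linkage on the distance 1 − uncentered correlation, where the uncentered
correlation is Σxᵢyᵢ/√(Σxᵢ²·Σyᵢ²). On row-standardized data this coincides
with the Pearson correlation, and the uncentered form is what the classic
Cluster/TreeView setting computes. The tree is cut into at most six flat
clusters (`extract_seed_clusters()`), each annotated with its mean
within-cluster pairwise correlation. The original analysis interposed a
manual curation step at this point — choosing the probes that displayed
distinct patterns; that judgment call is not reproducible algorithmically,
so the automatic cut replaces it. A consequence is that a large planted
module can split across two cut clusters; both expand to the same
signature, so nothing is lost downstream.

Each seed cluster is summarized by its centroid — the per-sample arithmetic
mean of the seed probes' log2 values — and expanded to every probe in the
complete filtered matrix whose profile has Pearson r ≥ 0.7 with the
centroid. Pearson r is location/scale invariant, so membership is identical
whether computed on log2 or z-scored values; the stored centroid uses the
interpretable log2 scale. Surrogate biomarkers are the members with the
highest r; a single well-chosen surrogate (ALAS2-like) stands in for the
whole signature in clinical correlation.

### Parametric gene-set enrichment (PAGE)

A set's enrichment is the size-adjusted z of its mean metric:
Z = (Sm − μ)·√m/δ, with m the number of set genes present in the metric
universe, Sm their mean metric, and μ, δ the mean and population SD of the
full metric vector; p is the two-sided standard-normal tail; sets with
m < 10 are unreported. Probe-level data are collapsed to genes by the probe
with the highest mean expression (a deterministic, standard choice); symbol
matching is case-insensitive and exact, without alias expansion, to avoid
dictionary drift. No correction beyond the p ≤ 0.01 cutoff is applied
across sets, matching the reporting convention of pathway tables; BH across
sets can be applied to the returned table if desired.

Three metric kinds feed the score: the **z-ratio** (difference of group
means of within-sample z-scores, re-standardized over genes) for internal
contrasts; the **simple difference** of group mean log2 for external
datasets, whose submitter-processed scales make the z-ratio's implicit
variance assumptions unsafe; and, for the **landscape** variant, each
sample's own per-gene z vector after row normalization, scored per sample
and averaged by group *on the Z scale* (averaging the input metrics instead
would weight samples differently and was rejected; the group view describes
typical per-sample enrichment).

### Clinical association

Correlations between a surrogate's log2 expression and hemodynamic
covariates use the customary t-test on (r, n): t = r·√(n−2)/√(1−r²) with
n − 2 df. Subjects qualify when catheterization occurred within 120 days of
blood draw — the conventional reading of a four-month window, configurable.
Group summaries use mean ± t-quantile 84% confidence intervals: with group
sizes as small as 8, the t quantile rather than the normal 1.405·SE limit
is appropriate; non-overlap of two 84% intervals approximates a 0.05-level
mean difference. Cardiac-index strata split at 2.2 L/min/m², with the
boundary assigned to the high stratum because the poor-prognosis stratum is
defined as strictly below the cut. qPCR validation uses
ΔCt = Ct(target) − mean Ct(GAPDH, ACTB, PGK1), ΔΔCt against a calibrator
sample, RQ = 2^−ΔΔCt.

## The synthetic cohort generator

`cohort_config()` defaults encode the study conditions: five groups of
41/19/30/42/8 subjects (140 total), 20000 probes, log2 noise SD 0.5,
expressed baseline at log2 = 8, 35% unexpressed background probes, and a
per-sample multiplicative scale jitter (SD 0.15 in log2) so median scaling
is exercised. Six planted modules mirror the major PBMC patterns: EDS (169
probes / 149 genes), platelet (456/384, subject amplitudes correlated 0.6
with the EDS), immune-response blocks up- and down-regulated in all disease
groups (81 and 58 probes), a nonspecific immature-neutrophil signature
(40), and a sex-driven positive-control cluster (10). Module activation is
continuous: an active subject's amplitude is the module effect size (log2
units; EDS default 2.0) times a log-normal grade, so cohorts show the
graded signature levels seen in patients, and penetrance (the fraction of a
group that is active; EDS default 0.5 in IPAH/SSc-PAH, 0.9 in SSc-PH-ILD,
0.1 in SSc, 0.02 in controls) is a mixture. The penetrance values are
configuration, not established fact — the source cohort shows only that *a
subset* of each group is EDS-positive.

Within-module correlation is a calibrated target (default 0.8 for all
modules): when the cohort variance of the activation amplitudes falls short
of the variance the target implies given the noise SD, a shared per-subject
nuisance component is added; when it exceeds it, extra per-probe noise is
added instead. The uniform 0.8 default keeps all six modules at comparable
across-sample variance so each planted pattern can surface in the top-500
variance ranking, as the six-cluster heatmap structure requires.
Cross-module correlation is imposed on the full shared component by an
orthogonalized blend, so the configured value is realized at the centroid
level, attenuated only by probe noise averaging.

Detection p-values are drawn U(0, 0.005) for expressed-probe cells (97% of
cells; the remainder U(0.02, 1), so the 80% gate is occasionally binding)
and U(0.02, 1) for background probes, making both detection filters
meaningfully selective. Hemodynamic covariates for catheterized groups are
baseline mean + coupling·SD·z(EDS amplitude) + SD·√(1−coupling²)·noise, so
the population correlation equals the configured coupling: IPAH defaults
0.776 (RAmean), 0.752 (PVRI), −0.71 (PA saturation), −0.449 (CI), with
SSc-PAH and SSc-PH-ILD decoupled — reproducing the dissociation between
EDS level and severity outside IPAH. Catheterization-to-draw offsets are
U(0, 300) days, so the 120-day window retains about 40% of catheterized
subjects.

What the generator does **not** emulate: bead-level summarization
statistics, batch and array spatial effects, probe cross-hybridization,
annotation errors, non-normal heavy-tailed noise, and correlation structure
among background probes. Passing tests on synthetic cohorts therefore
demonstrate that the implementation recovers the structure it assumes, at
the planted effect sizes — not that real cohorts meet those assumptions.

## Validation design and problem sizes

The test suite validates each statistic against an independent route:
Welch t against `stats::t.test`, BH q-values against a from-scratch step-up
(1000 random vectors, agreement to 10^-12), PAGE against its closed form
evaluated independently (1000 instances, 10^-12), the correlation t-test
against a 20000-draw permutation null, and 84% CI coverage by Monte Carlo.
Null calibration uses 2000 random sets of 20 genes on an i.i.d. normal
metric of 4000 genes (acceptance band 0.01 ± 0.005 for p < 0.01). Recovery
checks run the full pipeline on the default 140 × 20000 cohort (EDS
sensitivity and precision ≥ 0.9 at r ≥ 0.7; in practice recovery is exact)
and scaled-down cohorts of ~1200 probes for per-operation tests. DE
calibration uses 20 seeded null cohorts (2000 probes, 41 vs 30 subjects;
zero significant calls expected in ≥ 95%) and 10 power cohorts with a fully
penetrant 100-probe module at amplitude 2.0 (≥ 90% of planted probes
called). These sizes were chosen so each property is measured with adequate
Monte Carlo precision while the whole suite runs in well under a minute per
file.

One acceptance bound deserves an explicit calculation. Sign recovery of a
coupling ρ from n = 12 subjects succeeds with probability approximately
Φ(atanh(|ρ|)·√(n−3)) (Fisher z). For the three strong couplings
(|ρ| ≥ 0.71) this exceeds 0.995, and the suite requires ≥ 95% over 200
seeded runs. For the cardiac-index coupling ρ = −0.449 the same formula
gives ≈ 0.93: no implementation can recover that sign in 95% of n = 12
samples, so the suite instead checks that the observed rate matches this
theoretical prediction — the correct behaviour, verified rather than
asserted away.

## Known limitations

* The six-cluster cut replaces the original manual curation; cluster
  boundaries on real data may need inspection, and a split of one module
  across two clusters is possible (and harmless after expansion).
* Symbol matching is exact; external datasets annotated with aliases will
  lose genes from the effective set.
* The z-ratio assumes comparably scaled within-sample z-distributions
  across groups; for heterogeneous external data use the difference metric,
  as the pipeline does.
* The series-matrix reader targets the tab-separated dialect with
  `!`-prefixed metadata and `key: value` characteristics fields; exotic
  dialects may need the `group_key` regex adjusted.
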