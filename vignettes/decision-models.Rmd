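---
title: "Bayesian MRI-biomarker decision models for early parkinsonism: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian MRI-biomarker decision models for early parkinsonism: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdmri)
```

## The diagnostic problem

Parkinson's disease (PD), multiple system atrophy (MSA) and progressive
supranuclear palsy (PSP) overlap clinically at early disease stages, when
patients often carry a "clinically unclassifiable parkinsonism" label.
Quantitative MRI offers measurements that diverge earlier than the clinical
picture: brainstem and third-ventricle atrophy indices (elevated in PSP),
putaminal and nigral mineralization visible as reduced normalized
susceptibility-weighted signal (more pronounced in MSA and PSP), and
diffusion-tensor fractional anisotropy in cerebellar peduncles. `pdmri`
implements the full statistical pathway from such biomarker panels to a
three-way probabilistic diagnosis, together with the infrastructure needed
to study the procedure's behaviour when the original patient data are not
available.

## Biomarkers

Eleven biomarkers form the panel (`biomarkerNames()`), in three families:

* **Atrophy indices** (dimensionless ratios from midsagittal areas in mm²
  and widths in mm): the pons-to-midbrain area ratio (`t1_pm_ratio`); the
  Magnetic Resonance Parkinsonian Index `mrpi` = (pons/midbrain) ×
  (mean MCP width / mean SCP width), where the peduncle means are
  arithmetic means of the left and right widths; and `mrpi2` = MRPI ×
  (third-ventricle width / frontal-horn width). All are invariant under a
  common rescaling of lengths and areas; all must be strictly positive.
* **Normalized SWI** (`swi_put`, `swi_stn`, `swi_rn`): mean
  susceptibility-weighted signal of a region divided by the mean
  white-matter signal of the same scan. A common receiver gain cancels;
  values below 1 indicate signal below white matter, i.e. iron deposition.
* **Fractional anisotropy** (`fa_scp`, `fa_cb`, `fa_mcp`, `fa_stn`,
  `fa_put`): region-averaged FA stored on the ×1000 scale used in the
  published group summaries. `derivePanels(..., faScale = "native")`
  converts inputs on the native [0, 1] scale.

Missing biomarkers are represented as `NA`, never as zero: zero is a
legal-looking but impossible value for a ratio biomarker, and the posterior
handles missingness by marginalization instead.

Cohorts are `BiomarkerCohort` objects — a `SummarizedExperiment` with one
biomarker-by-patient assay and the diagnosis (and any MSA subtype) in
`colData`. MSA-P, MSA-C and MSA-u collapse to MSA for every analysis; with
only a couple of cerebellar-subtype patients in cohorts of this size, a
subtype-level model is not estimable, so the subtype is retained as
metadata only.

## Screening: one-way ANOVA from data or summaries

`anovaOneway()` applies the classical fixed-effects one-way ANOVA to
patient-level values (through `stats::oneway.test(var.equal = TRUE)`);
`anovaFromSummary()` evaluates the identical statistic from per-group
(n, mean, SD) triples:

$$F = \frac{\sum_g n_g(\bar x_g - \bar x)^2 / (k-1)}
           {\sum_g (n_g-1) s_g^2 / (N-k)},$$

so a published summary table is sufficient input. The two routes agree to
machine precision on exact summaries, which the test suite exercises as its
primary correctness check for this module.

`selectBiomarkers()` retains biomarkers with p < `alpha`. The default
`alpha = 0.05` is the conventional screening level; it is a configurable
choice, not a fitted constant. On the reference group summaries it retains
the three atrophy indices and three SWI ratios and drops all five FA
biomarkers. No multiple-testing correction is applied across the eleven
biomarkers, matching the screening procedure this package mechanizes. When
F is significant, the screening table reports the descending order of group
means as a descriptive label; no formal post-hoc test is run because none
is part of the procedure.

Two reporting conventions: p-values below 10⁻³ are displayed as
power-of-ten upper bounds (e.g. `<10^-4`) with the raw float kept in the
result object; and one row of the reference table (`swi_rn`) is internally
inconsistent — the F recomputed from its own printed summaries is ≈ 13.72,
not the printed 10.289 (plausibly a patient subset with missing red-nucleus
values entered the original calculation). The package reports the
recomputed value; the test suite asserts the discrepancy rather than
targeting the printed number.

## Classification: Gaussian naive Bayes in two topologies

The class-conditional likelihood is an independent (diagonal-covariance)
Gaussian per class: published per-group means and SDs are the only
available parameterization of the cohort, which makes this the minimal
faithful model. Posteriors are computed in log space and normalized,

$$P(c \mid x) \propto \pi_c \prod_{f \in \text{present}(x)}
  N(x_f;\, \mu_{cf}, \sigma_{cf}),$$

with missing features skipped (exactly marginalization under independence).
Ties in the argmax break in the fixed order PD, MSA, PSP — deterministic
and documented rather than random.

* **Model I** is a single three-class posterior over the retained panel.
* **Model II** chains two binary stages: PSP vs rest on the atrophy
  indices, then MSA vs PD. With p₁ = P(PSP) and p₂ = P(MSA | not PSP), the
  combined posterior is P(PSP) = p₁, P(MSA) = (1−p₁)p₂,
  P(PD) = (1−p₁)(1−p₂). Which features feed the second stage is genuinely
  open; the default includes the SWI ratios *and* the atrophy indices,
  because PD/MSA atrophy differences carry real signal even though they
  overlap, and a flag restricts stage 2 to SWI only. The original
  rule-based tree used hard cut-offs; this implementation replaces them
  with the probabilistic stages and deliberately does not reimplement
  cut-off thresholds.

**Priors** default to uniform: the balanced bootstrap exists precisely to
neutralize the 38/25/10 imbalance, and empirical priors (`prior_mode =
"empirical"`) would partly re-introduce it. **Evaluation protocol**
defaults to resubstitution (fit and classify the same patients), mirroring
the procedure being reproduced; leave-one-out (`protocol = "loo"` in
`classifyCohort()`) and out-of-bag bootstrap scoring are available
separately, because resubstitution optimism is real and worth quantifying.

Numerical choices: fitted SDs are floored at 10⁻⁶ × the feature's pooled
within-class SD (falling back to 10⁻⁶ × max(1, |grand mean|) if even the
pooled SD vanishes), so a degenerate column cannot produce a zero-width
density; posterior normalization subtracts the max log-score before
exponentiating; fitting requires at least two usable values per class and
feature and fails with a named error otherwise.

## Balanced bootstrap evaluation

Each of B iterations draws `groupSize` patients per class with replacement
(default 10, the size of the smallest group), refits the chosen model on
the balanced sample, classifies it, and records per-class one-vs-rest
sensitivity, specificity and accuracy. Defaults B = 25,000 and 10 per
group are the reference study's conditions. Design points:

* **Interval method.** Both a standard-error-of-the-mean interval
  (mean ± 1.96·sd/√B) and a 2.5/97.5 percentile interval are computed. The
  SE-of-mean interval is labeled primary: at B = 25,000 it is a few
  thousandths wide, consistent with the very narrow intervals reported for
  this procedure, whereas percentile intervals are much wider. Which one
  the original analysis used is an inference from the printed widths, not
  a documented fact, so both are kept.
* **PSP resampling.** Whether the smallest group is resampled or enters
  as-is is ambiguous in the procedure's description; the default resamples
  all three classes, and `resamplePsp = FALSE` holds the full PSP group
  fixed.
* **Per-iteration protocol.** Refit-and-score-on-the-same-sample
  (resubstitution) is the default, matching the re-run-inference-under-
  bootstrap description; `protocol = "oob"` scores out-of-bag patients.
* **Degenerate iterations.** A metric undefined in an iteration (possible
  under out-of-bag scoring when a class has no held-out patients) is
  excluded from that metric's average and counted in `nUndefined`, with a
  warning.
* **Convergence.** Running means are recorded every 100 iterations;
  `convergenceTrace()` declares a metric converged when all checkpoints
  after the burn-in stay within `tolerance` (default 0.005) of the final
  mean. With the reference generator the traces stabilize well before
  iteration 15,000 of 25,000, the steady-state behaviour reported for the
  original cohort.
* **Determinism.** One integer seed drives the whole run; identical inputs
  give bit-identical reports.

The bootstrap core operates on plain matrices (per-class pools, closed-form
Gaussian refits, vectorized log-densities), which keeps the full
25,000-iteration run in the tens of seconds on one CPU.

## Synthetic cohorts: what they do and do not emulate

The patient data behind the reference study are confidential, so
`simulateCohort()` generates stand-in cohorts from a `CohortSpec`:
per-group sizes (default PD 38 / MSA 25 / PSP 10) and per-(group,
biomarker) mean/SD pairs (default: the published table,
`referenceGroupSummary()`), independent marginals unless a per-group
correlation matrix is supplied, and a positivity floor (default 0) below
which draws are rejected and redrawn. Per-group random streams derive
deterministically from the root seed and the group name, so adding or
resizing one group never perturbs another group's draws.

One calibration detail matters. Rejecting draws at 0 truncates the
Gaussian, and for MRPI2 — whose group means sit only ≈ 2.0–2.4 SDs above
zero — naive truncation would inflate the delivered mean by a bias that is
an order of magnitude larger than the standard error at large n, defeating
the generator's stated purpose of matching the published moments. The
generator therefore solves, per biomarker, for pre-truncation parameters
(μ\*, σ\*) such that the left-truncated normal has exactly the target mean
and SD (skipped when the mean is more than 8 SDs above the floor, where the
adjustment is below machine noise; applied marginally when a correlation
matrix is present, where joint rejection makes it an approximation). The
test suite verifies recovery of every published (mean, SD) within four
standard errors on a 100,000-per-group cohort.

What the generator does **not** emulate: real biomarker correlations
(MRPI2 is arithmetically coupled to MRPI in real panels; the default is
independence, with the correlation hook available), non-Gaussian tails,
diagnostic label noise, missingness patterns, and MSA-subtype structure.
Consequently synthetic cohorts are *easier* to classify than the real one:
passing tests demonstrate correctness of the machinery and the structural
properties of the procedure (balanced-bootstrap behaviour, interval
scaling, PSP being the most separable class), not clinical performance.
The published per-class performance of the original cohort is not
reproducible without the confidential data, and the package makes no
attempt to tune toward it.

## Outlier flagging

The original outlier analysis was visual (patients "far from" their group
in scatter plots). To make that reproducible, `flagOutliers()` substitutes
a robust z-score: within each group and biomarker,
z = (x − median)/(1.4826 × MAD), flagging |z| > 2.5 by default. The
threshold is an artifact convention (2.5 robust SDs is a common outlier
screen), not a value from the source procedure, and is a parameter. Groups
with fewer than three present values or zero MAD are skipped with a
warning. Flags are affine-invariant per biomarker and monotone in the
threshold; `outlierReport()` joins them with posterior percentages and
predicted-vs-final labels in a case-review layout.

## Pipeline, configuration and problem sizes

`runPipeline()` executes screening → feature selection → classification →
balanced bootstrap → outlier report, writing CSVs and logging every
decision (selected features, seed, protocol flags). Configuration is a
plain list or JSON/YAML file; command-line access is a thin wrapper script
(`inst/scripts/pdmri.R`) over the exported functions, with distinct exit
codes for configuration, input-format and numerical errors.

The test suite runs its statistical checks at sizes chosen to make each
property measurable at its stated tolerance: oracle-equivalence loops at
50 random datasets, posterior-oracle checks at 100 panels, type-I error
calibration at 10,000 null datasets, parameter recovery at 100,000 patients
per group, the closed-form two-class error check at 100,000 draws, and one
full B = 25,000 bootstrap with a B = 1,000 companion to verify the 1/√B
interval-width scaling.

## Known limitations

* Independent-Gaussian class conditionals ignore real covariance between
  atrophy indices; a shared- or full-covariance variant is a natural
  extension the data model already supports.
* Resubstitution metrics are optimistic; the leave-one-out and out-of-bag
  options quantify but do not remove this.
* The measurement convention for the pons and midbrain (midsagittal areas
  vs linear measures) varies across the literature; the data model stores
  areas (mm²) while the ratio operations only require positive inputs, so
  linear-measure tables load unchanged.
* Whether the original inference used shared or per-class variances, and
  resubstitution or cross-validation, is not documented; the package
  defaults to per-class variances and resubstitution and exposes the
  alternatives as options rather than guessing silently.
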