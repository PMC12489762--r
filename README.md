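# pdmri

Differentiating Parkinson's disease (PD) from multiple system atrophy (MSA)
and progressive supranuclear palsy (PSP) is hardest exactly when it matters
most: at early disease stages, when the clinical picture is still
"clinically unclassifiable parkinsonism" and treatment and counselling
decisions are pending. `pdmri` implements a complete quantitative-MRI
decision pipeline for this three-way diagnostic problem, aimed at
neuroimaging statisticians and methods researchers who want to study,
stress-test or extend biomarker-panel classifiers of parkinsonism:

* **Biomarker derivation** — brainstem atrophy indices from geometric
  measurements: the Magnetic Resonance Parkinsonian Index
  (MRPI = pons/midbrain area ratio × mean MCP width / mean SCP width), its
  third-ventricle extension MRPI2 = MRPI × (third-ventricle width /
  frontal-horn width), the plain pons-to-midbrain ratio, plus
  white-matter–normalized susceptibility-weighted signal (SWI) in putamen,
  subthalamic nucleus region and red nucleus, and region-averaged
  fractional anisotropy (FA).
* **Biomarker screening** — one-way ANOVA per biomarker across the three
  diagnosis groups, from patient-level data *or directly from published
  per-group summaries* (n, mean, SD):
  F = [Σ n₉(x̄₉ − x̄)²/(k−1)] / [Σ (n₉−1)s₉²/(N−k)],
  with selection of the biomarkers showing significant group differences.
* **Bayesian classification** — Gaussian naive-Bayes posteriors
  P(c|x) ∝ π_c ∏_f N(x_f; μ_cf, σ_cf), under two decision-model
  topologies: model I, a single three-class stage over the full retained
  panel; and model II, a decision tree chaining a PSP-vs-rest stage on the
  atrophy indices with an MSA-vs-PD stage (P(PSP)=p₁, P(MSA)=(1−p₁)p₂,
  P(PD)=(1−p₁)(1−p₂)).
* **Class-balanced bootstrap evaluation** — resample an equal number of
  patients per class with replacement (default 10 per group, B = 25,000
  iterations), refit and score one-vs-rest sensitivity/specificity/accuracy
  each time, and report per-class means with 95% intervals and a
  running-mean convergence trace.
* **Outlier flagging** — robust z-scores ((x − median)/(1.4826·MAD)) within
  each diagnosis group, joined with the posterior report.
* **Synthetic cohorts** — the patient data behind the reference study are
  confidential, so the package ships a generator that reproduces the
  published per-group biomarker means and SDs (PD n = 38, MSA n = 25,
  PSP n = 10) as positivity-respecting Gaussian marginals, with optional
  per-group correlation.

## Worked example

```r
library(pdmri)

## screen the published group summaries (no patient data needed)
tab <- screenSummary(referenceGroupSummary())
tab[, c("biomarker", "f_value", "p_display", "ordering")]
#>      biomarker  f_value p_display       ordering
#> 1         mrpi 10.58882    <10^-4 PSP > PD > MSA
#> 2        mrpi2 10.39690    <10^-3 PSP > MSA > PD
#> 3  t1_pm_ratio 16.36670    <10^-5 PSP > MSA > PD
#> 4       fa_scp  2.09226      0.13              -
#> 5        fa_cb  0.56222      0.57              -
#> 6       fa_mcp  2.45051      0.09              -
#> 7       fa_stn  0.59963      0.55              -
#> 8       fa_put  0.49914      0.61              -
#> 9      swi_put 11.51509    <10^-4 PD > MSA > PSP
#> 10     swi_stn 12.05640    <10^-4 PD > MSA > PSP
#> 11      swi_rn 13.71847    <10^-5 PD > MSA > PSP

selectBiomarkers(tab, alpha = 0.05)
#> [1] "mrpi"  "mrpi2"  "t1_pm_ratio"  "swi_put"  "swi_stn"  "swi_rn"
```

The atrophy and SWI biomarkers separate at least two of the groups (PSP
shows the most distinctive atrophy, and normalized SWI decreases from PD to
PSP, reflecting increasing mineralization), while none of the five FA
biomarkers reaches significance — so the decision models run on the six
retained biomarkers.

```r
## simulate a reference-sized cohort, classify, and bootstrap-evaluate
cohort <- simulateCohort(referenceCohortSpec(), seed = 42)
head(classifyCohort(cohort, model = "I"), 3)
#>   patient_id diagnosis msa_pct pd_pct psp_pct predicted correct
#> 1     PD_001        PD   18.00  81.91    0.09        PD    TRUE
#> 2     PD_002        PD    3.01  96.98    0.00        PD    TRUE
#> 3     PD_003        PD   24.14  75.46    0.40        PD    TRUE

bootstrapEvaluate(cohort, model = "I", iterations = 25000, seed = 42)
#> BootstrapReport (model I): B = 25000, 10 per group, seed 42
#>   PD  sens 0.972 (0.971-0.972)  spec 0.964 (0.964-0.965)  accu 0.967 (0.966-0.967)
#>   MSA sens 0.927 (0.926-0.928)  spec 0.943 (0.942-0.944)  accu 0.938 (0.937-0.938)
#>   PSP sens 0.914 (0.913-0.916)  spec 0.999 (0.999-0.999)  accu 0.971 (0.971-0.971)
```

Each row gives the across-iteration mean and its 95%
standard-error-of-the-mean interval for one class treated as "positive"
against the other two pooled. Synthetic cohorts are cleaner than real
patients (independent Gaussian marginals, no mislabeled diagnoses), so
these metrics sit well above what is achievable on clinical data; their
*structure* — PSP easiest to separate, very narrow intervals at
B = 25,000 — is the reproducible part.

`runPipeline()` chains all stages (screening → classification → bootstrap →
outlier report) and writes CSV reports; `inst/scripts/pdmri.R` exposes the
same steps as shell subcommands (`simulate`, `anova`, `classify`,
`evaluate`, `outliers`, `run`).

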