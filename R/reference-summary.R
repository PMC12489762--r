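# Published per-group biomarker summaries (mean, SD) for the 73-patient
# early-stage parkinsonism cohort: PD n=38, MSA n=25, PSP n=10. Atrophy
# indices are dimensionless, FA is on the x1000 scale, SWI values are ratios
# to white-matter signal. These summaries are the only published
# parameterization of the cohort (the raw data are confidential) and drive
# both the synthetic-cohort generator and summary-statistic ANOVA.

.REF_GROUP_N <- c(PD = 38L, MSA = 25L, PSP = 10L)

.REF_GROUP_MEAN <- matrix(c(
  # PD,      MSA,     PSP
  143.054, 142.024, 210.761,   # mrpi
   32.964,  33.539,  59.316,   # mrpi2
    3.414,   3.421,   4.753,   # t1_pm_ratio
  670.262, 638.731, 623.115,   # fa_scp
  490.666, 476.603, 482.678,   # fa_cb
  518.756, 484.072, 529.740,   # fa_mcp
  527.369, 532.173, 497.292,   # fa_stn
  430.992, 429.342, 446.568,   # fa_put
    0.925,   0.804,   0.796,   # swi_put
    0.941,   0.842,   0.698,   # swi_stn
    0.921,   0.857,   0.703),  # swi_rn
  nrow = 11L, byrow = TRUE,
  dimnames = list(.BIOMARKERS, .CLASSES))

.REF_GROUP_SD <- matrix(c(
   36.019,  48.005,  56.858,
   13.735,  16.816,  25.985,
    0.573,   0.738,   0.927,
   51.586, 107.831,  71.839,
   44.345,  65.668,  37.284,
   62.025,  88.165,  25.134,
   94.702,  72.043,  93.808,
   49.452,  49.454,  38.180,
    0.083,   0.118,   0.168,
    0.103,   0.141,   0.258,
    0.049,   0.111,   0.256),
  nrow = 11L, byrow = TRUE,
  dimnames = list(.BIOMARKERS, .CLASSES))

#' Published per-group biomarker summaries
#'
#' Long-format table of the published per-diagnosis biomarker means and
#' standard deviations for the 73-patient early-stage cohort (PD n = 38,
#' MSA n = 25, PSP n = 10). These are the inputs for summary-statistic ANOVA
#' ([anovaFromSummary()]) and the default parameterization of the synthetic
#' cohort generator ([referenceCohortSpec()], [simulateCohort()]).
#'
#' @return A `data.frame` with columns `biomarker`, `group`, `n`, `mean`, `sd`
#'   (33 rows: 11 biomarkers x 3 groups).
#' @seealso [referenceCohortSpec()], [anovaFromSummary()]
#' @export
#' @examples
#' head(referenceGroupSummary())
referenceGroupSummary <- function() {
  data.frame(
    biomarker = rep(.BIOMARKERS, times = 3L),
    group = rep(.CLASSES, each = 11L),
    n = rep(unname(.REF_GROUP_N), each = 11L),
    mean = as.vector(.REF_GROUP_MEAN),
    sd = as.vector(.REF_GROUP_SD),
    stringsAsFactors = FALSE
  )
}
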