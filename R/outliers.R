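#' Flag within-group biomarker outliers by robust z-score
#'
#' A mechanized stand-in for visual outlier identification on scatter plots:
#' for every diagnosis group and biomarker, each patient's robust z-score is
#' `(x - median) / (1.4826 * MAD)` over that group's values, and a flag is
#' emitted when its absolute value exceeds `threshold` (default 2.5, an
#' artifact convention). A group/biomarker combination with zero MAD, or with
#' fewer than 3 present values, is skipped with a warning. Flags are
#' invariant under per-biomarker affine rescaling of the cohort and
#' monotone in the threshold.
#'
#' @param cohort A labeled [BiomarkerCohort-class].
#' @param threshold Positive robust-z cutoff.
#' @return Data.frame: `patient_id`, `diagnosis`, `biomarker`, `value`,
#'   `robust_z`, `direction` (`"high"`/`"low"`), ordered by |z| descending.
#' @export
#' @examples
#' cohort <- simulateCohort(referenceCohortSpec(), seed = 1)
#' head(flagOutliers(cohort))
flagOutliers <- function(cohort, threshold = 2.5) {
  stopifnot(methods::is(cohort, "BiomarkerCohort"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    .pdmriStop("pdmri_config_error", "threshold must be a positive number")
  m <- biomarkers(cohort)
  dx <- diagnosis(cohort)
  ids <- patientIds(cohort)
  rows <- list(); r <- 0L
  for (cl in intersect(.CLASSES, unique(dx[!is.na(dx)]))) {
    sel <- which(!is.na(dx) & dx == cl)
    for (b in rownames(m)) {
      v <- m[b, sel]
      present <- !is.na(v)
      if (sum(present) < 3L) {
        warning(sprintf("group %s, biomarker %s: fewer than 3 values, skipped",
                        cl, b))
        next
      }
      med <- median(v[present])
      madv <- mad(v[present])   # mad() already applies the 1.4826 constant
      if (madv == 0) {
        warning(sprintf("group %s, biomarker %s: zero MAD, skipped", cl, b))
        next
      }
      z <- (v - med) / madv
      hit <- which(present & abs(z) > threshold)
      for (i in hit) {
        r <- r + 1L
        rows[[r]] <- data.frame(patient_id = ids[sel[i]], diagnosis = cl,
                                biomarker = b, value = v[i], robust_z = z[i],
                                direction = if (z[i] > 0) "high" else "low",
                                stringsAsFactors = FALSE)
      }
    }
  }
  if (!r)
    return(data.frame(patient_id = character(), diagnosis = character(),
                      biomarker = character(), value = numeric(),
                      robust_z = numeric(), direction = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$robust_z)), ]
  rownames(out) <- NULL
  out
}

#' Outlier report with posterior probabilities
#'
#' Joins the robust-z outlier flags with each flagged patient's posterior
#' percentages and predicted class — the layout of a case-review table:
#' one row per flagged patient with the final clinical diagnosis, the
#' posterior percentages for MSA, PD and PSP, the prediction and whether it
#' matches, plus the biomarkers that triggered the flag.
#'
#' @param cohort A labeled [BiomarkerCohort-class].
#' @param classification Per-patient classification table from
#'   [classifyCohort()]; computed with model I defaults when omitted.
#' @param threshold Robust-z cutoff passed to [flagOutliers()].
#' @return Data.frame with one row per flagged patient.
#' @export
outlierReport <- function(cohort, classification = NULL, threshold = 2.5) {
  flags <- flagOutliers(cohort, threshold = threshold)
  if (is.null(classification))
    classification <- classifyCohort(cohort, model = "I")
  if (!nrow(flags)) {
    out <- classification[0, , drop = FALSE]
    out$flagged_biomarkers <- character(0)
    out$max_abs_robust_z <- numeric(0)
    return(out)
  }
  perPatient <- split(flags, flags$patient_id)
  ids <- names(perPatient)
  joined <- classification[match(ids, classification$patient_id), ,
                           drop = FALSE]
  joined$flagged_biomarkers <- vapply(perPatient, function(d)
    paste(sprintf("%s(%s)", d$biomarker, d$direction), collapse = ";"), "")
  joined$max_abs_robust_z <- vapply(perPatient, function(d)
    max(abs(d$robust_z)), 0)
  joined <- joined[order(-joined$max_abs_robust_z), ]
  rownames(joined) <- NULL
  joined
}
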