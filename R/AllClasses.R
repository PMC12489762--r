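#' @import methods
#' @importFrom stats dnorm pf pnorm qnorm quantile rnorm sd mad median oneway.test var setNames complete.cases
#' @importFrom utils read.csv write.csv head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' BiomarkerCohort: a labeled cohort of biomarker panels
#'
#' S4 container for a cohort of patients with (possibly incomplete) MRI
#' biomarker panels, built on [SummarizedExperiment::SummarizedExperiment].
#' The single assay `"biomarkers"` holds a biomarker-by-patient numeric
#' matrix (rows drawn from [biomarkerNames()], `NA` = missing); `colData`
#' carries `diagnosis` (PD/MSA/PSP, possibly `NA` for unlabeled panels) and
#' `subtype` (MSA-P/MSA-C/MSA-u, `NA` otherwise). MSA subtypes collapse to
#' MSA for all analyses; the subtype is retained as metadata only.
#'
#' Validity enforces unique patient identifiers, known biomarker and
#' diagnosis names, subtype only on MSA patients, strictly positive values
#' for the ratio biomarkers (atrophy indices and normalized SWI) and
#' nonnegative values for fractional anisotropy.
#'
#' @seealso [BiomarkerCohort()] constructor, [readCohort()], [simulateCohort()]
#' @aliases BiomarkerCohort-class
#' @export
setClass("BiomarkerCohort", contains = "SummarizedExperiment")

setValidity("BiomarkerCohort", function(object) {
  msgs <- character()
  if (!("biomarkers" %in% SummarizedExperiment::assayNames(object)))
    return("assay 'biomarkers' is required")
  m <- SummarizedExperiment::assay(object, "biomarkers")
  if (!is.numeric(m))
    msgs <- c(msgs, "assay 'biomarkers' must be numeric")
  bad <- setdiff(rownames(object), .BIOMARKERS)
  if (length(bad))
    msgs <- c(msgs, paste0("unknown biomarker row(s): ",
                           paste(bad, collapse = ", ")))
  ids <- colnames(object)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    msgs <- c(msgs, "every patient needs a nonempty identifier (column name)")
  else if (anyDuplicated(ids))
    msgs <- c(msgs, "patient identifiers must be unique within a cohort")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("diagnosis", "subtype") %in% colnames(cd)))
    msgs <- c(msgs, "colData must contain 'diagnosis' and 'subtype'")
  else {
    dx <- as.character(cd$diagnosis)
    if (any(!is.na(dx) & !(dx %in% .CLASSES)))
      msgs <- c(msgs, "diagnosis must be one of PD, MSA, PSP (or NA)")
    st <- as.character(cd$subtype)
    if (any(!is.na(st) & !(st %in% .MSA_SUBTYPES)))
      msgs <- c(msgs, "subtype must be one of MSA-P, MSA-C, MSA-u (or NA)")
    if (any(!is.na(st) & (is.na(dx) | dx != "MSA")))
      msgs <- c(msgs, "subtype is only meaningful for MSA patients")
  }
  if (is.numeric(m) && nrow(m)) {
    ratio <- intersect(rownames(m), .RATIO_BIOMARKERS)
    if (length(ratio) && any(m[ratio, , drop = FALSE] <= 0, na.rm = TRUE))
      msgs <- c(msgs, "ratio biomarkers (atrophy and SWI) must be > 0 when present")
    fa <- intersect(rownames(m), .FA)
    if (length(fa) && any(m[fa, , drop = FALSE] < 0, na.rm = TRUE))
      msgs <- c(msgs, "fractional anisotropy values must be nonnegative")
  }
  if (length(msgs)) msgs else TRUE
})

#' CohortSpec: parameterization of a synthetic cohort
#'
#' Per-group sizes plus per-(group, biomarker) Gaussian marginals (mean, SD),
#' an optional per-group correlation matrix over biomarkers (default:
#' identity, i.e. independent marginals) and a positivity floor below which
#' draws are rejected and redrawn. The published group summaries provide the
#' default parameterization ([referenceCohortSpec()]).
#'
#' @slot groupSizes named integer vector (names from [diagnosisClasses()]).
#' @slot means,sds biomarker-by-group numeric matrices.
#' @slot correlation named list of per-group correlation matrices
#'   (biomarker-by-biomarker, unit diagonal, symmetric PSD), or empty list
#'   for independence.
#' @slot positivityFloor single nonnegative number; any draw with a
#'   biomarker value at or below the floor is rejected and redrawn.
#' @aliases CohortSpec-class
#' @export
setClass("CohortSpec",
  representation(groupSizes = "integer", means = "matrix", sds = "matrix",
                 correlation = "list", positivityFloor = "numeric"))

setValidity("CohortSpec", function(object) {
  msgs <- character()
  gs <- object@groupSizes
  if (is.null(names(gs)) || any(!(names(gs) %in% .CLASSES)))
    msgs <- c(msgs, "groupSizes must be named with diagnosis classes")
  if (any(gs < 1L)) msgs <- c(msgs, "group sizes must be positive")
  for (nm in c("means", "sds")) {
    m <- slot(object, nm)
    if (!identical(colnames(m), names(gs)))
      msgs <- c(msgs, paste0(nm, " columns must match groupSizes names"))
    if (any(!(rownames(m) %in% .BIOMARKERS)))
      msgs <- c(msgs, paste0(nm, " rows must be known biomarkers"))
  }
  if (!identical(dim(object@means), dim(object@sds)))
    msgs <- c(msgs, "means and sds must have identical dimensions")
  if (any(object@sds < 0)) msgs <- c(msgs, "standard deviations must be >= 0")
  if (length(object@correlation)) {
    if (any(!(names(object@correlation) %in% names(gs))))
      msgs <- c(msgs, "correlation list names must be groups")
    p <- nrow(object@means)
    for (g in names(object@correlation)) {
      R <- object@correlation[[g]]
      if (!is.matrix(R) || !identical(dim(R), c(p, p)))
        msgs <- c(msgs, sprintf("correlation[%s] must be %dx%d", g, p, p))
      else {
        if (max(abs(R - t(R))) > 1e-8 || max(abs(diag(R) - 1)) > 1e-8)
          msgs <- c(msgs, sprintf("correlation[%s] must be symmetric with unit diagonal", g))
        else if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
          msgs <- c(msgs, sprintf("correlation[%s] must be positive semidefinite", g))
      }
    }
  }
  if (length(object@positivityFloor) != 1L || object@positivityFloor < 0)
    msgs <- c(msgs, "positivityFloor must be a single nonnegative number")
  if (length(msgs)) msgs else TRUE
})

#' AnovaResult: one-way ANOVA of a biomarker across diagnosis groups
#'
#' @slot fValue nonnegative F statistic.
#' @slot dfBetween,dfWithin integer degrees of freedom (k-1 and N-k).
#' @slot pValue upper-tail probability of F(dfBetween, dfWithin) at fValue.
#' @slot pDisplay p-value rendered for reports; values below 1e-3 are shown
#'   as a power-of-ten upper bound (e.g. `"<10^-4"`).
#' @aliases AnovaResult-class
#' @export
setClass("AnovaResult",
  representation(fValue = "numeric", dfBetween = "integer",
                 dfWithin = "integer", pValue = "numeric",
                 pDisplay = "character"))

setValidity("AnovaResult", function(object) {
  msgs <- character()
  if (object@fValue < 0) msgs <- c(msgs, "fValue must be nonnegative")
  if (object@dfBetween < 1L || object@dfWithin < 1L)
    msgs <- c(msgs, "degrees of freedom must be positive")
  if (object@pValue < 0 || object@pValue > 1)
    msgs <- c(msgs, "pValue must be in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' ClassConditionalModel: Gaussian naive-Bayes parameters
#'
#' Per-class, per-feature Gaussian parameters plus class priors — the state
#' of the Bayesian inference engine. Class-conditional densities are
#' independent (diagonal-covariance) Gaussians; posteriors are computed in
#' log space and missing features are marginalized out by omission.
#'
#' @slot classes ordered character vector of class labels.
#' @slot features ordered character vector of biomarker names.
#' @slot means,sds feature-by-class numeric matrices; all SDs strictly
#'   positive (fitting applies a variance floor).
#' @slot priors named numeric vector over classes, summing to 1.
#' @aliases ClassConditionalModel-class
#' @export
setClass("ClassConditionalModel",
  representation(classes = "character", features = "character",
                 means = "matrix", sds = "matrix", priors = "numeric"))

setValidity("ClassConditionalModel", function(object) {
  msgs <- character()
  k <- length(object@classes); p <- length(object@features)
  if (k < 2L) msgs <- c(msgs, "at least two classes are required")
  for (nm in c("means", "sds")) {
    m <- slot(object, nm)
    if (!identical(rownames(m), object@features) ||
        !identical(colnames(m), object@classes))
      msgs <- c(msgs, paste0(nm, " must be a features x classes matrix"))
  }
  if (any(object@sds <= 0)) msgs <- c(msgs, "all sds must be strictly positive")
  pr <- object@priors
  if (!identical(names(pr), object@classes))
    msgs <- c(msgs, "priors must be named by class, in class order")
  if (any(pr <= 0 | pr >= 1))
    msgs <- c(msgs, "priors must lie strictly in (0, 1)")
  if (abs(sum(pr) - 1) > 1e-12) msgs <- c(msgs, "priors must sum to 1")
  if (length(msgs)) msgs else TRUE
})

#' PosteriorResult: posterior class probabilities for one panel
#'
#' @slot probabilities named numeric vector over PD, MSA, PSP (sums to 1
#'   within 1e-9).
#' @slot predicted the argmax class; ties break in the fixed order
#'   PD, MSA, PSP.
#' @slot modelId `"I"` (single multi-class stage) or `"II"` (two-stage
#'   decision tree).
#' @aliases PosteriorResult-class
#' @export
setClass("PosteriorResult",
  representation(probabilities = "numeric", predicted = "character",
                 modelId = "character"))

setValidity("PosteriorResult", function(object) {
  msgs <- character()
  p <- object@probabilities
  if (any(p < -1e-12) || any(p > 1 + 1e-12))
    msgs <- c(msgs, "probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-9)
    msgs <- c(msgs, "probabilities must sum to 1 (within 1e-9)")
  if (!(object@predicted %in% names(p)))
    msgs <- c(msgs, "predicted must be one of the classes")
  if (!(object@modelId %in% c("I", "II")))
    msgs <- c(msgs, "modelId must be 'I' or 'II'")
  if (length(msgs)) msgs else TRUE
})

#' BootstrapReport: class-balanced bootstrap evaluation results
#'
#' Per-class, per-metric summaries over B balanced resamples: mean,
#' across-iteration SD, the standard-error-of-the-mean 95% interval
#' (primary), the 2.5/97.5 percentile interval, plus a running-mean
#' convergence trace recorded on a fixed schedule.
#'
#' @slot iterations number of bootstrap iterations B.
#' @slot groupSize patients resampled per class per iteration.
#' @slot seed integer seed that makes the report bit-reproducible.
#' @slot modelId `"I"` or `"II"`.
#' @slot summary data.frame: class, metric, mean, sd, ciLow, ciHigh
#'   (SE-of-mean), pctLow, pctHigh (percentile), nUsed, nUndefined.
#' @slot trace 3-d array (checkpoint x class x metric) of running means.
#' @slot traceEvery iterations between trace checkpoints.
#' @aliases BootstrapReport-class
#' @export
setClass("BootstrapReport",
  representation(iterations = "integer", groupSize = "integer",
                 seed = "integer", modelId = "character",
                 summary = "data.frame", trace = "array",
                 traceEvery = "integer"))

setValidity("BootstrapReport", function(object) {
  msgs <- character()
  s <- object@summary
  need <- c("class", "metric", "mean", "sd", "ciLow", "ciHigh",
            "pctLow", "pctHigh", "nUsed", "nUndefined")
  if (!all(need %in% colnames(s)))
    msgs <- c(msgs, "summary is missing required columns")
  else {
    if (any(s$ciLow > s$mean + 1e-12 | s$mean > s$ciHigh + 1e-12, na.rm = TRUE))
      msgs <- c(msgs, "each SE-of-mean interval must bracket its mean")
    ok <- stats::complete.cases(s[, c("mean", "ciLow", "ciHigh")])
    vals <- unlist(s[ok, c("mean", "pctLow", "pctHigh")])
    if (length(vals) && (min(vals) < -1e-12 || max(vals) > 1 + 1e-12))
      msgs <- c(msgs, "metrics must lie in [0, 1]")
  }
  if (object@iterations < 1L) msgs <- c(msgs, "iterations must be >= 1")
  if (length(msgs)) msgs else TRUE
})
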