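#' Construct a Gaussian class-conditional model
#'
#' Builds a [ClassConditionalModel-class] from explicit per-class, per-feature
#' Gaussian parameters — e.g. directly from a published group-summary table.
#'
#' @param means,sds Feature-by-class numeric matrices with matching dimnames;
#'   all SDs strictly positive.
#' @param priors Named numeric vector of class priors; defaults to uniform.
#' @return A [ClassConditionalModel-class].
#' @export
#' @examples
#' spec <- referenceCohortSpec()
#' m <- classConditionalModel(spec@means[1:3, ], spec@sds[1:3, ])
#' m
classConditionalModel <- function(means, sds, priors = NULL) {
  means <- as.matrix(means); sds <- as.matrix(sds)
  classes <- colnames(means)
  if (is.null(priors))
    priors <- setNames(rep(1 / length(classes), length(classes)), classes)
  priors <- priors[classes] / sum(priors)
  methods::new("ClassConditionalModel", classes = classes,
               features = rownames(means), means = means, sds = sds,
               priors = priors)
}

setMethod("show", "ClassConditionalModel", function(object) {
  cat(sprintf("ClassConditionalModel: %d classes (%s), %d features\n",
              length(object@classes), paste(object@classes, collapse = ", "),
              length(object@features)))
  cat("  features:", paste(object@features, collapse = ", "), "\n")
  cat("  priors:", paste(sprintf("%s=%.3f", names(object@priors),
                                 object@priors), collapse = ", "), "\n")
  invisible(NULL)
})

#' ClassConditionalModel accessors
#' @param x A [ClassConditionalModel-class].
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
setGeneric("modelClasses", function(x) standardGeneric("modelClasses"))
#' @rdname model-accessors
#' @export
setMethod("modelClasses", "ClassConditionalModel", function(x) x@classes)

#' @rdname model-accessors
#' @export
setGeneric("modelFeatures", function(x) standardGeneric("modelFeatures"))
#' @rdname model-accessors
#' @export
setMethod("modelFeatures", "ClassConditionalModel", function(x) x@features)

#' @rdname model-accessors
#' @export
setGeneric("classPriors", function(x) standardGeneric("classPriors"))
#' @rdname model-accessors
#' @export
setMethod("classPriors", "ClassConditionalModel", function(x) x@priors)

#' Fit class-conditional Gaussians to a labeled cohort
#'
#' Estimates, per class and feature, the sample mean and sample standard
#' deviation (denominator n - 1) over the patients of that class with the
#' feature present. Each SD is floored at 1e-6 times the feature's pooled
#' within-class SD (or, if that pooled SD is itself zero, at 1e-6 times
#' max(1, |grand mean|)), so degenerate columns cannot produce a zero-width
#' density. Priors are uniform or proportional to class counts.
#'
#' @param cohort A labeled [BiomarkerCohort-class].
#' @param features Biomarker names to use (default: the six retained by
#'   screening — atrophy indices and SWI ratios).
#' @param priorMode `"uniform"` (default; the balanced bootstrap exists to
#'   neutralize class imbalance) or `"empirical"` (proportional to counts).
#' @param classes Classes to fit, in order (default PD, MSA, PSP).
#' @return A [ClassConditionalModel-class].
#' @export
#' @examples
#' cohort <- simulateCohort(referenceCohortSpec(), seed = 1)
#' fitClassConditionals(cohort)
fitClassConditionals <- function(cohort,
                                 features = c(atrophyBiomarkers(),
                                              swiBiomarkers()),
                                 priorMode = c("uniform", "empirical"),
                                 classes = diagnosisClasses()) {
  stopifnot(methods::is(cohort, "BiomarkerCohort"))
  priorMode <- match.arg(priorMode)
  m <- biomarkers(cohort)
  missingF <- setdiff(features, rownames(m))
  if (length(missingF))
    .pdmriStop("pdmri_input_error", "cohort lacks feature(s): %s",
               paste(missingF, collapse = ", "))
  dx <- diagnosis(cohort)
  counts <- integer(length(classes)); names(counts) <- classes
  mu <- sdm <- matrix(NA_real_, length(features), length(classes),
                      dimnames = list(features, classes))
  for (cl in classes) {
    sel <- !is.na(dx) & dx == cl
    counts[cl] <- sum(sel)
    for (f in features) {
      v <- m[f, sel]
      v <- v[!is.na(v)]
      if (length(v) < 2L)
        .pdmriStop("pdmri_input_error",
                   "cannot fit class %s, feature %s: fewer than 2 usable values",
                   cl, f)
      mu[f, cl] <- mean(v)
      sdm[f, cl] <- sd(v)
    }
  }
  sdm <- .floorSds(sdm, mu, counts)
  priors <- if (priorMode == "uniform")
    setNames(rep(1 / length(classes), length(classes)), classes)
  else counts / sum(counts)
  classConditionalModel(mu, sdm, priors)
}

# variance floor: 1e-6 x pooled within-class SD per feature, with a scale
# fallback when even the pooled SD vanishes
.floorSds <- function(sdm, mu, counts) {
  w <- pmax(counts - 1L, 1L)
  for (f in rownames(sdm)) {
    pooled <- sqrt(sum(w * sdm[f, ]^2) / sum(w))
    floorv <- if (pooled > 0) 1e-6 * pooled
              else 1e-6 * max(1, abs(sum(counts * mu[f, ]) / sum(counts)))
    sdm[f, ] <- pmax(sdm[f, ], floorv)
  }
  sdm
}

#' Posterior class probabilities for one biomarker panel
#'
#' Computes \eqn{P(c \mid x) \propto \pi_c \prod_f N(x_f; \mu_{cf},
#' \sigma_{cf})} over the model's features present in the panel, in log
#' space, then normalizes. Missing features are skipped — under the
#' independence assumption this marginalizes them out. The predicted class is
#' the argmax, with ties broken in the fixed order PD, MSA, PSP.
#'
#' @param model A [ClassConditionalModel-class].
#' @param panel Named numeric vector of biomarker values (NAs allowed), or a
#'   single-patient [BiomarkerCohort-class] column.
#' @param modelId Label stored in the result (`"I"` by default).
#' @return A [PosteriorResult-class].
#' @export
#' @examples
#' m <- classConditionalModel(
#'   matrix(c(0, 1), 1, 2, dimnames = list("x", c("A", "B"))),
#'   matrix(c(1, 1), 1, 2, dimnames = list("x", c("A", "B"))))
#' posteriorProbs(m, c(x = 0.5))
posteriorProbs <- function(model, panel, modelId = "I") {
  stopifnot(methods::is(model, "ClassConditionalModel"))
  x <- .panelVector(panel)
  feats <- intersect(model@features, names(x)[!is.na(x)])
  if (!length(feats))
    .pdmriStop("pdmri_input_error",
               "panel shares no present feature with the model")
  logp <- .logPosterior(model, x[feats], feats)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  .posteriorResult(prob, model@classes, modelId)
}

.logPosterior <- function(model, xv, feats) {
  vapply(model@classes, function(cl) {
    log(model@priors[[cl]]) +
      sum(dnorm(xv, model@means[feats, cl], model@sds[feats, cl], log = TRUE))
  }, 0)
}

.panelVector <- function(panel) {
  if (methods::is(panel, "BiomarkerCohort")) {
    if (ncol(panel) != 1L)
      .pdmriStop("pdmri_input_error",
                 "pass a single-patient cohort or a named vector")
    return(setNames(biomarkers(panel)[, 1L], rownames(panel)))
  }
  if (is.null(names(panel)))
    .pdmriStop("pdmri_input_error", "panel must be a named numeric vector")
  panel
}

# order probabilities canonically and break argmax ties PD < MSA < PSP
.posteriorResult <- function(prob, classes, modelId) {
  ord <- order(match(classes, c(.CLASSES, setdiff(classes, .CLASSES))))
  prob <- prob[ord]
  methods::new("PosteriorResult", probabilities = prob,
               predicted = names(prob)[which.max(prob)], modelId = modelId)
}

setMethod("show", "PosteriorResult", function(object) {
  cat(sprintf("PosteriorResult (model %s): %s\n", object@modelId,
              paste(sprintf("%s=%.2f%%", names(object@probabilities),
                            100 * object@probabilities), collapse = ", ")))
  cat("  predicted:", object@predicted, "\n")
  invisible(NULL)
})

#' PosteriorResult accessors
#' @param x A [PosteriorResult-class].
#' @name posterior-accessors
NULL

#' @rdname posterior-accessors
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))
#' @rdname posterior-accessors
#' @export
setMethod("probabilities", "PosteriorResult", function(x) x@probabilities)

#' @rdname posterior-accessors
#' @export
setGeneric("predictedClass", function(x) standardGeneric("predictedClass"))
#' @rdname posterior-accessors
#' @export
setMethod("predictedClass", "PosteriorResult", function(x) x@predicted)

#' Classify a panel with decision model I (single multi-class stage)
#'
#' Model I considers all retained biomarkers at once in one three-class
#' Gaussian naive-Bayes posterior over PD, MSA and PSP.
#'
#' @param model A three-class [ClassConditionalModel-class] over the retained
#'   feature panel.
#' @param panel Named numeric vector or single-patient cohort.
#' @return A [PosteriorResult-class] with `modelId = "I"`.
#' @export
classifyModelI <- function(model, panel) {
  if (!setequal(model@classes, .CLASSES))
    .pdmriStop("pdmri_input_error",
               "model I requires the three classes PD, MSA, PSP")
  posteriorProbs(model, panel, modelId = "I")
}

#' Classify a panel with decision model II (two-stage decision tree)
#'
#' Model II chains two binary classifications: stage 1 separates PSP from
#' the rest using the atrophy indices (MRPI, MRPI2, pons-to-midbrain ratio);
#' stage 2 separates MSA from PD using the SWI ratios plus, by default, the
#' atrophy indices again. With \eqn{p_1 = P(\mathrm{PSP})} from stage 1 and
#' \eqn{p_2 = P(\mathrm{MSA})} from stage 2, the combined posterior is
#' \eqn{P(\mathrm{PSP}) = p_1}, \eqn{P(\mathrm{MSA}) = (1 - p_1) p_2},
#' \eqn{P(\mathrm{PD}) = (1 - p_1)(1 - p_2)}.
#'
#' @param stagePsp Binary [ClassConditionalModel-class] with classes
#'   `c("PSP", "rest")` (either order).
#' @param stageMsaPd Binary [ClassConditionalModel-class] with classes
#'   `c("PD", "MSA")` (either order).
#' @param panel Named numeric vector or single-patient cohort.
#' @return A [PosteriorResult-class] with `modelId = "II"`.
#' @seealso [fitModelII()] to fit both stages from a cohort.
#' @export
classifyModelII <- function(stagePsp, stageMsaPd, panel) {
  if (!("PSP" %in% stagePsp@classes) || length(stagePsp@classes) != 2L)
    .pdmriStop("pdmri_input_error",
               "stage 1 must be binary with PSP as one class")
  if (!setequal(stageMsaPd@classes, c("PD", "MSA")))
    .pdmriStop("pdmri_input_error", "stage 2 must be binary over PD and MSA")
  x <- .panelVector(panel)
  p1 <- probabilities(posteriorProbs(stagePsp, x))[["PSP"]]
  p2 <- probabilities(posteriorProbs(stageMsaPd, x))[["MSA"]]
  prob <- c(PD = (1 - p1) * (1 - p2), MSA = (1 - p1) * p2, PSP = p1)
  .posteriorResult(prob, names(prob), "II")
}

#' Fit both stages of decision model II
#'
#' Stage 1 is fitted as PSP vs the pooled PD+MSA patients on the atrophy
#' indices; stage 2 as MSA vs PD (PSP patients excluded) on the SWI ratios
#' plus, by default, the atrophy indices.
#'
#' @param cohort A labeled [BiomarkerCohort-class].
#' @param stage1Features Features for the PSP-vs-rest stage.
#' @param stage2Features Features for the MSA-vs-PD stage.
#' @param priorMode As in [fitClassConditionals()].
#' @return List with elements `stagePsp` and `stageMsaPd`.
#' @export
fitModelII <- function(cohort,
                       stage1Features = atrophyBiomarkers(),
                       stage2Features = c(swiBiomarkers(),
                                          atrophyBiomarkers()),
                       priorMode = c("uniform", "empirical")) {
  priorMode <- match.arg(priorMode)
  dx <- diagnosis(cohort)
  newDx <- ifelse(!is.na(dx) & dx == "PSP", "PSP",
                  ifelse(is.na(dx), NA, "rest"))
  stagePsp <- .fitBinary(biomarkers(cohort), newDx, c("PSP", "rest"),
                         stage1Features, priorMode)
  keep <- !is.na(dx) & dx %in% c("PD", "MSA")
  stageMsaPd <- .fitBinary(biomarkers(cohort)[, keep, drop = FALSE],
                           dx[keep], c("PD", "MSA"), stage2Features,
                           priorMode)
  list(stagePsp = stagePsp, stageMsaPd = stageMsaPd)
}

.fitBinary <- function(m, labels, classes, features, priorMode) {
  missingF <- setdiff(features, rownames(m))
  if (length(missingF))
    .pdmriStop("pdmri_input_error", "cohort lacks feature(s): %s",
               paste(missingF, collapse = ", "))
  counts <- integer(2L); names(counts) <- classes
  mu <- sdm <- matrix(NA_real_, length(features), 2L,
                      dimnames = list(features, classes))
  for (cl in classes) {
    sel <- !is.na(labels) & labels == cl
    counts[cl] <- sum(sel)
    for (f in features) {
      v <- m[f, sel]; v <- v[!is.na(v)]
      if (length(v) < 2L)
        .pdmriStop("pdmri_input_error",
                   "cannot fit class %s, feature %s: fewer than 2 usable values",
                   cl, f)
      mu[f, cl] <- mean(v); sdm[f, cl] <- sd(v)
    }
  }
  sdm <- .floorSds(sdm, mu, counts)
  priors <- if (priorMode == "uniform") setNames(c(0.5, 0.5), classes)
            else counts / sum(counts)
  classConditionalModel(mu, sdm, priors)
}

#' Classify every patient of a cohort
#'
#' Fits the requested decision model on the cohort (resubstitution, the
#' default evaluation protocol) or uses leave-one-out refitting, classifies
#' each patient, and returns a per-patient table in the layout of a clinical
#' posterior report: identifier, final diagnosis, posterior percentages for
#' MSA, PD and PSP (two decimals), predicted class and whether it matches.
#'
#' @param cohort A labeled [BiomarkerCohort-class].
#' @param model `"I"` or `"II"`.
#' @param features Feature panel for model I (stage features of model II are
#'   set by [fitModelII()]).
#' @param priorMode As in [fitClassConditionals()].
#' @param protocol `"resubstitution"` (default) or `"loo"` (leave-one-out:
#'   the model is refitted without the patient being classified).
#' @return Data.frame with columns `patient_id`, `diagnosis`, `msa_pct`,
#'   `pd_pct`, `psp_pct` (numeric percentages), `predicted`, `correct`.
#' @export
#' @examples
#' cohort <- simulateCohort(referenceCohortSpec(), seed = 1)
#' head(classifyCohort(cohort, model = "I"))
classifyCohort <- function(cohort, model = c("I", "II"),
                           features = c(atrophyBiomarkers(), swiBiomarkers()),
                           priorMode = c("uniform", "empirical"),
                           protocol = c("resubstitution", "loo")) {
  model <- match.arg(model)
  priorMode <- match.arg(priorMode)
  protocol <- match.arg(protocol)
  ids <- patientIds(cohort)
  classifyOne <- function(train, i) {
    panel <- setNames(biomarkers(cohort)[, i], rownames(cohort))
    if (model == "I") {
      fit <- fitClassConditionals(train, features = features,
                                  priorMode = priorMode)
      classifyModelI(fit, panel)
    } else {
      fit <- fitModelII(train, priorMode = priorMode)
      classifyModelII(fit$stagePsp, fit$stageMsaPd, panel)
    }
  }
  res <- if (protocol == "resubstitution") {
    lapply(seq_along(ids), classifyOne, train = cohort)
  } else {
    lapply(seq_along(ids), function(i) classifyOne(cohort[, -i], i))
  }
  prob <- t(vapply(res, probabilities, setNames(numeric(3), .CLASSES)))
  dx <- unname(diagnosis(cohort))
  data.frame(patient_id = ids,
             diagnosis = dx,
             msa_pct = round(100 * prob[, "MSA"], 2),
             pd_pct = round(100 * prob[, "PD"], 2),
             psp_pct = round(100 * prob[, "PSP"], 2),
             predicted = vapply(res, predictedClass, ""),
             correct = vapply(res, predictedClass, "") == dx,
             stringsAsFactors = FALSE)
}
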