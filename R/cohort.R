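#' Construct a BiomarkerCohort
#'
#' @param biomarkers Numeric biomarker-by-patient matrix. Rownames must come
#'   from [biomarkerNames()] (any subset, any order is accepted and reordered);
#'   column names are the patient identifiers. `NA` marks a missing biomarker.
#' @param diagnosis Character vector of diagnosis labels (PD/MSA/PSP, `NA`
#'   for unlabeled), one per patient. MSA subtype labels (`MSA-P`, `MSA-C`,
#'   `MSA-u`) are accepted and collapsed to `MSA` with the subtype recorded.
#' @param subtype Optional character vector of MSA subtypes; filled from
#'   `diagnosis` when subtype labels are passed there.
#' @param provenance Free-text provenance (file source or synthetic seed),
#'   stored in `metadata()`.
#' @return A [BiomarkerCohort-class] object.
#' @seealso [readCohort()], [writeCohort()], [simulateCohort()]
#' @export
#' @examples
#' m <- matrix(c(150, 34, 3.5, 0.9, 0.95, 0.92), nrow = 6,
#'             dimnames = list(c("mrpi", "mrpi2", "t1_pm_ratio",
#'                               "swi_put", "swi_stn", "swi_rn"), "pt01"))
#' BiomarkerCohort(m, diagnosis = "PD")
BiomarkerCohort <- function(biomarkers, diagnosis = NULL, subtype = NULL,
                            provenance = "") {
  biomarkers <- as.matrix(biomarkers)
  storage.mode(biomarkers) <- "double"
  n <- ncol(biomarkers)
  if (is.null(colnames(biomarkers)))
    colnames(biomarkers) <- sprintf("patient_%03d", seq_len(n))
  bad <- setdiff(rownames(biomarkers), .BIOMARKERS)
  if (length(bad))
    .pdmriStop("pdmri_input_error", "unknown biomarker(s): %s",
               paste(bad, collapse = ", "))
  biomarkers <- biomarkers[intersect(.BIOMARKERS, rownames(biomarkers)), ,
                           drop = FALSE]
  if (is.null(diagnosis)) diagnosis <- rep(NA_character_, n)
  diagnosis <- as.character(diagnosis)
  if (length(diagnosis) != n)
    .pdmriStop("pdmri_input_error", "diagnosis length must match patient count")
  if (is.null(subtype)) subtype <- rep(NA_character_, n)
  subtype <- as.character(subtype)
  # accept subtype labels given directly as the diagnosis
  isSub <- !is.na(diagnosis) & diagnosis %in% .MSA_SUBTYPES
  subtype[isSub] <- diagnosis[isSub]
  diagnosis[isSub] <- "MSA"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(biomarkers = biomarkers),
    colData = S4Vectors::DataFrame(diagnosis = diagnosis, subtype = subtype,
                                   row.names = colnames(biomarkers)),
    metadata = list(provenance = provenance))
  methods::new("BiomarkerCohort", se)
}

#' Cohort accessors
#'
#' `biomarkers()` returns the biomarker-by-patient matrix; `diagnosis()` the
#' per-patient diagnosis labels (MSA subtypes already collapsed);
#' `msaSubtype()` the recorded MSA subtype (`NA` elsewhere); `patientIds()`
#' the identifiers; `provenance()` the free-text provenance; `groupSizes()`
#' the per-diagnosis patient counts.
#'
#' @param x A [BiomarkerCohort-class].
#' @return See each accessor's description.
#' @name cohort-accessors
#' @aliases biomarkers diagnosis msaSubtype patientIds provenance groupSizes
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("biomarkers", function(x) standardGeneric("biomarkers"))
#' @rdname cohort-accessors
#' @export
setMethod("biomarkers", "BiomarkerCohort", function(x)
  SummarizedExperiment::assay(x, "biomarkers"))

#' @rdname cohort-accessors
#' @export
setGeneric("diagnosis", function(x) standardGeneric("diagnosis"))
#' @rdname cohort-accessors
#' @export
setMethod("diagnosis", "BiomarkerCohort", function(x)
  setNames(as.character(SummarizedExperiment::colData(x)$diagnosis),
           colnames(x)))

#' @rdname cohort-accessors
#' @export
setGeneric("msaSubtype", function(x) standardGeneric("msaSubtype"))
#' @rdname cohort-accessors
#' @export
setMethod("msaSubtype", "BiomarkerCohort", function(x)
  setNames(as.character(SummarizedExperiment::colData(x)$subtype),
           colnames(x)))

#' @rdname cohort-accessors
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))
#' @rdname cohort-accessors
#' @export
setMethod("patientIds", "BiomarkerCohort", function(x) colnames(x))

#' @rdname cohort-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname cohort-accessors
#' @export
setMethod("provenance", "BiomarkerCohort", function(x)
  S4Vectors::metadata(x)$provenance)

#' @rdname cohort-accessors
#' @export
setGeneric("groupSizes", function(x) standardGeneric("groupSizes"))
#' @rdname cohort-accessors
#' @export
setMethod("groupSizes", "BiomarkerCohort", function(x) {
  dx <- factor(diagnosis(x), levels = .CLASSES)
  table(diagnosis = dx)
})

setMethod("show", "BiomarkerCohort", function(object) {
  dx <- diagnosis(object)
  counts <- table(factor(dx, levels = .CLASSES), useNA = "ifany")
  cat(sprintf("BiomarkerCohort: %d patients x %d biomarkers\n",
              ncol(object), nrow(object)))
  cat("  groups:", paste(sprintf("%s=%d", names(counts), counts),
                         collapse = ", "), "\n")
  miss <- sum(is.na(biomarkers(object)))
  if (miss) cat(sprintf("  missing values: %d\n", miss))
  prov <- provenance(object)
  if (!is.null(prov) && nzchar(prov)) cat("  provenance:", prov, "\n")
  invisible(NULL)
})

#' Read and write cohort tables
#'
#' The on-disk format is delimited text (comma-separated, UTF-8, header row)
#' with columns `patient_id`, `diagnosis`, `subtype`, then the eleven
#' biomarker columns of [biomarkerNames()]; an empty cell is a missing value.
#' `writeCohort()` prints numbers with 17 significant digits so that a
#' write/read round trip reproduces every value bit-exactly. `readCohort()`
#' also accepts the raw-measurement schema (see [derivePanels()]): if no
#' biomarker column is present but raw measurement columns are, the panel is
#' derived on the fly.
#'
#' @param x A [BiomarkerCohort-class].
#' @param file Path to a CSV file.
#' @param faScale Passed to [derivePanels()] when reading raw measurements.
#' @return `readCohort()` returns a [BiomarkerCohort-class]; `writeCohort()`
#'   returns `file` invisibly.
#' @export
readCohort <- function(file, faScale = c("printed", "native")) {
  if (!file.exists(file))
    .pdmriStop("pdmri_input_error", "cohort file not found: %s", file)
  df <- read.csv(file, stringsAsFactors = FALSE)
  if (!("patient_id" %in% names(df)))
    .pdmriStop("pdmri_input_error",
               "cohort file %s is missing required column 'patient_id'", file)
  if (!any(.BIOMARKERS %in% names(df))) {
    rawCols <- c("pons_area", "midbrain_area", "swi_wm_mean")
    if (any(rawCols %in% names(df)))
      df <- derivePanels(df, faScale = faScale)
    else
      .pdmriStop("pdmri_input_error",
                 "cohort file %s has neither biomarker nor raw measurement columns",
                 file)
  }
  cohortFromPanels(df, provenance = paste0("file:", file))
}

#' @rdname readCohort
#' @export
writeCohort <- function(x, file) {
  stopifnot(methods::is(x, "BiomarkerCohort"))
  m <- biomarkers(x)
  full <- matrix(NA_real_, length(.BIOMARKERS), ncol(m),
                 dimnames = list(.BIOMARKERS, colnames(m)))
  full[rownames(m), ] <- m
  df <- data.frame(patient_id = colnames(m),
                   diagnosis = unname(diagnosis(x)),
                   subtype = unname(msaSubtype(x)),
                   stringsAsFactors = FALSE)
  for (b in .BIOMARKERS)
    df[[b]] <- sprintf("%.17g", full[b, ])
  df[df == "NA"] <- ""
  write.csv(df, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

#' Build a cohort from a panel data.frame
#'
#' @param df Data.frame with `patient_id`, optional `diagnosis`/`subtype`,
#'   and any subset of the biomarker columns.
#' @param provenance Free-text provenance.
#' @return A [BiomarkerCohort-class].
#' @export
cohortFromPanels <- function(df, provenance = "") {
  stopifnot(is.data.frame(df))
  if (!("patient_id" %in% names(df)))
    .pdmriStop("pdmri_input_error", "panel table is missing 'patient_id'")
  present <- intersect(.BIOMARKERS, names(df))
  if (!length(present))
    .pdmriStop("pdmri_input_error", "panel table has no biomarker columns")
  m <- t(as.matrix(as.data.frame(lapply(df[present], as.numeric))))
  rownames(m) <- present
  colnames(m) <- as.character(df$patient_id)
  dx <- if ("diagnosis" %in% names(df)) df$diagnosis else NULL
  st <- if ("subtype" %in% names(df)) df$subtype else NULL
  if (!is.null(st)) st[!is.na(st) & !nzchar(st)] <- NA_character_
  if (!is.null(dx)) dx[!is.na(dx) & !nzchar(dx)] <- NA_character_
  BiomarkerCohort(m, diagnosis = dx, subtype = st, provenance = provenance)
}
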