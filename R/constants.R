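#' Biomarker and class vocabulary
#'
#' Canonical names used throughout the package. `biomarkerNames()` returns the
#' eleven biomarkers in report order (atrophy indices, then diffusion-tensor
#' fractional anisotropy, then normalized susceptibility-weighted signal);
#' `diagnosisClasses()` returns the three diagnostic classes in the fixed
#' order used for tie-breaking (PD before MSA before PSP).
#'
#' @return Character vector of names.
#' @export
#' @examples
#' biomarkerNames()
#' diagnosisClasses()
biomarkerNames <- function() .BIOMARKERS

#' @rdname biomarkerNames
#' @export
diagnosisClasses <- function() .CLASSES

#' @rdname biomarkerNames
#' @export
atrophyBiomarkers <- function() .ATROPHY

#' @rdname biomarkerNames
#' @export
swiBiomarkers <- function() .SWI

#' @rdname biomarkerNames
#' @export
faBiomarkers <- function() .FA

.BIOMARKERS <- c("mrpi", "mrpi2", "t1_pm_ratio",
                 "fa_scp", "fa_cb", "fa_mcp", "fa_stn", "fa_put",
                 "swi_put", "swi_stn", "swi_rn")

.CLASSES <- c("PD", "MSA", "PSP")

.MSA_SUBTYPES <- c("MSA-P", "MSA-C", "MSA-u")

.ATROPHY <- c("mrpi", "mrpi2", "t1_pm_ratio")
.SWI     <- c("swi_put", "swi_stn", "swi_rn")
.FA      <- c("fa_scp", "fa_cb", "fa_mcp", "fa_stn", "fa_put")

# order in which retained biomarkers are reported after screening
.SELECTION_ORDER <- c(.ATROPHY, .SWI, .FA)

# FA is stored on the x1000 scale used in published group summaries; ratio
# biomarkers (everything else) must be strictly positive when present
.RATIO_BIOMARKERS <- c(.ATROPHY, .SWI)

# structured condition helper: class is one of pdmri_config_error,
# pdmri_input_error, pdmri_numeric_error (pipeline maps these to exit codes)
.pdmriStop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "pdmri_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
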