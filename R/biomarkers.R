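#' Brainstem atrophy indices from geometric measurements
#'
#' `computePMRatio()` is the pons-to-midbrain ratio from midsagittal areas.
#' `computeMRPI()` is the Magnetic Resonance Parkinsonian Index: the
#' pons-to-midbrain ratio multiplied by the ratio of the mean middle
#' cerebellar peduncle (MCP) width to the mean superior cerebellar peduncle
#' (SCP) width, where "mean" is the arithmetic mean of the left and right
#' widths. `computeMRPI2()` multiplies an MRPI value by the ratio of the
#' third-ventricle width to the frontal-horn width. All three are
#' dimensionless and invariant under a common rescaling of all lengths and
#' areas; MRPI and MRPI2 are elevated in progressive supranuclear palsy.
#'
#' @param g A list or data.frame of geometric measurements with fields
#'   `pons_area`, `midbrain_area` (mm^2), `mcp_width_left`,
#'   `mcp_width_right`, `scp_width_left`, `scp_width_right`,
#'   `third_ventricle_width`, `frontal_horns_width` (mm). Only the fields a
#'   given index uses need be present; all used fields must be strictly
#'   positive. Vectorized over rows/elements.
#' @param mrpi Numeric MRPI value(s), as returned by `computeMRPI()`.
#' @return Numeric vector of index values.
#' @seealso [derivePanels()] to derive a full biomarker panel table.
#' @export
#' @examples
#' g <- list(pons_area = 620, midbrain_area = 124,
#'           mcp_width_left = 8.8, mcp_width_right = 8.4,
#'           scp_width_left = 2.2, scp_width_right = 1.8,
#'           third_ventricle_width = 10.5, frontal_horns_width = 37.5)
#' computePMRatio(g)
#' computeMRPI(g)
#' computeMRPI2(computeMRPI(g), g)
computeMRPI <- function(g) {
  .checkPositive(g, c("pons_area", "midbrain_area", "mcp_width_left",
                      "mcp_width_right", "scp_width_left", "scp_width_right"))
  mcp <- (g$mcp_width_left + g$mcp_width_right) / 2
  scp <- (g$scp_width_left + g$scp_width_right) / 2
  (g$pons_area / g$midbrain_area) * (mcp / scp)
}

#' @rdname computeMRPI
#' @export
computePMRatio <- function(g) {
  .checkPositive(g, c("pons_area", "midbrain_area"))
  g$pons_area / g$midbrain_area
}

#' @rdname computeMRPI
#' @export
computeMRPI2 <- function(mrpi, g) {
  if (any(mrpi <= 0 | is.nan(mrpi) | is.infinite(mrpi), na.rm = TRUE))
    .pdmriStop("pdmri_input_error", "invalid measurement: mrpi must be > 0")
  .checkPositive(g, c("third_ventricle_width", "frontal_horns_width"))
  mrpi * g$third_ventricle_width / g$frontal_horns_width
}

# NA raw values propagate to NA biomarkers (missing, never zero); anything
# else non-positive or non-finite is a hard error naming the field
.checkPositive <- function(g, fields) {
  for (f in fields) {
    v <- g[[f]]
    if (is.null(v))
      .pdmriStop("pdmri_input_error", "invalid measurement: field '%s' is missing", f)
    if (any(v <= 0 | is.nan(v) | is.infinite(v), na.rm = TRUE))
      .pdmriStop("pdmri_input_error",
                 "invalid measurement: field '%s' must be strictly positive", f)
  }
  invisible(TRUE)
}

#' Normalize a susceptibility-weighted signal to white matter
#'
#' Divides the mean SWI signal of a region of interest by the mean SWI signal
#' in white matter from the same scan. Values below 1 indicate signal lower
#' than white matter, i.e. increased mineralization (iron deposition) in the
#' region. The ratio is homogeneous of degree zero: a common gain applied to
#' both signals cancels.
#'
#' @param roiMean Nonnegative mean signal in the region of interest.
#' @param wmMean Strictly positive mean signal in white matter.
#' @return `roiMean / wmMean`, vectorized.
#' @export
#' @examples
#' normalizeSWI(370, 400)
normalizeSWI <- function(roiMean, wmMean) {
  if (any(wmMean <= 0 | is.nan(wmMean) | is.infinite(wmMean), na.rm = TRUE))
    .pdmriStop("pdmri_input_error",
               "invalid measurement: field 'swi_wm_mean' must be strictly positive")
  if (any(roiMean < 0 | is.nan(roiMean) | is.infinite(roiMean), na.rm = TRUE))
    .pdmriStop("pdmri_input_error",
               "invalid measurement: ROI mean signal must be nonnegative")
  roiMean / wmMean
}

#' Mean of values inside a region mask
#'
#' Arithmetic mean of `values` at the positions where `mask` is `TRUE` —
#' the primitive behind region-averaged biomarkers such as mean fractional
#' anisotropy within a segmented peduncle.
#'
#' @param values Numeric vector (e.g. voxel values).
#' @param mask Logical vector of the same length; at least one `TRUE`.
#' @return The mean of the masked values.
#' @export
#' @examples
#' meanInMask(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, FALSE))
meanInMask <- function(values, mask) {
  if (length(values) != length(mask))
    .pdmriStop("pdmri_input_error",
               "values (%d) and mask (%d) lengths differ",
               length(values), length(mask))
  if (!is.logical(mask))
    .pdmriStop("pdmri_input_error", "mask must be logical")
  if (!any(mask))
    .pdmriStop("pdmri_input_error", "empty region: mask selects no values")
  mean(values[mask])
}

#' Derive biomarker panels from raw measurement tables
#'
#' Accepts a per-patient table of raw geometric and signal measurements and
#' emits the derived biomarker panel columns. Geometric columns (all in mm or
#' mm^2): `pons_area`, `midbrain_area`, `mcp_width_left`, `mcp_width_right`,
#' `scp_width_left`, `scp_width_right`, `third_ventricle_width`,
#' `frontal_horns_width`. Signal columns: `swi_put_mean`, `swi_stn_mean`,
#' `swi_rn_mean`, `swi_wm_mean` (arbitrary units, white matter > 0) and
#' `fa_scp`, `fa_cb`, `fa_mcp`, `fa_stn`, `fa_put`. Fractional anisotropy is
#' stored on the x1000 scale used in published group summaries; set
#' `faScale = "native"` if the inputs are on the native [0, 1] scale to have
#' them converted.
#'
#' Any raw column may be absent, in which case the biomarkers that need it
#' are emitted as `NA` (missing), never as zero. Identifier and label columns
#' (`patient_id`, `diagnosis`, `subtype`) are passed through when present.
#'
#' @param raw A data.frame of raw measurements, one row per patient.
#' @param faScale `"printed"` (default; values already on the x1000 scale) or
#'   `"native"` (values in [0, 1], multiplied by 1000).
#' @return A data.frame with `patient_id`, `diagnosis`, `subtype` (when
#'   available) and the eleven biomarker columns of [biomarkerNames()].
#' @export
derivePanels <- function(raw, faScale = c("printed", "native")) {
  faScale <- match.arg(faScale)
  stopifnot(is.data.frame(raw))
  n <- nrow(raw)
  out <- data.frame(row.names = seq_len(n))
  for (col in c("patient_id", "diagnosis", "subtype"))
    if (col %in% names(raw)) out[[col]] <- raw[[col]]

  geomCols <- c("pons_area", "midbrain_area", "mcp_width_left",
                "mcp_width_right", "scp_width_left", "scp_width_right")
  haveGeom <- all(geomCols %in% names(raw))
  havePM <- all(c("pons_area", "midbrain_area") %in% names(raw))
  haveVent <- all(c("third_ventricle_width", "frontal_horns_width") %in% names(raw))

  out$mrpi <- if (haveGeom) computeMRPI(raw) else NA_real_
  out$mrpi2 <- if (haveGeom && haveVent) computeMRPI2(out$mrpi, raw) else NA_real_
  out$t1_pm_ratio <- if (havePM) computePMRatio(raw) else NA_real_

  for (f in .FA) {
    if (f %in% names(raw)) {
      v <- raw[[f]]
      if (any(v < 0, na.rm = TRUE))
        .pdmriStop("pdmri_input_error",
                   "invalid measurement: '%s' must be nonnegative", f)
      out[[f]] <- if (faScale == "native") v * 1000 else v
    } else out[[f]] <- NA_real_
  }

  haveWM <- "swi_wm_mean" %in% names(raw)
  for (s in .SWI) {
    rawCol <- paste0(s, "_mean")
    out[[s]] <- if (haveWM && rawCol %in% names(raw))
      normalizeSWI(raw[[rawCol]], raw$swi_wm_mean) else NA_real_
  }
  out
}
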