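#' One-way ANOVA across diagnosis groups
#'
#' `anovaOneway()` runs the classical fixed-effects one-way analysis of
#' variance on raw per-group values (delegating to
#' [stats::oneway.test()] with `var.equal = TRUE`). `anovaFromSummary()`
#' computes the identical F statistic directly from per-group summary
#' statistics (n, mean, SD):
#' \deqn{F = \frac{\sum_g n_g (\bar x_g - \bar x)^2 / (k - 1)}
#'            {\sum_g (n_g - 1) s_g^2 / (N - k)}}
#' with \eqn{\bar x} the grand mean. The summary form lets published
#' group-summary tables be screened without patient-level data; the two
#' routes agree to machine precision on exact summaries.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 values, not all values identical).
#' @return An [AnovaResult-class].
#' @seealso [selectBiomarkers()], [screenBiomarkers()]
#' @export
#' @examples
#' anovaFromSummary(n = c(38, 25, 10),
#'                  means = c(143.054, 142.024, 210.761),
#'                  sds = c(36.019, 48.005, 56.858))
anovaOneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    .pdmriStop("pdmri_input_error", "need at least two groups")
  n <- lengths(groups)
  if (any(n < 2L))
    .pdmriStop("pdmri_input_error", "every group needs at least two values")
  x <- unlist(groups, use.names = FALSE)
  if (!all(is.finite(x)))
    .pdmriStop("pdmri_input_error", "group values must be finite")
  if (all(x == x[1L]))
    .pdmriStop("pdmri_numeric_error",
               "degenerate variance: all values are identical")
  g <- factor(rep(seq_along(groups), times = n))
  ow <- oneway.test(x ~ g, var.equal = TRUE)
  .anovaResult(unname(ow$statistic), length(groups) - 1L,
               length(x) - length(groups), unname(ow$p.value))
}

#' @rdname anovaOneway
#' @param n,means,sds Numeric vectors of per-group sizes, means and sample
#'   standard deviations (denominator n - 1), in the same group order.
#' @export
anovaFromSummary <- function(n, means, sds) {
  if (length(n) < 2L || length(means) != length(n) || length(sds) != length(n))
    .pdmriStop("pdmri_input_error",
               "need matching n, means, sds for at least two groups")
  if (any(sds < 0)) .pdmriStop("pdmri_input_error", "sds must be nonnegative")
  k <- length(n)
  N <- sum(n)
  ssWithin <- sum((n - 1) * sds^2)
  if (ssWithin <= 0)
    .pdmriStop("pdmri_numeric_error",
               "degenerate variance: pooled within-group variance is zero")
  grand <- sum(n * means) / N
  msBetween <- sum(n * (means - grand)^2) / (k - 1)
  msWithin <- ssWithin / (N - k)
  f <- msBetween / msWithin
  .anovaResult(f, k - 1L, as.integer(N - k),
               pf(f, k - 1, N - k, lower.tail = FALSE))
}

.anovaResult <- function(f, df1, df2, p) {
  methods::new("AnovaResult", fValue = f, dfBetween = as.integer(df1),
               dfWithin = as.integer(df2), pValue = p,
               pDisplay = formatPValue(p))
}

#' Render a p-value the way screening tables print it
#'
#' Values at or above `cut` are printed to two decimals; smaller values are
#' shown as a power-of-ten upper bound (e.g. `1.5e-5` becomes `"<10^-4"`),
#' keeping the raw float available in the result object.
#'
#' @param p Numeric p-value(s).
#' @param cut Threshold below which the bound notation is used.
#' @return Character vector.
#' @export
#' @examples
#' formatPValue(c(0.13, 3.2e-5))
formatPValue <- function(p, cut = 1e-3) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi <= 0) return("<10^-300")
    if (pi >= cut) sprintf("%.2f", pi)
    else sprintf("<10^-%d", -ceiling(log10(pi)))
  }, character(1))
}

#' AnovaResult accessors
#' @param x An [AnovaResult-class].
#' @return `fValue()` the F statistic; `pValue()` the upper-tail p-value;
#'   `degreesOfFreedom()` c(between, within).
#' @name anova-accessors
NULL

#' @rdname anova-accessors
#' @export
setGeneric("fValue", function(x) standardGeneric("fValue"))
#' @rdname anova-accessors
#' @export
setMethod("fValue", "AnovaResult", function(x) x@fValue)

#' @rdname anova-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname anova-accessors
#' @export
setMethod("pValue", "AnovaResult", function(x) x@pValue)

#' @rdname anova-accessors
#' @export
setGeneric("degreesOfFreedom", function(x) standardGeneric("degreesOfFreedom"))
#' @rdname anova-accessors
#' @export
setMethod("degreesOfFreedom", "AnovaResult", function(x)
  c(between = x@dfBetween, within = x@dfWithin))

setMethod("show", "AnovaResult", function(object) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %s (%.4g)\n",
              object@dfBetween, object@dfWithin, object@fValue,
              object@pDisplay, object@pValue))
  invisible(NULL)
})

#' Screen biomarkers across diagnosis groups
#'
#' Runs the one-way ANOVA for each biomarker and assembles a screening table
#' in the shape of a published group-comparison table: per-group
#' `mean (sd)`, F, p, and — when F is significant at `alpha` — the
#' descending ordering of the group means as a descriptive label (no formal
#' post-hoc test is applied).
#'
#' `screenBiomarkers()` works on a patient-level [BiomarkerCohort-class];
#' `screenSummary()` works on a long-format summary table such as
#' [referenceGroupSummary()].
#'
#' @param cohort A labeled [BiomarkerCohort-class].
#' @param summary Data.frame with columns biomarker, group, n, mean, sd.
#' @param alpha Significance level for the descriptive ordering column.
#' @return Data.frame with one row per biomarker: `biomarker`, per-group
#'   `mean_<class>`/`sd_<class>` (and `n_<class>`), `f_value`, `df_between`,
#'   `df_within`, `p_value`, `p_display`, `ordering`.
#' @export
screenBiomarkers <- function(cohort, alpha = 0.05) {
  stopifnot(methods::is(cohort, "BiomarkerCohort"))
  dx <- diagnosis(cohort)
  m <- biomarkers(cohort)
  classes <- intersect(.CLASSES, unique(dx[!is.na(dx)]))
  rows <- lapply(rownames(m), function(b) {
    groups <- lapply(classes, function(cl) {
      v <- m[b, !is.na(dx) & dx == cl]
      v[!is.na(v)]
    })
    names(groups) <- classes
    summ <- data.frame(biomarker = b, group = classes,
                       n = lengths(groups),
                       mean = vapply(groups, mean, 0),
                       sd = vapply(groups, sd, 0))
    list(summ = summ, res = anovaOneway(groups))
  })
  summary <- do.call(rbind, lapply(rows, `[[`, "summ"))
  .screenTable(summary, lapply(rows, `[[`, "res"),
               unique(summary$biomarker), alpha)
}

#' @rdname screenBiomarkers
#' @export
screenSummary <- function(summary, alpha = 0.05) {
  need <- c("biomarker", "group", "n", "mean", "sd")
  if (!all(need %in% names(summary)))
    .pdmriStop("pdmri_input_error",
               "summary needs columns: %s", paste(need, collapse = ", "))
  bms <- unique(summary$biomarker)
  res <- lapply(bms, function(b) {
    s <- summary[summary$biomarker == b, ]
    anovaFromSummary(s$n, s$mean, s$sd)
  })
  .screenTable(summary, res, bms, alpha)
}

.screenTable <- function(summary, results, bms, alpha) {
  classes <- unique(summary$group)
  out <- data.frame(biomarker = bms, stringsAsFactors = FALSE)
  for (cl in classes) {
    s <- summary[summary$group == cl, ]
    i <- match(bms, s$biomarker)
    out[[paste0("n_", cl)]] <- s$n[i]
    out[[paste0("mean_", cl)]] <- s$mean[i]
    out[[paste0("sd_", cl)]] <- s$sd[i]
  }
  out$f_value <- vapply(results, fValue, 0)
  dfs <- vapply(results, degreesOfFreedom, c(between = 0L, within = 0L))
  out$df_between <- dfs["between", ]
  out$df_within <- dfs["within", ]
  out$p_value <- vapply(results, pValue, 0)
  out$p_display <- formatPValue(out$p_value)
  out$ordering <- vapply(seq_along(bms), function(i) {
    if (out$p_value[i] >= alpha) return("-")
    mu <- vapply(classes, function(cl) out[[paste0("mean_", cl)]][i], 0)
    paste(names(sort(mu, decreasing = TRUE)), collapse = " > ")
  }, character(1))
  rownames(out) <- NULL
  out
}

#' Select biomarkers with significant group differences
#'
#' Keeps the biomarkers whose ANOVA p-value is below `alpha`, returned in a
#' fixed canonical order (atrophy indices, normalized SWI, fractional
#' anisotropy). With the published group summaries and `alpha = 0.05`, this
#' retains the three atrophy indices and the three SWI ratios and drops all
#' five FA biomarkers — the feature panel used by the decision models.
#'
#' @param results Named list of [AnovaResult-class] (names are biomarkers),
#'   or a screening table from [screenBiomarkers()]/[screenSummary()].
#' @param alpha Significance level in (0, 1).
#' @return Character vector of retained biomarker names.
#' @export
#' @examples
#' tab <- screenSummary(referenceGroupSummary())
#' selectBiomarkers(tab)
selectBiomarkers <- function(results, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    .pdmriStop("pdmri_config_error", "alpha must lie in (0, 1)")
  if (is.data.frame(results)) {
    p <- setNames(results$p_value, results$biomarker)
  } else {
    if (!length(results))
      .pdmriStop("pdmri_input_error", "no ANOVA results supplied")
    p <- vapply(results, pValue, 0)
  }
  keep <- names(p)[p < alpha]
  keep[order(match(keep, .SELECTION_ORDER))]
}
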