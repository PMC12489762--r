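#' Synthetic cohort specification
#'
#' `cohortSpec()` assembles a [CohortSpec-class] from per-group sizes and
#' per-(biomarker, group) Gaussian marginals. `referenceCohortSpec()` returns
#' the default specification: the published per-group means and standard
#' deviations of all eleven biomarkers with group sizes PD = 38, MSA = 25,
#' PSP = 10 ([referenceGroupSummary()]), independent marginals and a
#' positivity floor of 0 (every biomarker here is a positive ratio or a
#' nonnegative anisotropy). Pre-truncation parameters are calibrated so the
#' truncated marginals deliver the specified means and SDs exactly; see
#' [simulateCohort()].
#'
#' @param groupSizes Named positive integers (names from
#'   [diagnosisClasses()]).
#' @param means,sds Biomarker-by-group numeric matrices with matching
#'   dimnames; SDs nonnegative.
#' @param correlation Optional named list (per group) of correlation matrices
#'   over the biomarkers (unit diagonal, symmetric, positive semidefinite).
#'   Empty list = independent marginals.
#' @param positivityFloor Draws with any biomarker at or below this value are
#'   rejected and redrawn.
#' @return A [CohortSpec-class].
#' @export
#' @examples
#' spec <- referenceCohortSpec()
#' spec
cohortSpec <- function(groupSizes, means, sds, correlation = list(),
                       positivityFloor = 0) {
  gs <- as.integer(groupSizes)
  names(gs) <- names(groupSizes)
  means <- as.matrix(means); sds <- as.matrix(sds)
  methods::new("CohortSpec", groupSizes = gs, means = means, sds = sds,
               correlation = correlation,
               positivityFloor = as.numeric(positivityFloor))
}

#' @rdname cohortSpec
#' @export
referenceCohortSpec <- function(groupSizes = .REF_GROUP_N) {
  cohortSpec(groupSizes, .REF_GROUP_MEAN[, names(groupSizes), drop = FALSE],
             .REF_GROUP_SD[, names(groupSizes), drop = FALSE])
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d biomarkers x %d groups\n",
              nrow(object@means), length(object@groupSizes)))
  cat("  group sizes:",
      paste(sprintf("%s=%d", names(object@groupSizes), object@groupSizes),
            collapse = ", "), "\n")
  cat("  correlation:",
      if (length(object@correlation)) "per-group matrices" else "independent",
      "\n")
  cat("  positivity floor:", object@positivityFloor, "\n")
  invisible(NULL)
})

#' Spec serialization
#'
#' Writes/reads a [CohortSpec-class] as JSON or YAML (chosen by file
#' extension), mirroring the spec's slots.
#'
#' @param spec A [CohortSpec-class].
#' @param file Path ending in `.json`, `.yaml` or `.yml`.
#' @return `readCohortSpec()` returns a [CohortSpec-class];
#'   `writeCohortSpec()` returns `file` invisibly.
#' @export
writeCohortSpec <- function(spec, file) {
  stopifnot(methods::is(spec, "CohortSpec"))
  x <- list(
    group_sizes = as.list(setNames(as.integer(spec@groupSizes),
                                   names(spec@groupSizes))),
    biomarkers = rownames(spec@means),
    means = apply(spec@means, 2, identity, simplify = FALSE),
    sds = apply(spec@sds, 2, identity, simplify = FALSE),
    correlation = lapply(spec@correlation, function(m) apply(m, 1, identity,
                                                             simplify = FALSE)),
    positivity_floor = spec@positivityFloor)
  if (grepl("\\.json$", file, ignore.case = TRUE))
    jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA)
  else
    yaml::write_yaml(x, file)
  invisible(file)
}

#' @rdname writeCohortSpec
#' @export
readCohortSpec <- function(file) {
  if (!file.exists(file))
    .pdmriStop("pdmri_config_error", "spec file not found: %s", file)
  x <- if (grepl("\\.json$", file, ignore.case = TRUE))
    jsonlite::read_json(file, simplifyVector = TRUE)
  else
    yaml::read_yaml(file)
  bm <- x$biomarkers
  toMat <- function(lst) {
    m <- do.call(cbind, lapply(lst, as.numeric))
    rownames(m) <- bm
    m
  }
  corr <- lapply(x$correlation, function(g) {
    m <- do.call(rbind, lapply(g, as.numeric))
    dimnames(m) <- list(bm, bm)
    m
  })
  cohortSpec(unlist(x$group_sizes), toMat(x$means), toMat(x$sds),
             correlation = corr,
             positivityFloor = x$positivity_floor %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a labeled synthetic cohort
#'
#' Draws each group's panels from a (multivariate) normal with the spec's
#' marginals and correlation, then rejects and redraws any panel with a
#' biomarker at or below the positivity floor. So that rejection does not
#' bias the delivered moments, each biomarker's pre-truncation (mean, SD) is
#' solved such that the left-truncated normal has exactly the specified
#' mean and SD (a marginal approximation when a correlation matrix makes
#' rejection a joint event). Each group uses its own
#' random stream, derived deterministically from the root seed and the group
#' name, so adding or resizing one group never perturbs the draws of the
#' others. The result is bit-reproducible given `(spec, seed)`.
#'
#' @param spec A [CohortSpec-class].
#' @param seed Single integer root seed.
#' @return A [BiomarkerCohort-class]; patient identifiers are
#'   `<group>_<index>` and provenance records the seed.
#' @export
#' @examples
#' cohort <- simulateCohort(referenceCohortSpec(), seed = 1)
#' groupSizes(cohort)
simulateCohort <- function(spec, seed) {
  stopifnot(methods::is(spec, "CohortSpec"))
  methods::validObject(spec)
  seed <- as.integer(seed)
  groups <- names(spec@groupSizes)
  panels <- vector("list", length(groups))
  names(panels) <- groups
  for (g in groups) {
    set.seed(.groupSeed(seed, g))
    panels[[g]] <- .drawGroup(spec, g)
  }
  m <- t(do.call(rbind, panels))
  rownames(m) <- rownames(spec@means)
  dx <- rep(groups, times = spec@groupSizes[groups])
  colnames(m) <- sprintf("%s_%03d", dx,
                         unlist(lapply(spec@groupSizes[groups], seq_len)))
  BiomarkerCohort(m, diagnosis = dx,
                  provenance = sprintf("synthetic(seed=%d)", seed))
}

# deterministic per-group stream: fold the group name into the root seed,
# kept within 32-bit integer range
.groupSeed <- function(seed, group) {
  h <- sum(utf8ToInt(group) * seq_along(utf8ToInt(group)) * 131L)
  as.integer((as.double(seed) * 7919 + h) %% 2147483647)
}

# Pre-truncation parameters (muStar, sdStar) of a normal left-truncated at
# `lower` whose truncated mean/SD equal the targets. Solved per biomarker so
# that positivity rejection does not bias the delivered marginals; when the
# target mean sits more than 8 SDs above the floor the adjustment is below
# machine noise and is skipped.
.truncnormParams <- function(m, s, lower) {
  if (s <= 0 || !is.finite(m) || (m - lower) / s > 8)
    return(c(mu = m, sd = s))
  if (m <= lower)
    return(c(mu = m, sd = s))  # infeasible target; rejection loop will report
  lambda <- function(a) dnorm(a) / pnorm(a, lower.tail = FALSE)
  gap <- function(a) {
    l <- lambda(a)
    delta <- l * (l - a)
    s * (l - a) / sqrt(max(1 - delta, 1e-12)) - (m - lower)
  }
  a <- tryCatch(stats::uniroot(gap, c(-40, 7.5), tol = 1e-12)$root,
                error = function(e) NA_real_)
  if (is.na(a)) return(c(mu = m, sd = s))
  l <- lambda(a)
  sdStar <- s / sqrt(max(1 - l * (l - a), 1e-12))
  c(mu = lower - a * sdStar, sd = sdStar)   # a = (lower - mu)/sd

}

.drawGroup <- function(spec, g) {
  n <- spec@groupSizes[[g]]
  target_mu <- spec@means[, g]
  target_sd <- spec@sds[, g]
  p <- length(target_mu)
  R <- spec@correlation[[g]]
  floorv <- spec@positivityFloor
  adj <- vapply(seq_len(p), function(i)
    .truncnormParams(target_mu[i], target_sd[i], floorv), c(mu = 0, sd = 0))
  mu <- adj["mu", ]
  sdv <- adj["sd", ]
  draw <- function(k) {
    if (is.null(R)) {
      matrix(rnorm(k * p, mean = rep(mu, each = k),
                   sd = rep(sdv, each = k)), nrow = k)
    } else {
      Sigma <- diag(sdv, p) %*% R %*% diag(sdv, p)
      MASS::mvrnorm(k, mu, Sigma)
    }
  }
  out <- matrix(NA_real_, n, p)
  need <- n
  attempts <- 0L
  drawn <- 0L
  accepted <- 0L
  while (need > 0L) {
    x <- draw(need)
    if (is.vector(x)) x <- matrix(x, nrow = 1L)
    ok <- rowSums(x <= floorv) == 0L
    drawn <- drawn + need
    k <- sum(ok)
    if (k) {
      out[(accepted + 1L):(accepted + k), ] <- x[ok, , drop = FALSE]
      accepted <- accepted + k
    }
    need <- n - accepted
    attempts <- attempts + 1L
    if (attempts >= 20L && accepted / drawn < 0.01) {
      worst <- which.max(pnorm(floorv, mu, sdv))
      .pdmriStop("pdmri_numeric_error",
                 paste0("infeasible cohort spec for group %s: rejection rate ",
                        ">99%% (worst biomarker: %s)"),
                 g, rownames(spec@means)[worst])
    }
  }
  colnames(out) <- rownames(spec@means)
  out
}
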