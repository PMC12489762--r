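test_that("zero between-group variation gives F = 0", {
  res <- anovaOneway(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(fValue(res), 0)
  expect_equal(degreesOfFreedom(res), c(between = 2L, within = 6L))
  expect_equal(pValue(res), 1)

  # identical means, unequal variances
  res2 <- anovaOneway(list(c(-1, 0, 1), c(-2, 0, 2), c(-5, 0, 5)))
  expect_equal(fValue(res2), 0, tolerance = 1e-12)

  s <- anovaFromSummary(n = c(5, 7, 9), means = c(2, 2, 2),
                        sds = c(1, 2, 0.5))
  expect_equal(fValue(s), 0)
})

test_that("raw-data and summary-statistic routes agree to 1e-10", {
  set.seed(101)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j)
      rnorm(sample(3:40, 1), mean = rnorm(1, 0, 2), sd = runif(1, 0.5, 3)))
    raw <- anovaOneway(groups)
    summ <- anovaFromSummary(n = lengths(groups),
                             means = vapply(groups, mean, 0),
                             sds = vapply(groups, sd, 0))
    expect_equal(fValue(summ), fValue(raw),
                 tolerance = 1e-10)
    expect_equal(pValue(summ), pValue(raw), tolerance = 1e-10)
    expect_identical(degreesOfFreedom(summ), degreesOfFreedom(raw))
  }
})

test_that("F is invariant under common affine transforms", {
  set.seed(55)
  groups <- lapply(1:3, function(i) rnorm(10, i, 1))
  f0 <- fValue(anovaOneway(groups))
  for (i in 1:10) {
    a <- runif(1, -4, 4); if (abs(a) < 0.1) a <- 1
    b <- rnorm(1, 0, 10)
    expect_equal(fValue(anovaOneway(lapply(groups, function(g) a * g + b))),
                 f0, tolerance = 1e-9)
  }
})

test_that("type-I error at alpha = 0.05 is calibrated under the null", {
  set.seed(202)
  B <- 10000L
  n <- 10L
  hits <- 0L
  for (b in seq_len(B)) {
    x <- matrix(rnorm(3 * n), n, 3)
    res <- anovaFromSummary(n = rep(n, 3), means = colMeans(x),
                            sds = apply(x, 2, sd))
    hits <- hits + (pValue(res) < 0.05)
  }
  expect_gt(hits / B, 0.04)
  expect_lt(hits / B, 0.06)
})

test_that("degenerate and malformed inputs are rejected", {
  expect_error(anovaOneway(list(c(1, 2, 3))), "two groups",
               class = "pdmri_input_error")
  expect_error(anovaOneway(list(c(2, 2), c(2, 2, 2))),
               class = "pdmri_numeric_error")
  expect_error(anovaFromSummary(n = c(5, 5), means = c(1, 2), sds = c(0, 0)),
               "degenerate", class = "pdmri_numeric_error")
  expect_error(anovaFromSummary(n = c(5, 5), means = c(1, 2, 3),
                                sds = c(1, 1)),
               class = "pdmri_input_error")
})

test_that("biomarker selection respects alpha and canonical order", {
  tab <- screenSummary(referenceGroupSummary())
  expect_identical(selectBiomarkers(tab, alpha = 1 - 1e-12),
                   pdmri:::.SELECTION_ORDER)
  expect_identical(selectBiomarkers(tab, alpha = 1e-12), character(0))
  # selection also works from a named list of results
  res <- list(
    swi_put = anovaFromSummary(c(10, 10), c(0, 3), c(1, 1)),
    mrpi = anovaFromSummary(c(10, 10), c(0, 3), c(1, 1)),
    fa_cb = anovaFromSummary(c(10, 10), c(0, 0.1), c(1, 1)))
  expect_identical(selectBiomarkers(res, alpha = 0.01),
                   c("mrpi", "swi_put"))
  expect_error(selectBiomarkers(res, alpha = 1.5),
               class = "pdmri_config_error")
})

test_that("cohort screening matches per-biomarker raw ANOVA", {
  co <- makeCohort(seed = 9, groupSizes = c(PD = 12, MSA = 10, PSP = 8))
  tab <- screenBiomarkers(co)
  m <- biomarkers(co); dx <- diagnosis(co)
  for (b in c("mrpi", "swi_stn", "fa_put")) {
    res <- anovaOneway(lapply(c("PD", "MSA", "PSP"),
                              function(cl) m[b, dx == cl]))
    expect_equal(tab$f_value[tab$biomarker == b], fValue(res),
                 tolerance = 1e-12)
  }
  expect_true(all(c("ordering", "p_display") %in% names(tab)))
})

test_that("tiny p-values are displayed as power-of-ten bounds", {
  expect_equal(formatPValue(c(0.13, 0.572)), c("0.13", "0.57"))
  expect_equal(formatPValue(3.2e-5), "<10^-4")
  expect_equal(formatPValue(9.6e-5), "<10^-4")
  expect_equal(formatPValue(1.47e-6), "<10^-5")
})
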