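test_that("confusion counts match a brute-force pairwise tally", {
  expect_equal(confusionCounts(c("PD", "MSA"), c("PD", "MSA")),
               matrix(c(1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L), 3, 3,
                      dimnames = list(true = c("PD", "MSA", "PSP"),
                                      predicted = c("PD", "MSA", "PSP"))))
  expect_warning(cmEmpty <- confusionCounts(character(), character()),
                 "empty")
  expect_true(all(cmEmpty == 0L))
  set.seed(77)
  truth <- sample(c("PD", "MSA", "PSP"), 1000, replace = TRUE)
  pred <- sample(c("PD", "MSA", "PSP"), 1000, replace = TRUE)
  cm <- confusionCounts(truth, pred)
  for (a in c("PD", "MSA", "PSP")) for (b in c("PD", "MSA", "PSP"))
    expect_equal(cm[a, b], sum(truth == a & pred == b))
  expect_equal(sum(cm), 1000L)
  expect_error(confusionCounts(c("PD", "QQ"), c("PD", "PD")),
               class = "pdmri_input_error")
  expect_error(confusionCounts(c("PD"), c("PD", "PD")),
               class = "pdmri_input_error")
})

test_that("one-vs-rest metrics follow the collapsed 2x2 table", {
  classes <- c("PD", "MSA", "PSP")
  cm <- matrix(c(30, 10, 2, 5, 11, 2, 3, 4, 6), 3, 3,
               dimnames = list(classes, classes))
  got <- oneVsRest(cm, "PSP")
  expect_equal(unname(got), c(6 / 10, 56 / 63, 62 / 73))

  perfect <- diag(c(5L, 4L, 3L)); dimnames(perfect) <- list(classes, classes)
  for (cl in classes)
    expect_equal(unname(oneVsRest(perfect, cl)), c(1, 1, 1))

  allPsp <- matrix(0L, 3, 3, dimnames = list(classes, classes))
  allPsp[, "PSP"] <- c(10L, 5L, 5L)
  got <- oneVsRest(allPsp, "PSP")
  expect_equal(unname(got[1:2]), c(1, 0))

  noPsp <- matrix(0L, 3, 3, dimnames = list(classes, classes))
  noPsp["PD", "PD"] <- 10L
  expect_warning(und <- oneVsRest(noPsp, "PSP"), "sensitivity undefined")
  expect_true(is.na(und[["sensitivity"]]))
})

test_that("a single-iteration bootstrap degenerates to its one sample", {
  co <- makeCohort(seed = 4, groupSizes = c(PD = 8, MSA = 7, PSP = 6))
  rep1 <- bootstrapEvaluate(co, model = "I", iterations = 1, groupSize = 5,
                            seed = 3)
  s <- bootstrapSummary(rep1)
  expect_equal(s$ciLow, s$mean, tolerance = 1e-12)
  expect_equal(s$ciHigh, s$mean, tolerance = 1e-12)
  expect_equal(s$sd, rep(0, 9))
  expect_equal(s$nUsed, rep(1L, 9))
})

test_that("perfectly separated classes bootstrap to unit metrics", {
  spec <- referenceCohortSpec(c(PD = 12, MSA = 12, PSP = 12))
  feats <- c(atrophyBiomarkers(), swiBiomarkers())
  spec@means[feats, "PD"] <- c(100, 30, 3, 1, 1, 1)
  spec@means[feats, "MSA"] <- c(500, 150, 15, 5, 5, 5)
  spec@means[feats, "PSP"] <- c(2500, 750, 75, 25, 25, 25)
  spec@sds[feats, ] <- spec@means[feats, ] * 0.005   # ~20 pooled SDs apart
  co <- simulateCohort(spec, seed = 12)
  rep <- bootstrapEvaluate(co, model = "I", iterations = 300, groupSize = 8,
                           seed = 5)
  s <- bootstrapSummary(rep)
  expect_true(all(s$mean == 1))
  expect_true(all(s$ciHigh - s$ciLow == 0))
})

test_that("bootstrap reports are bit-reproducible and intervals consistent", {
  co <- makeCohort(seed = 10)
  a <- bootstrapEvaluate(co, model = "II", iterations = 400, seed = 21)
  b <- bootstrapEvaluate(co, model = "II", iterations = 400, seed = 21)
  expect_identical(bootstrapSummary(a), bootstrapSummary(b))
  expect_identical(bootstrapTrace(a), bootstrapTrace(b))
  s <- bootstrapSummary(a)
  # SE-of-mean interval identity and [0,1] bounds
  expect_equal(s$ciHigh - s$mean, 1.96 * s$sd / sqrt(s$nUsed),
               tolerance = 1e-12)
  expect_equal(s$mean - s$ciLow, 1.96 * s$sd / sqrt(s$nUsed),
               tolerance = 1e-12)
  expect_true(all(s$mean >= 0 & s$mean <= 1))
  expect_true(all(s$pctLow <= s$mean + 1e-12 & s$mean <= s$pctHigh + 1e-12))
  # percentile intervals are at least as wide as SE-of-mean intervals
  expect_true(all(s$pctHigh - s$pctLow >= s$ciHigh - s$ciLow - 1e-12))
  # trace schedule: every 100 iterations plus the final checkpoint
  tr <- bootstrapTrace(a)
  expect_equal(as.numeric(dimnames(tr)$checkpoint), c(100, 200, 300, 400))
  expect_equal(tr[4, , ],
               matrix(s$mean, 3, 3, byrow = TRUE,
                      dimnames = dimnames(tr)[2:3]),
               tolerance = 1e-12)
})

test_that("alternative protocols run: out-of-bag and fixed PSP sample", {
  co <- makeCohort(seed = 13, groupSizes = c(PD = 15, MSA = 12, PSP = 8))
  oob <- bootstrapEvaluate(co, model = "I", iterations = 100, groupSize = 6,
                           seed = 2, protocol = "oob")
  expect_true(all(bootstrapSummary(oob)$mean >= 0, na.rm = TRUE))
  fixed <- bootstrapEvaluate(co, model = "I", iterations = 100,
                             groupSize = 8, seed = 2, resamplePsp = FALSE)
  expect_s4_class(fixed, "BootstrapReport")
})

test_that("convergence criterion reacts to trace stability", {
  co <- makeCohort(seed = 14)
  rep <- bootstrapEvaluate(co, model = "I", iterations = 600, seed = 9)
  # constant traces converge even at zero tolerance; stochastic ones do not
  tr <- bootstrapTrace(rep)
  stoch <- apply(tr, 2:3, function(v) length(unique(v)) > 1)
  expect_true(any(stoch))
  conv0 <- convergenceTrace(rep, burnInFraction = 0.1, tolerance = 0)
  expect_false(all(conv0[stoch]))
  convBig <- convergenceTrace(rep, burnInFraction = 0.1, tolerance = 1)
  expect_true(all(convBig))
})
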