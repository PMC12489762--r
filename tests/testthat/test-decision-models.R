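test_that("fitting recovers per-class sample moments, priors and floors", {
  co <- makeCohort(seed = 2)
  fit <- fitClassConditionals(co, priorMode = "empirical")
  expect_equal(unname(classPriors(fit)), c(38, 25, 10) / 73)
  m <- biomarkers(co); dx <- diagnosis(co)
  expect_equal(fit@means["mrpi", "PSP"], mean(m["mrpi", dx == "PSP"]))
  expect_equal(fit@sds["swi_put", "PD"], sd(m["swi_put", dx == "PD"]))

  # a degenerate column hits the variance floor instead of collapsing
  m2 <- m
  m2["mrpi", dx == "PSP"] <- 210.761
  co2 <- BiomarkerCohort(m2, diagnosis = dx)
  fit2 <- fitClassConditionals(co2)
  expect_equal(fit2@means["mrpi", "PSP"], 210.761)
  expect_gt(fit2@sds["mrpi", "PSP"], 0)
  expect_lt(fit2@sds["mrpi", "PSP"], 1e-3)
  expect_equal(unname(classPriors(fit2)), rep(1 / 3, 3))

  tiny <- makeCohort(seed = 3, groupSizes = c(PD = 2, MSA = 2, PSP = 1))
  expect_error(fitClassConditionals(tiny), "PSP",
               class = "pdmri_input_error")
})

test_that("posterior matches the brute-force normalization oracle", {
  set.seed(314)
  for (i in 1:10) {
    model <- randomModel(p = sample(2:6, 1))
    for (j in 1:10) {
      panel <- setNames(rnorm(length(modelFeatures(model)), 0, 4),
                        modelFeatures(model))
      got <- probabilities(posteriorProbs(model, panel))
      want <- bruteForcePosterior(model, panel)
      expect_equal(got[names(want)], want, tolerance = 1e-10)
      expect_equal(sum(got), 1, tolerance = 1e-12)
    }
  }
})

test_that("posterior symmetry, dominance and missing-feature handling", {
  feats <- c("mrpi", "swi_put")
  mu <- matrix(c(1, 0.9, 1, 0.9), 2, 2,
               dimnames = list(feats, c("PD", "MSA")))
  sdm <- matrix(0.1, 2, 2, dimnames = dimnames(mu))
  twin <- classConditionalModel(mu, sdm)
  p <- probabilities(posteriorProbs(twin, c(mrpi = 1.3, swi_put = 0.7)))
  expect_equal(unname(p), c(0.5, 0.5))
  # symmetric tie predicts the first class in canonical order (PD)
  expect_equal(predictedClass(posteriorProbs(twin, c(mrpi = 1.3))), "PD")

  sep <- classConditionalModel(
    matrix(c(0, 10, 20), 1, 3, dimnames = list("mrpi", c("PD", "MSA", "PSP"))),
    matrix(1, 1, 3, dimnames = list("mrpi", c("PD", "MSA", "PSP"))))
  expect_gt(probabilities(posteriorProbs(sep, c(mrpi = 10)))[["MSA"]], 0.99)

  # NA features are marginalized: equivalent to a model without them
  model <- randomModel(p = 4, uniformPriors = TRUE)
  panel <- setNames(rnorm(4), modelFeatures(model))
  panel[2] <- NA
  small <- classConditionalModel(model@means[-2, ], model@sds[-2, ],
                                 classPriors(model))
  expect_equal(probabilities(posteriorProbs(model, panel)),
               probabilities(posteriorProbs(small, panel[-2])),
               tolerance = 1e-12)
  expect_error(posteriorProbs(model, c(nothere = 1)),
               class = "pdmri_input_error")
})

test_that("posteriors are invariant under per-feature affine transforms", {
  set.seed(99)
  model <- randomModel(p = 5)
  feats <- modelFeatures(model)
  for (i in 1:20) {
    panel <- setNames(rnorm(5, 0, 3), feats)
    a <- runif(5, 0.2, 5); b <- rnorm(5, 0, 10)
    tmodel <- classConditionalModel(model@means * a + b, model@sds * a,
                                    classPriors(model))
    expect_equal(
      probabilities(posteriorProbs(tmodel, setNames(a * panel + b, feats))),
      probabilities(posteriorProbs(model, panel)), tolerance = 1e-9)
  }
})

test_that("model I favors the class whose mean vector the panel sits on", {
  spec <- referenceCohortSpec()
  model <- classConditionalModel(spec@means[c(1:3, 9:11), ],
                                 spec@sds[c(1:3, 9:11), ])
  pspPanel <- setNames(spec@means[c(1:3, 9:11), "PSP"],
                       rownames(spec@means)[c(1:3, 9:11)])
  res <- classifyModelI(model, pspPanel)
  expect_equal(predictedClass(res), "PSP")
  expect_equal(res@modelId, "I")
  # verify against the brute-force oracle at the same point
  expect_equal(probabilities(res)[names(bruteForcePosterior(model, pspPanel))],
               bruteForcePosterior(model, pspPanel), tolerance = 1e-12)
  # a lone putaminal SWI value at the PD group mean favors PD
  res2 <- classifyModelI(model, c(swi_put = 0.925))
  expect_equal(predictedClass(res2), "PD")

  binary <- randomModel(p = 2, classes = c("PD", "MSA"))
  expect_error(classifyModelI(binary, c(f1 = 0, f2 = 0)),
               class = "pdmri_input_error")
})

test_that("model II chains the two binary stages by the chain rule", {
  set.seed(41)
  stage1 <- randomModel(p = 3, classes = c("PSP", "rest"),
                        uniformPriors = TRUE)
  stage2 <- randomModel(p = 3, classes = c("PD", "MSA"),
                        uniformPriors = TRUE)
  feats <- modelFeatures(stage1)
  for (i in 1:100) {
    panel <- setNames(rnorm(3, 0, 3), feats)
    res <- classifyModelII(stage1, stage2, panel)
    p <- probabilities(res)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    p1 <- bruteForcePosterior(stage1, panel)[["PSP"]]
    p2 <- bruteForcePosterior(stage2, panel)[["MSA"]]
    expect_equal(unname(p[c("PD", "MSA", "PSP")]),
                 c((1 - p1) * (1 - p2), (1 - p1) * p2, p1),
                 tolerance = 1e-12)
    expect_equal(res@modelId, "II")
    # stage-1 output agrees with the generic posterior on the same problem
    expect_equal(p[["PSP"]],
                 probabilities(posteriorProbs(stage1, panel))[["PSP"]],
                 tolerance = 1e-12)
  }

  # p1 ~ 1 forces PSP regardless of stage 2
  far <- classConditionalModel(
    matrix(c(0, 100), 1, 2, dimnames = list("x", c("PSP", "rest"))),
    matrix(1, 1, 2, dimnames = list("x", c("PSP", "rest"))))
  res <- classifyModelII(far, randomModel(p = 1, classes = c("PD", "MSA")),
                         c(x = 0, f1 = 0))
  expect_equal(probabilities(res)[["PSP"]], 1, tolerance = 1e-12)
  expect_equal(predictedClass(res), "PSP")

  # symmetric stages give (0.25, 0.25, 0.5) and predict PSP
  mu <- matrix(c(0, 0), 1, 2, dimnames = list("x", c("PSP", "rest")))
  sdm <- matrix(1, 1, 2, dimnames = list("x", c("PSP", "rest")))
  tie1 <- classConditionalModel(mu, sdm)
  mu2 <- mu; colnames(mu2) <- c("PD", "MSA")
  sdm2 <- sdm; colnames(sdm2) <- c("PD", "MSA")
  tie2 <- classConditionalModel(mu2, sdm2)
  res <- classifyModelII(tie1, tie2, c(x = 0.3))
  expect_equal(unname(probabilities(res)), c(0.25, 0.25, 0.5))
  expect_equal(predictedClass(res), "PSP")
})

test_that("cohort classification reports posterior percentages per patient", {
  co <- makeCohort(seed = 6, groupSizes = c(PD = 10, MSA = 8, PSP = 6))
  for (mid in c("I", "II")) {
    cls <- classifyCohort(co, model = mid)
    expect_equal(nrow(cls), 24L)
    expect_true(all(abs(cls$msa_pct + cls$pd_pct + cls$psp_pct - 100) < 0.02))
    expect_true(all(cls$predicted %in% c("PD", "MSA", "PSP")))
  }
  loo <- classifyCohort(co, model = "I", protocol = "loo")
  expect_equal(nrow(loo), 24L)
})
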