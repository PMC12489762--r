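# shared fixtures: all data is generated in code

# small labeled cohort from the reference generator
makeCohort <- function(seed = 1, groupSizes = NULL) {
  spec <- if (is.null(groupSizes)) referenceCohortSpec()
          else referenceCohortSpec(groupSizes)
  simulateCohort(spec, seed = seed)
}

# random valid geometric measurement sets (vectorized over n)
randomGeometry <- function(n = 1) {
  data.frame(
    pons_area = runif(n, 400, 700),
    midbrain_area = runif(n, 80, 200),
    mcp_width_left = runif(n, 6, 11),
    mcp_width_right = runif(n, 6, 11),
    scp_width_left = runif(n, 1.5, 4.5),
    scp_width_right = runif(n, 1.5, 4.5),
    third_ventricle_width = runif(n, 3, 12),
    frontal_horns_width = runif(n, 25, 45)
  )
}

# random Gaussian class-conditional model over arbitrary feature names
randomModel <- function(p = 4, classes = c("PD", "MSA", "PSP"),
                        uniformPriors = FALSE) {
  feats <- paste0("f", seq_len(p))
  mu <- matrix(rnorm(p * length(classes), 0, 3), p,
               dimnames = list(feats, classes))
  sdm <- matrix(runif(p * length(classes), 0.2, 2), p,
                dimnames = list(feats, classes))
  pr <- if (uniformPriors) rep(1 / length(classes), length(classes))
        else { w <- runif(length(classes), 0.5, 2); w / sum(w) }
  classConditionalModel(mu, sdm, setNames(pr, classes))
}

# independent oracle: posterior by direct density-product normalization,
# rescaled by the largest class log-likelihood so extreme panels do not
# underflow double precision
bruteForcePosterior <- function(model, panel) {
  feats <- intersect(modelFeatures(model), names(panel)[!is.na(panel)])
  ll <- vapply(modelClasses(model), function(cl) {
    log(classPriors(model)[[cl]]) +
      sum(log(dnorm(panel[feats], model@means[feats, cl],
                    model@sds[feats, cl])))
  }, 0)
  lik <- exp(ll - max(ll))
  lik / sum(lik)
}
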