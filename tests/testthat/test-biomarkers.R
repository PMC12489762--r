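test_that("atrophy indices reproduce hand-computed values", {
  unity <- list(pons_area = 150, midbrain_area = 150,
                mcp_width_left = 8, mcp_width_right = 8,
                scp_width_left = 8, scp_width_right = 8)
  expect_equal(computeMRPI(unity), 1.0)

  g <- list(pons_area = 400, midbrain_area = 100,
            mcp_width_left = 9, mcp_width_right = 9,
            scp_width_left = 3, scp_width_right = 3)
  expect_equal(computeMRPI(g), 12.0)

  g2 <- list(pons_area = 620, midbrain_area = 124,
             mcp_width_left = 8.8, mcp_width_right = 8.4,
             scp_width_left = 2.2, scp_width_right = 1.8)
  expect_equal(computeMRPI(g2), (620 / 124) * (8.6 / 2.0))
  expect_equal(computeMRPI(g2), 21.5)

  expect_equal(computePMRatio(list(pons_area = 5, midbrain_area = 5)), 1.0)
  expect_equal(computePMRatio(list(pons_area = 500, midbrain_area = 100)), 5.0)
  expect_equal(computePMRatio(list(pons_area = 590.4, midbrain_area = 124.2)),
               590.4 / 124.2)

  gv <- list(third_ventricle_width = 7, frontal_horns_width = 7)
  expect_equal(computeMRPI2(140, gv), 140)
  expect_equal(computeMRPI2(140, list(third_ventricle_width = 8,
                                      frontal_horns_width = 32)), 35.0)
  expect_equal(computeMRPI2(210.761, list(third_ventricle_width = 10.5,
                                          frontal_horns_width = 37.5)),
               210.761 * 0.28)
})

test_that("atrophy indices are scale-invariant and mutually consistent", {
  set.seed(42)
  for (i in 1:25) {
    g <- as.list(randomGeometry(1))
    scale <- runif(1, 0.1, 10)
    gScaled <- lapply(g, `*`, scale)
    expect_equal(computeMRPI(gScaled), computeMRPI(g), tolerance = 1e-12)
    expect_equal(computePMRatio(gScaled), computePMRatio(g),
                 tolerance = 1e-12)
    mrpi <- computeMRPI(g)
    expect_equal(computeMRPI2(mrpi, g),
                 mrpi * g$third_ventricle_width / g$frontal_horns_width,
                 tolerance = 1e-15)
  }
})

test_that("invalid measurements raise errors naming the field", {
  g <- as.list(randomGeometry(1))
  g$midbrain_area <- 0
  expect_error(computeMRPI(g), "midbrain_area", class = "pdmri_input_error")
  expect_error(computePMRatio(g), "midbrain_area",
               class = "pdmri_input_error")
  expect_error(computeMRPI2(10, list(third_ventricle_width = 5,
                                     frontal_horns_width = -1)),
               "frontal_horns_width", class = "pdmri_input_error")
  expect_error(computeMRPI2(-3, list(third_ventricle_width = 5,
                                     frontal_horns_width = 30)),
               "mrpi", class = "pdmri_input_error")
  expect_error(computeMRPI(g[-1]), "missing", class = "pdmri_input_error")
})

test_that("SWI normalization is a degree-0 ratio to white matter", {
  expect_equal(normalizeSWI(400, 400), 1.0)
  expect_equal(normalizeSWI(0, 400), 0.0)
  expect_equal(normalizeSWI(370, 400), 0.925)
  set.seed(7)
  roi <- runif(20, 0, 500); wm <- runif(20, 100, 600); k <- runif(20, 0.5, 4)
  expect_equal(normalizeSWI(k * roi, k * wm), normalizeSWI(roi, wm),
               tolerance = 1e-12)
  expect_error(normalizeSWI(370, 0), "swi_wm_mean",
               class = "pdmri_input_error")
  expect_error(normalizeSWI(-1, 10), class = "pdmri_input_error")
})

test_that("meanInMask matches brute-force accumulation", {
  expect_equal(meanInMask(rep(3.7, 5), c(TRUE, FALSE, TRUE, TRUE, FALSE)),
               3.7)
  expect_equal(meanInMask(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, FALSE)), 2.0)
  set.seed(11)
  values <- rnorm(1000)
  mask <- sample(c(TRUE, FALSE), 1000, replace = TRUE)
  acc <- 0; cnt <- 0
  for (i in seq_along(values)) if (mask[i]) { acc <- acc + values[i]; cnt <- cnt + 1 }
  expect_equal(meanInMask(values, mask), acc / cnt, tolerance = 1e-12)
  expect_error(meanInMask(1:3, c(TRUE, FALSE)), "length",
               class = "pdmri_input_error")
  expect_error(meanInMask(1:3, rep(FALSE, 3)), "empty region",
               class = "pdmri_input_error")
})

test_that("derivePanels derives a consistent panel from raw measurements", {
  set.seed(3)
  raw <- randomGeometry(12)
  raw$patient_id <- sprintf("pt%02d", 1:12)
  raw$swi_put_mean <- runif(12, 200, 400)
  raw$swi_stn_mean <- runif(12, 200, 400)
  raw$swi_rn_mean <- runif(12, 200, 400)
  raw$swi_wm_mean <- runif(12, 350, 450)
  raw$fa_scp <- runif(12, 0.4, 0.8)   # native [0,1] scale
  panel <- derivePanels(raw, faScale = "native")
  expect_equal(panel$mrpi2,
               panel$mrpi * raw$third_ventricle_width /
                 raw$frontal_horns_width, tolerance = 1e-14)
  expect_equal(panel$t1_pm_ratio, raw$pons_area / raw$midbrain_area)
  expect_equal(panel$swi_put, raw$swi_put_mean / raw$swi_wm_mean)
  expect_equal(panel$fa_scp, raw$fa_scp * 1000)
  # absent raw columns produce missing biomarkers, never zeros
  expect_true(all(is.na(panel$fa_cb)))
  raw$swi_wm_mean <- NULL
  expect_true(all(is.na(derivePanels(raw)$swi_put)))
})
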