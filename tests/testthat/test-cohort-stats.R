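test_that("MBL classification honors the clinical cutoffs", {
  expect_equal(classifyMbl(c(0, NA, 40, 84.9, 85, 100)),
               c("none", "none", "lc_mbl", "lc_mbl", "hc_mbl", "hc_mbl"))
  expect_equal(classifyMbl(clonalBCount = c(0, 250, 499, 500, 5000),
                           rule = "absolute"),
               c("none", "lc_mbl", "lc_mbl", "hc_mbl", "hc_mbl"))
  expect_warning(
    res <- classifyMbl(clonalBCount = 6000, rule = "absolute"), "5000")
  expect_true(is.na(res))
  expect_error(classifyMbl(clonalBPct = 50, rule = "absolute"),
               "clonalBCount")
  expect_error(classifyMbl(clonalBPct = 120), "100")
})

test_that("prevalence percentages reproduce printed rounding", {
  expect_equal(prevalence(173, 332)$percent, 52.1)
  expect_equal(prevalence(4, 2971)$percent, 0.1)
  expect_equal(prevalence(0, 100)$percent, 0)
  expect_true(is.na(prevalence(0, 0)$percent))
  ## half-up rounding, not banker's
  expect_equal(roundHalfUp(0.15, 1), 0.2)
  expect_equal(roundHalfUp(52.108, 1), 52.1)
  expect_equal(roundHalfUp(14.976, 1), 15.0)
})

test_that("screening metrics recompute from 2x2 counts", {
  m <- screeningMetrics(tp = 190, fp = 54, fn = 142, tn = 3645)
  expect_equal(m$sensitivity, 57.2)
  expect_equal(m$specificity, 98.5)
  expect_warning(mSpec <- screeningMetrics(0, 4, 0, 2967), "sensitivity")
  expect_equal(mSpec$specificity, 99.9)
  expect_warning(m0 <- screeningMetrics(0, 1, 0, 1), "sensitivity")
  expect_true(is.na(m0$sensitivity))
})

test_that("crude odds ratio follows the cross-product with Woolf CI", {
  expect_equal(crudeOr(10, 10, 10, 10)$or, 1)
  r <- crudeOr(173, 159, 4, 2967)
  expect_equal(r$or, 513291 / 636)
  expect_equal(r$or, 807.1, tolerance = 1e-3)
  expect_true(r$ci[1] < r$or && r$or < r$ci[2])
  z <- crudeOr(5, 0, 3, 10)
  expect_false(z$finite)
  zc <- crudeOr(5, 0, 3, 10, correction = TRUE)
  expect_true(zc$finite && is.finite(zc$or))
})

test_that("adjusted OR without covariates equals the crude OR", {
  ## 2x2 expanded to individual rows
  a <- 30; b <- 20; c <- 15; d <- 60
  df <- data.frame(
    outcome = rep(c(1, 1, 0, 0), c(a, b, c, d)),
    exposure = rep(c(1, 0, 1, 0), c(a, b, c, d)))
  crude <- crudeOr(a, b, c, d)
  adj <- adjustedOr(df, "outcome", "exposure")
  expect_equal(signif(adj$or, 3), signif(crude$or, 3))
  expect_equal(adj$ci, crude$ci, tolerance = 1e-3)
})

test_that("adjusted OR CI covers the null for an independent exposure", {
  hits <- vapply(1:100, function(s) {
    d <- simulateOrCohort(5000, oddsRatio = 1, seed = s)
    r <- adjustedOr(d, "outcome", "exposure", c("age", "sex"))
    r$ci[1] <= 1 && 1 <= r$ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.93)
})

test_that("quasi-separation is flagged, not silently reported", {
  set.seed(17)
  d <- simulateOrCohort(400, oddsRatio = 1, seed = 17)
  d$exposure <- ifelse(d$outcome == 1, rbinom(nrow(d), 1, 0.4), 0)
  r <- adjustedOr(d, "outcome", "exposure")
  expect_true(r$separated)
  rOk <- adjustedOr(simulateOrCohort(2000, 5, seed = 2), "outcome",
                    "exposure")
  expect_false(rOk$separated)
})

test_that("clone-size comparison behaves on degenerate and shifted input", {
  ## identical multisets: U = n^2 / 2
  a <- c(1, 2, 3, 4, 5)
  r <- cloneSizeTest(a, a)
  expect_equal(r$U, 12.5)
  expect_gt(r$p, 0.9)
  ## all tied
  r0 <- cloneSizeTest(rep(2, 10), rep(2, 8))
  expect_equal(r0$p, 1)
  expect_equal(r0$U, 40)
  ## stochastically larger group
  set.seed(5)
  big <- rnorm(200, 2); small <- rnorm(200, 0)
  r1 <- cloneSizeTest(big, small)
  expect_gt(r1$medianA, r1$medianB)
  expect_lt(r1$p, 1e-10)
  expect_error(cloneSizeTest(numeric(0), 1), "non-empty")
})

test_that("polygenic score is a weighted dosage average", {
  expect_equal(prsScore(rep(0, 41), runif(41)), 0)
  expect_equal(prsScore(rep(1, 41), rep(0.3, 41)), 1)
  expect_equal(prsScore(c(2, 0), c(1, 2)), 2 / 3)
  expect_equal(prsScore(c(2, NA, 0), c(1, 1, 1)), 2 / 3 * 1.5)  # impute 1
  expect_error(prsScore(c(1, 2), 1), "length")
  expect_error(prsScore(c(1, 3), c(1, 1)), "\\[0, 2\\]")
})

test_that("rank AUC is exact and transform-invariant", {
  scores <- c(0.9, 0.8, 0.3, 0.2)
  labels <- c(1, 1, 0, 0)
  expect_equal(aucRank(scores, labels), 1)
  set.seed(9)
  s <- rnorm(500); y <- rbinom(500, 1, plogis(s))
  expect_equal(aucRank(s, y), aucRank(exp(3 * s) + 5, y))
  expect_error(aucRank(s, rep(0, 500)), "classes")
})

test_that("cross-validated AUC is calibrated at the null and at separation", {
  d <- simulateOrCohort(3000, oddsRatio = 1, seed = 23)
  d$noise <- withSeed(23, rnorm(3000))
  expect_lt(abs(cvPredictAuc(d, "noise", seed = 23)$auc - 0.5), 0.03)
  ## perfectly separating feature
  d$perfect <- d$outcome * 10 + withSeed(24, runif(3000))
  expect_equal(cvPredictAuc(d, "perfect", seed = 23)$auc, 1)
  expect_error(cvPredictAuc(d[d$outcome == 0, ], "noise"), "outcome class")
})

test_that("nested prediction models do not beat their supersets on average", {
  aucs <- sapply(1:10, function(s) {
    cc <- CohortConfig(groupSizes = c(none = 700, lc_mbl = 170,
                                      hc_mbl = 80, cll = 0, sll = 0),
                      seed = s)
    coh <- generateCohort(cc)
    ind <- coh$individuals
    ind$outcome <- as.integer(ind$group == "hc_mbl")
    ind$has_driver <- as.integer(ind$truth_canonical |
                                   ind$truth_driver_extra)
    ind$sex <- as.integer(ind$sex == "male")
    spec <- hcMblModelSpecs()
    c(alc = cvPredictAuc(ind, spec$alc, seed = s)$auc,
      mca = cvPredictAuc(ind, spec$mca, seed = s)$auc,
      demo = cvPredictAuc(ind, spec$demo_mca_prs, seed = s)$auc,
      full = cvPredictAuc(ind, spec$full, seed = s)$auc)
  })
  m <- rowMeans(aucs)
  expect_gte(m[["full"]] + 0.01, m[["alc"]])
  expect_gte(m[["full"]] + 0.01, m[["mca"]])
  expect_gte(m[["full"]] + 0.01, m[["demo"]])
  expect_gte(m[["demo"]] + 0.01, m[["mca"]])
})
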