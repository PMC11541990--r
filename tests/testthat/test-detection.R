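test_that("signed phased deviation behaves at its edge cases", {
  s <- data.frame(baf = rep(0.5, 100), hap = rep(c(1L, -1L), 50))
  r <- signedPhasedDeviation(s)
  expect_equal(r$dbaf, 0)
  expect_equal(r$z, 0)

  ## 1000 hets with hap * (baf - 0.5) = +0.25 exactly (noiseless CNN-LOH at
  ## f = 0.5); half the hets carry the B allele on the other haplotype
  hap <- rep(c(1L, -1L), 500)
  s <- data.frame(baf = 0.5 + hap * 0.25, hap = hap)
  r <- signedPhasedDeviation(s)
  expect_equal(r$dbaf, 0.25)
  expect_equal(r$n, 1000)

  r <- signedPhasedDeviation(data.frame(baf = rep(0.6, 10), hap = 1L))
  expect_true(r$noCall)
  expect_true(is.na(r$dbaf))
})

test_that("segment scan finds an injected event with tight boundaries", {
  ## event spanning hets ~2000-6000 of 10000
  s <- eventSites("cnn_loh", f = 0.3, nSites = 10000, start = 50e6,
                  end = 150e6, seed = 21)
  cand <- segmentScan(s, detectionConfig())
  expect_equal(nrow(cand), 1)
  jac <- (min(cand$end, 150e6) - max(cand$start, 50e6)) /
    (max(cand$end, 150e6) - min(cand$start, 50e6))
  expect_gte(jac, 0.9)
})

test_that("a whole-chromosome event yields one candidate spanning all hets", {
  s <- eventSites("cnn_loh", f = 0.3, nSites = 2000, seed = 6)
  cand <- segmentScan(s, detectionConfig())
  expect_equal(nrow(cand), 1)
  expect_equal(cand$n_hets, sum(s$genotype == "AB"))
  expect_equal(cand$start, min(s$pos))
})

test_that("segment scan rejects unsorted input and is quiet on noise", {
  s <- eventSites(type = NULL, nSites = 1000, seed = 1)
  expect_error(segmentScan(s[rev(seq_len(nrow(s))), ]), "sorted")
  fp <- vapply(1:50, function(seed)
    nrow(segmentScan(eventSites(type = NULL, nSites = 1000,
                                hetFraction = 0.33, seed = seed))),
    numeric(1))
  expect_equal(sum(fp), 0)
})

test_that("boundary refinement recovers true change points", {
  ## noiseless step: the single CUSUM fit (nBoot = 1) is exact
  s <- stepSites(n = 300, i0 = 101, i1 = 200, dbaf = 0.25)
  cand <- segmentScan(s, detectionConfig())
  rb1 <- refineBoundaries(s, cand[1, ], nBoot = 1, seed = 1)
  expect_equal(rb1$start, s$pos[101])
  expect_equal(rb1$end, s$pos[200] + 1)
  ## bootstrap median stays on the true boundaries
  rb <- refineBoundaries(s, cand[1, ], nBoot = 51, seed = 2)
  expect_equal(rb$start, s$pos[101])
  expect_equal(rb$end, s$pos[200] + 1)
  expect_error(refineBoundaries(s, cand[1, ], nBoot = 0), ">= 1")
})

test_that("refined boundaries fall within 50 hets of truth under noise", {
  s <- eventSites("cnn_loh", f = 0.2, nSites = 10000, start = 50e6,
                  end = 150e6, seed = 31)
  cand <- segmentScan(s, detectionConfig())
  rb <- refineBoundaries(s, cand[1, ], nBoot = 100, seed = 3)
  hs <- s[s$genotype == "AB", ]
  startErr <- sum(hs$pos >= min(rb$start, 50e6) & hs$pos < max(rb$start, 50e6))
  endErr <- sum(hs$pos >= min(rb$end, 150e6) & hs$pos < max(rb$end, 150e6))
  expect_lte(startErr, 50)
  expect_lte(endErr, 50)
})

test_that("detection power is monotone in cell fraction and het count", {
  rate <- function(f, n) {
    mean(vapply(1:20, function(seed) {
      s <- eventSites("cnn_loh", f = f, nSites = n,
                      seed = seed + round(1e4 * f) + n)
      nrow(segmentScan(s, detectionConfig())) >= 1
    }, logical(1)))
  }
  grid <- sapply(c(100, 1000, 10000), function(n)
    sapply(c(0.01, 0.05, 0.2), function(f) rate(f, n)))
  ## rows: f increasing; cols: n_hets increasing
  expect_true(all(apply(grid, 1, diff) >= 0))
  expect_true(all(apply(grid, 2, diff) >= 0))
  expect_equal(grid[3, 3], 1)
})

test_that("full detector types events and estimates their cell fraction", {
  for (spec in list(list(type = "loss", f = 0.4),
                    list(type = "gain", f = 0.4),
                    list(type = "cnn_loh", f = 0.3))) {
    s <- eventSites(spec$type, f = spec$f, nSites = 4000, start = 50e6,
                    end = 200e6, hetFraction = 0.4, seed = 13)
    calls <- detectMca(s, detectionConfig(seed = 13))
    expect_equal(nrow(calls), 1)
    expect_equal(calls$type, spec$type)
    expect_lt(abs(calls$cell_fraction - spec$f), 0.05)
    expect_gt(calls$phase_concordance, 0.9)
  }
})

test_that("sex chromosome loss is called from the LRR shift", {
  expect_error(detectSexChromLoss(eventSites(type = NULL, seed = 1), "male"),
               "sex chromosome")
  ## no shift -> no call
  s <- eventSites(type = NULL, nSites = 1000, hetFraction = 0, seed = 2,
                  chrom = "chrY")
  expect_null(detectSexChromLoss(s, "male"))
  ## female has no Y signal to call
  expect_null(detectSexChromLoss(s, "female"))
  ## LoY at f = 0.3: median LRR ~ log2(0.85), f recovered within 0.05
  s <- eventSites("loss", f = 0.3, nSites = 1000, hetFraction = 0,
                  chrom = "chrY", end = 57227415, seed = 9)
  call <- detectSexChromLoss(s, "male")
  expect_equal(call$type, "loss")
  expect_lt(abs(call$cell_fraction - 0.3), 0.05)
  ## complete loss: median LRR -1 -> f = 1
  s <- eventSites("loss", f = 1, nSites = 1000, hetFraction = 0,
                  chrom = "chrY", end = 57227415, seed = 10)
  expect_equal(detectSexChromLoss(s, "male")$cell_fraction, 1,
               tolerance = 0.05)
})

test_that("call filters drop germline and low-quality calls", {
  qc <- list(call_rate = 1.0, baf_median = 0.5)
  nominal <- data.frame(chrom = "chr1", dbaf = 0.1, mean_lrr = -0.2,
                        type = "loss", phase_concordance = 0.98)
  expect_equal(applyFilters(nominal, qc)$filter, "PASS")

  ## constitutional deletion: dbaf 0.5 with LRR -1
  germ <- transform(nominal, dbaf = 0.5, mean_lrr = -1)
  flagged <- applyFilters(germ, qc, drop = FALSE)
  expect_match(flagged$filter, "germline")
  expect_equal(nrow(applyFilters(germ, qc)), 0)

  ## random phase (concordance 0.5) below the 0.6 threshold
  noisy <- transform(nominal, phase_concordance = 0.5)
  expect_match(applyFilters(noisy, qc, drop = FALSE)$filter, "phase_quality")

  ## sample-level failures hit every call
  expect_match(applyFilters(nominal, list(call_rate = 0.9, baf_median = 0.5),
                            drop = FALSE)$filter, "sample_call_rate")
  expect_match(applyFilters(nominal, list(call_rate = 1, baf_median = 0.6),
                            drop = FALSE)$filter, "sample_baf")
  expect_error(applyFilters(nominal, list(call_rate = 1)), "baf_median")
  expect_error(applyFilters(nominal[, -2], qc), "dbaf")
})
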