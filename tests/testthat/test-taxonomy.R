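lists <- exampleRegionLists()

call1 <- function(chrom, start, end, type, cf = 0.2)
  data.frame(chrom = chrom, start = start, end = end, type = type,
             cell_fraction = cf)

test_that("canonical rules match the FISH-panel loci", {
  ## loss overlapping 13q14
  expect_true(isCanonical(call1("chr13", 45e6, 60e6, "loss"), lists))
  ## loss confined to 13p does not touch the q arm
  expect_false(isCanonical(call1("chr13", 1e6, 10e6, "loss"), lists))
  ## CNN-LOH on 13q must contain the MIR16-1 anchor
  expect_true(isCanonical(call1("chr13", 40e6, 114e6, "cnn_loh"), lists))
  expect_false(isCanonical(call1("chr13", 60e6, 114e6, "cnn_loh"), lists))
  ## trisomy 12 = whole-chromosome gain; a 12p-only gain is not canonical
  expect_true(isCanonical(call1("chr12", 0, 133275309, "gain"), lists))
  expect_false(isCanonical(call1("chr12", 0, 30e6, "gain"), lists))
  ## type must match the entry
  expect_false(isCanonical(call1("chr13", 45e6, 60e6, "gain"), lists))
  expect_true(isCanonical(call1("chr17", 0, 5e6, "loss"), lists))
  expect_true(isCanonical(call1("chr6", 60e6, 170e6, "loss"), lists))
  expect_true(isCanonical(call1("chr11", 100e6, 135e6, "loss"), lists))
  expect_error(isCanonical(call1("chr99", 0, 1e6, "loss"), lists),
               "arm_table")
})

test_that("driver classification requires full containment of a candidate", {
  ## candidate chr8:0.1-40 Mb loss
  expect_true(isCllDriver(call1("chr8", 0, 90e6, "loss"), lists))
  ## partial overlap of the candidate is not containment
  expect_false(isCllDriver(call1("chr8", 25e6, 90e6, "loss"), lists))
  ## type must match exactly (a cnn_loh containing a loss candidate is not
  ## a driver)
  expect_false(isCllDriver(call1("chr8", 0, 90e6, "cnn_loh"), lists))
  ## canonical calls are drivers even with an empty candidate list
  empty <- tinyRegionLists(emptyDriver = TRUE)
  expect_true(isCllDriver(call1("chr11", 100e6, 135e6, "loss"), empty))
  expect_warning(
    res <- isCllDriver(call1("chr8", 0, 90e6, "loss"), empty),
    "list-dependent")
  expect_false(res)
})

test_that("lymphoid matching uses the canonical overlap rules", {
  expect_true(isLymphoid(call1("chr11", 100e6, 135e6, "loss"), lists))
  expect_true(isLymphoid(call1("chr22", 20e6, 50e6, "loss"), lists))
  ## sex-chromosome events are not on the lymphoid list
  expect_false(isLymphoid(call1("chrY", 0, 57e6, "loss"), lists))
  expect_false(isLymphoid(call1("chr11", 100e6, 135e6, "loss"),
                          tinyRegionLists(emptyLymphoid = TRUE)))
})

test_that("canonical implies driver over randomized calls", {
  set.seed(404)
  at <- defaultArmTable()
  for (i in 1:200) {
    ch <- sample(at$chrom, 1)
    len <- at$length[at$chrom == ch]
    a <- sort(sample.int(len, 2))
    call <- call1(ch, a[1], a[2], sample(c("loss", "gain", "cnn_loh"), 1))
    if (isCanonical(call, lists)) expect_true(isCllDriver(call, lists))
  }
})

test_that("classification is order-independent and idempotent", {
  calls <- rbind(call1("chr13", 45e6, 60e6, "loss"),
                 call1("chr8", 0, 90e6, "loss"),
                 call1("chr12", 0, 133275309, "gain"),
                 call1("chr22", 20e6, 50e6, "loss"))
  ann <- classifyCalls(calls, lists)
  perm <- c(3, 1, 4, 2)
  annPerm <- classifyCalls(calls[perm, ], lists)
  expect_equal(annPerm$is_canonical, ann$is_canonical[perm])
  expect_equal(annPerm$is_cll_driver, ann$is_cll_driver[perm])
  ## idempotent: re-annotating annotated calls changes nothing
  expect_equal(classifyCalls(ann, lists)$is_canonical, ann$is_canonical)
  ## categories overlap: an 11q loss is canonical AND lymphoid
  a11 <- classifyCalls(call1("chr11", 100e6, 135e6, "loss"), lists)
  expect_true(a11$is_canonical && a11$is_lymphoid)
})

test_that("individual flags aggregate calls with the right implications", {
  expect_equal(summarizeIndividual(NULL, lists)$n_autosomal, 0)
  none <- summarizeIndividual(data.frame(chrom = character(0),
                                         start = numeric(0),
                                         end = numeric(0),
                                         type = character(0)), lists)
  expect_false(any(unlist(none[1:7])))

  one <- summarizeIndividual(call1("chr13", 45e6, 60e6, "loss", cf = 0.35),
                             lists)
  expect_true(one$has_canonical && one$has_driver && one$has_autosomal)
  expect_false(one$has_autosomal_without_driver_or_lymphoid)
  expect_equal(one$max_driver_cf, 0.35)

  other <- summarizeIndividual(call1("chr5", 50e6, 180e6, "loss"), lists)
  expect_true(other$has_autosomal_without_driver_or_lymphoid)
  expect_false(other$has_driver)
  expect_equal(other$max_driver_cf, 0)

  sexy <- summarizeIndividual(call1("chrY", 0, 57e6, "loss"), lists)
  expect_true(sexy$has_loy)
  expect_false(sexy$has_autosomal)

  dup <- cbind(rbind(call1("chr13", 45e6, 60e6, "loss"),
                     call1("chr13", 45e6, 60e6, "loss")),
               call_id = c("c1", "c1"))
  expect_error(summarizeIndividual(dup, lists), "duplicate")
})

test_that("truth events from the generator classify into their categories", {
  cc <- CohortConfig(groupSizes = c(none = 0, lc_mbl = 0, hc_mbl = 200,
                                    cll = 0, sll = 0), seed = 12)
  coh <- generateCohort(cc)
  fl <- summarizeCohort(coh$events, lists,
                        individualIds = coh$individuals$individual_id)
  merged <- merge(coh$individuals, fl, by = "individual_id")
  expect_equal(merged$has_canonical, merged$truth_canonical)
  expect_true(all(merged$has_driver[merged$truth_driver_extra]))
  expect_equal(merged$has_loy, merged$truth_loy)
})
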