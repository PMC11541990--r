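## Synthetic cohorts and synthetic phased SNP-array signals. The generator and
## the detector share one contract: injected events shift het BAF by
## cfToDbaf(type, f) with the sign of the affected haplotype, and LRR by
## expectedLrr(type, f), so detector estimates are directly comparable with
## generator truth.

## Region geometry used when injecting truth events; keyed so that downstream
## taxonomy (with exampleRegionLists()) classifies each category correctly and
## no two categories collide on a chromosome.
truthEventMenu <- function(at) {
  len <- function(ch) at$length[at$chrom == ch]
  cen <- function(ch) at$centromere[at$chrom == ch]
  list(
    canonical = list(
      list(chrom = "chr6", start = cen("chr6"), end = len("chr6"),
           type = "loss"),
      list(chrom = "chr11", start = cen("chr11"), end = len("chr11"),
           type = "loss"),
      list(chrom = "chr12", start = 0, end = len("chr12"), type = "gain"),
      list(chrom = "chr13", start = cen("chr13"), end = len("chr13"),
           type = "loss"),
      list(chrom = "chr17", start = 0, end = cen("chr17"), type = "loss"),
      list(chrom = "chr13", start = cen("chr13"), end = len("chr13"),
           type = "cnn_loh")),
    driver_extra = list(
      list(chrom = "chr8", start = 0, end = 41e6, type = "loss"),
      list(chrom = "chr2", start = 0, end = 61e6, type = "gain"),
      list(chrom = "chr10", start = 101e6, end = 105e6, type = "loss")),
    lymphoid_extra = list(
      list(chrom = "chr14", start = cen("chr14"), end = len("chr14"),
           type = "cnn_loh"),
      list(chrom = "chr22", start = cen("chr22"), end = len("chr22"),
           type = "loss")),
    autosomal_other = list(
      list(chrom = "chr5", start = cen("chr5"), end = len("chr5"),
           type = "loss"),
      list(chrom = "chr4", start = 50e6, end = 120e6, type = "gain"),
      list(chrom = "chr9", start = 0, end = cen("chr9"),
           type = "cnn_loh")),
    loy = list(list(chrom = "chrY", start = 0, end = len("chrY"),
                    type = "loss")),
    lox = list(list(chrom = "chrX", start = 0, end = len("chrX"),
                    type = "loss"))
  )
}

drawDist <- function(spec, n) {
  if (is.null(spec)) return(rep(0, n))
  switch(spec$dist %||% "beta_scaled",
         uniform = runif(n, spec$lower, spec$upper),
         beta_scaled = spec$lower +
           (spec$upper - spec$lower) * rbeta(n, spec$shape1, spec$shape2),
         stop("unknown distribution spec: ", spec$dist))
}

#' Generate a synthetic MBL/CLL cohort with truth mCA events
#'
#' Draws a cohort with the configured group sizes exactly, per-individual
#' phenotypes (sex, age, ALC, B-cell fraction, clonal B-cell percentage,
#' polygenic score, DNA source) from the configured distributions, and
#' per-individual truth mCA events by Bernoulli draws from the group-by-
#' category prevalence matrix. Truth events are placed on disjoint
#' chromosomes per category so each individual's event set is non-overlapping
#' and classifiable by [exampleRegionLists()]. Fully reproducible from the
#' config seed.
#'
#' @param config A [CohortConfig()] object.
#' @return List with `individuals` (one row per individual, including truth
#'   category columns `truth_canonical`, `truth_driver_extra`, ...) and
#'   `events` (chrom, start, end, type, cell_fraction, individual_id,
#'   category).
#' @examples
#' cc <- CohortConfig(groupSizes = c(none = 50, lc_mbl = 10, hc_mbl = 5,
#'                                   cll = 0, sll = 0), seed = 7)
#' coh <- generateCohort(cc)
#' table(coh$individuals$group)
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  at <- defaultArmTable()
  menu <- truthEventMenu(at)
  cats <- mcaCategories()
  withSeed(config@seed, {
    indRows <- list(); evRows <- list()
    for (g in cohortGroups()) {
      n <- config@groupSizes[[g]]
      if (n < 1) next
      ids <- sprintf("%s_%05d", g, seq_len(n))
      male <- runif(n) < config@maleProb[[g]]
      age <- round(rnorm(n, config@ageDist[[g]]$mean,
                         config@ageDist[[g]]$sd), 1)
      alc <- rlnorm(n, config@alcDist[[g]]$meanlog,
                    config@alcDist[[g]]$sdlog)
      prs <- rnorm(n) + config@prsShift[[g]]
      bfrac <- rbeta(n, config@bcellFractionDist[[g]]$shape1,
                     config@bcellFractionDist[[g]]$shape2)
      cpct <- drawDist(config@clonePctDist[[g]], n)
      ccount <- alc * bfrac * cpct / 100
      dna <- ifelse(runif(n) < config@pbmcProb[[g]], "pbmc", "whole_blood")
      carrier <- sapply(cats, function(cat)
        runif(n) < config@categoryPrevalence[g, cat])
      carrier <- matrix(carrier, nrow = n,
                        dimnames = list(NULL, cats))
      carrier[, "loy"] <- carrier[, "loy"] & male
      carrier[, "lox"] <- carrier[, "lox"] & !male
      for (i in seq_len(n)) {
        for (cat in cats) {
          if (!carrier[i, cat]) next
          opts <- menu[[cat]]
          ev <- opts[[if (length(opts) > 1) sample.int(length(opts), 1)
                      else 1L]]
          cf <- config@cfDist$min + (1 - config@cfDist$min) *
            rbeta(1, config@cfDist$shape1, config@cfDist$shape2)
          evRows[[length(evRows) + 1L]] <- data.frame(
            chrom = ev$chrom, start = ev$start, end = ev$end,
            type = ev$type, cell_fraction = cf, individual_id = ids[i],
            category = cat)
        }
      }
      df <- data.frame(individual_id = ids, group = g,
                       sex = ifelse(male, "male", "female"), age = age,
                       alc = alc, prs = prs, bcell_fraction = bfrac,
                       clonal_b_pct = cpct, clonal_b_count = ccount,
                       dna_source = dna,
                       array_type = sample(c("omni", "gsa"), n,
                                           replace = TRUE),
                       batch = sample(paste0("b", 1:4), n, replace = TRUE))
      indRows[[length(indRows) + 1L]] <- cbind(df, carrier)
    }
  })
  individuals <- do.call(rbind, indRows)
  names(individuals)[match(cats, names(individuals))] <-
    paste0("truth_", cats)
  rownames(individuals) <- NULL
  events <- if (length(evRows)) do.call(rbind, evRows)
  else data.frame(chrom = character(0), start = numeric(0),
                  end = numeric(0), type = character(0),
                  cell_fraction = numeric(0), individual_id = character(0),
                  category = character(0))
  rownames(events) <- NULL
  list(individuals = individuals, events = events)
}

#' Simulate phased SNP-array signals with injected mosaic events
#'
#' Emits a site table per chromosome: probe positions uniform over the
#' chromosome, heterozygous with the configured probability, BAF centered at
#' 0/0.5/1 by genotype and LRR at 0, with Gaussian noise. Inside an injected
#' event, heterozygous BAF is shifted by `cfToDbaf(type, f)` with the sign
#' given by which haplotype carries the B allele (the event always affects
#' haplotype 1), and LRR is shifted by `expectedLrr(type, f)` at all probes.
#' Phased haplotype labels carry cumulative switch errors at the configured
#' rate. BAF is truncated (not resampled) to \code{[0, 1]}.
#'
#' @param events data.frame of events (`chrom`, `start`, `end`, `type`,
#'   `cell_fraction`), non-overlapping within a chromosome; may be empty.
#' @param config An [ArraySimConfig()] object.
#' @param chroms Chromosomes to emit; defaults to the event chromosomes, or
#'   `"chr1"` when there are none.
#' @param armTable Chromosome lengths (defaults to [defaultArmTable()]).
#' @return data.frame of sites: `chrom`, `pos`, `genotype` (`AA`/`AB`/`BB`),
#'   `hap` (+1/-1, `NA` for homozygotes), `baf`, `lrr`.
#' @examples
#' ev <- data.frame(chrom = "chr1", start = 1e6, end = 5e7,
#'                  type = "cnn_loh", cell_fraction = 0.4)
#' sites <- simulateArraySignals(ev, ArraySimConfig(nSites = 2000, seed = 3))
#' @export
simulateArraySignals <- function(events, config = ArraySimConfig(),
                                 chroms = NULL, armTable = defaultArmTable()) {
  stopifnot(is(config, "ArraySimConfig"))
  validObject(config)
  chroms <- chroms %||% (if (nrow(events)) unique(events$chrom) else "chr1")
  for (ch in unique(events$chrom)) {
    ev <- events[events$chrom == ch, , drop = FALSE]
    ev <- ev[order(ev$start), , drop = FALSE]
    if (nrow(ev) > 1 && any(ev$start[-1] < ev$end[-nrow(ev)]))
      stop("overlapping events on ", ch)
  }
  out <- withSeed(config@seed, lapply(chroms, function(ch) {
    len <- armTable$length[armTable$chrom == ch]
    if (!length(len)) stop("chromosome ", ch, " not in arm table")
    n <- config@nSites
    pos <- sort(sample.int(len, n))
    het <- runif(n) < config@hetFraction
    genotype <- ifelse(het, "AB", ifelse(runif(n) < 0.5, "AA", "BB"))
    ## truth phase: +1 when the B allele sits on haplotype 1 (the haplotype
    ## every injected event affects)
    tHap <- ifelse(runif(n) < 0.5, 1L, -1L)
    bafMu <- ifelse(genotype == "AB", 0.5, ifelse(genotype == "BB", 1, 0))
    lrrMu <- rep(0, n)
    ev <- events[events$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      inEv <- pos >= ev$start[i] & pos < ev$end[i]
      shift <- cfToDbaf(ev$type[i], ev$cell_fraction[i])
      bafMu[inEv & het] <- 0.5 + tHap[inEv & het] * shift
      lrrMu[inEv] <- expectedLrr(ev$type[i], ev$cell_fraction[i])
    }
    baf <- pmin(1, pmax(0, bafMu + rnorm(n, 0, config@bafSd)))
    lrr <- lrrMu + rnorm(n, 0, config@lrrSd)
    ## observed phase labels: cumulative switch errors along het sites
    hap <- rep(NA_integer_, n)
    idx <- which(het)
    if (length(idx)) {
      sw <- if (length(idx) > 1)
        rbinom(length(idx) - 1L, 1L, config@phaseSwitchRate) else integer(0)
      flip <- cumprod(c(1L, 1L - 2L * sw))
      hap[idx] <- tHap[idx] * flip
    }
    data.frame(chrom = ch, pos = pos, genotype = genotype, hap = hap,
               baf = baf, lrr = lrr)
  }))
  do.call(rbind, out)
}

#' Simulate a case-control cohort with a known exposure odds ratio
#'
#' Utility for parameter-recovery checks of the logistic association
#' machinery: a binary exposure with prevalence `exposurePrev`, age and sex
#' covariates, and an outcome drawn from a logistic model whose exposure
#' coefficient is `log(oddsRatio)`.
#'
#' @param n Cohort size.
#' @param oddsRatio True exposure odds ratio.
#' @param seed RNG seed.
#' @param exposurePrev Exposure prevalence.
#' @param baselineLogit Intercept of the outcome model.
#' @param betaAge,betaSex Covariate effects (age centered at 65).
#' @return data.frame with `outcome`, `exposure`, `age`, `sex`.
#' @export
simulateOrCohort <- function(n, oddsRatio, seed = 1L, exposurePrev = 0.15,
                             baselineLogit = qlogis(0.10), betaAge = 0.02,
                             betaSex = 0.3) {
  withSeed(seed, {
    exposure <- as.integer(runif(n) < exposurePrev)
    age <- rnorm(n, 65, 9)
    sex <- as.integer(runif(n) < 0.45)
    eta <- baselineLogit + log(oddsRatio) * exposure +
      betaAge * (age - 65) + betaSex * sex
    outcome <- as.integer(runif(n) < plogis(eta))
    data.frame(outcome = outcome, exposure = exposure, age = age, sex = sex)
  })
}
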