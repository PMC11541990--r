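#' @import methods
#' @importFrom stats rnorm runif rbeta rbinom rlnorm sd mad median qlogis plogis
#'   glm binomial coef vcov wilcox.test quantile setNames complete.cases
#' @importFrom utils read.delim write.table head
NULL

## ---------------------------------------------------------------------------
## ArraySimConfig: signal model for one simulated SNP array
## ---------------------------------------------------------------------------

#' @rdname ArraySimConfig
#' @export
setClass("ArraySimConfig", representation(
  nSites = "integer",
  hetFraction = "numeric",
  bafSd = "numeric",
  lrrSd = "numeric",
  phaseSwitchRate = "numeric",
  seed = "integer"
))

setValidity("ArraySimConfig", function(object) {
  msg <- character()
  if (object@nSites < 1) msg <- c(msg, "nSites must be >= 1")
  if (object@hetFraction < 0 || object@hetFraction > 1)
    msg <- c(msg, "hetFraction must lie in [0, 1]")
  if (object@bafSd <= 0) msg <- c(msg, "bafSd must be > 0")
  if (object@lrrSd <= 0) msg <- c(msg, "lrrSd must be > 0")
  if (object@phaseSwitchRate < 0 || object@phaseSwitchRate >= 0.5)
    msg <- c(msg, "phaseSwitchRate must lie in [0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic SNP-array signal model
#'
#' Describes per-site noise of a simulated genotyping array: how many probes a
#' chromosome carries, the fraction that are heterozygous, Gaussian noise on
#' B-allele frequency (BAF) and log R ratio (LRR), and the rate of phase switch
#' errors between adjacent heterozygous sites.
#'
#' @param nSites Number of probes per chromosome.
#' @param hetFraction Probability that a probe is heterozygous.
#' @param bafSd Standard deviation of per-site BAF noise (BAF is truncated to
#'   \code{[0, 1]} after noise is added).
#' @param lrrSd Standard deviation of per-site LRR noise.
#' @param phaseSwitchRate Probability, per adjacent heterozygous pair, that the
#'   phased haplotype label flips (switch errors accumulate along the
#'   chromosome, as in real statistical phasing).
#' @param seed Integer RNG seed.
#' @return An `ArraySimConfig` object.
#' @examples
#' ArraySimConfig(nSites = 5000, bafSd = 0.03)
#' @export
ArraySimConfig <- function(nSites = 10000L, hetFraction = 0.33,
                           bafSd = 0.03, lrrSd = 0.14,
                           phaseSwitchRate = 0.002, seed = 1L) {
  new("ArraySimConfig", nSites = as.integer(nSites),
      hetFraction = hetFraction, bafSd = bafSd, lrrSd = lrrSd,
      phaseSwitchRate = phaseSwitchRate, seed = as.integer(seed))
}

setMethod("show", "ArraySimConfig", function(object) {
  cat("ArraySimConfig:", object@nSites, "sites/chrom,",
      sprintf("het %.2f, bafSd %.3f, lrrSd %.3f, switch %.4f, seed %d\n",
              object@hetFraction, object@bafSd, object@lrrSd,
              object@phaseSwitchRate, object@seed))
})

## ---------------------------------------------------------------------------
## CohortConfig: generative model for a synthetic MBL/CLL cohort
## ---------------------------------------------------------------------------

#' @rdname CohortConfig
#' @export
setClass("CohortConfig", representation(
  groupSizes = "numeric",
  categoryPrevalence = "matrix",
  clonePctDist = "list",
  bcellFractionDist = "list",
  alcDist = "list",
  prsShift = "numeric",
  cfDist = "list",
  maleProb = "numeric",
  ageDist = "list",
  pbmcProb = "numeric",
  seed = "integer"
))

cohortGroups <- function() c("none", "lc_mbl", "hc_mbl", "cll", "sll")
mcaCategories <- function()
  c("canonical", "driver_extra", "lymphoid_extra", "autosomal_other",
    "loy", "lox")

setValidity("CohortConfig", function(object) {
  msg <- character()
  g <- cohortGroups()
  if (!all(g %in% names(object@groupSizes)))
    msg <- c(msg, "groupSizes must be named for all five groups")
  if (any(object@groupSizes < 0)) msg <- c(msg, "group sizes must be >= 0")
  p <- object@categoryPrevalence
  if (!all(rownames(p) == g) || !all(colnames(p) == mcaCategories()))
    msg <- c(msg, "categoryPrevalence must be a group x category matrix")
  if (any(p < 0 | p > 1)) msg <- c(msg, "prevalences must lie in [0, 1]")
  if (object@cfDist$min <= 0 || object@cfDist$min > 1)
    msg <- c(msg, "cfDist$min must lie in (0, 1]")
  if (any(object@maleProb < 0 | object@maleProb > 1))
    msg <- c(msg, "maleProb must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

defaultCategoryPrevalence <- function() {
  g <- cohortGroups()
  p <- matrix(0, nrow = length(g), ncol = length(mcaCategories()),
              dimnames = list(g, mcaCategories()))
  p[, "canonical"]       <- c(0.0013, 0.011, 0.521, 0.671, 0.452)
  p[, "driver_extra"]    <- c(0.010, 0.012, 0.051, 0.073, 0.106)
  p[, "lymphoid_extra"]  <- c(0.002, 0.002, 0.010, 0.010, 0.056)
  p[, "autosomal_other"] <- c(0.100, 0.100, 0.100, 0.120, 0.120)
  p[, "loy"]             <- 0.150
  p[, "lox"]             <- 0.017
  p
}

#' Configuration of the synthetic cohort generator
#'
#' Encodes the generative assumptions of a screened MBL/CLL cohort: group
#' sizes, per-group prevalence of each mCA category, clone-size and B-cell
#' fraction distributions, lymphocyte counts, and a polygenic-score shift.
#' Defaults mirror a large single-center cohort: 2971 individuals without MBL,
#' 728 with low-count MBL, 332 with high-count MBL, 497 with CLL and 104 with
#' SLL, with canonical CLL-associated mCAs common in HC-MBL (around half of
#' individuals) and rare otherwise.
#'
#' @param groupSizes Named counts for groups `none`, `lc_mbl`, `hc_mbl`,
#'   `cll`, `sll`.
#' @param categoryPrevalence Group-by-category probability matrix; categories
#'   are `canonical`, `driver_extra` (CLL-driver but not canonical),
#'   `lymphoid_extra` (lymphoid but not driver), `autosomal_other`, `loy`
#'   (males only), `lox` (females only).
#' @param clonePctDist Per-group distribution spec for clonal B cells as a
#'   percentage of total B cells. Low-count MBL uses a Beta scaled to
#'   (0, 85); high-count MBL Uniform(85, 100).
#' @param bcellFractionDist Per-group Beta parameters for the B-cell fraction
#'   of PBMCs.
#' @param alcDist Per-group lognormal (`meanlog`, `sdlog`) for absolute
#'   lymphocyte count in cells/uL.
#' @param prsShift Per-group mean shift of a standard-normal polygenic risk
#'   score.
#' @param cfDist Beta spec (`shape1`, `shape2`, `min`) for event cell
#'   fractions, rescaled to (`min`, 1].
#' @param maleProb Per-group probability of male sex.
#' @param ageDist Per-group normal (`mean`, `sd`) for age in years.
#' @param pbmcProb Per-group probability that DNA came from PBMCs rather than
#'   whole blood.
#' @param seed Integer RNG seed.
#' @return A `CohortConfig` object.
#' @examples
#' cfg <- CohortConfig(groupSizes = c(none = 100, lc_mbl = 20, hc_mbl = 10,
#'                                    cll = 0, sll = 0))
#' cfg
#' @export
CohortConfig <- function(groupSizes = c(none = 2971, lc_mbl = 728,
                                        hc_mbl = 332, cll = 497, sll = 104),
                         categoryPrevalence = defaultCategoryPrevalence(),
                         clonePctDist = list(
                           none   = NULL,
                           lc_mbl = list(dist = "beta_scaled", shape1 = 1.5,
                                         shape2 = 4, lower = 0, upper = 85),
                           hc_mbl = list(dist = "uniform", lower = 85,
                                         upper = 100),
                           cll    = list(dist = "uniform", lower = 90,
                                         upper = 100),
                           sll    = list(dist = "uniform", lower = 90,
                                         upper = 100)),
                         bcellFractionDist = list(
                           none   = list(shape1 = 2, shape2 = 18),
                           lc_mbl = list(shape1 = 2, shape2 = 18),
                           hc_mbl = list(shape1 = 4, shape2 = 12),
                           cll    = list(shape1 = 12, shape2 = 4),
                           sll    = list(shape1 = 6, shape2 = 10)),
                         alcDist = list(
                           none   = list(meanlog = log(1700), sdlog = 0.25),
                           lc_mbl = list(meanlog = log(2000), sdlog = 0.25),
                           hc_mbl = list(meanlog = log(4500), sdlog = 0.35),
                           cll    = list(meanlog = log(12000), sdlog = 0.60),
                           sll    = list(meanlog = log(2500), sdlog = 0.40)),
                         prsShift = c(none = 0, lc_mbl = 0.25, hc_mbl = 0.55,
                                      cll = 0.70, sll = 0.70),
                         cfDist = list(shape1 = 1.2, shape2 = 2.5,
                                       min = 0.01),
                         maleProb = c(none = 0.401, lc_mbl = 0.45,
                                      hc_mbl = 0.55, cll = 0.717, sll = 0.65),
                         ageDist = list(
                           none   = list(mean = 65, sd = 9),
                           lc_mbl = list(mean = 72, sd = 8),
                           hc_mbl = list(mean = 70, sd = 8),
                           cll    = list(mean = 66, sd = 9),
                           sll    = list(mean = 67, sd = 9)),
                         pbmcProb = c(none = 0, lc_mbl = 0.003, hc_mbl = 0.10,
                                      cll = 0.05, sll = 0.01),
                         seed = 1L) {
  gs <- setNames(rep(0, length(cohortGroups())), cohortGroups())
  gs[names(groupSizes)] <- groupSizes
  new("CohortConfig", groupSizes = gs,
      categoryPrevalence = categoryPrevalence,
      clonePctDist = clonePctDist, bcellFractionDist = bcellFractionDist,
      alcDist = alcDist, prsShift = prsShift[cohortGroups()],
      cfDist = cfDist, maleProb = maleProb[cohortGroups()],
      ageDist = ageDist, pbmcProb = pbmcProb[cohortGroups()],
      seed = as.integer(seed))
}

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig with", sum(object@groupSizes), "individuals:\n")
  print(object@groupSizes)
  cat("mCA category prevalence (group x category):\n")
  print(round(object@categoryPrevalence, 4))
})

## ---------------------------------------------------------------------------
## RegionLists: interval definitions behind the mCA taxonomy
## ---------------------------------------------------------------------------

#' @rdname RegionLists
#' @export
setClass("RegionLists", representation(
  canonical = "data.frame",
  driverCandidates = "data.frame",
  lymphoid = "data.frame",
  armTable = "data.frame",
  genome = "character",
  trisomyCoverage = "numeric"
))

setValidity("RegionLists", function(object) {
  msg <- character()
  at <- object@armTable
  need <- c("chrom", "length", "centromere")
  if (!all(need %in% names(at)))
    msg <- c(msg, "armTable needs columns chrom, length, centromere")
  else {
    if (any(at$centromere <= 0 | at$centromere >= at$length))
      msg <- c(msg, "centromere must fall inside the chromosome")
    refd <- unique(c(object@canonical$chrom, object@driverCandidates$chrom,
                     object@lymphoid$chrom))
    if (!all(refd %in% at$chrom))
      msg <- c(msg, paste("armTable missing chromosomes:",
                          paste(setdiff(refd, at$chrom), collapse = ", ")))
  }
  dc <- object@driverCandidates
  if (nrow(dc) && any(dc$start >= dc$end))
    msg <- c(msg, "driver candidate intervals must satisfy start < end")
  if (nrow(dc) && !all(dc$type %in% mcaTypes()))
    msg <- c(msg, "driver candidate types must be loss/gain/cnn_loh")
  if (object@trisomyCoverage <= 0 || object@trisomyCoverage > 1)
    msg <- c(msg, "trisomyCoverage must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Region definitions for the mCA taxonomy
#'
#' Bundles the interval rules used to classify mosaic chromosomal alteration
#' calls: the canonical CLL FISH-panel loci (del 6q, del 11q, trisomy 12,
#' del 13q, del 17p, plus copy-neutral LOH on 13q anchored at *MIR16-1*), a
#' list of candidate CLL-driver regions matched by full containment, a list of
#' lymphoid-malignancy-associated chromosome/arm entries, and a chromosome arm
#' table (length and centromere per chromosome).
#'
#' @param canonical data.frame with columns `chrom`, `arm` (`"p"`, `"q"` or
#'   `NA` for whole-chromosome rules), `type`, `rule` (`"arm_overlap"`,
#'   `"whole_chromosome"` or `"anchor"`), `anchor_start`, `anchor_end`.
#' @param driverCandidates data.frame with columns `chrom`, `start`, `end`,
#'   `type` (0-based half-open coordinates).
#' @param lymphoid data.frame with columns `chrom`, `arm` (`NA` for whole
#'   chromosome), `type`.
#' @param armTable data.frame with columns `chrom`, `length`, `centromere`.
#' @param genome Genome build tag the coordinates refer to.
#' @param trisomyCoverage Minimum fraction of the chromosome a gain call must
#'   cover to count as a whole-chromosome trisomy.
#' @return A `RegionLists` object.
#' @seealso [exampleRegionLists()] for a ready-made example set,
#'   [readRegionLists()] to load definitions from YAML.
#' @export
RegionLists <- function(canonical, driverCandidates, lymphoid, armTable,
                        genome = "unspecified", trisomyCoverage = 0.8) {
  new("RegionLists", canonical = canonical,
      driverCandidates = driverCandidates, lymphoid = lymphoid,
      armTable = armTable, genome = genome,
      trisomyCoverage = trisomyCoverage)
}

setMethod("show", "RegionLists", function(object) {
  cat("RegionLists (genome ", object@genome, "):\n", sep = "")
  cat("  canonical loci:    ", nrow(object@canonical), "\n")
  cat("  driver candidates: ", nrow(object@driverCandidates), "\n")
  cat("  lymphoid entries:  ", nrow(object@lymphoid), "\n")
  cat("  arm table:         ", nrow(object@armTable), "chromosomes\n")
})

#' @describeIn RegionLists Arm table accessor.
#' @param x A `RegionLists` object.
#' @export
armTable <- function(x) x@armTable

#' @describeIn RegionLists Canonical locus table accessor.
#' @export
canonicalRegions <- function(x) x@canonical

#' @describeIn RegionLists Driver candidate table accessor.
#' @export
driverCandidates <- function(x) x@driverCandidates

#' @describeIn RegionLists Lymphoid entry table accessor.
#' @export
lymphoidRegions <- function(x) x@lymphoid
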