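## mCA detection from phased BAF/LRR site tables: CUSUM binary segmentation of
## the signed phased deviation, z-threshold candidate emission, bootstrap
## boundary refinement, type classification, and call-level filters.

#' Detection tuning parameters
#'
#' Defaults are chosen so that event-free chromosomes at realistic array noise
#' essentially never produce a call (family-wise z threshold of 5) while
#' clones at a fraction of a percent remain detectable on well-covered
#' chromosomes.
#'
#' @param minHets Minimum heterozygous sites for any statistic or segment.
#' @param zThreshold z statistic a segment must reach to be emitted.
#' @param splitZ CUSUM z a change point must reach for a segment split.
#' @param lrrMargin Copy-neutral LRR band half-width for type calls.
#' @param nBoot Bootstrap resamples for boundary refinement.
#' @param fpRate Target family-wise false-positive calls per chromosome; a
#'   reporting target, not a knob the detector reads.
#' @param minCallRate Sample-level genotype call-rate filter.
#' @param maxBafDev Sample-level `|median BAF - 0.5|` filter (high B-allele
#'   frequency).
#' @param minPhaseConcordance Minimum fraction of sign-consistent hets in a
#'   segment (phase-quality proxy).
#' @param germlineDbafTol A call within this tolerance of the constitutional
#'   deviation 0.5 (with matching integer-copy LRR) is flagged germline.
#' @param germlineLrrTol LRR tolerance for the germline flag.
#' @param minSexLossCf Minimum LRR-derived fraction for a sex-chromosome loss
#'   call.
#' @param sexLossP p-value threshold of the median-shift test for LoY/LoX.
#' @param seed Seed for the boundary bootstrap.
#' @return A named list of parameters.
#' @export
detectionConfig <- function(minHets = 25L, zThreshold = 5, splitZ = 5,
                            lrrMargin = 0.05, nBoot = 25L, fpRate = 0.01,
                            minCallRate = 0.97, maxBafDev = 0.05,
                            minPhaseConcordance = 0.6,
                            germlineDbafTol = 0.05, germlineLrrTol = 0.1,
                            minSexLossCf = 0.05, sexLossP = 0.01,
                            seed = 1L) {
  stopifnot(minHets >= 2, zThreshold > 0, splitZ > 0, nBoot >= 1)
  list(minHets = as.integer(minHets), zThreshold = zThreshold,
       splitZ = splitZ, lrrMargin = lrrMargin, nBoot = as.integer(nBoot),
       fpRate = fpRate, minCallRate = minCallRate, maxBafDev = maxBafDev,
       minPhaseConcordance = minPhaseConcordance,
       germlineDbafTol = germlineDbafTol, germlineLrrTol = germlineLrrTol,
       minSexLossCf = minSexLossCf, sexLossP = sexLossP,
       seed = as.integer(seed))
}

#' Signed phased BAF deviation of a window of heterozygous sites
#'
#' The workhorse statistic of the detector: per-site deviations
#' `hap * (baf - 0.5)` share a common sign inside a mosaic event when phasing
#' is correct, so their mean estimates the event's BAF shift even at cell
#' fractions far below the per-site noise.
#'
#' @param sites data.frame of heterozygous sites with columns `baf` and `hap`
#'   (+1/-1 phased haplotype label).
#' @param minHets Windows with fewer hets return a no-call (`NA` statistics).
#' @return List with `dbaf` (|mean deviation|), `z` (mean / standard error),
#'   `n` and `noCall`.
#' @examples
#' s <- data.frame(baf = rep(0.75, 100), hap = 1)
#' signedPhasedDeviation(s)  # dbaf 0.25
#' @export
signedPhasedDeviation <- function(sites, minHets = 25L) {
  d <- sites$hap * (sites$baf - 0.5)
  n <- length(d)
  if (n < minHets)
    return(list(dbaf = NA_real_, z = NA_real_, n = n, noCall = TRUE))
  m <- mean(d)
  s <- sd(d)
  dbaf <- abs(m)
  z <- if (s > 0) dbaf / (s / sqrt(n)) else if (dbaf > 0) Inf else 0
  list(dbaf = dbaf, z = z, n = n, noCall = FALSE)
}

## Best single change point of the mean of d by standardized CUSUM.
## Returns k (last index of the left part) and the z of the split; the argmax
## is restricted to k in [lo, hi]; ties break toward the smaller index.
cusumChangepoint <- function(d, lo = 1L, hi = length(d) - 1L,
                             sigma = NULL) {
  n <- length(d)
  if (n < 2L || lo > hi) return(list(k = NA_integer_, z = 0))
  s <- cumsum(d)
  k <- lo:hi
  sigma <- sigma %||% max(sd(d), 1e-9)
  z <- abs(s[k] - (k / n) * s[n]) / (sigma * sqrt(k * (n - k) / n))
  j <- which.max(z)           # first maximum: ties toward the smaller index
  list(k = k[j], z = z[j])
}

#' Scan one chromosome for allelic-imbalance segments
#'
#' Recursive binary change-point segmentation of the signed phased deviation
#' sequence: the sequence is split wherever the standardized CUSUM of a
#' candidate change point exceeds `splitZ` (with both sides keeping at least
#' `minHets` hets), and each resulting leaf segment whose mean-deviation z
#' statistic reaches `zThreshold` is emitted as a candidate. Candidates are
#' non-overlapping by construction; a whole-chromosome event yields a single
#' candidate spanning all hets.
#'
#' @param sites data.frame of one chromosome's sites, sorted by `pos`, with
#'   columns `pos`, `genotype`, `hap`, `baf`.
#' @param config A [detectionConfig()] list.
#' @return data.frame of candidates: `start`, `end` (bp, 0-based half-open),
#'   `i0`, `i1` (het-index range), `n_hets`, `dbaf`, `z`.
#' @export
segmentScan <- function(sites, config = detectionConfig()) {
  if (is.unsorted(sites$pos)) stop("sites must be sorted by position")
  hs <- sites[sites$genotype == "AB", , drop = FALSE]
  d <- hs$hap * (hs$baf - 0.5)
  n <- length(d)
  out <- list()
  if (n >= config$minHets) {
    sigma <- max(sd(d), 1e-9)
    stack <- list(c(1L, n))
    while (length(stack)) {
      rg <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      i <- rg[1]; j <- rg[2]; m <- j - i + 1L
      split <- FALSE
      if (m >= 2L * config$minHets) {
        cp <- cusumChangepoint(d[i:j], lo = config$minHets,
                               hi = m - config$minHets, sigma = sigma)
        if (!is.na(cp$k) && cp$z > config$splitZ) {
          stack <- c(stack, list(c(i, i + cp$k - 1L), c(i + cp$k, j)))
          split <- TRUE
        }
      }
      if (!split) {
        st <- signedPhasedDeviation(hs[i:j, , drop = FALSE],
                                    minHets = config$minHets)
        if (!st$noCall && st$z >= config$zThreshold)
          out[[length(out) + 1L]] <- data.frame(
            start = hs$pos[i], end = hs$pos[j] + 1, i0 = i, i1 = j,
            n_hets = st$n, dbaf = st$dbaf, z = st$z)
      }
    }
  }
  if (!length(out))
    return(data.frame(start = numeric(0), end = numeric(0),
                      i0 = integer(0), i1 = integer(0),
                      n_hets = integer(0), dbaf = numeric(0),
                      z = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' Refine segment boundaries by resampling
#'
#' Re-localizes the two change points of a candidate segment by maximizing the
#' CUSUM of the signed phased deviation in a flanked window around each
#' boundary, over bootstrap resamples of the het sites; the per-boundary
#' median across resamples is returned. The first replicate uses the original
#' data, so `nBoot = 1` is the plain (deterministic) CUSUM fit.
#'
#' @param sites One chromosome's sites, sorted by `pos`.
#' @param segment One row of [segmentScan()] output (needs `i0`, `i1`).
#' @param nBoot Number of resamples (>= 1).
#' @param seed RNG seed for the resampling.
#' @param flank Hets of flank on each side of the segment used for
#'   localization; defaults to the segment's het count, clipped to the
#'   chromosome.
#' @return List with `start` and `end` (bp, half-open) medians, plus the
#'   per-replicate `starts` and `ends`.
#' @export
refineBoundaries <- function(sites, segment, nBoot = 100L, seed = 1L,
                             flank = NULL) {
  if (nBoot < 1) stop("nBoot must be >= 1")
  hs <- sites[sites$genotype == "AB", , drop = FALSE]
  d <- hs$hap * (hs$baf - 0.5)
  n <- length(d)
  i0 <- segment$i0; i1 <- segment$i1
  w <- i1 - i0 + 1L
  flank <- flank %||% w
  mid <- i0 + (i1 - i0) %/% 2L
  locate <- function(idx, leftBoundary) {
    ## change index within idx; returns boundary in bp
    cp <- cusumChangepoint(d[idx])
    if (is.na(cp$k)) return(NA_real_)
    if (leftBoundary) {
      ## first het of the event is element k+1 of idx
      hs$pos[idx[min(cp$k + 1L, length(idx))]]
    } else {
      hs$pos[idx[cp$k]] + 1
    }
  }
  leftWin <- max(1L, i0 - flank):mid
  rightWin <- mid:min(n, i1 + flank)
  starts <- numeric(nBoot); ends <- numeric(nBoot)
  withSeed(seed, {
    for (b in seq_len(nBoot)) {
      li <- if (b == 1L) leftWin else sort(sample(leftWin, length(leftWin),
                                                  replace = TRUE))
      ri <- if (b == 1L) rightWin else sort(sample(rightWin, length(rightWin),
                                                   replace = TRUE))
      starts[b] <- locate(li, leftBoundary = TRUE)
      ends[b] <- locate(ri, leftBoundary = FALSE)
    }
  })
  list(start = median(starts, na.rm = TRUE),
       end = median(ends, na.rm = TRUE), starts = starts, ends = ends)
}

fullClonalLrr <- function(type) {
  vapply(type, function(t) switch(t, loss = -1, gain = log2(1.5),
                                  cnn_loh = 0, NA_real_), numeric(1),
         USE.NAMES = FALSE)
}

#' Filter mCA calls on sample- and call-level quality
#'
#' Drops (or flags) calls from samples with low genotype call rate or a
#' shifted baseline B-allele frequency, calls with poor phase concordance, and
#' likely germline events: a deviation within tolerance of the constitutional
#' value 0.5 together with a mean LRR matching the corresponding integer copy
#' number (-1 for a constitutional deletion, 0 for isodisomy, log2(1.5) for a
#' duplication).
#'
#' @param calls data.frame with columns `dbaf`, `mean_lrr`, `type` and
#'   `phase_concordance`.
#' @param sampleQc Named list or one-row data.frame with `call_rate` and
#'   `baf_median`.
#' @param config A [detectionConfig()] list.
#' @param drop If `TRUE` (default) only passing calls are returned; otherwise
#'   all calls are returned with the `filter` column set.
#' @return The call table with a `filter` column (`"PASS"` or
#'   semicolon-joined reasons), subset to passing calls when `drop`.
#' @export
applyFilters <- function(calls, sampleQc, config = detectionConfig(),
                         drop = TRUE) {
  for (m in c("call_rate", "baf_median"))
    if (is.null(sampleQc[[m]]) || is.na(sampleQc[[m]]))
      stop("sample QC metric missing: ", m)
  for (m in c("dbaf", "mean_lrr", "type", "phase_concordance"))
    if (is.null(calls[[m]]))
      stop("call metric missing: ", m)
  n <- nrow(calls)
  reasons <- vector("list", n)
  if (sampleQc$call_rate < config$minCallRate)
    reasons <- lapply(reasons, c, "sample_call_rate")
  if (abs(sampleQc$baf_median - 0.5) > config$maxBafDev)
    reasons <- lapply(reasons, c, "sample_baf")
  for (i in seq_len(n)) {
    if (!is.na(calls$phase_concordance[i]) &&
        calls$phase_concordance[i] < config$minPhaseConcordance)
      reasons[[i]] <- c(reasons[[i]], "phase_quality")
    expLrr <- fullClonalLrr(calls$type[i])
    if (!is.na(calls$dbaf[i]) && !is.na(expLrr) &&
        calls$dbaf[i] >= 0.5 - config$germlineDbafTol &&
        abs(calls$mean_lrr[i] - expLrr) <= config$germlineLrrTol)
      reasons[[i]] <- c(reasons[[i]], "germline")
  }
  calls$filter <- vapply(reasons, function(r)
    if (length(r)) paste(r, collapse = ";") else "PASS", character(1))
  if (drop) calls[calls$filter == "PASS", , drop = FALSE] else calls
}

#' Detect mosaic loss of a sex chromosome from LRR
#'
#' Male X/Y and the inactive-X problem leave no usable het BAF on the sex
#' chromosomes, so LoY (males) and LoX (females) are called from the median
#' LRR shift alone: `f = 2 * (1 - 2^medianLrr)`, clipped to \code{[0, 1]},
#' with a one-sided location test guarding against noise.
#'
#' @param sites Sites on chrX or chrY (columns `chrom`, `pos`, `lrr`).
#' @param sex `"male"` or `"female"`.
#' @param config A [detectionConfig()] list.
#' @return A one-row call data.frame, or `NULL` when no loss is called.
#' @export
detectSexChromLoss <- function(sites, sex, config = detectionConfig()) {
  chrom <- unique(sites$chrom)
  if (length(chrom) != 1L || !chrom %in% c("chrX", "chrY"))
    stop("sites must come from a single sex chromosome (chrX or chrY)")
  sex <- match.arg(sex, c("male", "female"))
  if ((sex == "male" && chrom == "chrX") ||
      (sex == "female" && chrom == "chrY"))
    return(NULL)
  med <- median(sites$lrr)
  f <- min(1, max(0, 2 * (1 - 2^med)))
  p <- tryCatch(stats::t.test(sites$lrr, mu = 0,
                              alternative = "less")$p.value,
                error = function(e) 1)
  if (f < config$minSexLossCf || p >= config$sexLossP) return(NULL)
  data.frame(chrom = chrom, start = 0, end = max(sites$pos) + 1,
             type = "loss", dbaf = NA_real_, mean_lrr = med,
             cell_fraction = f, n_hets = 0L,
             quality = -log10(max(p, 1e-300)),
             phase_concordance = NA_real_)
}

#' Detect mCAs on a sample's site table
#'
#' End-to-end per-sample detector: per autosome, [segmentScan()] proposes
#' candidate segments, [refineBoundaries()] sharpens their end points, and
#' each refined segment is summarized (phased deviation, mean LRR over all
#' probes in the interval, phase concordance), typed with
#' [classifyEventType()] and converted to a cell fraction with [dbafToCf()]
#' (undetermined calls fall back to the copy-neutral relation `f = 2 dbaf`).
#' Sex chromosomes, when present and `sex` is given, are screened with
#' [detectSexChromLoss()]. If `sampleQc` is supplied, [applyFilters()] is
#' applied with `drop = FALSE` so the `filter` column is populated.
#'
#' @param sites Site table (`chrom`, `pos`, `genotype`, `hap`, `baf`, `lrr`),
#'   sorted by position within chromosome.
#' @param config A [detectionConfig()] list.
#' @param sex Optional `"male"`/`"female"` for sex-chromosome screening.
#' @param sampleQc Optional sample QC metrics for [applyFilters()].
#' @return data.frame of calls: `chrom`, `start`, `end`, `type`, `dbaf`,
#'   `mean_lrr`, `cell_fraction`, `n_hets`, `quality`, `phase_concordance`
#'   (+ `filter` when QC given).
#' @export
detectMca <- function(sites, config = detectionConfig(), sex = NULL,
                      sampleQc = NULL) {
  calls <- list()
  for (chrom in unique(sites$chrom)) {
    cs <- sites[sites$chrom == chrom, , drop = FALSE]
    if (chrom %in% c("chrX", "chrY")) {
      if (!is.null(sex)) {
        sc <- detectSexChromLoss(cs, sex, config)
        if (!is.null(sc)) calls[[length(calls) + 1L]] <- sc
      }
      next
    }
    cand <- segmentScan(cs, config)
    if (!nrow(cand)) next
    hs <- cs[cs$genotype == "AB", , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      rb <- refineBoundaries(cs, cand[i, ], nBoot = config$nBoot,
                             seed = childSeed(config$seed, i))
      start <- rb$start; end <- rb$end
      inHet <- hs$pos >= start & hs$pos < end
      if (sum(inHet) < config$minHets) { start <- cand$start[i]
        end <- cand$end[i]
        inHet <- hs$pos >= start & hs$pos < end }
      st <- signedPhasedDeviation(hs[inHet, , drop = FALSE],
                                  minHets = config$minHets)
      if (st$noCall || st$z < config$zThreshold) next
      d <- hs$hap[inHet] * (hs$baf[inHet] - 0.5)
      conc <- max(mean(d > 0), mean(d < 0))
      inAll <- cs$pos >= start & cs$pos < end
      meanLrr <- mean(cs$lrr[inAll])
      type <- classifyEventType(st$dbaf, meanLrr, config$lrrMargin)
      dbafCapped <- min(st$dbaf, 0.5)
      cf <- if (type == "undetermined") 2 * dbafCapped
            else if (type == "gain" && dbafCapped > 1/6) 1
            else dbafToCf(type, dbafCapped)
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = chrom, start = start, end = end, type = type,
        dbaf = st$dbaf, mean_lrr = meanLrr, cell_fraction = cf,
        n_hets = st$n, quality = st$z, phase_concordance = conc)
    }
  }
  if (!length(calls))
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), type = character(0),
                      dbaf = numeric(0), mean_lrr = numeric(0),
                      cell_fraction = numeric(0), n_hets = integer(0),
                      quality = numeric(0), phase_concordance = numeric(0))
  else out <- do.call(rbind, calls)
  rownames(out) <- NULL
  if (!is.null(sampleQc)) out <- applyFilters(out, sampleQc, config,
                                              drop = FALSE)
  out
}
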