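## mCA taxonomy: canonical CLL-associated / CLL-driver / lymphoid categories
## assigned to segment calls by genomic-interval rules.

#' Chromosome arm table (GRCh38)
#'
#' Chromosome lengths and centromere midpoints for chr1-chr22, chrX and chrY
#' on GRCh38. Acrocentric p arms (13, 14, 15, 21, 22) are represented by the
#' short pericentromeric region; taxonomy rules only use q arms there.
#'
#' @return data.frame with columns `chrom`, `length`, `centromere`.
#' @export
defaultArmTable <- function() {
  data.frame(
    chrom = paste0("chr", c(1:22, "X", "Y")),
    length = c(248956422, 242193529, 198295559, 190214555, 181538259,
               170805979, 159345973, 145138636, 138394717, 133797422,
               135086622, 133275309, 114364328, 107043718, 101991189,
               90338345, 83257441, 80373285, 58617616, 64444167,
               46709983, 50818468, 156040895, 57227415),
    centromere = c(123400000, 93900000, 90900000, 50000000, 48800000,
                   59800000, 60100000, 45200000, 43000000, 39800000,
                   53400000, 35500000, 17700000, 17200000, 19000000,
                   36800000, 25100000, 18500000, 26200000, 28100000,
                   12000000, 15000000, 60500000, 10400000),
    stringsAsFactors = FALSE
  )
}

## MIR16-1 anchor on 13q14 (GRCh38); shipped as a configurable constant.
mir16AnchorDefault <- function() c(start = 50049119, end = 50049201)

#' Example region lists for the mCA taxonomy
#'
#' A ready-to-use [RegionLists-class] with the canonical CLL FISH-panel loci
#' (del 6q, del 11q, trisomy 12, del 13q, del 17p, CNN-LOH at 13q/*MIR16-1*)
#' and deliberately small EXAMPLE driver-candidate and lymphoid lists. The
#' driver candidates cover a handful of recurrent CLL lesions (13q14, 11q22
#' ATM, 17p13 TP53, 6q21, 8p loss, 2p gain, 10q24 loss, 13q CNN-LOH); the full
#' published candidate lists from large CLL sequencing studies must be
#' supplied by the user for faithful replication.
#'
#' @param genome Genome tag recorded in the object.
#' @return A [RegionLists-class] object.
#' @examples
#' exampleRegionLists()
#' @export
exampleRegionLists <- function(genome = "GRCh38") {
  anchor <- mir16AnchorDefault()
  canonical <- data.frame(
    chrom = c("chr6", "chr11", "chr12", "chr13", "chr17", "chr13"),
    arm   = c("q", "q", NA, "q", "p", "q"),
    type  = c("loss", "loss", "gain", "loss", "loss", "cnn_loh"),
    rule  = c("arm_overlap", "arm_overlap", "whole_chromosome",
              "arm_overlap", "arm_overlap", "anchor"),
    anchor_start = c(NA, NA, NA, NA, NA, anchor[["start"]]),
    anchor_end   = c(NA, NA, NA, NA, NA, anchor[["end"]]),
    stringsAsFactors = FALSE
  )
  driver <- data.frame(
    chrom = c("chr13", "chr11", "chr17", "chr6", "chr8", "chr2",
              "chr10", "chr13", "chr12"),
    start = c(49900000, 108200000, 7500000, 106000000, 100000, 100000,
              102000000, 40000000, 100000),
    end   = c(50100000, 108400000, 7700000, 108000000, 40000000, 60000000,
              104000000, 114000000, 133200000),
    type  = c("loss", "loss", "loss", "loss", "loss", "gain",
              "loss", "cnn_loh", "gain"),
    stringsAsFactors = FALSE
  )
  lymphoid <- data.frame(
    chrom = c("chr11", "chr13", "chr17", "chr12", "chr14", "chr22"),
    arm   = c("q", "q", "p", NA, "q", "q"),
    type  = c("loss", "loss", "loss", "gain", "cnn_loh", "loss"),
    stringsAsFactors = FALSE
  )
  RegionLists(canonical = canonical, driverCandidates = driver,
              lymphoid = lymphoid, armTable = defaultArmTable(),
              genome = genome, trisomyCoverage = 0.8)
}

## [armStart, armEnd) of an arm; whole chromosome when arm is NA.
armInterval <- function(lists, chrom, arm) {
  at <- armTable(lists)
  i <- match(chrom, at$chrom)
  if (is.na(i)) stop("chromosome ", chrom, " missing from arm_table")
  if (is.na(arm)) c(0, at$length[i])
  else if (arm == "p") c(0, at$centromere[i])
  else if (arm == "q") c(at$centromere[i], at$length[i])
  else stop("unknown arm label: ", arm)
}

## bp overlap between a set of calls and one interval on one chromosome
overlapBp <- function(calls, chrom, lo, hi) {
  ifelse(calls$chrom == chrom,
         pmax(0, pmin(calls$end, hi) - pmax(calls$start, lo)), 0)
}

matchesEntry <- function(calls, lists, chrom, arm, type, rule,
                         anchorStart = NA, anchorEnd = NA) {
  hit <- rep(FALSE, nrow(calls))
  typeOk <- calls$type == type
  if (rule == "whole_chromosome") {
    iv <- armInterval(lists, chrom, NA)
    cov <- overlapBp(calls, chrom, iv[1], iv[2]) / (iv[2] - iv[1])
    hit <- typeOk & cov >= lists@trisomyCoverage
  } else if (rule == "anchor") {
    hit <- typeOk & calls$chrom == chrom &
      calls$start <= anchorStart & calls$end >= anchorEnd
  } else {
    iv <- armInterval(lists, chrom, arm)
    hit <- typeOk & overlapBp(calls, chrom, iv[1], iv[2]) >= 1
  }
  hit
}

checkCallFrame <- function(calls, lists = NULL) {
  need <- c("chrom", "start", "end", "type")
  miss <- setdiff(need, names(calls))
  if (length(miss))
    stop("call table lacks required columns: ", paste(miss, collapse = ", "))
  if (!is.null(lists)) {
    unknown <- setdiff(unique(calls$chrom), armTable(lists)$chrom)
    if (length(unknown))
      stop("chromosome(s) missing from arm_table: ",
           paste(unknown, collapse = ", "))
  }
  invisible(calls)
}

#' Canonical CLL-associated mCA test
#'
#' A call is canonical when it matches one of the loci typically tested on
#' clinical CLL FISH panels: a loss overlapping the 6q, 11q, 13q or 17p arm, a
#' gain covering (by default) at least 80\% of chromosome 12 (trisomy 12), or
#' a copy-neutral LOH call on 13q that fully contains the *MIR16-1* anchor
#' locus.
#'
#' @param calls data.frame of segment calls with columns `chrom`, `start`,
#'   `end` (0-based half-open) and `type` (`loss`/`gain`/`cnn_loh`).
#' @param lists A [RegionLists-class] object.
#' @return Logical vector, one element per call.
#' @examples
#' lists <- exampleRegionLists()
#' calls <- data.frame(chrom = "chr13", start = 45e6, end = 60e6,
#'                     type = "loss")
#' isCanonical(calls, lists)
#' @export
isCanonical <- function(calls, lists) {
  checkCallFrame(calls, lists)
  if (!nrow(calls)) return(logical(0))
  can <- canonicalRegions(lists)
  hit <- rep(FALSE, nrow(calls))
  for (i in seq_len(nrow(can))) {
    hit <- hit | matchesEntry(calls, lists, can$chrom[i], can$arm[i],
                              can$type[i], can$rule[i],
                              can$anchor_start[i], can$anchor_end[i])
  }
  hit
}

#' CLL-driver mCA test
#'
#' A call is a CLL driver when it is canonical ([isCanonical()]) or when it
#' fully contains a candidate driver region of matching type (candidate start
#' and end both inside the call interval). With an empty candidate list the
#' driver category degenerates to the canonical one and a warning notes that
#' driver classification is list-dependent.
#'
#' @inheritParams isCanonical
#' @return Logical vector, one element per call.
#' @export
isCllDriver <- function(calls, lists) {
  checkCallFrame(calls, lists)
  if (!nrow(calls)) return(logical(0))
  hit <- isCanonical(calls, lists)
  cand <- driverCandidates(lists)
  if (!nrow(cand)) {
    if (!all(hit))
      warning("empty driver candidate list: driver classification is ",
              "list-dependent and reduces to the canonical loci")
    return(hit)
  }
  lev <- union(unique(calls$chrom), unique(cand$chrom))
  callGr <- GenomicRanges::GRanges(
    factor(calls$chrom, lev), IRanges::IRanges(calls$start + 1, calls$end))
  candGr <- GenomicRanges::GRanges(
    factor(cand$chrom, lev), IRanges::IRanges(cand$start + 1, cand$end))
  ov <- GenomicRanges::findOverlaps(candGr, callGr, type = "within")
  ok <- cand$type[S4Vectors::queryHits(ov)] ==
    calls$type[S4Vectors::subjectHits(ov)]
  hit[unique(S4Vectors::subjectHits(ov)[ok])] <- TRUE
  hit
}

#' Lymphoid mCA test
#'
#' A call matches the lymphoid list when its type matches an entry and it
#' overlaps the entry's chromosome arm (any overlap), or, for whole-chromosome
#' gain entries, covers the chromosome at the trisomy threshold — the same
#' overlap rules as [isCanonical()]. Sex-chromosome events are excluded unless
#' explicitly listed.
#'
#' @inheritParams isCanonical
#' @return Logical vector, one element per call.
#' @export
isLymphoid <- function(calls, lists) {
  checkCallFrame(calls, lists)
  if (!nrow(calls)) return(logical(0))
  ly <- lymphoidRegions(lists)
  hit <- rep(FALSE, nrow(calls))
  if (!nrow(ly)) return(hit)
  for (i in seq_len(nrow(ly))) {
    rule <- if (is.na(ly$arm[i]) && ly$type[i] == "gain")
      "whole_chromosome" else "arm_overlap"
    hit <- hit | matchesEntry(calls, lists, ly$chrom[i], ly$arm[i],
                              ly$type[i], rule)
  }
  hit
}

#' Classify calls into all mCA categories
#'
#' Adds logical columns `is_canonical`, `is_cll_driver`, `is_lymphoid` and
#' `is_autosomal` to a call table. Categories are overlapping annotations, not
#' a partition: a call can be canonical and lymphoid at once, and canonical
#' implies driver by definition.
#'
#' @inheritParams isCanonical
#' @return The call table with four added logical columns.
#' @export
classifyCalls <- function(calls, lists) {
  checkCallFrame(calls)
  calls$is_canonical <- isCanonical(calls, lists)
  calls$is_cll_driver <- isCllDriver(calls, lists)
  calls$is_lymphoid <- isLymphoid(calls, lists)
  calls$is_autosomal <- calls$chrom %in% paste0("chr", 1:22)
  calls
}

emptyFlags <- function() {
  data.frame(has_canonical = FALSE, has_driver = FALSE, has_lymphoid = FALSE,
             has_autosomal = FALSE,
             has_autosomal_without_driver_or_lymphoid = FALSE,
             has_loy = FALSE, has_lox = FALSE, n_autosomal = 0L,
             max_driver_cf = 0)
}

#' Per-individual mCA category flags
#'
#' Rolls one individual's calls up into the category flags used by the cohort
#' statistics. `has_autosomal_without_driver_or_lymphoid` is true only for
#' individuals carrying an autosomal mCA but neither a CLL-driver nor a
#' lymphoid mCA anywhere in their call set.
#'
#' @param calls data.frame of one individual's calls; an optional `call_id`
#'   column must be duplicate-free; an optional `cell_fraction` column feeds
#'   `max_driver_cf`.
#' @param lists A [RegionLists-class] object.
#' @return One-row data.frame of flags (`has_canonical`, `has_driver`,
#'   `has_lymphoid`, `has_autosomal`,
#'   `has_autosomal_without_driver_or_lymphoid`, `has_loy`, `has_lox`,
#'   `n_autosomal`, `max_driver_cf`).
#' @examples
#' lists <- exampleRegionLists()
#' calls <- data.frame(chrom = "chr12", start = 0, end = 133275309,
#'                     type = "gain", cell_fraction = 0.3)
#' summarizeIndividual(calls, lists)
#' @export
summarizeIndividual <- function(calls, lists) {
  if (is.null(calls) || !nrow(calls)) return(emptyFlags())
  if (!is.null(calls$call_id) && anyDuplicated(calls$call_id))
    stop("duplicate call IDs within one individual")
  ann <- classifyCalls(calls, lists)
  cf <- ann$cell_fraction %||% rep(NA_real_, nrow(ann))
  hasDriver <- any(ann$is_cll_driver)
  hasLymph <- any(ann$is_lymphoid)
  hasAuto <- any(ann$is_autosomal)
  data.frame(
    has_canonical = any(ann$is_canonical),
    has_driver = hasDriver,
    has_lymphoid = hasLymph,
    has_autosomal = hasAuto,
    has_autosomal_without_driver_or_lymphoid =
      hasAuto && !hasDriver && !hasLymph,
    has_loy = any(ann$chrom == "chrY" & ann$type == "loss"),
    has_lox = any(ann$chrom == "chrX" & ann$type == "loss"),
    n_autosomal = sum(ann$is_autosomal),
    max_driver_cf = if (hasDriver && any(is.finite(cf[ann$is_cll_driver])))
      max(cf[ann$is_cll_driver], na.rm = TRUE) else 0
  )
}

#' Per-individual flags for a whole cohort
#'
#' @param calls data.frame of calls with an `individual_id` column.
#' @param lists A [RegionLists-class] object.
#' @param individualIds Optional vector of all cohort IDs, so call-free
#'   individuals get all-false rows.
#' @return data.frame with one row per individual (`individual_id` first).
#' @export
summarizeCohort <- function(calls, lists, individualIds = NULL) {
  ids <- individualIds %||% unique(calls$individual_id)
  rows <- lapply(ids, function(id) {
    fl <- summarizeIndividual(calls[calls$individual_id == id, , drop = FALSE],
                              lists)
    cbind(data.frame(individual_id = id), fl)
  })
  do.call(rbind, rows)
}

#' Per-locus positivity of a call set at the canonical FISH loci
#'
#' Maps an individual's calls onto the five clinical FISH loci (6q, 11q, 12,
#' 13q, 17p) using the canonical interval rules. For 13q, copy-neutral LOH
#' calls containing the *MIR16-1* anchor can be counted as positive alongside
#' deletions (`include13qCnnLoh`), reflecting that FISH del(13q) probes also
#' light up CNN-LOH clones homozygous for the deleted haplotype.
#'
#' @inheritParams isCanonical
#' @param include13qCnnLoh Count anchored 13q CNN-LOH as 13q-positive.
#' @return Named logical vector over loci `6q`, `11q`, `12`, `13q`, `17p`.
#' @export
callLocusPositivity <- function(calls, lists, include13qCnnLoh = TRUE) {
  checkCallFrame(calls)
  pos <- c(`6q` = FALSE, `11q` = FALSE, `12` = FALSE, `13q` = FALSE,
           `17p` = FALSE)
  if (!nrow(calls)) return(pos)
  pos[["6q"]] <- any(matchesEntry(calls, lists, "chr6", "q", "loss",
                                  "arm_overlap"))
  pos[["11q"]] <- any(matchesEntry(calls, lists, "chr11", "q", "loss",
                                   "arm_overlap"))
  pos[["12"]] <- any(matchesEntry(calls, lists, "chr12", NA, "gain",
                                  "whole_chromosome"))
  anchor <- canonicalRegions(lists)
  anchor <- anchor[anchor$rule == "anchor", , drop = FALSE]
  p13 <- any(matchesEntry(calls, lists, "chr13", "q", "loss", "arm_overlap"))
  if (include13qCnnLoh && nrow(anchor))
    p13 <- p13 || any(matchesEntry(calls, lists, anchor$chrom[1], "q",
                                   "cnn_loh", "anchor",
                                   anchor$anchor_start[1],
                                   anchor$anchor_end[1]))
  pos[["13q"]] <- p13
  pos[["17p"]] <- any(matchesEntry(calls, lists, "chr17", "p", "loss",
                                   "arm_overlap"))
  pos
}

#' Read region lists from YAML
#'
#' @param path YAML file with keys `genome`, `trisomy_coverage`, `canonical`,
#'   `driver_candidates`, `lymphoid` and `arm_table` (see the example file in
#'   `system.file("extdata", "example_region_lists.yaml", package =
#'   "mosaicMBL")`).
#' @return A [RegionLists-class] object.
#' @export
readRegionLists <- function(path) {
  y <- yaml::read_yaml(path)
  asDf <- function(entries, cols) {
    if (is.null(entries) || !length(entries))
      return(as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                    cols)))
    do.call(rbind, lapply(entries, function(e) {
      row <- lapply(cols, function(cn) e[[cn]] %||% NA)
      as.data.frame(setNames(row, cols), stringsAsFactors = FALSE)
    }))
  }
  canonical <- asDf(y$canonical, c("chrom", "arm", "type", "rule",
                                   "anchor_start", "anchor_end"))
  canonical$rule[is.na(canonical$rule)] <- "arm_overlap"
  driver <- asDf(y$driver_candidates, c("chrom", "start", "end", "type"))
  lymphoid <- asDf(y$lymphoid, c("chrom", "arm", "type"))
  at <- do.call(rbind, lapply(names(y$arm_table), function(ch) {
    data.frame(chrom = ch, length = y$arm_table[[ch]]$length,
               centromere = y$arm_table[[ch]]$centromere)
  }))
  RegionLists(canonical = canonical, driverCandidates = driver,
              lymphoid = lymphoid, armTable = at,
              genome = y$genome %||% "unspecified",
              trisomyCoverage = y$trisomy_coverage %||% 0.8)
}

#' Write region lists to YAML
#'
#' @param lists A [RegionLists-class] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeRegionLists <- function(lists, path) {
  dfToEntries <- function(df) lapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, , drop = FALSE])
    row[!vapply(row, function(v) is.na(v) || is.null(v), logical(1))]
  })
  at <- armTable(lists)
  armList <- setNames(lapply(seq_len(nrow(at)), function(i)
    list(length = at$length[i], centromere = at$centromere[i])), at$chrom)
  yaml::write_yaml(list(
    genome = lists@genome,
    trisomy_coverage = lists@trisomyCoverage,
    canonical = dfToEntries(canonicalRegions(lists)),
    driver_candidates = dfToEntries(driverCandidates(lists)),
    lymphoid = dfToEntries(lymphoidRegions(lists)),
    arm_table = armList
  ), path)
  invisible(path)
}
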