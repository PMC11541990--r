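## TSV I/O for site, call, phenotype and count tables, plus the end-to-end
## pipeline driver. All interval columns are 0-based half-open (BED
## convention); a flag on the readers shifts 1-based closed input.

writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

readTsv <- function(path, required) {
  x <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop(basename(path), " lacks required column(s): ",
         paste(miss, collapse = ", "))
  x
}

#' Read and write mCA call tables
#'
#' Calls are TSV with BED-compatible first three columns (`chrom`, `start`,
#' `end`) and at least a `type` column; any further columns (dbaf, mean_lrr,
#' cell_fraction, ...) round-trip unchanged. `readCalls` validates row types
#' and reports the offending line on malformed input.
#'
#' @param path File path.
#' @param oneBased Input uses 1-based closed coordinates; shifted to 0-based
#'   half-open on read (`start - 1`).
#' @return `readCalls`: data.frame of calls. `writeCalls`: `path`, invisibly.
#' @export
readCalls <- function(path, oneBased = FALSE) {
  x <- readTsv(path, c("chrom", "start", "end", "type"))
  bad <- which(!is.finite(x$start) | !is.finite(x$end) | x$start >= x$end |
                 !x$type %in% c(mcaTypes(), "undetermined"))
  if (length(bad))
    stop("malformed call row at line ", bad[1] + 1L, " of ", basename(path))
  if (oneBased) x$start <- x$start - 1
  x
}

#' @rdname readCalls
#' @param calls Call table to write.
#' @export
writeCalls <- function(calls, path) writeTsv(calls, path)

#' Read and write site tables
#'
#' Sites are TSV with columns `chrom`, `pos`, `genotype`, `hap`, `baf`,
#' `lrr`.
#'
#' @param path File path.
#' @return `readSites`: data.frame of sites. `writeSites`: `path`, invisibly.
#' @export
readSites <- function(path)
  readTsv(path, c("chrom", "pos", "genotype", "hap", "baf", "lrr"))

#' @rdname readSites
#' @param sites Site table to write.
#' @export
writeSites <- function(sites, path) writeTsv(sites, path)

#' Read a cohort phenotype table
#'
#' @param path TSV with at least `individual_id` and `group`.
#' @return data.frame.
#' @export
readPhenotypes <- function(path) readTsv(path, c("individual_id", "group"))

#' Read the published cohort summary-count fixture
#'
#' The package ships, under `inst/extdata/cohort_counts.tsv`, the printed
#' group-level counts of a large single-center MBL/CLL cohort (carrier and
#' denominator per labelled fraction), from which the prevalence and
#' screening statistics recompute without any individual-level data.
#'
#' @param path TSV with columns `label`, `numerator`, `denominator`;
#'   defaults to the shipped fixture.
#' @return data.frame keyed by `label`.
#' @export
readCohortCounts <- function(path = system.file("extdata",
                                                "cohort_counts.tsv",
                                                package = "mosaicMBL")) {
  readTsv(path, c("label", "numerator", "denominator"))
}

#' Run the synthetic end-to-end pipeline
#'
#' Orchestrates the analysis chain on a generated cohort: cohort and truth
#' events from [generateCohort()]; optional array simulation + detection on a
#' subset of individuals ([simulateArraySignals()], [detectMca()]); taxonomy
#' flags ([summarizeCohort()]); lineage assessment ([assessLineage()]);
#' prevalence cross-tabs per group and category. All stage outputs are
#' written as TSV under `outDir` together with a JSON manifest recording
#' seeds, parameters and per-file MD5 digests, so a rerun with the same
#' configuration is byte-identical.
#'
#' @param outDir Output directory (created if needed).
#' @param cohortConfig A [CohortConfig()] object.
#' @param lists A [RegionLists-class] object.
#' @param detectN Number of event-carrying individuals to push through array
#'   simulation and detection (0 skips the stage).
#' @param arrayConfig An [ArraySimConfig()] for the detection stage.
#' @param detectConfig A [detectionConfig()] for the detection stage.
#' @param seed Master seed; stage seeds derive from it.
#' @return The manifest, invisibly (list with seeds, parameters, files).
#' @export
runPipeline <- function(outDir, cohortConfig = CohortConfig(),
                        lists = exampleRegionLists(), detectN = 0L,
                        arrayConfig = ArraySimConfig(),
                        detectConfig = detectionConfig(), seed = 1L) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cohortConfig@seed <- childSeed(seed, 1L)
  coh <- generateCohort(cohortConfig)
  writeTsv(coh$individuals, file.path(outDir, "individuals.tsv"))
  writeTsv(coh$events, file.path(outDir, "truth_events.tsv"))

  flags <- summarizeCohort(coh$events, lists,
                           individualIds = coh$individuals$individual_id)
  writeTsv(flags, file.path(outDir, "flags.tsv"))

  detected <- NULL
  if (detectN > 0 && nrow(coh$events)) {
    ids <- unique(coh$events$individual_id)
    ids <- head(ids, detectN)
    detected <- do.call(rbind, lapply(seq_along(ids), function(i) {
      ev <- coh$events[coh$events$individual_id == ids[i], , drop = FALSE]
      ev <- ev[!ev$chrom %in% c("chrX", "chrY"), , drop = FALSE]
      if (!nrow(ev)) return(NULL)
      ac <- arrayConfig
      ac@seed <- childSeed(seed, 100L + i)
      sites <- simulateArraySignals(ev, ac)
      calls <- detectMca(sites, detectConfig)
      if (nrow(calls)) cbind(individual_id = ids[i], calls) else NULL
    }))
    if (!is.null(detected))
      writeTsv(detected, file.path(outDir, "detected_calls.tsv"))
  }

  pheno <- coh$individuals
  lin <- assessLineage(coh$events, pheno, lists)
  writeTsv(lin, file.path(outDir, "lineage.tsv"))
  writeTsv(lineageSummary(lin), file.path(outDir, "lineage_summary.tsv"))

  merged <- merge(pheno, flags, by = "individual_id")
  prevRows <- do.call(rbind, lapply(cohortGroups(), function(g) {
    gi <- merged[merged$group == g, , drop = FALSE]
    if (!nrow(gi)) return(NULL)
    do.call(rbind, lapply(
      c("has_canonical", "has_driver", "has_lymphoid", "has_autosomal",
        "has_autosomal_without_driver_or_lymphoid"),
      function(fl) cbind(data.frame(group = g, category = fl),
                         prevalence(sum(gi[[fl]]), nrow(gi)))))
  }))
  writeTsv(prevRows, file.path(outDir, "prevalence.tsv"))

  files <- list.files(outDir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package = "mosaicMBL",
    version = as.character(utils::packageVersion("mosaicMBL")),
    seed = seed,
    parameters = list(detectN = detectN,
                      groupSizes = as.list(cohortConfig@groupSizes)),
    files = lapply(setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
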