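## Lineage inference: does the clone carrying an mCA extend beyond the B-cell
## compartment? If an mCA were confined to B cells, the fraction of cells
## carrying it could not exceed the flow-cytometric B-cell fraction; a cell
## fraction above that bound implies an origin before B-lineage commitment.

lineageCategories <- function() c("canonical", "driver", "lymphoid")

categoryColumn <- function(category) {
  switch(category, canonical = "is_canonical", driver = "is_cll_driver",
         lymphoid = "is_lymphoid", stop("unknown category: ", category))
}

#' Compare mCA cell fractions with the B-cell fraction
#'
#' For every individual in the phenotype table and every requested category,
#' the category cell fraction is the maximum cell fraction among that
#' individual's calls in the category (0 when the category was not detected),
#' and `exceeds` records whether it strictly exceeds the individual's B-cell
#' fraction. Individuals lacking a B-cell fraction are skipped with a
#' warning. Ties count as not exceeding — conservative with respect to a
#' pre-B-lineage origin.
#'
#' @param calls Cohort call table (`individual_id`, `chrom`, `start`, `end`,
#'   `type`, `cell_fraction`).
#' @param phenotype data.frame with `individual_id`, `bcell_fraction` and
#'   optionally `dna_source`.
#' @param lists A [RegionLists-class] object used to annotate calls.
#' @param categories Subset of `canonical`, `driver`, `lymphoid`.
#' @return data.frame of assessments: `individual_id`, `category`, `mca_cf`,
#'   `bcell_fraction`, `exceeds`, `dna_source`.
#' @examples
#' lists <- exampleRegionLists()
#' calls <- data.frame(individual_id = "a", chrom = "chr13", start = 45e6,
#'                     end = 60e6, type = "loss", cell_fraction = 0.4)
#' pheno <- data.frame(individual_id = c("a", "b"),
#'                     bcell_fraction = c(0.1, 0.2))
#' assessLineage(calls, pheno, lists)
#' @export
assessLineage <- function(calls, phenotype, lists,
                          categories = lineageCategories()) {
  categories <- match.arg(categories, lineageCategories(),
                          several.ok = TRUE)
  missing <- is.na(phenotype$bcell_fraction)
  if (any(missing)) {
    warning(sum(missing), " individual(s) lack bcell_fraction; skipped")
    phenotype <- phenotype[!missing, , drop = FALSE]
  }
  stopIfNot01(phenotype$bcell_fraction, "bcell_fraction")
  ann <- classifyCalls(calls, lists)
  rows <- lapply(seq_len(nrow(phenotype)), function(i) {
    id <- phenotype$individual_id[i]
    mine <- ann[ann$individual_id == id, , drop = FALSE]
    do.call(rbind, lapply(categories, function(cat) {
      inCat <- mine[[categoryColumn(cat)]]
      cf <- if (any(inCat)) max(mine$cell_fraction[inCat], na.rm = TRUE)
            else 0
      data.frame(individual_id = id, category = cat, mca_cf = cf,
                 bcell_fraction = phenotype$bcell_fraction[i],
                 exceeds = cf > phenotype$bcell_fraction[i],
                 dna_source = phenotype$dna_source[i] %||% NA_character_)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize lineage assessments per category
#'
#' Counts, over carriers only (individuals with a detected mCA of the
#' category, `mca_cf > 0`), how many have a cell fraction exceeding their
#' B-cell fraction.
#'
#' @param assessments Output of [assessLineage()].
#' @param restrictDnaSource Optionally restrict to one DNA source (e.g.
#'   `"pbmc"`, where flow cytometry and DNA come from the same cells and the
#'   comparison is cleanest).
#' @return data.frame per category: `n_carriers`, `n_exceeds`.
#' @export
lineageSummary <- function(assessments, restrictDnaSource = NULL) {
  if (!is.null(restrictDnaSource))
    assessments <- assessments[
      !is.na(assessments$dna_source) &
        assessments$dna_source == restrictDnaSource, , drop = FALSE]
  cats <- unique(assessments$category)
  do.call(rbind, lapply(cats, function(cat) {
    x <- assessments[assessments$category == cat, , drop = FALSE]
    carriers <- x$mca_cf > 0
    data.frame(category = cat, n_carriers = sum(carriers),
               n_exceeds = sum(x$exceeds[carriers]))
  }))
}
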