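## Per-locus concordance of mCA calls against clinical FISH results at the
## canonical CLL panel loci.

fishLoci <- function() c("6q", "11q", "12", "13q", "17p")

#' Per-individual positivity matrix at the FISH panel loci
#'
#' @param calls Cohort call table with `individual_id`.
#' @param lists A [RegionLists-class] object.
#' @param individualIds All IDs to report (call-free individuals are
#'   negative at every locus).
#' @param include13qCnnLoh Count anchored 13q CNN-LOH calls as 13q-positive
#'   (see [callLocusPositivity()]).
#' @return data.frame: `individual_id` plus one logical column per locus.
#' @export
cohortLocusPositivity <- function(calls, lists, individualIds = NULL,
                                  include13qCnnLoh = TRUE) {
  ids <- individualIds %||% unique(calls$individual_id)
  rows <- lapply(ids, function(id) {
    pos <- callLocusPositivity(
      calls[calls$individual_id == id, , drop = FALSE], lists,
      include13qCnnLoh = include13qCnnLoh)
    cbind(data.frame(individual_id = id),
          as.data.frame(as.list(pos), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Concordance of mCA calls with clinical FISH
#'
#' Cross-tabulates, per canonical locus, SNP-array mCA positivity against
#' FISH positivity over individuals assayed by both, and reports sensitivity
#' `tp / (tp + fn)` and specificity `tn / (tn + fp)` (as proportions; `NA`
#' when a denominator is zero).
#'
#' @param positivity Output of [cohortLocusPositivity()] (or any data.frame
#'   with `individual_id` and logical locus columns).
#' @param fish data.frame with `individual_id`, `locus` (one of `6q`, `11q`,
#'   `12`, `13q`, `17p`) and logical `positive`.
#' @return data.frame per locus: `locus`, `n`, `tp`, `fp`, `fn`, `tn`,
#'   `sensitivity`, `specificity`.
#' @examples
#' pos <- data.frame(individual_id = c("a", "b"), `6q` = c(TRUE, FALSE),
#'                   `11q` = FALSE, `12` = FALSE, `13q` = FALSE,
#'                   `17p` = FALSE, check.names = FALSE)
#' fish <- data.frame(individual_id = c("a", "b"), locus = "6q",
#'                    positive = c(TRUE, FALSE))
#' fishConcordance(pos, fish)
#' @export
fishConcordance <- function(positivity, fish) {
  bad <- setdiff(unique(fish$locus), fishLoci())
  if (length(bad))
    stop("unknown FISH locus label(s): ", paste(bad, collapse = ", "))
  do.call(rbind, lapply(fishLoci(), function(loc) {
    f <- fish[fish$locus == loc, , drop = FALSE]
    f <- f[f$individual_id %in% positivity$individual_id, , drop = FALSE]
    callPos <- positivity[[loc]][match(f$individual_id,
                                       positivity$individual_id)]
    tp <- sum(callPos & f$positive)
    fp <- sum(callPos & !f$positive)
    fn <- sum(!callPos & f$positive)
    tn <- sum(!callPos & !f$positive)
    data.frame(locus = loc, n = nrow(f), tp = tp, fp = fp, fn = fn, tn = tn,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  }))
}
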