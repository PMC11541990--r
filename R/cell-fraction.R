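## Two-population mixture algebra linking phased BAF deviation, LRR, and the
## fraction of cells carrying a mosaic event.
##
## With a fraction f of cells carrying the event, a heterozygous site has
## expected BAF 1/(2-f) (loss of the other haplotype), (1+f)/(2+f) (gain of
## the carrier haplotype), or (1+f)/2 (copy-neutral LOH); the deviation from
## 0.5 is f/(2(2-f)), f/(2(2+f)) and f/2 respectively. Total intensity gives
## LRR = log2(((1-f)*2 + f*c)/2) with c = 1 (loss), 2 (CNN-LOH), 3 (gain).

checkType <- function(type) {
  bad <- setdiff(unique(type), mcaTypes())
  if (length(bad))
    stop("unknown mCA type(s): ", paste(bad, collapse = ", "))
  invisible(type)
}

#' Convert cell fraction to expected phased BAF deviation
#'
#' @param type Event type(s): `"loss"`, `"gain"` or `"cnn_loh"`; recycled
#'   against `f`.
#' @param f Cell fraction(s) in \code{[0, 1]}.
#' @return Expected deviation of heterozygous-site BAF from 0.5 (`dbaf`).
#' @examples
#' cfToDbaf("cnn_loh", 0.5)  # 0.25
#' cfToDbaf("gain", 1)       # 1/6
#' @export
cfToDbaf <- function(type, f) {
  checkType(type)
  stopIfNot01(f, "cell fraction")
  n <- max(length(type), length(f))
  type <- rep_len(type, n); f <- rep_len(f, n)
  unname(ifelse(type == "loss", f / (2 * (2 - f)),
                ifelse(type == "gain", f / (2 * (2 + f)), f / 2)))
}

#' Convert phased BAF deviation to cell fraction
#'
#' Inverse of [cfToDbaf()]. Gain fractions are capped at 1 (a single extra
#' copy is assumed, so `dbaf >= 1/6` already implies a fully clonal gain).
#'
#' @param type Event type(s); recycled against `dbaf`.
#' @param dbaf Deviation(s) in \code{[0, 0.5]}.
#' @return Estimated cell fraction(s) in \code{[0, 1]}.
#' @examples
#' dbafToCf("cnn_loh", 0.25)  # 0.5
#' dbafToCf("loss", 0.5)      # 1
#' @export
dbafToCf <- function(type, dbaf) {
  checkType(type)
  if (any(!is.finite(dbaf)) || any(dbaf < 0) || any(dbaf > 0.5))
    stop("dbaf must lie in [0, 0.5]")
  n <- max(length(type), length(dbaf))
  type <- rep_len(type, n); dbaf <- rep_len(dbaf, n)
  unname(ifelse(type == "loss", 4 * dbaf / (1 + 2 * dbaf),
                ifelse(type == "gain", pmin(1, 4 * dbaf / (1 - 2 * dbaf)),
                       2 * dbaf)))
}

#' Expected log R ratio of a mosaic event
#'
#' @inheritParams cfToDbaf
#' @return Expected LRR, `log2(((1 - f) * 2 + f * c) / 2)` with copy number
#'   `c` of 1 (loss), 2 (CNN-LOH) or 3 (gain).
#' @examples
#' expectedLrr("loss", 1)  # -1
#' @export
expectedLrr <- function(type, f) {
  checkType(type)
  stopIfNot01(f, "cell fraction")
  n <- max(length(type), length(f))
  type <- rep_len(type, n); f <- rep_len(f, n)
  cn <- ifelse(type == "loss", 1, ifelse(type == "gain", 3, 2))
  unname(log2(((1 - f) * 2 + f * cn) / 2))
}

#' Classify a detected event from its BAF deviation and LRR
#'
#' Mean LRR below `-lrrMargin` marks a loss, above `+lrrMargin` a gain; a
#' copy-neutral LRR combined with a positive phased BAF deviation marks
#' CNN-LOH; anything else is undetermined.
#'
#' @param dbaf Phased BAF deviation(s), `>= 0`.
#' @param meanLrr Mean log R ratio(s) over the segment.
#' @param lrrMargin Half-width of the copy-neutral LRR band.
#' @return Character vector: `"loss"`, `"gain"`, `"cnn_loh"` or
#'   `"undetermined"`.
#' @examples
#' classifyEventType(0.25, 0)      # cnn_loh
#' classifyEventType(0.1, -0.32)   # loss
#' @export
classifyEventType <- function(dbaf, meanLrr, lrrMargin = 0.05) {
  if (any(dbaf < 0, na.rm = TRUE)) stop("dbaf must be >= 0")
  n <- max(length(dbaf), length(meanLrr))
  dbaf <- rep_len(dbaf, n); meanLrr <- rep_len(meanLrr, n)
  unname(ifelse(meanLrr < -lrrMargin, "loss",
                ifelse(meanLrr > lrrMargin, "gain",
                       ifelse(dbaf > 0, "cnn_loh", "undetermined"))))
}
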