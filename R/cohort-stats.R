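## Cohort-level statistics: MBL classification, prevalences, screening
## metrics, crude/adjusted odds ratios, clone-size comparison, polygenic
## scoring, and cross-validated prediction of HC-MBL.

#' Classify MBL status from clone size
#'
#' Two rule systems are in clinical use. The relative rule uses the clonal
#' B-cell percentage of total B cells: high-count MBL at >= 85\%, low-count
#' below, none when no clone is present — the classification appropriate when
#' a concurrent blood count is unavailable. The absolute rule uses the clonal
#' B-cell count: below 500 cells/uL is low-count, 500-5000 cells/uL
#' high-count; counts above 5000 cells/uL exceed the MBL range (CLL
#' territory) and return `NA` with a warning.
#'
#' @param clonalBPct Clonal B cells as a percentage of total B cells (0-100);
#'   0 or `NA` means no clone.
#' @param clonalBCount Clonal B-cell count in cells/uL (absolute rule).
#' @param rule `"relative"` or `"absolute"`.
#' @return Character vector: `"none"`, `"lc_mbl"` or `"hc_mbl"`.
#' @examples
#' classifyMbl(c(0, 40, 85, 84.9))
#' classifyMbl(clonalBCount = c(0, 499, 500, 5000), rule = "absolute")
#' @export
classifyMbl <- function(clonalBPct = NULL, clonalBCount = NULL,
                        rule = c("relative", "absolute")) {
  rule <- match.arg(rule)
  if (rule == "relative") {
    if (is.null(clonalBPct))
      stop("relative rule requires clonalBPct")
    if (any(clonalBPct < 0 | clonalBPct > 100, na.rm = TRUE))
      stop("clonalBPct must lie in [0, 100]")
    ifelse(is.na(clonalBPct) | clonalBPct <= 0, "none",
           ifelse(clonalBPct >= 85, "hc_mbl", "lc_mbl"))
  } else {
    if (is.null(clonalBCount))
      stop("absolute rule requires clonalBCount")
    if (any(clonalBCount > 5000, na.rm = TRUE))
      warning("clonal B-cell counts above 5000 cells/uL exceed the MBL ",
              "range; returned as NA")
    ifelse(is.na(clonalBCount) | clonalBCount <= 0, "none",
           ifelse(clonalBCount < 500, "lc_mbl",
                  ifelse(clonalBCount <= 5000, "hc_mbl", NA)))
  }
}

#' Carrier prevalence as a printed percentage
#'
#' @param carriers Carrier count(s).
#' @param n Group size(s).
#' @return data.frame with `carriers`, `n` and `percent`
#'   (`100 * carriers / n` rounded half-up to one decimal; `NA` when
#'   `n == 0`).
#' @examples
#' prevalence(173, 332)$percent  # 52.1
#' @export
prevalence <- function(carriers, n) {
  pct <- ifelse(n > 0, roundHalfUp(100 * carriers / n, 1), NA_real_)
  data.frame(carriers = carriers, n = n, percent = pct)
}

#' Screening sensitivity and specificity
#'
#' @param tp,fp,fn,tn Confusion-matrix counts (non-negative).
#' @return List with `sensitivity` and `specificity` as percentages rounded
#'   half-up to one decimal; `NA` with a warning when a denominator is zero.
#' @examples
#' screeningMetrics(tp = 190, fp = 54, fn = 142, tn = 3645)
#' @export
screeningMetrics <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  sens <- if (tp + fn > 0) roundHalfUp(100 * tp / (tp + fn), 1) else {
    warning("zero denominator for sensitivity"); NA_real_ }
  spec <- if (tn + fp > 0) roundHalfUp(100 * tn / (tn + fp), 1) else {
    warning("zero denominator for specificity"); NA_real_ }
  list(sensitivity = sens, specificity = spec)
}

#' Crude (unadjusted) odds ratio with Woolf confidence interval
#'
#' Cell layout: `a` exposed cases, `b` unexposed cases, `c` exposed controls,
#' `d` unexposed controls, so `OR = (a d) / (b c)`.
#'
#' @param a,b,c,d 2x2 table counts.
#' @param correction Apply the Haldane-Anscombe +0.5 correction when any cell
#'   is zero.
#' @param level Confidence level.
#' @return List with `or`, `ci` (length 2), and `finite` (`FALSE` when a zero
#'   cell makes the uncorrected OR infinite, zero or undefined).
#' @examples
#' crudeOr(173, 159, 4, 2967)$or  # ~807
#' @export
crudeOr <- function(a, b, c, d, correction = FALSE, level = 0.95) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  zeroCell <- any(c(a, b, c, d) == 0)
  if (zeroCell && correction) { a <- a + 0.5; b <- b + 0.5
    c <- c + 0.5; d <- d + 0.5; zeroCell <- FALSE }
  or <- (a * d) / (b * c)
  if (zeroCell)
    return(list(or = or, ci = c(NA_real_, NA_real_), finite = FALSE))
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, ci = exp(log(or) + c(-1, 1) * z * se), finite = TRUE)
}

#' Covariate-adjusted odds ratio by logistic regression
#'
#' Maximum-likelihood logistic fit of a binary outcome on a binary exposure
#' plus covariates; the exposure odds ratio is `exp` of its coefficient with
#' a Wald confidence interval. Quasi-separation (the del-17p situation, where
#' the exposure is absent in one outcome class and the coefficient diverges)
#' is detected and reported rather than silently returned as a huge OR.
#'
#' @param data data.frame holding all variables.
#' @param outcome Name of the binary (0/1 or logical) outcome column.
#' @param exposure Name of the exposure column.
#' @param covariates Character vector of covariate column names (factors are
#'   expanded to indicators by the model matrix; age-like covariates enter
#'   linearly).
#' @param level Confidence level.
#' @return List with `or`, `ci`, `p`, `coef`, `se`, `converged` and
#'   `separated`.
#' @examples
#' d <- simulateOrCohort(2000, oddsRatio = 10, seed = 2)
#' adjustedOr(d, "outcome", "exposure", c("age", "sex"))$or
#' @export
adjustedOr <- function(data, outcome, exposure, covariates = character(),
                       level = 0.95) {
  fm <- stats::reformulate(c(exposure, covariates), response = outcome)
  fit <- suppressWarnings(glm(fm, data = data, family = binomial(),
                              control = list(maxit = 100, epsilon = 1e-8)))
  co <- coef(fit)
  term <- if (exposure %in% names(co)) exposure
          else grep(paste0("^", exposure), names(co), value = TRUE)[1]
  beta <- co[[term]]
  se <- sqrt(diag(vcov(fit)))[[term]]
  separated <- !is.finite(beta) || !is.finite(se) ||
    abs(beta) > 12 || se > 50
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- 2 * stats::pnorm(-abs(beta / se))
  list(or = exp(beta), ci = exp(beta + c(-1, 1) * z * se), p = p,
       coef = beta, se = se, converged = fit$converged,
       separated = separated)
}

#' Two-sided Mann-Whitney comparison of clone sizes
#'
#' Normal-approximation Mann-Whitney U test with tie and continuity
#' correction, plus the two group medians. Fully tied input returns `p = 1`
#' and the null expectation `U = n1 n2 / 2`.
#'
#' @param a,b Numeric vectors (e.g. clonal B-cell percentages of two groups).
#' @return List with `U`, `p`, `medianA`, `medianB`.
#' @examples
#' cloneSizeTest(c(1, 2, 3), c(4, 5, 6))
#' @export
cloneSizeTest <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (length(unique(c(a, b))) == 1L)
    return(list(U = length(a) * length(b) / 2, p = 1,
                medianA = median(a), medianB = median(b)))
  wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       medianA = median(a), medianB = median(b))
}

#' Polygenic risk score as a weighted dosage average
#'
#' @param dosages Risk-allele dosages in \code{[0, 2]}; `NA`s are
#'   mean-imputed from the observed dosages when `impute` is `TRUE`.
#' @param weights Per-SNP weights, same length as `dosages`.
#' @param impute Mean-impute missing dosages.
#' @return The score `sum(w * d) / sum(w)`.
#' @examples
#' prsScore(c(2, 0), c(1, 2))  # 2/3
#' @export
prsScore <- function(dosages, weights, impute = TRUE) {
  if (length(dosages) != length(weights))
    stop("dosages and weights must have equal length")
  if (any(dosages < 0 | dosages > 2, na.rm = TRUE))
    stop("dosages must lie in [0, 2]")
  if (anyNA(dosages)) {
    if (!impute) stop("missing dosages with impute = FALSE")
    dosages[is.na(dosages)] <- mean(dosages, na.rm = TRUE)
  }
  sum(weights * dosages) / sum(weights)
}

#' AUC by the rank (Mann-Whitney) formulation
#'
#' @param scores Predicted scores.
#' @param labels Binary outcome (logical or 0/1).
#' @return Area under the ROC curve; ties handled by average ranks, so the
#'   result is invariant to monotone transforms of `scores`.
#' @export
aucRank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both outcome classes required for AUC")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated AUC of a logistic prediction model
#'
#' Stratified k-fold cross-validation: cases and controls are split into
#' folds separately (seeded), a logistic model on the listed predictors is
#' fit on each training set, out-of-fold predicted probabilities are pooled,
#' and a single AUC is computed by the rank formulation.
#'
#' @param data data.frame with the outcome and predictor columns.
#' @param predictors Character vector of predictor column names.
#' @param outcome Name of the binary outcome column.
#' @param k Number of folds.
#' @param seed RNG seed for the fold assignment.
#' @return List with `auc`, `n`, `k` and the pooled out-of-fold
#'   `predictions` data.frame.
#' @examples
#' d <- simulateOrCohort(600, oddsRatio = 8, seed = 4)
#' cvPredictAuc(d, c("exposure", "age"), outcome = "outcome", seed = 4)$auc
#' @export
cvPredictAuc <- function(data, predictors, outcome = "outcome", k = 10L,
                         seed = 1L) {
  y <- as.integer(as.logical(data[[outcome]]))
  keep <- complete.cases(data[, c(outcome, predictors), drop = FALSE])
  data <- data[keep, , drop = FALSE]; y <- y[keep]
  n <- nrow(data)
  if (sum(y) < 2 || sum(1 - y) < 2)
    stop("need at least two individuals of each outcome class")
  k <- min(k, sum(y), sum(1 - y))
  fold <- integer(n)
  withSeed(seed, {
    fold[y == 1] <- sample(rep(seq_len(k), length.out = sum(y)))
    fold[y == 0] <- sample(rep(seq_len(k), length.out = sum(1 - y)))
  })
  prob <- numeric(n)
  fm <- stats::reformulate(predictors, response = outcome)
  for (f in seq_len(k)) {
    test <- fold == f
    fit <- suppressWarnings(glm(fm, data = data[!test, , drop = FALSE],
                                family = binomial(),
                                control = list(maxit = 100)))
    prob[test] <- suppressWarnings(
      stats::predict(fit, newdata = data[test, , drop = FALSE],
                     type = "response"))
  }
  list(auc = aucRank(prob, y), n = n, k = k,
       predictions = data.frame(prob = prob, outcome = y, fold = fold))
}

#' Standard predictor sets for HC-MBL prediction
#'
#' The four nested model specifications used when distinguishing high-count
#' MBL from the combined group of low-count MBL and unaffected individuals:
#' lymphocyte count alone, driver-mCA presence alone, demographics + mCA +
#' polygenic score, and the full model adding ALC.
#'
#' @return Named list of predictor-name vectors.
#' @export
hcMblModelSpecs <- function() {
  list(alc = "alc",
       mca = "has_driver",
       demo_mca_prs = c("age", "sex", "has_driver", "prs"),
       full = c("age", "sex", "has_driver", "prs", "alc"))
}
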