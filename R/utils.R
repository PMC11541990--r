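#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.05 -> 0.1), matching how clinical
#' percentages are conventionally printed. Base [round()] rounds half to even,
#' which disagrees with printed cohort tables at exact .x5 boundaries.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector; `NA` stays `NA`.
#' @examples
#' roundHalfUp(100 * 173 / 332, 1)  # 52.1
#' roundHalfUp(0.15, 1)             # 0.2
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Derive a child RNG seed from a master seed; stays inside 32-bit signed range.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %% 2147483629)
}

#' Evaluate an expression under a local RNG state
#'
#' Seeds the generator, evaluates `expr`, and restores the caller's RNG
#' state, so seeded simulations do not disturb the surrounding random
#' stream.
#'
#' @param seed Integer seed (`NULL` leaves the RNG untouched).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mcaTypes <- function() c("loss", "gain", "cnn_loh")

stopIfNot01 <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  invisible(x)
}
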