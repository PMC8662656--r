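#' Run an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded package operations do not
#' disturb the caller's random number stream. A `NULL` seed runs the
#' expression against the current stream.
#'
#' @param seed integer seed or `NULL`
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' Every source of randomness in a pipeline run flows from one master seed
#' through this rule: `(master * 48271 + hash(stage label)) mod (2^31 - 1)`,
#' where the hash is the weighted sum of the label's UTF-8 code points.
#' The result always fits a 32-bit R integer.
#'
#' @param master integer master seed
#' @param stage character stage label
#' @return integer seed in `[1, 2^31 - 2]`
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  m <- 2147483647
  h <- sum(as.numeric(utf8ToInt(stage)) * seq_along(utf8ToInt(stage))) %% m
  as.integer(((as.numeric(master) %% m) * 48271 + h) %% (m - 1) + 1)
}

#' Weighted quantiles
#'
#' Quantiles of a weighted sample, by linear interpolation of the
#' normalized cumulative weight at the sorted values.
#'
#' @param x numeric values
#' @param w non-negative weights
#' @param probs probabilities
#' @return numeric vector of quantiles
#' @keywords internal
wquantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  cw <- cumsum(w) - w / 2
  cw <- cw / sum(w)
  vapply(probs, function(p) {
    if (p <= cw[1]) return(x[1])
    if (p >= cw[length(cw)]) return(x[length(x)])
    stats::approx(cw, x, xout = p, ties = "ordered")$y
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
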