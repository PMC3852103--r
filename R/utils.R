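# Internal numerical helpers shared by the outlier statistics.
#
# All quantiles in this package use linear interpolation between order
# statistics at 1-based position 1 + (n - 1) * p (R's type 7). The OS/ORT
# outlier cutoffs depend on this convention, so it is fixed package-wide.

q7 <- function(v, p) {
  as.numeric(stats::quantile(v, probs = p, type = 7, names = FALSE))
}

# Normal-consistent scaled MAD with a mean-absolute-deviation fallback for
# discrete or near-constant features. Returns 0 only if both are 0, in which
# case callers flag the feature degenerate rather than dividing by zero.
scale_or_fallback <- function(absdev) {
  s <- 1.4826 * stats::median(absdev)
  if (s <= 0) s <- 1.4826 * mean(absdev)
  s
}

degenerate_score <- function() structure(0, degenerate = TRUE)

is_degenerate <- function(x) isTRUE(attr(x, "degenerate"))

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded sub-computations (e.g. Monte-Carlo moment
# tables) do not perturb an enclosing simulation stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic, locale-independent ordering for character tie-breaks.
order_radix <- function(...) order(..., method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a
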