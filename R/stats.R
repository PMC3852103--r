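# The six per-feature two-group statistics.
#
# Each scalar function takes the control values x (normal samples) and the
# case values y (tumour samples) of a single feature and returns a signed
# score; larger values indicate stronger evidence of over-expression in a
# subset of the tumour samples. Features where no usable scale can be
# estimated return 0 carrying a `degenerate` attribute; [score_all()]
# collects these flags rather than propagating NaN.
#
# Conventions (fixed package-wide, see the methods vignette):
#   * quantiles are linearly interpolated at position 1 + (n - 1) p (type 7);
#   * MAD uses the normal-consistency constant 1.4826, with a scaled mean
#     absolute deviation fallback when the MAD is zero;
#   * OS/ORT outlier membership uses strict inequality at the cutoff.

#' Pooled-variance two-sample t statistic
#'
#' The classical Student t statistic with pooled variance, the baseline that
#' the outlier statistics are compared against. It averages over all tumour
#' samples and therefore dilutes signals present in only a subset of them.
#'
#' @param x Numeric vector of control (normal) values, length >= 2.
#' @param y Numeric vector of case (tumour) values, length >= 2.
#' @return Signed t value. Zero pooled variance yields a degenerate score
#'   (0 with attribute `degenerate = TRUE`).
#' @seealso [score_all()] for vectorised evaluation over a dataset.
#' @examples
#' ttest_stat(c(0, 2), c(3, 5))  # 3 / sqrt(2)
#' @export
ttest_stat <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per group")
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  if (sp2 <= 0) return(degenerate_score())
  (mean(y) - mean(x)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Cancer Outlier Profile Analysis (COPA) statistic
#'
#' Centres and scales all samples by the overall median and scaled MAD, then
#' reports the `r`-th percentile of the standardized tumour values. A high
#' percentile of the tumour distribution is sensitive to a shifted tumour
#' subset that leaves the mean almost unchanged.
#'
#' @inheritParams ttest_stat
#' @param r Percentile of the standardized tumour values to report
#'   (default 90).
#' @return The interpolated percentile of the standardized tumour values.
#' @examples
#' copa_stat(c(1, 2, 3, 4), c(1, 2, 3, 12))
#' @export
copa_stat <- function(x, y, r = 90) {
  all_v <- c(x, y)
  med <- stats::median(all_v)
  s <- scale_or_fallback(abs(all_v - med))
  if (s <= 0) return(degenerate_score())
  q7((y - med) / s, r / 100)
}

#' Outlier Sum (OS) statistic
#'
#' Standardizes all samples by the overall median and scaled MAD and sums
#' those standardized tumour values that lie strictly above
#' `q75 + IQR` of all standardized values. Returns 0 when no tumour sample
#' exceeds the cutoff.
#'
#' @inheritParams ttest_stat
#' @return Sum of standardized tumour values beyond the cutoff (0 if none).
#' @examples
#' os_stat(c(-1, 0, 1), c(-1, 0, 10))
#' @export
os_stat <- function(x, y) {
  all_v <- c(x, y)
  med <- stats::median(all_v)
  s <- scale_or_fallback(abs(all_v - med))
  if (s <= 0) return(degenerate_score())
  z_all <- (all_v - med) / s
  cutoff <- q7(z_all, 0.75) + (q7(z_all, 0.75) - q7(z_all, 0.25))
  zy <- (y - med) / s
  out <- zy[zy > cutoff]
  if (!length(out)) 0 else sum(out)
}

#' Outlier Robust T (ORT) statistic
#'
#' Like the Outlier Sum but fully group-aware: the scale pools absolute
#' deviations from each group's own median, and the outlier cutoff
#' `q75(x) + IQR(x)` is computed from the control group only. Tumour values
#' strictly above the cutoff contribute `(y - median(x)) / scale`.
#'
#' @inheritParams ttest_stat
#' @return Sum of scaled exceedances over the control-based cutoff (0 if
#'   none).
#' @examples
#' ort_stat(c(1, 2, 3), c(2, 2, 10))
#' @export
ort_stat <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need at least 2 samples per group")
  medx <- stats::median(x)
  s <- scale_or_fallback(c(abs(x - medx), abs(y - stats::median(y))))
  if (s <= 0) return(degenerate_score())
  cutoff <- q7(x, 0.75) + (q7(x, 0.75) - q7(x, 0.25))
  out <- y[y > cutoff]
  if (!length(out)) 0 else sum((out - medx) / s)
}

#' Monte-Carlo moments of partial sums of normal order statistics
#'
#' MOST standardizes the running sum of the k largest tumour values by the
#' null mean and standard deviation of the sum of the k largest of `n2` iid
#' standard normal variates. Those moments have no convenient closed form,
#' so they are estimated once by Monte Carlo and cached for the session.
#'
#' @param n2 Number of tumour samples (>= 1).
#' @param B Monte-Carlo replicates (default 10000; fewer than 100 rejected).
#' @param seed Seed for the Monte-Carlo draw. The caller's RNG state is
#'   untouched; the same `(n2, B, seed)` always yields the same table.
#' @return Object of class `"order_moments"`: list with `n2`, `B`, `seed`
#'   and numeric vectors `mu`, `sigma` of length `n2` (k-th entry = moments
#'   of the sum of the k largest of `n2` standard normals).
#' @examples
#' tab <- precompute_order_moments(4, B = 1000, seed = 1)
#' tab$mu  # increasing then flattening in k
#' @export
precompute_order_moments <- function(n2, B = 10000, seed = 1) {
  if (n2 < 1) stop("n2 must be >= 1")
  if (B < 100) stop("B must be >= 100 for usable moment estimates")
  key <- paste(n2, B, seed, sep = "_")
  cached <- .moments_cache[[key]]
  if (!is.null(cached)) return(cached)
  sums <- with_seed(seed, {
    z <- matrix(stats::rnorm(B * n2), nrow = B)
    if (n2 == 1L) z else
      t(apply(z, 1L, function(r) cumsum(sort(r, decreasing = TRUE))))
  })
  if (n2 == 1L) sums <- matrix(sums, ncol = 1L)
  tab <- structure(
    list(n2 = n2, B = B, seed = seed,
         mu = colMeans(sums), sigma = apply(sums, 2L, stats::sd)),
    class = "order_moments"
  )
  .moments_cache[[key]] <- tab
  tab
}

.moments_cache <- new.env(parent = emptyenv())

#' Maximum Ordered Subset T (MOST) statistic
#'
#' Sorts the tumour values in decreasing order, forms the running sum
#' `M_k = sum_{j<=k} (y_(j) - median(x)) / scale` with the ORT scale, and
#' returns the maximum over k of the standardized `(M_k - mu_k) / sigma_k`,
#' where `(mu_k, sigma_k)` are the null moments from
#' [precompute_order_moments()]. Maximizing over the subset size makes the
#' statistic adaptive to the unknown number of shifted tumour samples.
#'
#' @inheritParams ttest_stat
#' @param moments An `"order_moments"` table for at least `length(y)`
#'   tumour samples.
#' @return The maximal standardized ordered-subset sum.
#' @examples
#' tab <- precompute_order_moments(3, B = 5000, seed = 1)
#' most_stat(c(1, 2, 3), c(2, 2, 10), tab)
#' @export
most_stat <- function(x, y, moments) {
  if (missing(moments) || !inherits(moments, "order_moments")) {
    stop("`moments` must be precomputed with precompute_order_moments()")
  }
  n2 <- length(y)
  if (moments$n2 < n2) {
    stop("order-moment table covers n2 = ", moments$n2,
         " but ", n2, " tumour samples supplied; ",
         "precompute_order_moments(", n2, ") first")
  }
  medx <- stats::median(x)
  s <- scale_or_fallback(c(abs(x - medx), abs(y - stats::median(y))))
  if (s <= 0) return(degenerate_score())
  m_k <- cumsum((sort(y, decreasing = TRUE) - medx) / s)
  max((m_k - moments$mu[seq_len(n2)]) / moments$sigma[seq_len(n2)])
}

#' Least Sum of Ordered Subset Squares (LSOSS) statistic
#'
#' Models the tumour group as two latent subsets (shifted and background):
#' tumour values are sorted in decreasing order, the split after position k
#' minimizing the within-subset sum of squares is chosen (smallest k on
#' ties), and the statistic is `k* (mean(top k*) - mean(x)) / s` with the
#' pooled standard deviation `s^2 = (SS(x) + SSE(k*)) / (n1 + n2 - 3)`.
#'
#' @inheritParams ttest_stat
#' @return The scaled shifted-subset mean difference, weighted by the
#'   estimated subset size.
#' @examples
#' lsoss_stat(c(0, 0, 1, 1), c(5, 5, 1, 1))
#' @export
lsoss_stat <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n2 < 2) stop("LSOSS needs at least 2 tumour samples")
  ys <- sort(y, decreasing = TRUE)
  cs <- cumsum(ys)
  cs2 <- cumsum(ys^2)
  k <- seq_len(n2 - 1L)
  sse_top <- cs2[k] - cs[k]^2 / k
  sse_rest <- (cs2[n2] - cs2[k]) - (cs[n2] - cs[k])^2 / (n2 - k)
  sse <- sse_top + sse_rest
  kstar <- which.min(sse)  # which.min returns the first (smallest k) on ties
  ssx <- sum((x - mean(x))^2)
  s2 <- (ssx + sse[kstar]) / (n1 + n2 - 3)
  if (s2 <= 0) return(degenerate_score())
  kstar * (cs[kstar] / kstar - mean(x)) / sqrt(s2)
}
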