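# Independent naive reimplementations used as oracles. Everything here is
# written with explicit loops and first-principles formulas, deliberately
# sharing no helper code with the package.

o_quantile <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- 1 + (n - 1) * p
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

o_median <- function(v) o_quantile(v, 0.5)

o_madn <- function(v) {
  dev <- abs(v - o_median(v))
  s <- 1.4826 * o_median(dev)
  if (s <= 0) s <- 1.4826 * sum(dev) / length(dev)
  s
}

o_ttest <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  (mean(y) - mean(x)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

o_copa <- function(x, y, r = 90) {
  all_v <- c(x, y)
  med <- o_median(all_v)
  s <- o_madn(all_v)
  o_quantile((y - med) / s, r / 100)
}

o_os <- function(x, y) {
  all_v <- c(x, y)
  med <- o_median(all_v)
  s <- o_madn(all_v)
  z <- (all_v - med) / s
  cutoff <- o_quantile(z, 0.75) + (o_quantile(z, 0.75) - o_quantile(z, 0.25))
  total <- 0
  for (yy in y) {
    zy <- (yy - med) / s
    if (zy > cutoff) total <- total + zy
  }
  total
}

o_group_scale <- function(x, y) {
  dev <- c(abs(x - o_median(x)), abs(y - o_median(y)))
  s <- 1.4826 * o_median(dev)
  if (s <= 0) s <- 1.4826 * sum(dev) / length(dev)
  s
}

o_ort <- function(x, y) {
  s <- o_group_scale(x, y)
  cutoff <- o_quantile(x, 0.75) + (o_quantile(x, 0.75) - o_quantile(x, 0.25))
  medx <- o_median(x)
  total <- 0
  for (yy in y) if (yy > cutoff) total <- total + (yy - medx) / s
  total
}

o_most <- function(x, y, mu, sigma) {
  s <- o_group_scale(x, y)
  medx <- o_median(x)
  ys <- sort(y, decreasing = TRUE)
  best <- -Inf
  running <- 0
  for (k in seq_along(ys)) {
    running <- running + (ys[k] - medx) / s
    cand <- (running - mu[k]) / sigma[k]
    if (cand > best) best <- cand
  }
  best
}

o_lsoss <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  ys <- sort(y, decreasing = TRUE)
  best_k <- NA
  best_sse <- Inf
  for (k in 1:(n2 - 1)) {
    top <- ys[1:k]
    rest <- ys[(k + 1):n2]
    sse <- sum((top - mean(top))^2) + sum((rest - mean(rest))^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best_k <- k
    }
  }
  s2 <- (sum((x - mean(x))^2) + best_sse) / (n1 + n2 - 3)
  best_k * (mean(ys[1:best_k]) - mean(x)) / sqrt(s2)
}

# Exact upper-tail hypergeometric probability by combinatorial enumeration.
o_hyper <- function(N, K, n, k) {
  total <- 0
  for (j in k:min(K, n)) {
    total <- total + choose(K, j) * choose(N - K, n - j) / choose(N, n)
  }
  total
}

# Benjamini-Hochberg step-up by the textbook recursion.
o_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# Brute-force putative outliers + accuracies by explicit counting.
o_putative <- function(selected_sets, k_m) {
  features <- unique(unlist(selected_sets))
  put <- character(0)
  for (f in features) {
    cnt <- 0
    for (s in selected_sets) if (f %in% s) cnt <- cnt + 1
    if (cnt >= k_m) put <- c(put, f)
  }
  acc <- numeric(length(selected_sets))
  for (i in seq_along(selected_sets)) {
    hit <- 0
    for (f in selected_sets[[i]]) if (f %in% put) hit <- hit + 1
    acc[i] <- 100 * hit / length(selected_sets[[i]])
  }
  list(putative = sort(put), accuracy = acc)
}
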