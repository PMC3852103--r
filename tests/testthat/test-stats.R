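# Unit and property tests for the six outlier statistics.

test_that("hand-worked examples evaluate correctly", {
  expect_equal(ttest_stat(c(0, 2), c(3, 5)), 3 / sqrt(2), tolerance = 1e-12)
  expect_equal(copa_stat(c(1, 2, 3, 4), c(1, 2, 3, 12)), 4.58654,
               tolerance = 1e-4)
  expect_equal(os_stat(c(-1, 0, 1), c(-1, 0, 10)), 10 / 1.4826,
               tolerance = 1e-12)
  expect_equal(ort_stat(c(1, 2, 3), c(2, 2, 10)), 8 / (1.4826 * 0.5),
               tolerance = 1e-12)
  expect_equal(lsoss_stat(c(0, 0, 1, 1), c(5, 5, 1, 1)),
               2 * (5 - 0.5) / sqrt(0.2), tolerance = 1e-12)
})

test_that("identical groups and zero-variance features behave as contracted", {
  x <- c(1.3, 2.1, 0.4)
  expect_equal(ttest_stat(x, x), 0)
  deg <- ttest_stat(c(1, 1), c(1, 1))
  expect_equal(as.numeric(deg), 0)
  expect_true(isTRUE(attr(deg, "degenerate")))
  # all-equal values defeat both the MAD and its mean-deviation fallback
  for (f in list(copa_stat, os_stat, ort_stat)) {
    d <- f(c(2, 2, 2), c(2, 2, 2))
    expect_true(isTRUE(attr(d, "degenerate")))
  }
})

test_that("OS returns 0 when tumour values sit inside the control bulk", {
  expect_equal(os_stat(c(-2, -1, 0, 1, 2), c(-1, 0, 1)), 0)
  expect_equal(ort_stat(c(1, 2, 3, 4), c(2, 2, 3)), 0)
})

test_that("location and scale invariances hold for the robust statistics", {
  set.seed(71)
  for (i in 1:25) {
    x <- rnorm(sample(3:10, 1))
    y <- c(rnorm(sample(2:9, 1)), 4)  # guarantee an outlier
    shift <- runif(1, -5, 5)
    scale <- runif(1, 0.1, 4)
    tab <- precompute_order_moments(length(y), B = 2000, seed = 5)
    for (f in list(copa_stat, os_stat, ort_stat,
                   function(a, b) most_stat(a, b, tab))) {
      expect_equal(f(x + shift, y + shift), f(x, y), tolerance = 1e-9)
      expect_equal(f(x * scale, y * scale), f(x, y), tolerance = 1e-9)
    }
  }
})

test_that("raising a tumour value already in the outlier set increases OS and ORT", {
  x <- c(0, 0.5, 1, 1.5)
  y <- c(0.2, 0.8, 6)
  y2 <- c(0.2, 0.8, 7)
  expect_gt(os_stat(x, y2), os_stat(x, y))
  expect_gt(ort_stat(x, y2), ort_stat(x, y))
})

test_that("LSOSS picks the smallest k on SSE ties and stays finite", {
  # all tumour values equal: every split has SSE 0, so k* = 1
  val <- lsoss_stat(c(0, 1, 0, 1), c(3, 3, 3))
  expect_true(is.finite(val))
  # k* = 1 implies score = 1 * (3 - mean(x)) / s
  s2 <- (sum((c(0, 1, 0, 1) - 0.5)^2) + 0) / (4 + 3 - 3)
  expect_equal(as.numeric(val), (3 - 0.5) / sqrt(s2), tolerance = 1e-12)
})

test_that("every statistic matches its naive scalar oracle on random features", {
  set.seed(2024)
  n_cases <- 200
  max_n2 <- 12
  tab <- precompute_order_moments(max_n2, B = 5000, seed = 9)
  for (i in seq_len(n_cases)) {
    n1 <- sample(3:12, 1)
    n2 <- sample(3:max_n2, 1)
    x <- round(rnorm(n1, sd = runif(1, 0.5, 3)), 3)
    y <- round(rnorm(n2, sd = runif(1, 0.5, 3)) +
                 rbinom(n2, 1, 0.3) * runif(1, 0, 4), 3)
    expect_equal(as.numeric(ttest_stat(x, y)), o_ttest(x, y),
                 tolerance = 1e-9)
    expect_equal(as.numeric(copa_stat(x, y)), o_copa(x, y), tolerance = 1e-9)
    expect_equal(as.numeric(os_stat(x, y)), o_os(x, y), tolerance = 1e-9)
    expect_equal(as.numeric(ort_stat(x, y)), o_ort(x, y), tolerance = 1e-9)
    expect_equal(as.numeric(most_stat(x, y, tab)),
                 o_most(x, y, tab$mu, tab$sigma), tolerance = 1e-9)
    expect_equal(as.numeric(lsoss_stat(x, y)), o_lsoss(x, y),
                 tolerance = 1e-9)
  }
})

test_that("order-statistic moment tables are sane and deterministic", {
  tab1 <- precompute_order_moments(8, B = 5000, seed = 3)
  tab2 <- precompute_order_moments(8, B = 5000, seed = 3)
  expect_identical(tab1, tab2)
  single <- precompute_order_moments(1, B = 5000, seed = 3)
  expect_equal(single$mu, 0, tolerance = 0.05)
  expect_equal(single$sigma, 1, tolerance = 0.05)
  # partial sums of the top order statistics grow in k over the first half
  expect_true(all(diff(tab1$mu[1:4]) > 0))
  expect_error(precompute_order_moments(5, B = 50), "B must be")
  expect_error(most_stat(1:4, 1:6, precompute_order_moments(3, B = 200)),
               "precompute")
})

test_that("moment precomputation leaves the caller's RNG stream untouched", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(precompute_order_moments(4, B = 500, seed = 77))
  expect_identical(runif(1), a)
})

test_that("score_all finds down-shifted features only in both/down modes", {
  cfg <- simulation_config(n_normal = 20, n_tumor = 20, n_features = 200,
                           de_fraction = 0.1, outlier_fraction = 0.5,
                           shift = 3, direction = "down", n_datasets = 1,
                           seed = 5)
  g <- generate_dataset(cfg)
  recall <- function(mode) {
    sc <- score_all(g$dataset, methods = "ort", direction_mode = mode,
                    most_B = 1000)
    sel <- select_top_quantile(sc$ort, 0.05)
    mean(g$truth$de_features %in% sel$selected)
  }
  expect_lt(recall("up"), 0.2)
  expect_gt(recall("both"), 0.4)
  expect_gt(recall("down"), 0.4)
  sc <- score_all(g$dataset, methods = "ort", direction_mode = "both")
  sel <- select_top_quantile(sc$ort, 0.05)
  hits <- sc$ort[sc$ort$feature_id %in% sel$selected, ]
  expect_true(all(hits$direction[hits$feature_id %in% g$truth$de_features]
                  == "down"))
})

test_that("score_all validates its inputs", {
  cfg <- simulation_config(n_normal = 5, n_tumor = 5, n_features = 20,
                           n_datasets = 1, seed = 1)
  d <- generate_dataset(cfg)$dataset
  expect_error(score_all(d, methods = character(0)), "empty method list")
  expect_error(score_all(d, methods = "copA"), "unknown method")
})
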