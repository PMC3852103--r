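# Tests for top-quantile selection, the >=k-methods putative-outlier rule,
# method ranking and cross-dataset consensus.

mk_scores <- function(ids, score, degenerate = FALSE, method = "ort",
                      dataset_id = "d1") {
  structure(
    data.frame(feature_id = ids, method = method, score = score,
               direction = "up",
               degenerate = rep_len(degenerate, length(ids)),
               stringsAsFactors = FALSE),
    dataset_id = dataset_id, class = c("method_scores", "data.frame"))
}

mk_sel <- function(selected, method, dataset_id = "d1") {
  structure(list(method = method, dataset_id = dataset_id,
                 selected = selected, q = 0.05),
            class = "selection_result")
}

test_that("selection size is ceil(q * m) over non-degenerate features", {
  s40 <- mk_scores(sprintf("f%02d", 1:40), rnorm(40))
  expect_length(select_top_quantile(s40, 0.05)$selected, 2)
  s407 <- mk_scores(sprintf("f%03d", 1:407), rnorm(407))
  expect_length(select_top_quantile(s407, 0.05)$selected, 21)  # ceil(20.35)
  # degenerate features shrink the pool and are never selected
  sdeg <- mk_scores(sprintf("f%02d", 1:40), c(rep(0, 20), rnorm(20)),
                    degenerate = rep(c(TRUE, FALSE), each = 20))
  sel <- select_top_quantile(sdeg, 0.05)
  expect_length(sel$selected, 1)
  expect_false(any(sel$selected %in% sprintf("f%02d", 1:20)))
  expect_error(select_top_quantile(mk_scores("f1", 0, TRUE), 0.05),
               "degenerate")
  expect_error(select_top_quantile(s40, 0), "in \\(0, 1\\)")
})

test_that("boundary ties are broken by lexicographic feature id", {
  sc <- mk_scores(c("fb", "fa", "fc", "fd"), c(5, 5, 1, 0.5))
  sel <- select_top_quantile(sc, 0.26)  # ceil(0.26 * 4) = 2
  expect_identical(sort(sel$selected), c("fa", "fb"))
  # tie exactly at the boundary: only one slot, smaller id wins
  sel1 <- select_top_quantile(sc, 0.25)
  expect_identical(sel1$selected, "fa")
})

test_that("putative outliers follow the >= k_m rule with exact accuracies", {
  sels <- list(
    mk_sel(c("a", "b", "c"), "m1"), mk_sel(c("a", "b", "d"), "m2"),
    mk_sel(c("a", "e", "f"), "m3"), mk_sel(c("a", "b", "g"), "m4"),
    mk_sel(c("h", "i", "j"), "m5"), mk_sel(c("k", "l", "m"), "m6"))
  ev <- putative_outliers(sels, k_m = 3)
  expect_identical(ev$putative, c("a", "b"))      # a: 4 methods, b: exactly 3
  expect_equal(unname(ev$accuracy[c("m1", "m5")]), c(200 / 3, 0))
  # identical selections: every accuracy 100
  same <- lapply(paste0("m", 1:6), function(m) mk_sel(c("x", "y"), m))
  ev2 <- putative_outliers(same, k_m = 3)
  expect_true(all(ev2$accuracy == 100))
  expect_error(putative_outliers(list(mk_sel("a", "m1", "d1"),
                                      mk_sel("a", "m2", "d2")), 2),
               "mix dataset IDs")
})

test_that("putative outliers match brute-force counting on random selections", {
  set.seed(11)
  for (trial in 1:100) {
    n_m <- sample(3:6, 1)
    pool <- sprintf("g%02d", 1:30)
    sels <- lapply(seq_len(n_m), function(i) {
      mk_sel(sample(pool, sample(3:12, 1)), paste0("m", i))
    })
    k_m <- sample(1:n_m, 1)
    ev <- putative_outliers(sels, k_m)
    oracle <- o_putative(lapply(sels, `[[`, "selected"), k_m)
    expect_identical(ev$putative, oracle$putative)
    expect_equal(unname(ev$accuracy), oracle$accuracy, tolerance = 1e-12)
  }
})

test_that("putative sets obey the union/intersection identities in k_m", {
  set.seed(12)
  sels <- lapply(1:6, function(i) {
    mk_sel(sample(sprintf("g%02d", 1:25), 8), paste0("m", i))
  })
  sets <- lapply(sels, `[[`, "selected")
  expect_identical(putative_outliers(sels, 1)$putative,
                   sort(unique(unlist(sets))))
  expect_identical(putative_outliers(sels, 6)$putative,
                   sort(Reduce(intersect, sets)))
  sizes <- vapply(1:6, function(k) {
    length(putative_outliers(sels, k)$putative)
  }, 0L)
  expect_true(all(diff(sizes) <= 0))
  # accuracy is 100 iff the selection is a subset of the putative set
  ev <- putative_outliers(sels, 2)
  for (i in seq_along(sels)) {
    expect_equal(unname(ev$accuracy[i]) == 100,
                 all(sets[[i]] %in% ev$putative))
  }
})

mk_eval <- function(acc, dataset_id) {
  structure(list(dataset_id = dataset_id, putative = character(0), k_m = 3,
                 accuracy = acc), class = "consensus_eval")
}

test_that("method ranking uses median, then SD, then name", {
  evs <- lapply(1:4, function(i) {
    mk_eval(c(ort = c(80, 90, 85, 88)[i], ttest = c(50, 60, 55, 58)[i]),
            paste0("d", i))
  })
  r <- rank_methods(evs)
  expect_identical(r$best_method, "ort")
  # equal medians: smaller SD wins
  evs2 <- lapply(1:3, function(i) {
    mk_eval(c(a = c(70, 80, 90)[i], b = c(78, 80, 82)[i]), paste0("d", i))
  })
  expect_identical(rank_methods(evs2)$best_method, "b")
  # full tie: lexicographic
  evs3 <- lapply(1:2, function(i) {
    mk_eval(c(zz = 50, aa = 50), paste0("d", i))
  })
  expect_identical(rank_methods(evs3)$best_method, "aa")
  expect_warning(rank_methods(evs[1]), "single dataset")
  evs_bad <- c(evs[1:3], list(mk_eval(c(ort = 50), "d4")))
  expect_error(rank_methods(evs_bad), "missing from dataset d4")
})

test_that("cross-dataset consensus honours k_d and its identity cases", {
  sels <- list(d1 = c("a", "b", "c"), d2 = c("a", "b"), d3 = c("a", "d"),
               d4 = c("e"))
  expect_identical(cross_dataset_de_consensus(sels, 3), "a")
  expect_identical(cross_dataset_de_consensus(sels, 1),
                   sort(unique(unlist(sels))))
  expect_identical(cross_dataset_de_consensus(sels, 4), character(0))
  sels2 <- list(d1 = c("a", "b"), d2 = c("a", "b"), d3 = c("a", "b"))
  expect_identical(cross_dataset_de_consensus(sels2, 3), c("a", "b"))
  expect_error(cross_dataset_de_consensus(list(), 1), "empty input")
  expect_error(cross_dataset_de_consensus(sels, 5), "exceeds")
})
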