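#' Select the top score quantile of a method's features
#'
#' Implements the study's feature extraction rule: with outlier quantile `q`
#' (default 0.05, i.e. 5%), the `ceiling(q * m)` features with the largest
#' absolute score are selected, where `m` counts the non-degenerate
#' features. Ties at the selection boundary are broken by lexicographic
#' feature id; degenerate features are never selected.
#'
#' @param scores A `"method_scores"` data frame from [score_all()].
#' @param q Selection quantile in (0, 1).
#' @return Object of class `"selection_result"`: list with `method`,
#'   `dataset_id`, `selected` (character vector, in selection order) and `q`.
#' @export
select_top_quantile <- function(scores, q = 0.05) {
  stopifnot(inherits(scores, "method_scores"))
  if (!(q > 0 && q < 1)) stop("`q` must be in (0, 1)")
  keep <- !scores$degenerate
  if (!any(keep)) stop("all features degenerate for method ", scores$method[1])
  pool <- scores[keep, , drop = FALSE]
  n_sel <- ceiling(q * nrow(pool))
  ord <- order_radix(-abs(pool$score), pool$feature_id)
  structure(
    list(method = scores$method[1],
         dataset_id = attr(scores, "dataset_id") %||% "dataset1",
         selected = pool$feature_id[ord[seq_len(n_sel)]],
         q = q),
    class = "selection_result"
  )
}

#' Cross-method putative outliers and per-method accuracy
#'
#' A feature selected by at least `k_m` of the methods run on one dataset is
#' a putative outlier; each method's accuracy is the percentage of its own
#' selections that are putative. This is the consensus yardstick used to
#' compare the six statistics on real data, where no ground truth exists.
#'
#' @param selections List of `"selection_result"` objects for one dataset
#'   (one per method).
#' @param k_m Minimum number of agreeing methods (default 3).
#' @return Object of class `"consensus_eval"`: list with `dataset_id`,
#'   `putative` (sorted character vector), `k_m` and `accuracy` (named
#'   numeric, percentages in \[0, 100\]).
#' @export
putative_outliers <- function(selections, k_m = 3) {
  if (!length(selections)) stop("no selections supplied")
  stopifnot(all(vapply(selections, inherits, TRUE, "selection_result")))
  ids <- unique(vapply(selections, `[[`, "", "dataset_id"))
  if (length(ids) != 1) {
    stop("selections mix dataset IDs: ", paste(ids, collapse = ", "))
  }
  if (length(selections) < k_m) {
    stop("k_m = ", k_m, " but only ", length(selections), " methods present")
  }
  counts <- table(unlist(lapply(selections, `[[`, "selected")))
  putative <- sort(names(counts)[counts >= k_m])
  accuracy <- vapply(selections, function(s) {
    100 * sum(s$selected %in% putative) / length(s$selected)
  }, numeric(1))
  names(accuracy) <- vapply(selections, `[[`, "", "method")
  structure(
    list(dataset_id = ids, putative = putative, k_m = k_m,
         accuracy = accuracy),
    class = "consensus_eval"
  )
}

#' Rank methods by median consensus accuracy across datasets
#'
#' Computes the median and sample standard deviation of each method's
#' accuracy across datasets. The best method maximizes the median; ties are
#' broken by smaller standard deviation, then lexicographically by name.
#'
#' @param evaluations List of `"consensus_eval"` objects, one per dataset;
#'   every method must be present in every evaluation.
#' @return Object of class `"method_ranking"`: list with `table` (data frame
#'   of method, median_accuracy, sd_accuracy, ordered best first) and
#'   `best_method`.
#' @export
rank_methods <- function(evaluations) {
  if (!length(evaluations)) stop("no evaluations supplied")
  stopifnot(all(vapply(evaluations, inherits, TRUE, "consensus_eval")))
  if (length(evaluations) < 2) {
    warning("method ranking from a single dataset; ",
            "standard deviations are undefined")
  }
  methods <- names(evaluations[[1]]$accuracy)
  acc <- vapply(evaluations, function(ev) {
    missing <- setdiff(methods, names(ev$accuracy))
    if (length(missing)) {
      stop("method(s) missing from dataset ", ev$dataset_id, ": ",
           paste(missing, collapse = ", "))
    }
    ev$accuracy[methods]
  }, numeric(length(methods)))
  acc <- matrix(acc, nrow = length(methods),
                dimnames = list(methods, NULL))
  med <- apply(acc, 1L, stats::median)
  sdv <- if (ncol(acc) > 1) apply(acc, 1L, stats::sd) else rep(NA_real_, length(methods))
  sd_key <- ifelse(is.na(sdv), Inf, sdv)
  ord <- order_radix(-med, sd_key, methods)
  tab <- data.frame(method = methods[ord],
                    median_accuracy = med[ord],
                    sd_accuracy = sdv[ord],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, best_method = tab$method[1]),
            class = "method_ranking")
}

#' @export
print.method_ranking <- function(x, ...) {
  cat("Method ranking by median consensus accuracy (best first):\n")
  print(x$table, digits = 4)
  cat("Best method:", x$best_method, "\n")
  invisible(x)
}

#' Cross-dataset consensus of selected features
#'
#' Retains the features (compared by their shared global identifiers) that
#' appear in the selected sets of at least `k_d` datasets.
#'
#' @param selections Named list mapping dataset id to a character vector of
#'   selected feature IDs.
#' @param k_d Minimum number of datasets (default 3); must not exceed the
#'   number of datasets. `k_d = 1` yields the union, `k_d = n` the
#'   intersection.
#' @return Sorted character vector of consensus feature IDs.
#' @export
cross_dataset_de_consensus <- function(selections, k_d = 3) {
  if (!length(selections)) stop("empty input: no dataset selections")
  if (k_d > length(selections)) {
    stop("k_d = ", k_d, " exceeds number of datasets (", length(selections), ")")
  }
  counts <- table(unlist(lapply(selections, unique)))
  sort(names(counts)[counts >= k_d])
}
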