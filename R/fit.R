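#' Fit the outlier-detection consensus model to one dataset
#'
#' The central per-dataset fitting function: scores every feature with each
#' requested statistic ([score_all()]), selects each method's top score
#' quantile ([select_top_quantile()]) and evaluates the cross-method
#' consensus ([putative_outliers()]). The result is a classed object with
#' `print`, `summary`, `coef` and `plot` methods.
#'
#' @param dataset An [expression_dataset()].
#' @param methods Statistics to run (default all six).
#' @param q Outlier selection quantile (default 0.05).
#' @param k_methods Minimum number of agreeing methods for a putative
#'   outlier (default 3).
#' @param direction_mode Passed to [score_all()].
#' @param ... Further arguments to [score_all()] (`copa_r`, `most_B`,
#'   `most_seed`).
#' @return Object of class `"outlier_fit"`: list with `dataset_id`,
#'   `scores` (per-method score frames), `selections`, `consensus`
#'   (a `"consensus_eval"`), `q`, `methods` and the matched `call`.
#' @examples
#' cfg <- simulation_config(n_normal = 12, n_tumor = 12, n_features = 60,
#'                          n_datasets = 1, seed = 3)
#' fit <- outlier_fit(generate_dataset(cfg)$dataset,
#'                    methods = c("ttest", "ort", "os"))
#' fit
#' summary(fit)
#' @export
outlier_fit <- function(dataset, methods = outlier_methods(), q = 0.05,
                        k_methods = 3,
                        direction_mode = c("both", "up", "down"), ...) {
  direction_mode <- match.arg(direction_mode)
  if (k_methods > length(methods)) {
    stop("k_methods = ", k_methods, " exceeds the number of methods (",
         length(methods), ")")
  }
  scores <- score_all(dataset, methods = methods,
                      direction_mode = direction_mode, ...)
  selections <- lapply(scores, select_top_quantile, q = q)
  consensus <- putative_outliers(selections, k_m = k_methods)
  structure(
    list(dataset_id = dataset$dataset_id, scores = scores,
         selections = selections, consensus = consensus, q = q,
         methods = methods, call = match.call()),
    class = "outlier_fit"
  )
}

#' @export
print.outlier_fit <- function(x, ...) {
  cat("Outlier consensus fit for dataset '", x$dataset_id, "'\n", sep = "")
  cat("  methods: ", paste(x$methods, collapse = ", "), "\n", sep = "")
  cat("  selection quantile: ", x$q, " (",
      length(x$selections[[1]]$selected), " features per method)\n", sep = "")
  cat("  putative outliers (>= ", x$consensus$k_m, " methods): ",
      length(x$consensus$putative), "\n", sep = "")
  invisible(x)
}

#' @export
summary.outlier_fit <- function(object, ...) {
  acc <- object$consensus$accuracy
  out <- list(
    dataset_id = object$dataset_id,
    n_putative = length(object$consensus$putative),
    n_selected = length(object$selections[[1]]$selected),
    accuracy = data.frame(method = names(acc), accuracy_percent = unname(acc),
                          row.names = NULL, stringsAsFactors = FALSE)
  )
  class(out) <- "summary.outlier_fit"
  out
}

#' @export
print.summary.outlier_fit <- function(x, ...) {
  cat("Dataset '", x$dataset_id, "': ", x$n_selected,
      " features selected per method, ", x$n_putative,
      " putative outliers\n", sep = "")
  cat("Per-method consensus accuracy (%):\n")
  print(x$accuracy, digits = 4)
  invisible(x)
}

#' Extract the feature-by-method score matrix from a fit
#'
#' @param object An `"outlier_fit"`.
#' @param ... Unused.
#' @return Numeric matrix, features in rows, one column per method; signed
#'   scores (negative = down direction).
#' @export
coef.outlier_fit <- function(object, ...) {
  do.call(cbind, lapply(object$scores, function(s) {
    stats::setNames(s$score, s$feature_id)
  }))
}

#' Plot per-method consensus accuracy of a fit
#'
#' @param x An `"outlier_fit"`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.outlier_fit <- function(x, ...) {
  acc <- x$consensus$accuracy
  graphics::barplot(acc, ylab = "consensus accuracy (%)", ylim = c(0, 100),
                    main = paste0("Dataset '", x$dataset_id, "'"), ...)
  invisible(x)
}
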