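#' Score every feature of a dataset with one or more outlier statistics
#'
#' Applies the requested statistics feature-by-feature. The one-sided
#' statistics (COPA, OS, ORT, MOST, LSOSS) detect over-expression; with
#' `direction_mode = "both"` each is additionally evaluated on the negated
#' matrix to detect under-expression, and per feature the direction with the
#' larger score magnitude wins. Down-direction scores are stored with a
#' negative sign so that the sign of a score always encodes its direction
#' and `abs(score)` its strength. The t statistic is naturally two-sided:
#' its sign is kept and its direction read off the sign.
#'
#' @param dataset An [expression_dataset()].
#' @param methods Character vector of statistics to run; see
#'   [outlier_methods()].
#' @param direction_mode `"both"` (default), `"up"` or `"down"`. `"down"`
#'   evaluates the one-sided statistics on the negated matrix only.
#' @param copa_r COPA percentile, passed to [copa_stat()].
#' @param most_B,most_seed Monte-Carlo settings for the MOST order-statistic
#'   moment table; `most_seed` is a fixed internal stream so that MOST scores
#'   do not depend on the caller's RNG position.
#' @return Named list of `"method_scores"` data frames, one per method, with
#'   columns `feature_id`, `method`, `score`, `direction`, `degenerate` and
#'   the dataset id as an attribute.
#' @examples
#' cfg <- simulation_config(n_normal = 10, n_tumor = 10, n_features = 50,
#'                          n_datasets = 1, seed = 1)
#' d <- generate_dataset(cfg)$dataset
#' sc <- score_all(d, methods = c("ttest", "ort"))
#' head(sc$ort)
#' @export
score_all <- function(dataset, methods = outlier_methods(),
                      direction_mode = c("both", "up", "down"),
                      copa_r = 90, most_B = 10000, most_seed = 1) {
  stopifnot(inherits(dataset, "expr_dataset"))
  direction_mode <- match.arg(direction_mode)
  if (!length(methods)) stop("empty method list")
  unknown <- setdiff(methods, OUTLIER_METHODS)
  if (length(unknown)) {
    stop("unknown method name(s): ", paste(unknown, collapse = ", "))
  }
  gs <- group_split(dataset)
  moments <- if ("most" %in% methods) {
    precompute_order_moments(ncol(gs$Y), B = most_B, seed = most_seed)
  }
  out <- lapply(methods, function(m) {
    score_one_method(m, gs$X, gs$Y, direction_mode, copa_r, moments,
                     dataset$dataset_id)
  })
  stats::setNames(out, methods)
}

# Per-feature evaluation of one method over the whole matrix.
score_one_method <- function(method, X, Y, direction_mode, copa_r, moments,
                             dataset_id) {
  f <- switch(method,
    ttest = ttest_stat,
    copa  = function(x, y) copa_stat(x, y, r = copa_r),
    os    = os_stat,
    ort   = ort_stat,
    most  = function(x, y) most_stat(x, y, moments),
    lsoss = lsoss_stat
  )
  up <- eval_rows(f, X, Y)
  if (method == "ttest") {
    score <- up$score
    direction <- ifelse(score >= 0, "up", "down")
    degenerate <- up$degenerate
  } else if (direction_mode == "up") {
    score <- up$score
    direction <- rep("up", length(score))
    degenerate <- up$degenerate
  } else if (direction_mode == "down") {
    dn <- eval_rows(f, -X, -Y)
    score <- -dn$score
    direction <- rep("down", length(score))
    degenerate <- dn$degenerate
  } else {
    dn <- eval_rows(f, -X, -Y)
    take_down <- abs(dn$score) > abs(up$score)
    score <- ifelse(take_down, -dn$score, up$score)
    direction <- ifelse(take_down, "down", "up")
    degenerate <- up$degenerate | dn$degenerate
  }
  score[degenerate] <- 0
  structure(
    data.frame(feature_id = rownames(X), method = method, score = score,
               direction = direction, degenerate = degenerate,
               stringsAsFactors = FALSE, row.names = NULL),
    dataset_id = dataset_id,
    class = c("method_scores", "data.frame")
  )
}

eval_rows <- function(f, X, Y) {
  m <- nrow(X)
  score <- numeric(m)
  degenerate <- logical(m)
  for (i in seq_len(m)) {
    v <- f(X[i, ], Y[i, ])
    score[i] <- as.numeric(v)
    degenerate[i] <- is_degenerate(v)
  }
  list(score = score, degenerate = degenerate)
}
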