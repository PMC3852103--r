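#' Two-group expression dataset
#'
#' Container for one platform's feature-by-sample log-expression matrix with
#' binary sample labels (`normal` vs `tumor`). This is the input to
#' [outlier_fit()] and [score_all()].
#'
#' @param values Numeric matrix, features in rows and samples in columns.
#'   Row names are feature identifiers, column names sample identifiers;
#'   both must be unique. Values are assumed to be on the log scale.
#' @param group Character or factor of length `ncol(values)` with levels
#'   `"normal"` and `"tumor"`; at least two samples per group are required.
#' @param dataset_id Identifier used in downstream consensus tables.
#'
#' @return An object of class `"expr_dataset"`: a list with elements
#'   `values`, `group` (factor) and `dataset_id`.
#' @examples
#' m <- matrix(rnorm(40), nrow = 5,
#'             dimnames = list(paste0("f", 1:5), paste0("s", 1:8)))
#' d <- expression_dataset(m, rep(c("normal", "tumor"), each = 4))
#' d
#' @export
expression_dataset <- function(values, group, dataset_id = "dataset1") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (features x samples)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have feature row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) stop("duplicate sample IDs")
  if (length(group) != ncol(values)) {
    stop("`group` length (", length(group), ") != number of samples (",
         ncol(values), ")")
  }
  if (anyNA(group)) stop("missing group labels")
  group <- as.character(group)
  bad <- setdiff(unique(group), c("normal", "tumor"))
  if (length(bad)) stop("unknown group labels: ", paste(bad, collapse = ", "))
  group <- factor(group, levels = c("normal", "tumor"))
  if (any(table(group) < 2)) stop("need at least 2 samples per group")
  structure(
    list(values = values, group = group, dataset_id = as.character(dataset_id)),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat("Expression dataset '", x$dataset_id, "': ",
      nrow(x$values), " features x ", ncol(x$values), " samples (",
      sum(x$group == "normal"), " normal, ", sum(x$group == "tumor"),
      " tumor)\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

# Split the matrix into the control (normal) and case (tumour) blocks.
group_split <- function(dataset) {
  list(
    X = dataset$values[, dataset$group == "normal", drop = FALSE],
    Y = dataset$values[, dataset$group == "tumor", drop = FALSE]
  )
}
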