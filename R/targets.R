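#' miRNA-to-target-gene map
#'
#' A many-to-many relation between miRNAs and predicted target genes,
#' typically read from a prediction tool's output table.
#'
#' @param pairs Data frame with columns `mirna_id` and `gene_id` (extra
#'   columns dropped). Duplicate pairs are collapsed; empty IDs are an
#'   error.
#' @return Object of class `"target_map"`: list with `pairs` (unique,
#'   sorted data frame).
#' @export
target_map <- function(pairs) {
  if (!is.data.frame(pairs) || !all(c("mirna_id", "gene_id") %in% names(pairs))) {
    stop("`pairs` must be a data frame with columns mirna_id and gene_id")
  }
  pairs <- data.frame(mirna_id = as.character(pairs$mirna_id),
                      gene_id = as.character(pairs$gene_id),
                      stringsAsFactors = FALSE)
  if (any(!nzchar(pairs$mirna_id)) || any(!nzchar(pairs$gene_id)) ||
      anyNA(pairs)) {
    stop("empty or missing IDs in target map")
  }
  pairs <- unique(pairs)
  pairs <- pairs[order_radix(pairs$mirna_id, pairs$gene_id), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs), class = "target_map")
}

#' @export
print.target_map <- function(x, ...) {
  cat("Target map: ", nrow(x$pairs), " pairs, ",
      length(unique(x$pairs$mirna_id)), " miRNAs, ",
      length(unique(x$pairs$gene_id)), " genes\n", sep = "")
  invisible(x)
}

#' Intersect several target-prediction tables
#'
#' Keeps only the miRNA--gene pairs predicted by every table — the
#' "reliable" consensus of multiple prediction tools. The operation is
#' order-independent and idempotent.
#'
#' @param tables List of at least two [target_map()] objects.
#' @return A [target_map()] of the common pairs (possibly empty).
#' @export
intersect_predictions <- function(tables) {
  if (length(tables) < 2) stop("need at least 2 prediction tables")
  stopifnot(all(vapply(tables, inherits, TRUE, "target_map")))
  keys <- lapply(tables, function(tm) {
    paste(tm$pairs$mirna_id, tm$pairs$gene_id, sep = "\t")
  })
  common <- Reduce(intersect, keys)
  first <- tables[[1]]$pairs
  keep <- paste(first$mirna_id, first$gene_id, sep = "\t") %in% common
  target_map(first[keep, , drop = FALSE])
}

#' Target genes of a set of miRNAs
#'
#' Union of the target-gene sets of the listed miRNAs. miRNAs absent from
#' the map are reported in the `missing_mirnas` attribute (and a warning),
#' not treated as fatal.
#'
#' @param de_mirnas Character vector of miRNA IDs.
#' @param map A [target_map()].
#' @return Sorted character vector of target genes with attribute
#'   `missing_mirnas`.
#' @export
targets_of <- function(de_mirnas, map) {
  stopifnot(inherits(map, "target_map"))
  de_mirnas <- unique(as.character(de_mirnas))
  missing <- setdiff(de_mirnas, unique(map$pairs$mirna_id))
  if (length(missing)) {
    warning(length(missing), " miRNA(s) absent from the target map: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ...")
  }
  genes <- sort(unique(map$pairs$gene_id[map$pairs$mirna_id %in% de_mirnas]))
  attr(genes, "missing_mirnas") <- missing
  genes
}

#' Cross-dataset target-gene consensus
#'
#' Given each dataset's target-gene set (the union of targets of that
#' dataset's DE miRNAs), retains the genes present in at least `k_d`
#' datasets and reports how many genes occur in exactly j datasets for each
#' multiplicity j, so that the `>= k` count always equals the sum of the
#' exact counts from k upwards.
#'
#' @param per_dataset_targets Named list mapping dataset id to a character
#'   vector of target genes.
#' @param k_d Minimum number of datasets (default 3).
#' @return Object of class `"gene_consensus"`: list with `genes` (sorted,
#'   multiplicity >= `k_d`), `multiplicity` (named integer, all genes), and
#'   `breakdown` (data frame `multiplicity`, `n_genes`, exact counts).
#' @export
gene_consensus <- function(per_dataset_targets, k_d = 3) {
  if (!length(per_dataset_targets) || !sum(lengths(per_dataset_targets))) {
    stop("empty input: no target genes supplied")
  }
  n_ds <- length(per_dataset_targets)
  if (k_d > n_ds) stop("k_d = ", k_d, " exceeds number of datasets (", n_ds, ")")
  counts <- table(unlist(lapply(per_dataset_targets, unique)))
  multiplicity <- stats::setNames(as.integer(counts), names(counts))
  breakdown <- data.frame(
    multiplicity = seq_len(n_ds),
    n_genes = vapply(seq_len(n_ds), function(j) sum(multiplicity == j), 0L)
  )
  structure(
    list(genes = sort(names(multiplicity)[multiplicity >= k_d]),
         k_d = k_d, multiplicity = multiplicity, breakdown = breakdown),
    class = "gene_consensus"
  )
}

#' @export
print.gene_consensus <- function(x, ...) {
  cat("Gene consensus (>= ", x$k_d, " datasets): ", length(x$genes),
      " genes\n", sep = "")
  print(x$breakdown, row.names = FALSE)
  invisible(x)
}

#' Combine a primary target map with prediction-table consensus
#'
#' For miRNAs covered by the primary map the primary pairs are used; for
#' miRNAs missing from it, pairs from the intersection of the supplied
#' prediction tables fill the gap. This mirrors the practice of using a
#' curated database when available and the agreement of several sequence
#' predictors otherwise.
#'
#' @param primary A [target_map()].
#' @param prediction_tables Optional list of at least two [target_map()]
#'   objects.
#' @return A [target_map()].
#' @export
augment_target_map <- function(primary, prediction_tables = NULL) {
  stopifnot(inherits(primary, "target_map"))
  if (is.null(prediction_tables)) return(primary)
  consensus <- intersect_predictions(prediction_tables)
  extra <- consensus$pairs[
    !(consensus$pairs$mirna_id %in% unique(primary$pairs$mirna_id)), ,
    drop = FALSE]
  target_map(rbind(primary$pairs, extra))
}
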