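# Readers and writers for the pipeline's plain-text interchange formats.
# Every write_*/read_* pair is a round-trip identity, and readers report
# malformed input with the offending line or identifier.

#' Write / read an expression dataset as TSV plus sample metadata
#'
#' The expression table has the feature ID in the first column
#' (`feature_id`) and one column per sample; the metadata table has columns
#' `sample_id` and `group` (`normal` or `tumor`).
#'
#' @param dataset An [expression_dataset()].
#' @param file,meta_file Paths for the expression and metadata tables.
#' @param dataset_id Dataset identifier to attach on read.
#' @return `write_expression_tsv()` returns the paths invisibly;
#'   `read_expression_tsv()` returns an [expression_dataset()].
#' @export
write_expression_tsv <- function(dataset, file, meta_file) {
  stopifnot(inherits(dataset, "expr_dataset"))
  tab <- data.frame(feature_id = rownames(dataset$values),
                    dataset$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = colnames(dataset$values),
                     group = as.character(dataset$group),
                     stringsAsFactors = FALSE)
  utils::write.table(meta, meta_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(file, meta_file))
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(file, meta_file, dataset_id = "dataset1") {
  tab <- utils::read.delim(file, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "feature_id") {
    stop("expression table ", file, " must have 'feature_id' as first column")
  }
  if (anyDuplicated(tab$feature_id)) {
    stop("duplicate feature IDs in ", file, ": ",
         paste(unique(tab$feature_id[duplicated(tab$feature_id)]),
               collapse = ", "))
  }
  values <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric expression values in ", file)
  rownames(values) <- tab$feature_id
  meta <- utils::read.delim(meta_file, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(meta))) {
    stop("metadata ", meta_file, " must have columns sample_id and group")
  }
  missing <- setdiff(colnames(values), meta$sample_id)
  if (length(missing)) {
    stop("sample(s) in matrix missing from metadata: ",
         paste(missing, collapse = ", "))
  }
  group <- meta$group[match(colnames(values), meta$sample_id)]
  expression_dataset(values, group, dataset_id = dataset_id)
}

#' Write / read a miRNA target map as two-column TSV
#'
#' @param map A [target_map()].
#' @param file Path; columns `mirna_id`, `gene_id` with a header line.
#' @return `read_target_map()` returns a [target_map()].
#' @export
write_target_map <- function(map, file) {
  stopifnot(inherits(map, "target_map"))
  utils::write.table(map$pairs, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_target_map
#' @export
read_target_map <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("target map ", file, " needs two columns")
  names(tab)[1:2] <- c("mirna_id", "gene_id")
  target_map(tab[, 1:2])
}

#' Write / read a gene-set collection in GMT format
#'
#' One set per line: set name, description, then the tab-separated member
#' genes. Lines with fewer than three fields are a parse error reported
#' with their line number. The description field holds the collection label
#' on write and is not otherwise interpreted.
#'
#' @param collection A [gene_set_collection()].
#' @param file Path to a `.gmt` file.
#' @param label Collection label for the object built on read.
#' @param universe Optional universe for the object built on read
#'   (default: union of the sets).
#' @return `read_gmt()` returns a [gene_set_collection()].
#' @export
write_gmt <- function(collection, file) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$label, collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(file, label = "custom", universe = NULL) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    stop("GMT parse error in ", file, ": line ", bad[1], " has ",
         lengths(fields)[bad[1]], " field(s), need at least 3")
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1)
  gene_set_collection(sets, universe = universe, label = label)
}

#' Write a simulation truth or run report as JSON
#'
#' @param x A `"sim_truth"` or any list of plain values.
#' @param file Path to write.
#' @return The path, invisibly.
#' @export
write_json_report <- function(x, file) {
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' Write method scores as TSV
#'
#' Columns: `feature_id`, `method`, `score`, `direction`, `degenerate`.
#'
#' @param scores A `"method_scores"` data frame or a list of them.
#' @param file Path to write.
#' @export
write_scores_tsv <- function(scores, file) {
  if (inherits(scores, "method_scores")) scores <- list(scores)
  tab <- do.call(rbind, lapply(scores, as.data.frame))
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write the per-dataset, per-method accuracy table as TSV
#'
#' Columns: `dataset_id`, `method`, `accuracy_percent`.
#'
#' @param evaluations List of `"consensus_eval"` objects.
#' @param file Path to write.
#' @export
write_accuracy_tsv <- function(evaluations, file) {
  tab <- do.call(rbind, lapply(evaluations, function(ev) {
    data.frame(dataset_id = ev$dataset_id, method = names(ev$accuracy),
               accuracy_percent = unname(ev$accuracy),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write an enrichment table as TSV
#'
#' Fixed column order: set_name, set_size, query_size, overlap, p_value,
#' fdr, passes_threshold.
#'
#' @param table An `"enrichment_table"`.
#' @param file Path to write.
#' @export
write_enrichment_tsv <- function(table, file) {
  cols <- c("set_name", "set_size", "query_size", "overlap", "p_value",
            "fdr", "passes_threshold")
  utils::write.table(as.data.frame(table)[, cols], file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}
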