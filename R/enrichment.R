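#' Named gene-set collection over a gene universe
#'
#' @param sets Named list of character vectors (gene IDs); every set must be
#'   non-empty and contained in the universe.
#' @param universe Character vector of background genes; defaults to the
#'   union of all set members.
#' @param label Collection label (e.g. `"go"`, `"kegg"`), used to pick the
#'   threshold semantics in [enrich()] reporting.
#' @return Object of class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(sets, universe = NULL, label = "custom") {
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("`sets` must be a non-empty named list")
  }
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names")
  sets <- lapply(sets, function(g) sort(unique(as.character(g))))
  if (any(lengths(sets) == 0)) stop("every gene set must be non-empty")
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  universe <- sort(unique(as.character(universe)))
  outside <- setdiff(unlist(sets), universe)
  if (length(outside)) {
    stop("gene set members outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  structure(list(sets = sets, universe = universe, label = label),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene-set collection '", x$label, "': ", length(x$sets), " sets, ",
      length(x$universe), " universe genes\n", sep = "")
  invisible(x)
}

#' Upper-tail hypergeometric overlap probability
#'
#' Probability of observing an overlap of at least `k` between a query of
#' size `n` and a gene set of size `K` drawn from a universe of size `N`:
#' `P(X >= k)` with `X ~ Hypergeometric(N, K, n)`. This is the standard
#' over-representation p value.
#'
#' @param N Universe size.
#' @param K Gene-set size (`K <= N`).
#' @param n Query size (`n <= N`).
#' @param k Observed overlap (`k <= min(K, n)`).
#' @return Probability in \[0, 1\].
#' @examples
#' hypergeom_p(10, 5, 4, 4)  # 5/210
#' @export
hypergeom_p <- function(N, K, n, k) {
  if (K > N || n > N || k > min(K, n) || k < 0 || K < 0 || n < 0) {
    stop("inconsistent counts: need 0 <= k <= min(K, n) and K, n <= N")
  }
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up FDR adjustment, clipped at 1, returned in the original order.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' Tests every set of a collection for over-representation in a query gene
#' list. Query genes outside the universe are dropped (their number is
#' recorded). The table reports raw hypergeometric p values and BH-adjusted
#' FDR, sorted by p value, and flags the sets passing the collection's
#' threshold — the threshold applies to the raw p value for `"p"` semantics
#' (KEGG-style reporting) and to the FDR otherwise.
#'
#' @param query Character vector of gene IDs.
#' @param collection A [gene_set_collection()].
#' @param threshold Significance threshold (default 0.001).
#' @param threshold_type `"fdr"` (default) or `"p"`.
#' @param universe Optional custom background; gene sets and the query are
#'   intersected with it.
#' @return Data frame of class `"enrichment_table"` with columns
#'   `set_name`, `set_size`, `query_size`, `overlap`, `p_value`, `fdr`,
#'   `passes_threshold`, sorted ascending by p value (ties by set name);
#'   attributes `n_dropped` (query genes outside the universe),
#'   `threshold` and `threshold_type`.
#' @export
enrich <- function(query, collection, threshold = 0.001,
                   threshold_type = c("fdr", "p"), universe = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  threshold_type <- match.arg(threshold_type)
  universe <- if (is.null(universe)) collection$universe else
    sort(unique(as.character(universe)))
  if (!length(universe)) stop("empty universe")
  query <- unique(as.character(query))
  n_dropped <- sum(!(query %in% universe))
  query <- intersect(query, universe)
  if (!length(query)) stop("empty query after intersection with the universe")
  sets <- lapply(collection$sets, intersect, universe)
  N <- length(universe)
  n <- length(query)
  K <- lengths(sets)
  k <- vapply(sets, function(s) length(intersect(s, query)), 0L)
  p <- vapply(seq_along(sets), function(i) hypergeom_p(N, K[i], n, k[i]),
              numeric(1))
  fdr <- bh_fdr(p)
  tab <- data.frame(set_name = names(sets), set_size = as.integer(K),
                    query_size = n, overlap = as.integer(k),
                    p_value = p, fdr = fdr,
                    stringsAsFactors = FALSE, row.names = NULL)
  tab$passes_threshold <- if (threshold_type == "p") tab$p_value < threshold
                          else tab$fdr < threshold
  tab <- tab[order_radix(tab$p_value, tab$set_name), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, n_dropped = n_dropped, threshold = threshold,
            threshold_type = threshold_type,
            class = c("enrichment_table", "data.frame"))
}
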