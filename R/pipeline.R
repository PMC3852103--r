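#' Configuration for the full consensus pipeline
#'
#' Bundles every tunable of the workflow. The defaults reproduce the
#' study-style parameters: selection quantile 0.05, putative-outlier rule
#' "at least 3 methods", cross-dataset rule "at least 3 datasets",
#' enrichment threshold 0.001.
#'
#' @param q Outlier selection quantile.
#' @param k_methods Minimum agreeing methods for a putative outlier.
#' @param k_datasets Minimum datasets for cross-dataset consensus.
#' @param methods Statistics to run.
#' @param direction_mode Passed to [score_all()].
#' @param threshold Enrichment significance threshold.
#' @param threshold_type `"fdr"` or `"p"` (see [enrich()]).
#' @param consensus_level `"gene"` (default): per-dataset target-gene sets
#'   are intersected at `k_datasets`. `"mirna"`: DE miRNAs are intersected
#'   at `k_datasets` first and then mapped to targets.
#' @param seed Integer seed for the embedded simulation.
#' @param sim A [simulation_config()] describing the input scenario (its
#'   `seed` is overridden by `seed`), or `NULL` when `inputs` is given.
#' @param inputs Optional named list of pre-built inputs: `datasets` (list
#'   of [expression_dataset()]), `target_map`, `gene_sets`, and optionally
#'   `prediction_tables`.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(q = 0.05, k_methods = 3, k_datasets = 3,
                            methods = outlier_methods(),
                            direction_mode = "both",
                            threshold = 0.001, threshold_type = "fdr",
                            consensus_level = c("gene", "mirna"),
                            seed = 1, sim = simulation_config(),
                            inputs = NULL) {
  consensus_level <- match.arg(consensus_level)
  if (!(q > 0 && q < 1)) stop("q must be in (0, 1)")
  if (k_methods > length(methods)) {
    stop("k_methods = ", k_methods, " exceeds the number of methods (",
         length(methods), ")")
  }
  if (is.null(inputs)) {
    stopifnot(inherits(sim, "sim_config"))
    sim$seed <- as.integer(seed)
    if (k_datasets > sim$n_datasets) {
      stop("k_datasets = ", k_datasets, " exceeds n_datasets (",
           sim$n_datasets, ")")
    }
  } else {
    if (k_datasets > length(inputs$datasets)) {
      stop("k_datasets exceeds the number of supplied datasets")
    }
  }
  structure(
    list(q = q, k_methods = k_methods, k_datasets = k_datasets,
         methods = methods, direction_mode = direction_mode,
         threshold = threshold, threshold_type = threshold_type,
         consensus_level = consensus_level, seed = as.integer(seed),
         sim = if (is.null(inputs)) sim, inputs = inputs),
    class = "pipeline_config"
  )
}

#' Run the full outlier-consensus workflow
#'
#' Executes the stages in order: simulate (or load) the datasets; score
#' every feature with every method; select each method's top quantile;
#' form per-dataset putative outliers and rank the methods by consensus
#' accuracy; take the best method's selections as each dataset's DE
#' features; map them to target genes and compute the cross-dataset gene
#' consensus; test the consensus genes for gene-set over-representation.
#' Features private to a single dataset's panel are reported with a
#' warning, since they can never reach the cross-dataset consensus.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, all intermediates are
#'   written there as TSV/GMT/JSON (see the individual `write_*()`
#'   functions) along with the final `report.json`.
#' @return Object of class `"pipeline_run"`: list with `ranking`,
#'   `fits` (per-dataset [outlier_fit()] objects), `de_by_dataset`,
#'   `consensus` (a `"gene_consensus"`), `consensus_mirnas` (when
#'   `consensus_level = "mirna"`), `enrichment`, `truths` (when simulated),
#'   `report` (plain-list summary with config echo) and `config`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(seed = 42,
#'   sim = simulation_config(n_features = 120, n_normal = 10, n_tumor = 12))
#' run <- run_pipeline(cfg)
#' run
#' }
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  # -- stage: data ----------------------------------------------------------
  if (is.null(config$inputs)) {
    scenario <- generate_scenario(config$sim)
    datasets <- scenario$datasets
    map <- scenario$target_map
    collection <- scenario$gene_sets
    truths <- scenario$truths
  } else {
    datasets <- config$inputs$datasets
    map <- config$inputs$target_map
    collection <- config$inputs$gene_sets
    truths <- NULL
    if (!is.null(config$inputs$prediction_tables)) {
      map <- augment_target_map(map, config$inputs$prediction_tables)
    }
    # Cross-platform probe harmonisation is the caller's job: features are
    # compared by shared global IDs, so warn about IDs private to one panel.
    panels <- lapply(datasets, function(d) rownames(d$values))
    shared_counts <- table(unlist(lapply(panels, unique)))
    private <- names(shared_counts)[shared_counts == 1]
    if (length(private) && length(datasets) > 1) {
      warning(length(private), " feature(s) private to a single dataset ",
              "cannot reach the cross-dataset consensus (e.g. ",
              paste(utils::head(private, 3), collapse = ", "), ")")
    }
  }
  # -- stage: score + select + per-dataset consensus ------------------------
  fits <- lapply(datasets, function(d) {
    outlier_fit(d, methods = config$methods, q = config$q,
                k_methods = config$k_methods,
                direction_mode = config$direction_mode)
  })
  names(fits) <- vapply(fits, `[[`, "", "dataset_id")
  # -- stage: method ranking ------------------------------------------------
  ranking <- rank_methods(lapply(fits, `[[`, "consensus"))
  best <- ranking$best_method
  de_by_dataset <- lapply(fits, function(f) f$selections[[best]]$selected)
  # -- stage: targets + cross-dataset consensus -----------------------------
  consensus_mirnas <- NULL
  if (config$consensus_level == "mirna") {
    consensus_mirnas <- cross_dataset_de_consensus(de_by_dataset,
                                                   config$k_datasets)
    genes <- suppressWarnings(targets_of(consensus_mirnas, map))
    per_ds <- lapply(de_by_dataset, function(sel) {
      suppressWarnings(targets_of(sel, map))
    })
    consensus <- gene_consensus(per_ds, k_d = config$k_datasets)
    consensus$genes <- sort(as.character(genes))
  } else {
    per_ds <- lapply(de_by_dataset, function(sel) {
      suppressWarnings(targets_of(sel, map))
    })
    consensus <- gene_consensus(per_ds, k_d = config$k_datasets)
  }
  # -- stage: enrichment ----------------------------------------------------
  universe <- intersect(collection$universe, unique(map$pairs$gene_id))
  enrichment <- if (length(intersect(consensus$genes, universe))) {
    enrich(consensus$genes, collection, threshold = config$threshold,
           threshold_type = config$threshold_type, universe = universe)
  } else {
    # no consensus genes to test: an empty table, not a failed run
    structure(
      data.frame(set_name = character(0), set_size = integer(0),
                 query_size = integer(0), overlap = integer(0),
                 p_value = numeric(0), fdr = numeric(0),
                 passes_threshold = logical(0)),
      n_dropped = length(consensus$genes), threshold = config$threshold,
      threshold_type = config$threshold_type,
      class = c("enrichment_table", "data.frame"))
  }
  # -- report ---------------------------------------------------------------
  report <- list(
    seed = config$seed,
    config = config_echo(config),
    selection_sizes = stats::setNames(
      vapply(fits, function(f) length(f$selections[[1]]$selected), 0L),
      names(fits)),
    accuracy = lapply(fits, function(f) as.list(f$consensus$accuracy)),
    best_method = best,
    consensus_de_count = if (is.null(consensus_mirnas)) {
      length(cross_dataset_de_consensus(de_by_dataset, config$k_datasets))
    } else length(consensus_mirnas),
    consensus_gene_count = length(consensus$genes),
    multiplicity_breakdown = stats::setNames(
      as.list(consensus$breakdown$n_genes),
      paste0("exactly_", consensus$breakdown$multiplicity)),
    n_enriched = sum(enrichment$passes_threshold)
  )
  run <- structure(
    list(ranking = ranking, fits = fits, de_by_dataset = de_by_dataset,
         consensus = consensus, consensus_mirnas = consensus_mirnas,
         enrichment = enrichment, truths = truths, report = report,
         config = config),
    class = "pipeline_run"
  )
  if (!is.null(out_dir)) write_run(run, datasets, map, collection, out_dir)
  run
}

config_echo <- function(config) {
  list(q = config$q, k_methods = config$k_methods,
       k_datasets = config$k_datasets, methods = config$methods,
       direction_mode = config$direction_mode, threshold = config$threshold,
       threshold_type = config$threshold_type,
       consensus_level = config$consensus_level, seed = config$seed,
       sim = if (!is.null(config$sim)) unclass(config$sim))
}

write_run <- function(run, datasets, map, collection, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in datasets) {
    write_expression_tsv(d, file.path(out_dir, paste0(d$dataset_id, ".tsv")),
                         file.path(out_dir, paste0(d$dataset_id, "_meta.tsv")))
  }
  for (f in run$fits) {
    write_scores_tsv(f$scores,
                     file.path(out_dir, paste0(f$dataset_id, "_scores.tsv")))
  }
  write_accuracy_tsv(lapply(run$fits, `[[`, "consensus"),
                     file.path(out_dir, "accuracy.tsv"))
  write_json_report(list(table = run$ranking$table,
                         best_method = run$ranking$best_method),
                    file.path(out_dir, "ranking.json"))
  write_target_map(map, file.path(out_dir, "target_map.tsv"))
  write_gmt(collection, file.path(out_dir, "gene_sets.gmt"))
  mult <- data.frame(gene_id = names(run$consensus$multiplicity),
                     multiplicity = unname(run$consensus$multiplicity),
                     stringsAsFactors = FALSE)
  utils::write.table(mult[order_radix(mult$gene_id), ],
                     file.path(out_dir, "gene_multiplicity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(run$consensus$genes, file.path(out_dir, "consensus_genes.txt"))
  write_enrichment_tsv(run$enrichment, file.path(out_dir, "enrichment.tsv"))
  if (!is.null(run$truths)) {
    write_json_report(lapply(run$truths, unclass),
                      file.path(out_dir, "truth.json"))
  }
  write_json_report(run$report, file.path(out_dir, "report.json"))
  invisible(out_dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Outlier-consensus pipeline run (seed ", x$report$seed, ")\n", sep = "")
  cat("  datasets: ", length(x$fits), "; best method: ",
      x$ranking$best_method, "\n", sep = "")
  cat("  consensus DE features (>= ", x$config$k_datasets, " datasets): ",
      x$report$consensus_de_count, "\n", sep = "")
  cat("  consensus target genes: ", x$report$consensus_gene_count, "\n",
      sep = "")
  cat("  enriched gene sets (", x$config$threshold_type, " < ",
      x$config$threshold, "): ", x$report$n_enriched, "\n", sep = "")
  invisible(x)
}

#' @export
summary.pipeline_run <- function(object, ...) {
  cat("Method ranking:\n")
  print(object$ranking$table, digits = 4)
  cat("\nGene multiplicity breakdown:\n")
  print(object$consensus$breakdown, row.names = FALSE)
  cat("\nTop enriched sets:\n")
  print(utils::head(as.data.frame(object$enrichment), 5), digits = 3)
  invisible(object)
}
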