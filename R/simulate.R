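#' Configuration for synthetic multi-dataset expression scenarios
#'
#' Describes a collection of two-group log-expression datasets with planted
#' cancer-outlier features: each differentially expressed (DE) feature is
#' shifted by `shift` in only a fraction `outlier_fraction` of the tumour
#' samples, emulating tumour heterogeneity. Datasets draw their feature
#' panels from a shared global namespace so that any two panels overlap by a
#' controlled fraction, emulating a collection of different microarray
#' platforms. The defaults mirror a four-platform prostate miRNA collection:
#' group sizes (16/60, 12/12, 28/113, 20/20), a few hundred probes per
#' platform, and 40--60% probe overlap between platforms.
#'
#' @param n_normal,n_tumor Samples per group, a single count or one per
#'   dataset.
#' @param n_features Features (probes) per dataset panel.
#' @param de_fraction Fraction of each panel's features that are DE, in
#'   (0, 1).
#' @param outlier_fraction Fraction of tumour samples shifted per DE feature
#'   (pi), in (0, 1]; each DE feature shifts `max(1, round(pi * n_tumor))`
#'   tumour samples.
#' @param shift Log-expression shift mu (>= 0; 0 gives a pure null).
#' @param noise_sd Baseline noise standard deviation sigma (> 0).
#' @param direction `"mixed"` (default; DE features split 50/50 up/down,
#'   consistently across datasets), `"up"` or `"down"`.
#' @param n_datasets Number of datasets in a scenario.
#' @param probe_overlap_range Admissible pairwise panel overlap,
#'   `|A n B| / min(|A|, |B|)`, default `c(0.4, 0.6)`.
#' @param shared_de_fraction Fraction of each dataset's DE features drawn
#'   from a common cross-dataset DE core (default 0.5).
#' @param seed Integer seed; identical configurations generate identical
#'   scenarios.
#' @return Object of class `"sim_config"`.
#' @export
simulation_config <- function(n_normal = c(16, 12, 28, 20),
                              n_tumor = c(60, 12, 113, 20),
                              n_features = 400,
                              de_fraction = 0.05,
                              outlier_fraction = 0.2,
                              shift = 2,
                              noise_sd = 1,
                              direction = c("mixed", "up", "down"),
                              n_datasets = 4,
                              probe_overlap_range = c(0.4, 0.6),
                              shared_de_fraction = 0.5,
                              seed = 1) {
  direction <- match.arg(direction)
  if (n_datasets < 1) stop("n_datasets must be >= 1")
  n_normal <- rep_len(as.integer(n_normal), n_datasets)
  n_tumor <- rep_len(as.integer(n_tumor), n_datasets)
  if (any(n_normal < 2) || any(n_tumor < 2)) {
    stop("need at least 2 samples per group in every dataset")
  }
  if (n_features < 2) stop("n_features must be >= 2")
  if (!(de_fraction > 0 && de_fraction < 1)) stop("de_fraction must be in (0, 1)")
  if (!(outlier_fraction > 0 && outlier_fraction <= 1)) {
    stop("outlier_fraction must be in (0, 1]")
  }
  if (shift < 0) stop("shift must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (length(probe_overlap_range) != 2 ||
      probe_overlap_range[1] > probe_overlap_range[2] ||
      probe_overlap_range[1] <= 0 || probe_overlap_range[2] > 1) {
    stop("probe_overlap_range must be within (0, 1] with low <= high")
  }
  if (!(shared_de_fraction >= 0 && shared_de_fraction <= 1)) {
    stop("shared_de_fraction must be in [0, 1]")
  }
  structure(
    list(n_normal = n_normal, n_tumor = n_tumor,
         n_features = as.integer(n_features), de_fraction = de_fraction,
         outlier_fraction = outlier_fraction, shift = shift,
         noise_sd = noise_sd, direction = direction,
         n_datasets = as.integer(n_datasets),
         probe_overlap_range = probe_overlap_range,
         shared_de_fraction = shared_de_fraction, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config: ", x$n_datasets, " dataset(s), ",
      x$n_features, " features/panel, groups ",
      paste(x$n_normal, x$n_tumor, sep = "/", collapse = ", "), "\n",
      "  DE fraction ", x$de_fraction, ", outlier fraction ",
      x$outlier_fraction, ", shift ", x$shift, ", sd ", x$noise_sd,
      ", direction ", x$direction, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Deterministic scenario skeleton shared by generate_dataset() and
# generate_scenario(): the global feature pool, per-dataset panels (a
# common core plus disjoint private blocks, so every pairwise overlap is
# exactly core/m), the cross-dataset shared DE core, and the per-feature
# shift direction map.
scenario_structure <- function(config) {
  m <- config$n_features
  if (config$n_datasets == 1L) {
    core_n <- m
  } else {
    mid <- mean(config$probe_overlap_range)
    core_n <- round(mid * m)
    if (core_n / m < config$probe_overlap_range[1] ||
        core_n / m > config$probe_overlap_range[2] || core_n < 1 || core_n >= m) {
      stop("infeasible overlap constraints: cannot realise overlap in [",
           paste(config$probe_overlap_range, collapse = ", "),
           "] with ", m, " features")
    }
  }
  pool_n <- core_n + config$n_datasets * (m - core_n)
  pool <- sprintf("mir%05d", seq_len(pool_n))
  core <- pool[seq_len(core_n)]
  panels <- lapply(seq_len(config$n_datasets), function(i) {
    if (m == core_n) return(core)
    off <- core_n + (i - 1L) * (m - core_n)
    c(core, pool[(off + 1L):(off + m - core_n)])
  })
  n_de <- round(config$de_fraction * m)
  n_shared <- min(round(config$shared_de_fraction * n_de), core_n)
  skel <- with_seed(config$seed, {
    shared_de <- sort(sample(core, n_shared))
    dir_map <- if (config$direction == "mixed") {
      stats::setNames(sample(rep_len(c("up", "down"), pool_n)), pool)
    } else {
      stats::setNames(rep(config$direction, pool_n), pool)
    }
    list(shared_de = shared_de, dir_map = dir_map)
  })
  list(pool = pool, core = core, panels = panels, n_de = n_de,
       shared_de = skel$shared_de, dir_map = skel$dir_map)
}

#' Generate one synthetic two-group expression dataset
#'
#' Draws a baseline log-expression matrix with iid Normal(0, sigma^2) noise
#' and, for each planted DE feature, adds (direction `up`) or subtracts
#' (direction `down`) the shift `mu` in exactly
#' `max(1, round(pi * n_tumor))` randomly chosen tumour samples. Feature IDs
#' come from the scenario's global namespace, so datasets generated from the
#' same configuration share a controlled fraction of features.
#'
#' @param config A [simulation_config()].
#' @param dataset_index Which dataset of the scenario to generate
#'   (1-based); determines the feature panel and group sizes.
#' @return List with `dataset` (an [expression_dataset()]) and `truth`, a
#'   `"sim_truth"` list holding `de_features`, `shifted_samples` (per DE
#'   feature, indices into the tumour samples), and placeholders
#'   `true_target_genes` / `true_pathways` filled in by
#'   [generate_scenario()].
#' @examples
#' cfg <- simulation_config(n_normal = 10, n_tumor = 10, n_features = 100,
#'                          n_datasets = 1, seed = 42)
#' g <- generate_dataset(cfg)
#' g$dataset
#' length(g$truth$de_features)  # round(0.05 * 100) = 5
#' @export
generate_dataset <- function(config, dataset_index = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (dataset_index < 1 || dataset_index > config$n_datasets) {
    stop("dataset_index must be in 1..", config$n_datasets)
  }
  ss <- scenario_structure(config)
  i <- as.integer(dataset_index)
  n1 <- config$n_normal[i]
  n2 <- config$n_tumor[i]
  panel <- ss$panels[[i]]
  m <- length(panel)
  k_shift <- max(1L, round(config$outlier_fraction * n2))
  gen <- with_seed(config$seed + i, {
    extra <- sample(setdiff(panel, ss$shared_de),
                    ss$n_de - length(ss$shared_de))
    de <- sort(c(ss$shared_de, extra))
    v <- matrix(stats::rnorm(m * (n1 + n2), mean = 0, sd = config$noise_sd),
                nrow = m)
    shifted <- lapply(de, function(f) sort(sample.int(n2, k_shift)))
    names(shifted) <- de
    for (f in de) {
      sgn <- if (ss$dir_map[[f]] == "up") 1 else -1
      rows <- match(f, panel)
      v[rows, n1 + shifted[[f]]] <- v[rows, n1 + shifted[[f]]] +
        sgn * config$shift
    }
    list(v = v, de = de, shifted = shifted)
  })
  dimnames(gen$v) <- list(panel, c(sprintf("ds%d_N%03d", i, seq_len(n1)),
                                   sprintf("ds%d_T%03d", i, seq_len(n2))))
  dataset <- expression_dataset(gen$v,
                                rep(c("normal", "tumor"), c(n1, n2)),
                                dataset_id = sprintf("dataset%d", i))
  truth <- structure(
    list(dataset_id = dataset$dataset_id, de_features = gen$de,
         shifted_samples = gen$shifted,
         directions = ss$dir_map[gen$de],
         true_target_genes = character(0), true_pathways = character(0)),
    class = "sim_truth"
  )
  list(dataset = dataset, truth = truth)
}

#' Generate a full multi-dataset scenario with targets and gene sets
#'
#' Generates `n_datasets` expression datasets from a shared feature
#' namespace (pairwise panel overlap within `probe_overlap_range`), a
#' miRNA-to-target-gene map and a gene-set collection in which the targets
#' of the cross-dataset shared DE miRNAs are concentrated in a small number
#' of designated true pathways. The scenario ground truth
#' (`true_target_genes`, `true_pathways`) is what the downstream consensus
#' and enrichment stages are expected to recover.
#'
#' @param config A [simulation_config()] with `n_datasets >= 2`.
#' @param n_genes Size of the target-gene universe.
#' @param n_gene_sets Number of gene sets in the collection.
#' @param set_size Genes per set.
#' @param n_true_pathways Number of sets designated as true pathways.
#' @param targets_per_mirna Target genes drawn per miRNA.
#' @param target_purity Probability that a shared-DE miRNA's target is drawn
#'   from the true-pathway gene union rather than the whole universe.
#' @return Object of class `"sim_scenario"`: list with `datasets`, `truths`,
#'   `target_map`, `gene_sets` and `config`.
#' @export
generate_scenario <- function(config, n_genes = 2000, n_gene_sets = 20,
                              set_size = 60, n_true_pathways = 4,
                              targets_per_mirna = 30, target_purity = 0.8) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_datasets < 2) stop("a scenario needs n_datasets >= 2")
  ss <- scenario_structure(config)
  gens <- lapply(seq_len(config$n_datasets), function(i) {
    generate_dataset(config, i)
  })
  datasets <- lapply(gens, `[[`, "dataset")
  truths <- lapply(gens, `[[`, "truth")
  panels <- lapply(datasets, function(d) rownames(d$values))
  for (i in seq_along(panels)) {
    for (j in seq_len(i - 1L)) {
      ov <- length(intersect(panels[[i]], panels[[j]])) /
        min(length(panels[[i]]), length(panels[[j]]))
      if (ov < config$probe_overlap_range[1] - 1e-12 ||
          ov > config$probe_overlap_range[2] + 1e-12) {
        stop("infeasible overlap constraints: realised overlap ", round(ov, 3),
             " outside [", paste(config$probe_overlap_range, collapse = ", "), "]")
      }
    }
  }
  tg <- with_seed(config$seed + 104729L, {
    universe <- sprintf("g%05d", seq_len(n_genes))
    set_names <- sprintf("set%02d", seq_len(n_gene_sets))
    sets <- lapply(set_names, function(nm) sort(sample(universe, set_size)))
    names(sets) <- set_names
    true_pathways <- sort(sample(set_names, n_true_pathways))
    true_union <- sort(unique(unlist(sets[true_pathways])))
    pairs <- lapply(ss$pool, function(mir) {
      enriched <- mir %in% ss$shared_de
      from_true <- enriched &
        (stats::runif(targets_per_mirna) < target_purity)
      genes <- character(targets_per_mirna)
      genes[from_true] <- sample(true_union, sum(from_true), replace = TRUE)
      genes[!from_true] <- sample(universe, sum(!from_true), replace = TRUE)
      unique(genes)
    })
    list(universe = universe, sets = sets, true_pathways = true_pathways,
         map = data.frame(
           mirna_id = rep(ss$pool, lengths(pairs)),
           gene_id = unlist(pairs),
           stringsAsFactors = FALSE))
  })
  map <- target_map(tg$map)
  collection <- gene_set_collection(tg$sets, universe = tg$universe,
                                    label = "synthetic")
  true_target_genes <- sort(unique(
    map$pairs$gene_id[map$pairs$mirna_id %in% ss$shared_de]))
  truths <- lapply(truths, function(tr) {
    tr$true_target_genes <- true_target_genes
    tr$true_pathways <- tg$true_pathways
    tr
  })
  structure(
    list(datasets = datasets, truths = truths, target_map = map,
         gene_sets = collection, config = config,
         shared_de = ss$shared_de),
    class = "sim_scenario"
  )
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Synthetic scenario: ", length(x$datasets), " datasets, ",
      x$config$n_features, " features each; ",
      length(x$shared_de), " shared DE features; ",
      length(x$gene_sets$sets), " gene sets (",
      length(x$truths[[1]]$true_pathways), " true pathways)\n", sep = "")
  invisible(x)
}

#' Generate noisy synthetic target-prediction tables
#'
#' Emulates running several sequence-based target predictors: each table is
#' the reference map with pairs dropped at rate `noise` and an equal
#' expected number of spurious pairs added. Intersecting the tables
#' (see [intersect_predictions()]) recovers a high-precision subset.
#'
#' @param map Reference [target_map()].
#' @param n_predictors Number of tables (>= 2).
#' @param noise Dropout/spurious rate in \[0, 1).
#' @param seed Integer seed.
#' @return List of `n_predictors` target maps.
#' @export
generate_prediction_tables <- function(map, n_predictors, noise, seed = 1) {
  stopifnot(inherits(map, "target_map"))
  if (n_predictors < 2) stop("n_predictors must be >= 2")
  if (!(noise >= 0 && noise < 1)) stop("noise must be in [0, 1)")
  pairs <- map$pairs
  n <- nrow(pairs)
  key <- paste(pairs$mirna_id, pairs$gene_id, sep = "\t")
  mirnas <- unique(pairs$mirna_id)
  genes <- unique(pairs$gene_id)
  lapply(seq_len(n_predictors), function(p) {
    with_seed(seed + p, {
      keep <- stats::runif(n) >= noise
      tab <- pairs[keep, , drop = FALSE]
      n_spur <- round(noise * n)
      if (n_spur > 0) {
        spur <- data.frame(mirna_id = character(0), gene_id = character(0),
                           stringsAsFactors = FALSE)
        while (nrow(spur) < n_spur) {
          cand <- data.frame(
            mirna_id = sample(mirnas, n_spur, replace = TRUE),
            gene_id = sample(genes, n_spur, replace = TRUE),
            stringsAsFactors = FALSE)
          ck <- paste(cand$mirna_id, cand$gene_id, sep = "\t")
          cand <- cand[!(ck %in% key) & !duplicated(ck), , drop = FALSE]
          spur <- unique(rbind(spur, cand))
        }
        tab <- rbind(tab, spur[seq_len(n_spur), , drop = FALSE])
      }
      target_map(tab)
    })
  })
}
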