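# Tests for the synthetic-data generator.

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(de_fraction = 0), "de_fraction")
  expect_error(simulation_config(de_fraction = 1), "de_fraction")
  expect_error(simulation_config(outlier_fraction = 0), "outlier_fraction")
  expect_error(simulation_config(outlier_fraction = 1.2), "outlier_fraction")
  expect_error(simulation_config(noise_sd = 0), "noise_sd")
  expect_error(simulation_config(probe_overlap_range = c(0.6, 0.4)),
               "probe_overlap_range")
  expect_error(simulation_config(n_normal = 1), "at least 2 samples")
  expect_error(simulation_config(n_features = 0), "n_features")
})

test_that("generated datasets honour the truth count invariants", {
  cfg <- simulation_config(n_normal = 10, n_tumor = 13, n_features = 1000,
                           de_fraction = 0.1, outlier_fraction = 0.2,
                           n_datasets = 1, seed = 2)
  g <- generate_dataset(cfg)
  expect_length(g$truth$de_features, 100)          # round(0.1 * 1000)
  k <- max(1, round(0.2 * 13))
  expect_true(all(lengths(g$truth$shifted_samples) == k))
  expect_true(all(unlist(g$truth$shifted_samples) %in% 1:13))
  # tiny pi still shifts at least one sample
  cfg2 <- simulation_config(n_normal = 5, n_tumor = 5, n_features = 50,
                            outlier_fraction = 0.01, n_datasets = 1, seed = 2)
  g2 <- generate_dataset(cfg2)
  expect_true(all(lengths(g2$truth$shifted_samples) == 1))
})

test_that("the same seed reproduces a dataset exactly", {
  cfg <- simulation_config(n_features = 100, seed = 7)
  a <- generate_dataset(cfg, 2)
  b <- generate_dataset(cfg, 2)
  expect_identical(a$dataset$values, b$dataset$values)
  expect_identical(a$truth, b$truth)
  c <- generate_dataset(simulation_config(n_features = 100, seed = 8), 2)
  expect_false(identical(a$dataset$values, c$dataset$values))
})

test_that("scenario panels overlap within the configured range", {
  cfg <- simulation_config(n_features = 300, seed = 4)
  sc <- generate_scenario(cfg)
  panels <- lapply(sc$datasets, function(d) rownames(d$values))
  for (i in seq_along(panels)) {
    for (j in seq_len(i - 1)) {
      ov <- length(intersect(panels[[i]], panels[[j]])) /
        min(length(panels[[i]]), length(panels[[j]]))
      expect_gte(ov, 0.4)
      expect_lte(ov, 0.6)
    }
  }
  # datasets generated standalone agree with their scenario counterparts
  g2 <- generate_dataset(cfg, 2)
  expect_identical(g2$dataset$values, sc$datasets[[2]]$values)
})

test_that("shared_de_fraction = 1 gives identical DE sets across datasets", {
  cfg <- simulation_config(n_features = 200, shared_de_fraction = 1, seed = 9)
  sc <- generate_scenario(cfg)
  de_sets <- lapply(sc$truths, `[[`, "de_features")
  for (s in de_sets) expect_identical(s, de_sets[[1]])
})

test_that("planted pathways beat decoys under the enrichment oracle", {
  sc <- generate_scenario(simulation_config(seed = 6))
  truth <- sc$truths[[1]]
  tab <- enrich(truth$true_target_genes, sc$gene_sets)
  p_true <- tab$p_value[tab$set_name %in% truth$true_pathways]
  p_decoy <- tab$p_value[!(tab$set_name %in% truth$true_pathways)]
  expect_lt(max(p_true), min(p_decoy))
})

test_that("with no shift, truth-DE features are not enriched in selections", {
  hits <- 0
  n_sel_total <- 0
  for (s in 1:20) {
    cfg <- simulation_config(n_normal = 10, n_tumor = 10, n_features = 200,
                             de_fraction = 0.1, shift = 0, n_datasets = 1,
                             seed = 100 + s)
    g <- generate_dataset(cfg)
    sc <- score_all(g$dataset, methods = "ort")
    sel <- select_top_quantile(sc$ort, 0.05)
    hits <- hits + sum(sel$selected %in% g$truth$de_features)
    n_sel_total <- n_sel_total + length(sel$selected)
  }
  # under the null the truth-DE fraction among selections is ~de_fraction;
  # 3 binomial SDs of 200 draws at p = 0.1 is about 0.064
  expect_lt(abs(hits / n_sel_total - 0.1), 0.065)
})

test_that("prediction tables degrade gracefully with noise", {
  sc <- generate_scenario(simulation_config(n_features = 100, seed = 3),
                          n_genes = 300, targets_per_mirna = 10)
  map <- sc$target_map
  expect_error(generate_prediction_tables(map, 1, 0.1), "n_predictors")
  expect_error(generate_prediction_tables(map, 3, 1), "noise")
  clean <- generate_prediction_tables(map, 3, 0, seed = 1)
  for (tm in clean) expect_identical(tm$pairs, map$pairs)
  expect_identical(intersect_predictions(clean)$pairs, map$pairs)

  noisy <- generate_prediction_tables(map, 3, 0.3, seed = 1)
  truth_keys <- paste(map$pairs$mirna_id, map$pairs$gene_id)
  precision <- function(tm) {
    keys <- paste(tm$pairs$mirna_id, tm$pairs$gene_id)
    mean(keys %in% truth_keys)
  }
  inter <- intersect_predictions(noisy)
  expect_gte(precision(inter), max(vapply(noisy, precision, 0)))
})
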