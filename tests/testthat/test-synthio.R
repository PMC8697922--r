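# Synthetic data generator: determinism, planted structure, and the
# sensitivity/specificity contract of the prediction tables.

test_that("config validation names the offending field", {
  expect_error(synth_config(frac_de = 1.5), "frac_de")
  expect_error(synth_config(n_samples_per_condition = 1), "n_samples_per_condition")
  expect_error(synth_config(nb_dispersion = -0.1), "nb_dispersion")
  expect_error(synth_config(pred_sensitivity = 2), "pred_sensitivity")
  expect_error(synth_config(n_mrna = 10.5), "n_mrna")
})

test_that("identical seeds give identical outputs, different seeds differ", {
  cfg <- tiny_config(seed = 11)
  g1 <- generate_counts(cfg)
  g2 <- generate_counts(cfg)
  expect_identical(g1$matrices$mRNA$values, g2$matrices$mRNA$values)
  expect_identical(g1$truth$planted_de, g2$truth$planted_de)
  c1 <- generate_circ_candidates(cfg)
  c2 <- generate_circ_candidates(cfg)
  expect_identical(c1$candidates, c2$candidates)
  p1 <- generate_prediction_tables(g1$truth, cfg)
  p2 <- generate_prediction_tables(g2$truth, cfg)
  expect_identical(p1, p2)

  g3 <- generate_counts(tiny_config(seed = 12))
  expect_false(identical(g1$matrices$mRNA$values, g3$matrices$mRNA$values))
})

test_that("frac_de = 0 plants no DE features", {
  g <- generate_counts(tiny_config(seed = 2, frac_de = 0))
  expect_identical(nrow(g$truth$planted_de), 0L)
})

test_that("noiseless triplets have exact planted correlations on latent means", {
  g <- generate_counts(tiny_config(seed = 3, corr_noise_sd = 0, n_triplets = 4))
  for (lat in g$truth$triplet_latents) {
    expect_identical(cor(rank(lat$miRNA), rank(lat$mRNA)), -1)
    expect_identical(cor(rank(lat$miRNA), rank(lat$ceRNA)), -1)
    expect_equal(cor(lat$ceRNA, lat$mRNA), 1)
  }
})

test_that("every planted id exists in the generated matrices", {
  g <- generate_counts(tiny_config(seed = 4))
  all_ids <- unlist(lapply(g$matrices, function(m) rownames(m$values)))
  expect_true(all(g$truth$planted_de$feature_id %in% all_ids))
  tp <- g$truth$planted_triplets
  expect_true(all(c(tp$ceRNA_id, tp$miRNA_id, tp$mRNA_id) %in% all_ids))
  expect_identical(sort(unname(unlist(g$truth$features))), sort(unname(all_ids)))
})

test_that("planted DE features are up or down in GF_T by the stated magnitude", {
  # with zero dispersion and large counts the empirical condition means
  # reflect the planted means closely
  cfg <- tiny_config(seed = 5, nb_dispersion = 0, frac_de = 0.3,
                     log2fc_magnitude = 2, n_triplets = 0,
                     n_samples_per_condition = 30)
  g <- generate_counts(cfg)
  em <- g$matrices$mRNA
  pl <- g$truth$planted_de[g$truth$planted_de$layer == "mRNA", ]
  mc <- rowMeans(em$values[, em$conditions == "GF_C"])
  mt <- rowMeans(em$values[, em$conditions == "GF_T"])
  lfc <- log2(mt / mc)
  expect_equal(unname(lfc[pl$feature_id[pl$direction == "up"]]),
               rep(2, sum(pl$direction == "up")), tolerance = 0.15)
  expect_equal(unname(lfc[pl$feature_id[pl$direction == "down"]]),
               rep(-2, sum(pl$direction == "down")), tolerance = 0.15)
  nonde <- setdiff(rownames(em$values), pl$feature_id)
  expect_equal(unname(lfc[nonde]), rep(0, length(nonde)), tolerance = 0.15)
})

test_that("circ candidate truth equals per-criterion re-evaluation", {
  res <- generate_circ_candidates(tiny_config(seed = 6, n_circ_candidates = 300))
  oracle <- naive_circ_oracle(res$candidates, 6L)
  for (col in colnames(oracle)) {
    expect_identical(res$circ_truth[[col]], unname(oracle[, col]))
  }
  # both verdicts are exercised for every criterion
  for (col in paste0("crit_", letters[1:7])) {
    expect_true(any(res$circ_truth[[col]]) && any(!res$circ_truth[[col]]),
                info = col)
  }
})

test_that("zero requested circ candidates give an empty list", {
  res <- generate_circ_candidates(tiny_config(seed = 1), n = 0)
  expect_identical(nrow(res$candidates), 0L)
})

test_that("perfect prediction tables equal the true pair set; zero sensitivity empties it", {
  cfg <- tiny_config(seed = 7, pred_sensitivity = 1, pred_specificity = 1)
  g <- generate_counts(cfg)
  preds <- generate_prediction_tables(g$truth, cfg)
  tp <- g$truth$planted_triplets
  true_pairs <- sort(c(paste(tp$miRNA_id, tp$mRNA_id),
                       paste(tp$miRNA_id, tp$ceRNA_id)))
  for (tab in preds) {
    expect_identical(sort(paste(tab$miRNA_id, tab$target_id)), true_pairs)
  }

  cfg0 <- tiny_config(seed = 7, pred_sensitivity = 0, pred_specificity = 0.9)
  p0 <- generate_prediction_tables(generate_counts(cfg0)$truth, cfg0)
  inter <- intersect_predictions(p0)
  expect_false(any(paste(inter$miRNA_id, inter$target_id) %in% true_pairs))
})

test_that("three-way intersection retains true pairs at about sensitivity cubed", {
  sens <- 0.8
  n_trip <- 5L
  survived <- vapply(1:200, function(s) {
    cfg <- tiny_config(seed = s, n_triplets = n_trip, pred_sensitivity = sens,
                       pred_specificity = 1, n_mrna = 30L, n_lncrna = 10L,
                       n_mirna = 10L, n_circrna = 10L)
    g <- generate_counts(cfg)
    preds <- generate_prediction_tables(g$truth, cfg)
    nrow(intersect_predictions(preds))
  }, numeric(1))
  n_true <- 2 * n_trip # one mRNA and one ceRNA pair per triplet
  expected <- n_true * sens^3
  se <- sqrt(n_true * sens^3 * (1 - sens^3) / 200)
  expect_lt(abs(mean(survived) - expected), 4 * se)
})
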