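# Pearson gate, triplet admission, network topology, hubs, and export.

# minimal DE table marking every listed feature as DE
de_stub <- function(ids, layers, directions = "up") {
  data.frame(feature_id = ids, layer = layers,
             log2FC = ifelse(rep_len(directions, length(ids)) == "up", 2, -2),
             p_value = 0.01, fdr = 0.01,
             direction = rep_len(directions, length(ids)),
             is_de = TRUE, group_exclusive = FALSE, filtered = FALSE,
             stringsAsFactors = FALSE)
}

gated_stub <- function(mirna, target) {
  data.frame(miRNA_id = mirna, target_id = target, scc = -1,
             p_value = 0.002, n = 6L, stringsAsFactors = FALSE)
}

# expression over six samples: miRNA rising, targets falling and collinear
triplet_em <- function() {
  x <- rbind(mi1 = c(1, 2, 4, 8, 16, 32),
             ce1 = c(64, 32, 16, 8, 4, 2),
             mr1 = c(32, 16, 8, 4, 2, 1),
             mr2 = c(30, 40, 20, 25, 35, 22))
  colnames(x) <- paste0("GF_", 1:6)
  make_em(x, layer = "mRNA")
}

test_that("pearson matches a hand-computed product-moment coefficient", {
  expect_equal(pearson_test(1:6, 1:6 * 3 + 2)$coefficient, 1)
  expect_equal(pearson_test(1:6, -(1:6))$coefficient, -1)
  x <- 1:6
  y <- c(2, 1, 4, 3, 6, 5)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_test(x, y)$coefficient, manual)
  # t-based p agrees with the standard test
  expect_equal(pearson_test(x, y)$p_value, cor.test(x, y)$p.value)
  expect_error(pearson_test(1:5, rep(1, 5)), "constant")
})

test_that("an admitted triplet yields three nodes and two miRNA-incident edges", {
  de <- de_stub(c("mi1", "ce1", "mr1"), c("miRNA", "lncRNA", "mRNA"),
                c("up", "down", "down"))
  res <- build_network(de, gated_stub("mi1", "mr1"), gated_stub("mi1", "ce1"),
                       list(triplet_em()))
  expect_identical(nrow(res$triplets), 1L)
  expect_equal(res$triplets$pcc_cerna_mrna, 1)
  net <- res$network
  expect_identical(nrow(net$nodes), 3L)
  expect_identical(nrow(net$edges), 2L)
  expect_identical(sort(net$edges$edge_type), c("lncRNA-miRNA", "mRNA-miRNA"))
  # regulation direction is copied from the DE records
  expect_identical(net$nodes$regulation[net$nodes$id == "mi1"], "up")
  expect_identical(net$nodes$regulation[net$nodes$id == "mr1"], "down")
  # every edge touches the miRNA
  expect_true(all(net$edges$to == "mi1"))
})

test_that("triplet admission requires the strict Pearson gate", {
  de <- de_stub(c("mi1", "ce1", "mr1", "mr2"),
                c("miRNA", "lncRNA", "mRNA", "mRNA"))
  em <- triplet_em()
  # a coefficient exactly at the threshold is rejected (strict ">")
  r <- pearson_test(em$values["ce1", ], em$values["mr1", ])
  expect_equal(r$coefficient, 1)
  res <- build_network(de, gated_stub("mi1", "mr1"), gated_stub("mi1", "ce1"),
                       list(em), pcc_threshold = r$coefficient)
  expect_identical(nrow(res$triplets), 0L)
  expect_identical(nrow(res$network$nodes), 0L)
  # an uncorrelated mRNA is not admitted even though its pair is gated
  res2 <- build_network(de, gated_stub(c("mi1", "mi1"), c("mr1", "mr2")),
                        gated_stub("mi1", "ce1"), list(em))
  expect_identical(res2$triplets$mRNA_id, "mr1")
})

test_that("pairs sharing no miRNA and non-DE features produce no network", {
  de <- de_stub(c("mi1", "mi2", "ce1", "mr1"),
                c("miRNA", "miRNA", "lncRNA", "mRNA"))
  res <- build_network(de, gated_stub("mi1", "mr1"), gated_stub("mi2", "ce1"),
                       list(triplet_em()))
  expect_identical(nrow(res$network$edges), 0L)
  # a pair whose member is not DE is excluded and logged
  de2 <- de_stub(c("mi1", "mr1"), c("miRNA", "mRNA"))
  res2 <- build_network(de2, gated_stub("mi1", "mr1"), gated_stub("mi1", "ce1"),
                        list(triplet_em()))
  expect_identical(nrow(res2$triplets), 0L)
  expect_match(attr(res2, "excluded"), "ce1", all = FALSE)
})

test_that("degree sums to twice the edge count and hubs rank deterministically", {
  # star network: one miRNA bound by two ceRNAs and two mRNAs
  de <- de_stub(c("mi1", "ce1", "ce2", "mr1", "mr2"),
                c("miRNA", "lncRNA", "circRNA", "mRNA", "mRNA"))
  x <- rbind(mi1 = c(1, 2, 4, 8, 16, 32),
             ce1 = c(64, 32, 16, 8, 4, 2), ce2 = c(128, 64, 32, 16, 8, 4),
             mr1 = c(32, 16, 8, 4, 2, 1), mr2 = c(16, 8, 4, 2, 1, 0.5))
  colnames(x) <- paste0("GF_", 1:6)
  em <- make_em(x, layer = "mRNA")
  res <- build_network(de, gated_stub(c("mi1", "mi1"), c("mr1", "mr2")),
                       gated_stub(c("mi1", "mi1"), c("ce1", "ce2")), list(em))
  net <- res$network
  expect_identical(sum(net$nodes$degree), 2L * nrow(net$edges))
  hubs <- degree_and_hubs(net, 3)
  expect_identical(hubs$id[1], "mi1")
  expect_identical(hubs$degree[1], 4L)
  # leaves tie at degree 1: lexicographically smaller id first
  expect_identical(hubs$id[2:3], c("ce1", "ce2"))
  expect_identical(nrow(degree_and_hubs(net, 0)), 0L)
  expect_error(degree_and_hubs(net, -1), "nonnegative")
  # no edge ever joins an mRNA to a ceRNA
  types <- stats::setNames(net$nodes$type, net$nodes$id)
  expect_true(all(types[net$edges$from] != "miRNA" &
                    types[net$edges$to] == "miRNA"))
})

test_that("network export round-trips through GraphML and SIF", {
  de <- de_stub(c("mi1", "ce1", "mr1"), c("miRNA", "circRNA", "mRNA"))
  res <- build_network(de, gated_stub("mi1", "mr1"), gated_stub("mi1", "ce1"),
                       list(triplet_em()))
  gml <- withr::local_tempfile(fileext = ".graphml")
  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(res$network, gml, "graphml")
  export_network(res$network, sif, "sif")
  back <- import_network(gml, "graphml")
  expect_identical(nrow(back$nodes), nrow(res$network$nodes))
  expect_identical(back$edges, res$network$edges)
  expect_identical(back$nodes$regulation, res$network$nodes$regulation)
  back_sif <- import_network(sif, "sif")
  expect_identical(nrow(back_sif$edges), nrow(res$network$edges))
  expect_identical(sort(back_sif$nodes$id), sort(res$network$nodes$id))
  # two SIF lines for a single-triplet network
  expect_identical(length(readLines(sif)), 2L)
  # empty network exports valid empty documents
  empty <- build_network(de_stub("mi1", "miRNA"), gated_stub("mi1", "mr1")[0, ],
                         gated_stub("mi1", "ce1")[0, ], list(triplet_em()))
  export_network(empty$network, gml, "graphml")
  expect_identical(nrow(import_network(gml, "graphml")$nodes), 0L)
  export_network(empty$network, sif, "sif")
  expect_identical(nrow(import_network(sif, "sif")$edges), 0L)
})

test_that("removing a gated pair never adds edges", {
  cfg <- tiny_config(seed = 14, corr_noise_sd = 0.05, nb_dispersion = 0.02,
                     n_triplets = 4, pred_sensitivity = 1, pred_specificity = 1)
  g <- generate_counts(cfg)
  normed <- lapply(g$matrices, normalize_layer)
  de_all <- do.call(rbind, c(lapply(g$matrices, call_de),
                             list(make.row.names = FALSE)))
  preds <- generate_prediction_tables(g$truth, cfg)
  inter <- intersect_predictions(preds)
  mm <- select_negative_pairs(inter, normed)
  cm <- select_negative_pairs(inter, normed) # prediction-restricted arm
  full <- build_network(de_all, mm, cm, normed)
  if (nrow(mm) > 1) {
    sub <- build_network(de_all, mm[-1, ], cm, normed)
    key <- function(net) paste(net$edges$from, net$edges$to)
    expect_true(all(key(sub$network) %in% key(full$network)))
  }
  expect_identical(sum(full$network$nodes$degree), 2L * nrow(full$network$edges))
})
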