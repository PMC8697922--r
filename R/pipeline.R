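# End-to-end orchestration: config validation with the published default
# thresholds, stage-by-stage execution, per-stage TSV artifacts, and a
# machine-readable run report.

.pipeline_defaults <- function() {
  list(
    synthetic = TRUE,
    seed = 1L,
    out_dir = NULL,
    synth = list(),
    input = list(),
    log2fc_threshold = 1,
    fdr_alpha = 0.05,
    p_alpha = 0.05,
    scc_threshold = -0.7,
    pcc_threshold = 0.9,
    enrich_alpha = 0.05,
    circ_thresholds = circ_filter_defaults(),
    require_predictions_for_cerna = FALSE,
    layers = c("mRNA", "lncRNA", "miRNA", "circRNA")
  )
}

#' Build a pipeline configuration
#'
#' All thresholds default to the published constants: |log2FC| > 1,
#' FDR < 0.05 (mRNA/lncRNA), p < 0.05 (miRNA/circRNA), Spearman gate
#' < -0.7, Pearson gate > 0.9, corrected enrichment p < 0.05, and the seven
#' circRNA filter constants of [circ_filter_defaults()].
#'
#' @param ... named overrides of the defaults (see [validate_config()] for
#'   the accepted keys and ranges).
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  validate_config(list(...))
}

#' Validate and normalise a pipeline configuration
#'
#' Fills defaults, rejects out-of-range thresholds, and (in strict mode)
#' rejects unknown keys. The normalised config is echoed into the run
#' report for provenance.
#'
#' @param config named list of overrides, or a path to a YAML file holding
#'   one.
#' @param strict reject unknown keys (`TRUE`, default) or warn (`FALSE`).
#' @return a `pipeline_config` list with every key present.
#' @export
validate_config <- function(config = list(), strict = TRUE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  defaults <- .pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    msg <- sprintf("unknown config key(s): %s", paste(unknown, collapse = ", "))
    if (strict) stopf("%s", msg) else warnf("%s", msg)
    config <- config[setdiff(names(config), unknown)]
  }
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (!is.logical(cfg$synthetic) || length(cfg$synthetic) != 1L) {
    stopf("synthetic must be a single logical")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || !is.finite(cfg$seed)) {
    stopf("seed must be a finite number")
  }
  if (!is_nonneg1(cfg$log2fc_threshold)) {
    stopf("log2fc_threshold must be a nonnegative scalar")
  }
  for (key in c("fdr_alpha", "p_alpha", "enrich_alpha")) {
    if (!is_frac1(cfg[[key]]) || cfg[[key]] <= 0) {
      stopf("%s must lie in (0, 1]", key)
    }
  }
  if (!is.numeric(cfg$scc_threshold) || cfg$scc_threshold >= 0 ||
      cfg$scc_threshold < -1) {
    stopf("scc_threshold must lie in [-1, 0)")
  }
  if (!is.numeric(cfg$pcc_threshold) || cfg$pcc_threshold <= 0 ||
      cfg$pcc_threshold > 1) {
    stopf("pcc_threshold must lie in (0, 1]")
  }
  if (!all(cfg$layers %in% .layers)) {
    stopf("layers must be a subset of: %s", paste(.layers, collapse = ", "))
  }
  if (!is.logical(cfg$require_predictions_for_cerna)) {
    stopf("require_predictions_for_cerna must be logical")
  }
  structure(cfg, class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full ceRNA-network inference pipeline
#'
#' Executes, in order: data acquisition (synthetic generation or file
#' input), layer normalisation, differential expression per layer, circRNA
#' candidate filtering, prediction intersection and Spearman gating of
#' miRNA-target pairs, ceRNA network assembly, and term enrichment of the
#' DE mRNAs. Writes per-stage TSVs, BED, GraphML/SIF and a JSON run report
#' under `config$out_dir` when set. The run is fully deterministic:
#' identical config (including seed) gives identical artifacts and report.
#'
#' In synthetic mode the generator seed is the pipeline seed and annotation
#' sets are generated over the mRNA universe. In file mode `config$input`
#' must name TSV paths: `counts` (named list per layer, written by
#' [write_expression_tsv()]), `circ_candidates`, `predictions` (three
#' paths), and optionally `annotation` (GMT).
#'
#' @param config a `pipeline_config` (or named list / YAML path accepted by
#'   [validate_config()]).
#' @return a `crn_report` list: normalised config echo plus per-stage
#'   counts (features and DE per layer, circRNA candidates and passes,
#'   pairs at each gate, triplets admitted, network nodes/edges by type,
#'   significant terms, and in synthetic mode planted-triplet recovery).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  save_tsv <- function(df, name) {
    if (!is.null(out_dir)) {
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }

  truth <- NULL
  annotation <- NULL
  if (isTRUE(config$synthetic)) {
    acq <- .stage("synthio", {
      scfg <- do.call(synth_config,
                      utils::modifyList(config$synth,
                                        list(seed = config$seed)))
      gen <- generate_counts(scfg)
      circ <- generate_circ_candidates(scfg)
      preds <- generate_prediction_tables(gen$truth, scfg)
      ann <- generate_annotation_sets(gen$truth$features$mRNA,
                                      seed = scfg$seed)
      list(matrices = gen$matrices, truth = gen$truth,
           candidates = circ$candidates, predictions = preds,
           annotation = ann)
    })
    truth <- acq$truth
  } else {
    acq <- .stage("input", {
      paths <- config$input
      need <- c("counts", "circ_candidates", "predictions")
      miss <- setdiff(need, names(paths))
      if (length(miss)) stopf("missing input path(s): %s", paste(miss, collapse = ", "))
      mats <- lapply(paths$counts, function(p) {
        if (!file.exists(p)) stopf("counts file not found: %s", p)
        read_expression_tsv(p)
      })
      names(mats) <- vapply(mats, function(m) m$layer, "")
      if (!file.exists(paths$circ_candidates)) {
        stopf("circ candidate file not found: %s", paths$circ_candidates)
      }
      cand <- utils::read.delim(paths$circ_candidates, check.names = FALSE)
      preds <- lapply(paths$predictions, function(p) {
        if (!file.exists(p)) stopf("prediction table not found: %s", p)
        utils::read.delim(p)
      })
      ann <- if (!is.null(paths$annotation)) read_gmt(paths$annotation)
      list(matrices = mats, truth = NULL, candidates = cand,
           predictions = preds, annotation = ann)
    })
  }
  matrices <- acq$matrices[intersect(.layers, names(acq$matrices))]
  matrices <- matrices[names(matrices) %in% config$layers]
  annotation <- acq$annotation

  normed <- .stage("quantnorm", lapply(matrices, normalize_layer))
  if (!is.null(out_dir)) {
    for (ly in names(normed)) {
      write_expression_tsv(normed[[ly]],
                           file.path(out_dir, sprintf("norm_%s.tsv", ly)))
    }
  }

  de <- .stage("diffexpr", {
    lapply(matrices, function(em) {
      call_de(em, lfc = config$log2fc_threshold,
              fdr_alpha = config$fdr_alpha, p_alpha = config$p_alpha)
    })
  })
  de_all <- do.call(rbind, c(de, list(make.row.names = FALSE)))
  save_tsv(de_all, "de_records.tsv")

  n_samples <- ncol(matrices[[1L]]$values)
  circ <- .stage("circfilter", {
    verdicts <- apply_filters(acq$candidates, n_samples,
                              thresholds = config$circ_thresholds)
    list(verdicts = verdicts)
  })
  save_tsv(circ$verdicts, "circ_verdicts.tsv")
  if (!is.null(out_dir)) {
    write_circ_bed(acq$candidates, circ$verdicts,
                   file.path(out_dir, "circ_pass.bed"))
  }

  de_ids <- function(layers) {
    de_all$feature_id[de_all$is_de & de_all$layer %in% layers]
  }
  pairs <- .stage("targetlink", {
    inter <- intersect_predictions(acq$predictions)
    # the mRNA arm requires prediction support; restrict to DE features
    mm_cand <- inter[inter$miRNA_id %in% de_ids("miRNA") &
                       inter$target_id %in% de_ids("mRNA"), , drop = FALSE]
    mm <- select_negative_pairs(mm_cand, normed,
                                scc_threshold = config$scc_threshold,
                                p_threshold = config$p_alpha)
    cm_cand <- candidate_cerna_pairs(
      de_ids(c("lncRNA", "circRNA")), de_ids("miRNA"),
      predictions = if (config$require_predictions_for_cerna) inter
    )
    cm <- select_negative_pairs(cm_cand, normed,
                                scc_threshold = config$scc_threshold,
                                p_threshold = config$p_alpha)
    list(intersected = inter, mirna_mrna = mm, cerna_mirna = cm)
  })
  save_tsv(pairs$mirna_mrna, "pairs_mirna_mrna.tsv")
  save_tsv(pairs$cerna_mirna, "pairs_cerna_mirna.tsv")

  net <- .stage("cernanet", {
    build_network(de_all, pairs$mirna_mrna, pairs$cerna_mirna, normed,
                  pcc_threshold = config$pcc_threshold,
                  p_threshold = config$p_alpha)
  })
  save_tsv(net$triplets, "triplets.tsv")
  if (!is.null(out_dir)) {
    export_network(net$network, file.path(out_dir, "network.graphml"), "graphml")
    export_network(net$network, file.path(out_dir, "network.sif"), "sif")
  }

  enr <- .stage("enrich", {
    if (is.null(annotation) || !"mRNA" %in% names(matrices)) {
      NULL
    } else {
      study <- de_ids("mRNA")
      population <- rownames(matrices$mRNA$values)
      if (!length(study)) NULL else {
        hypergeom_enrich(study, population, annotation,
                         alpha = config$enrich_alpha)
      }
    }
  })
  if (!is.null(enr)) save_tsv(enr, "enrichment.tsv")

  de_summary <- lapply(de, function(d) {
    list(n_features = nrow(d),
         n_de = sum(d$is_de),
         n_up = sum(d$is_de & d$direction %in% "up"),
         n_down = sum(d$is_de & d$direction %in% "down"),
         n_group_exclusive = sum(d$group_exclusive & d$is_de))
  })
  recovery <- NULL
  if (!is.null(truth) && nrow(truth$planted_triplets)) {
    key <- function(df) paste(df$ceRNA_id, df$miRNA_id, df$mRNA_id)
    tp <- length(intersect(key(net$triplets), key(truth$planted_triplets)))
    recovery <- list(
      planted = nrow(truth$planted_triplets),
      admitted = nrow(net$triplets),
      true_positives = tp,
      recall = tp / nrow(truth$planted_triplets),
      precision = if (nrow(net$triplets)) tp / nrow(net$triplets) else NA
    )
  }
  report <- structure(list(
    config = unclass(config)[setdiff(names(config), "out_dir")],
    samples = n_samples,
    de = de_summary,
    circ = list(n_candidates = nrow(acq$candidates),
                n_pass = sum(circ$verdicts$pass)),
    pairs = list(n_intersected = nrow(pairs$intersected),
                 n_mirna_mrna_gated = nrow(pairs$mirna_mrna),
                 n_cerna_mirna_gated = nrow(pairs$cerna_mirna)),
    network = list(
      n_triplets = nrow(net$triplets),
      n_nodes = nrow(net$network$nodes),
      n_edges = nrow(net$network$edges),
      nodes_by_type = as.list(table(net$network$nodes$type)),
      edges_by_type = as.list(table(net$network$edges$edge_type))
    ),
    enrichment = list(
      n_terms = if (is.null(enr)) 0L else nrow(enr),
      n_significant = if (is.null(enr)) 0L else sum(enr$significant)
    ),
    triplet_recovery = recovery
  ), class = "crn_report")
  if (!is.null(out_dir)) {
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  report
}

#' @export
print.crn_report <- function(x, ...) {
  cat("ceRNA pipeline run report\n")
  for (ly in names(x$de)) {
    d <- x$de[[ly]]
    cat(sprintf("  %-8s %5d features, %4d DE (%d up / %d down)\n",
                ly, d$n_features, d$n_de, d$n_up, d$n_down))
  }
  cat(sprintf("  circRNA candidates: %d, passing filters: %d\n",
              x$circ$n_candidates, x$circ$n_pass))
  cat(sprintf("  pairs: %d intersected, %d mRNA-miRNA gated, %d ceRNA-miRNA gated\n",
              x$pairs$n_intersected, x$pairs$n_mirna_mrna_gated,
              x$pairs$n_cerna_mirna_gated))
  cat(sprintf("  network: %d triplets, %d nodes, %d edges\n",
              x$network$n_triplets, x$network$n_nodes, x$network$n_edges))
  cat(sprintf("  enrichment: %d significant of %d terms\n",
              x$enrichment$n_significant, x$enrichment$n_terms))
  if (!is.null(x$triplet_recovery)) {
    cat(sprintf("  planted triplets: %d, recovered: %d (recall %.2f, precision %s)\n",
                x$triplet_recovery$planted, x$triplet_recovery$true_positives,
                x$triplet_recovery$recall,
                format(x$triplet_recovery$precision, digits = 3)))
  }
  invisible(x)
}
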