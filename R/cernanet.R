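# ceRNA network assembly: Pearson-gated triplet admission, typed nodes and
# miRNA-incident edges, degree/hub analysis, GraphML and SIF export.

.cerna_network <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "cerna_network")
}

.empty_network <- function() {
  .cerna_network(
    nodes = data.frame(id = character(), type = character(),
                       regulation = character(), degree = integer(),
                       stringsAsFactors = FALSE),
    edges = data.frame(from = character(), to = character(),
                       edge_type = character(), stringsAsFactors = FALSE)
  )
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf("cerna_network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$nodes)) print(table(x$nodes$type))
  if (nrow(x$edges)) print(table(x$edges$edge_type))
  invisible(x)
}

#' Assemble the lncRNA/circRNA-miRNA-mRNA ceRNA network
#'
#' For every ceRNA-miRNA pair and mRNA-miRNA pair sharing a miRNA (both
#' already gated by negative Spearman coexpression), the triplet is admitted
#' iff the Pearson correlation between the ceRNA and the mRNA is strictly
#' above `pcc_threshold` with p strictly below `p_threshold`: the two
#' sponged targets of a shared miRNA must co-vary positively. All features
#' must be DE in their layer; pairs involving non-DE features are excluded
#' and listed in the `"excluded"` attribute of the triplet table. The
#' network renders only miRNA-incident edges (ceRNA-miRNA and mRNA-miRNA,
#' deduplicated across triplets); the ceRNA-mRNA correlation is an attribute
#' of the triplet, not an edge.
#'
#' @param de_records data.frame of DE calls over all layers (rbind of
#'   [call_de()] outputs).
#' @param mirna_mrna_pairs gated mRNA-miRNA pairs from
#'   [select_negative_pairs()] (columns `miRNA_id`, `target_id` = mRNA).
#' @param cerna_mirna_pairs gated ceRNA-miRNA pairs (target = lncRNA or
#'   circRNA id).
#' @param expr list of [expression_matrix()] objects covering all features.
#' @param pcc_threshold Pearson gate (default 0.9, strict ">").
#' @param p_threshold p-value gate (default 0.05, strict "<").
#' @param pearson_permutation use the exact permutation p-value for the
#'   Pearson gate at small n (default `FALSE`: t approximation).
#' @return list with `triplets` (one row per admitted triplet with all
#'   three coefficients and p-values) and `network` (a `cerna_network`).
#' @export
build_network <- function(de_records, mirna_mrna_pairs, cerna_mirna_pairs,
                          expr, pcc_threshold = 0.9, p_threshold = 0.05,
                          pearson_permutation = FALSE) {
  if (!is.numeric(pcc_threshold) || pcc_threshold <= 0 || pcc_threshold > 1) {
    stopf("pcc_threshold must lie in (0, 1]")
  }
  de <- de_records[de_records$is_de %in% TRUE, , drop = FALSE]
  de_layer <- stats::setNames(de$layer, de$feature_id)
  de_dir <- stats::setNames(de$direction, de$feature_id)

  filter_de <- function(pairs, what) {
    ok <- pairs$miRNA_id %in% names(de_layer) &
      pairs$target_id %in% names(de_layer)
    attr_excl <- if (any(!ok)) {
      sprintf("%s: %s~%s not DE", what, pairs$miRNA_id[!ok], pairs$target_id[!ok])
    } else {
      character()
    }
    list(pairs = pairs[ok, , drop = FALSE], excluded = attr_excl)
  }
  mm <- filter_de(mirna_mrna_pairs, "mRNA-miRNA")
  cm <- filter_de(cerna_mirna_pairs, "ceRNA-miRNA")
  excluded <- c(mm$excluded, cm$excluded)

  lookup <- .expr_lookup(expr)
  triplets <- list()
  shared <- sort(intersect(mm$pairs$miRNA_id, cm$pairs$miRNA_id))
  for (mi in shared) {
    mrnas <- mm$pairs[mm$pairs$miRNA_id == mi, , drop = FALSE]
    cernas <- cm$pairs[cm$pairs$miRNA_id == mi, , drop = FALSE]
    for (i in seq_len(nrow(cernas))) {
      for (j in seq_len(nrow(mrnas))) {
        cid <- cernas$target_id[i]
        mid <- mrnas$target_id[j]
        if (!exists(cid, envir = lookup, inherits = FALSE) ||
            !exists(mid, envir = lookup, inherits = FALSE)) {
          excluded <- c(excluded,
                        sprintf("ceRNA-mRNA: %s~%s missing expression", cid, mid))
          next
        }
        pcc <- tryCatch(
          pearson_test(get(cid, envir = lookup), get(mid, envir = lookup),
                       id_a = cid, id_b = mid,
                       permutation = pearson_permutation),
          error = function(e) NULL
        )
        if (is.null(pcc)) next
        if (pcc$coefficient > pcc_threshold && pcc$p_value < p_threshold) {
          triplets[[length(triplets) + 1L]] <- data.frame(
            ceRNA_id = cid, ceRNA_layer = unname(de_layer[cid]),
            miRNA_id = mi, mRNA_id = mid,
            scc_cerna_mirna = cernas$scc[i], scc_cerna_mirna_p = cernas$p_value[i],
            scc_mrna_mirna = mrnas$scc[j], scc_mrna_mirna_p = mrnas$p_value[j],
            pcc_cerna_mrna = pcc$coefficient, pcc_cerna_mrna_p = pcc$p_value,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  triplets <- if (length(triplets)) {
    do.call(rbind, c(triplets, list(make.row.names = FALSE)))
  } else {
    data.frame(ceRNA_id = character(), ceRNA_layer = character(),
               miRNA_id = character(), mRNA_id = character(),
               scc_cerna_mirna = numeric(), scc_cerna_mirna_p = numeric(),
               scc_mrna_mirna = numeric(), scc_mrna_mirna_p = numeric(),
               pcc_cerna_mrna = numeric(), pcc_cerna_mrna_p = numeric(),
               stringsAsFactors = FALSE)
  }

  network <- if (nrow(triplets) == 0L) {
    .empty_network()
  } else {
    edges <- unique(rbind(
      data.frame(from = triplets$ceRNA_id, to = triplets$miRNA_id,
                 edge_type = paste0(triplets$ceRNA_layer, "-miRNA"),
                 stringsAsFactors = FALSE),
      data.frame(from = triplets$mRNA_id, to = triplets$miRNA_id,
                 edge_type = "mRNA-miRNA", stringsAsFactors = FALSE)
    ))
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
    ids <- sort(unique(c(edges$from, edges$to)))
    deg <- table(c(edges$from, edges$to))
    nodes <- data.frame(
      id = ids,
      type = ifelse(ids %in% triplets$miRNA_id, "miRNA",
                    ifelse(ids %in% triplets$mRNA_id, "mRNA",
                           unname(de_layer[ids]))),
      regulation = unname(de_dir[ids]),
      degree = as.integer(deg[ids]),
      stringsAsFactors = FALSE
    )
    rownames(nodes) <- NULL
    .cerna_network(nodes, edges)
  }
  out <- list(triplets = triplets, network = network)
  attr(out, "excluded") <- excluded
  out
}

#' Node degrees and hub ranking
#'
#' Degree is the number of incident edges. Hubs are the top `k` nodes by
#' degree; ties are broken by lexicographic node id, making the ranking
#' deterministic.
#'
#' @param network a `cerna_network`.
#' @param k number of hubs to return (>= 0).
#' @return data.frame of the top-`k` nodes (`id`, `type`, `degree`) in rank
#'   order.
#' @export
degree_and_hubs <- function(network, k) {
  stopifnot(inherits(network, "cerna_network"))
  if (!is_count1(k)) stopf("k must be a nonnegative integer")
  if (k == 0L) {
    return(data.frame(id = character(), type = character(),
                      degree = integer(), stringsAsFactors = FALSE))
  }
  if (nrow(network$nodes) == 0L) stopf("network is empty")
  nd <- network$nodes[order(-network$nodes$degree, network$nodes$id), , drop = FALSE]
  out <- nd[seq_len(min(k, nrow(nd))), c("id", "type", "degree"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert a ceRNA network to an igraph object
#'
#' @param network a `cerna_network`.
#' @return an undirected [igraph::graph] with vertex attributes `type`,
#'   `regulation`, `degree` and edge attribute `edge_type`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "cerna_network"))
  g <- igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = network$nodes[, c("id", "type", "regulation", "degree")]
  )
  g
}

#' Export a ceRNA network for visualisation
#'
#' GraphML (via igraph) carries node attributes (type, regulation, degree)
#' and the edge type; SIF writes one `source edge_type target` line per edge
#' (the standard Cytoscape import format). An empty network yields a valid
#' empty document.
#'
#' @param network a `cerna_network`.
#' @param path output file path.
#' @param format `"graphml"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "sif")) {
  stopifnot(inherits(network, "cerna_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  } else {
    lines <- if (nrow(network$edges)) {
      sprintf("%s\t%s\t%s", network$edges$from, network$edges$edge_type,
              network$edges$to)
    } else {
      character()
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a ceRNA network back from an exported file
#'
#' Round-trips [export_network()] output. SIF carries no node attributes,
#' so `regulation` is NA after a SIF round trip; degrees are recomputed.
#'
#' @param path file path.
#' @param format `"graphml"` or `"sif"`.
#' @return a `cerna_network`.
#' @export
import_network <- function(path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (igraph::vcount(g) == 0L) return(.empty_network())
    nodes <- data.frame(
      id = igraph::vertex_attr(g, "name"),
      type = igraph::vertex_attr(g, "type"),
      regulation = igraph::vertex_attr(g, "regulation"),
      stringsAsFactors = FALSE
    )
    el <- igraph::as_edgelist(g)
    edges <- data.frame(from = el[, 1L], to = el[, 2L],
                        edge_type = igraph::edge_attr(g, "edge_type"),
                        stringsAsFactors = FALSE)
    # igraph does not preserve endpoint order of undirected edges; restore
    # the miRNA-incident convention (miRNA is the "to" endpoint)
    type_of <- stats::setNames(nodes$type, nodes$id)
    flip <- !is.na(type_of[edges$to]) & type_of[edges$to] != "miRNA" &
      type_of[edges$from] %in% "miRNA"
    if (any(flip)) {
      tmp <- edges$from[flip]
      edges$from[flip] <- edges$to[flip]
      edges$to[flip] <- tmp
    }
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(.empty_network())
    parts <- strsplit(lines, "\t", fixed = TRUE)
    edges <- data.frame(
      from = vapply(parts, `[`, "", 1L),
      edge_type = vapply(parts, `[`, "", 2L),
      to = vapply(parts, `[`, "", 3L),
      stringsAsFactors = FALSE
    )[, c("from", "to", "edge_type")]
    ids <- sort(unique(c(edges$from, edges$to)))
    nodes <- data.frame(id = ids, type = NA_character_,
                        regulation = NA_character_, stringsAsFactors = FALSE)
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  deg <- table(c(edges$from, edges$to))
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  nodes$degree <- as.integer(deg[nodes$id])
  nodes$degree[is.na(nodes$degree)] <- 0L
  rownames(nodes) <- NULL
  .cerna_network(nodes, edges)
}
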