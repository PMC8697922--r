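# miRNA-target pairing: three-way prediction intersection, then gating by
# negative Spearman coexpression.

.norm_pairs <- function(tab, what) {
  if (!is.data.frame(tab) || !all(c("miRNA_id", "target_id") %in% names(tab))) {
    stopf("%s must be a data.frame with columns miRNA_id, target_id", what)
  }
  unique(data.frame(miRNA_id = as.character(tab$miRNA_id),
                    target_id = as.character(tab$target_id),
                    stringsAsFactors = FALSE))
}

#' Intersect three target-prediction tables
#'
#' A pair is retained only when predicted by all three sources; the
#' intersection of independent prediction tools is the conventional
#' high-credibility target set.
#'
#' @param tables list of exactly three data.frames, each with columns
#'   `miRNA_id` and `target_id` (duplicates within a source are ignored).
#' @return data.frame of the pairs present in all three tables, with
#'   `n_sources = 3`, ordered by miRNA then target id.
#' @export
intersect_predictions <- function(tables) {
  if (!is.list(tables) || length(tables) != 3L) {
    stopf("exactly three prediction tables are required (got %d)",
          if (is.list(tables)) length(tables) else 1L)
  }
  keys <- lapply(seq_along(tables), function(i) {
    tab <- .norm_pairs(tables[[i]], sprintf("prediction table %d", i))
    paste(tab$miRNA_id, tab$target_id, sep = "\r")
  })
  common <- Reduce(intersect, keys)
  common <- sort(common)
  parts <- strsplit(common, "\r", fixed = TRUE)
  data.frame(
    miRNA_id = vapply(parts, `[`, "", 1L),
    target_id = vapply(parts, `[`, "", 2L),
    n_sources = if (length(parts)) 3L else integer(),
    stringsAsFactors = FALSE
  )
}

# feature -> expression profile lookup across a list of expression matrices;
# all matrices must share the same sample columns
.expr_lookup <- function(expr) {
  if (inherits(expr, "expression_matrix")) expr <- list(expr)
  stopifnot(length(expr) >= 1L)
  cols <- colnames(expr[[1L]]$values)
  env <- new.env(parent = emptyenv())
  for (em in expr) {
    stopifnot(inherits(em, "expression_matrix"))
    if (!identical(colnames(em$values), cols)) {
      stopf("expression matrices must share identical sample columns")
    }
    v <- em$values
    for (i in seq_len(nrow(v))) assign(rownames(v)[i], v[i, ], envir = env)
  }
  env
}

#' Gate candidate pairs by negative Spearman coexpression
#'
#' For each (miRNA, target) pair, computes the Spearman correlation of the
#' two expression profiles across all samples and keeps the pair iff the
#' coefficient is strictly below `scc_threshold` and the two-sided p-value
#' is strictly below `p_threshold` (exact permutation p for small n, see
#' [spearman_test()]). Pairs whose members are missing from the expression
#' matrices, or whose profiles are constant, are skipped and reported in the
#' `"skipped"` attribute.
#'
#' @param pairs data.frame with columns `miRNA_id`, `target_id`.
#' @param expr list of [expression_matrix()] objects covering the features
#'   (typically the normalised matrices of the involved layers).
#' @param scc_threshold Spearman gate (default -0.7, strict "<").
#' @param p_threshold p-value gate (default 0.05, strict "<").
#' @return data.frame of retained pairs with `scc`, `p_value`, `n`;
#'   attribute `"skipped"` lists pairs that could not be evaluated.
#' @export
select_negative_pairs <- function(pairs, expr, scc_threshold = -0.7,
                                  p_threshold = 0.05) {
  pairs <- .norm_pairs(pairs, "pairs")
  if (!is_frac1(p_threshold) || p_threshold <= 0) {
    stopf("p_threshold must be in (0, 1]")
  }
  if (!is.numeric(scc_threshold) || scc_threshold >= 0 || scc_threshold < -1) {
    stopf("scc_threshold must lie in [-1, 0)")
  }
  lookup <- .expr_lookup(expr)
  keep <- logical(nrow(pairs))
  scc <- p <- rep(NA_real_, nrow(pairs))
  nvec <- rep(NA_integer_, nrow(pairs))
  skipped <- character()
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$miRNA_id[i]
    b <- pairs$target_id[i]
    xa <- if (exists(a, envir = lookup, inherits = FALSE)) get(a, envir = lookup)
    xb <- if (exists(b, envir = lookup, inherits = FALSE)) get(b, envir = lookup)
    if (is.null(xa) || is.null(xb)) {
      skipped <- c(skipped, sprintf("%s~%s: feature missing from expression", a, b))
      next
    }
    res <- tryCatch(spearman_test(xa, xb, id_a = a, id_b = b),
                    error = function(e) NULL)
    if (is.null(res)) {
      skipped <- c(skipped, sprintf("%s~%s: correlation undefined", a, b))
      next
    }
    scc[i] <- res$coefficient
    p[i] <- res$p_value
    nvec[i] <- res$n
    keep[i] <- res$coefficient < scc_threshold && res$p_value < p_threshold
  }
  out <- data.frame(miRNA_id = pairs$miRNA_id, target_id = pairs$target_id,
                    scc = scc, p_value = p, n = nvec,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Candidate ceRNA-miRNA pairs from differential-expression calls
#'
#' The ceRNA arms of the network (lncRNA-miRNA, circRNA-miRNA) are gated by
#' coexpression alone; candidates are all crossings of DE ceRNAs with DE
#' miRNAs, optionally restricted to pairs with prediction support when a
#' prediction table is supplied.
#'
#' @param cerna_ids,mirna_ids character vectors of DE ceRNA and DE miRNA
#'   feature ids.
#' @param predictions optional data.frame (`miRNA_id`, `target_id`): when
#'   given, only crossings present in it are kept.
#' @return data.frame with columns `miRNA_id`, `target_id`.
#' @export
candidate_cerna_pairs <- function(cerna_ids, mirna_ids, predictions = NULL) {
  grid <- expand.grid(miRNA_id = as.character(mirna_ids),
                      target_id = as.character(cerna_ids),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  if (!is.null(predictions)) {
    pred <- .norm_pairs(predictions, "predictions")
    grid <- grid[paste(grid$miRNA_id, grid$target_id) %in%
                   paste(pred$miRNA_id, pred$target_id), , drop = FALSE]
  }
  grid <- grid[order(grid$miRNA_id, grid$target_id), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}
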