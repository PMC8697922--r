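# Hypergeometric term enrichment of gene sets against GMT annotation.

#' Read / write gene-set annotation in GMT format
#'
#' GMT is tab-separated with one term per line: term id, description, then
#' member gene ids. The reader keeps the description column (many generic
#' GMT readers drop it).
#'
#' @param path file path.
#' @return `read_gmt` returns an `annotation_sets` object: list with `sets`
#'   (named list of member id vectors) and `descriptions` (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stopf("GMT line(s) with fewer than 3 fields: %s",
                         paste(bad, collapse = ", "))
  ids <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(ids)) stopf("duplicate term ids in GMT")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  if (any(lengths(sets) == 0L)) stopf("GMT term(s) with no members")
  names(sets) <- ids
  structure(
    list(sets = sets,
         descriptions = stats::setNames(vapply(parts, `[`, "", 2L), ids)),
    class = "annotation_sets"
  )
}

#' @rdname read_gmt
#' @param annotation an `annotation_sets` object.
#' @export
write_gmt <- function(annotation, path) {
  stopifnot(inherits(annotation, "annotation_sets"))
  ids <- names(annotation$sets)
  lines <- vapply(ids, function(id) {
    paste(c(id, annotation$descriptions[[id]], annotation$sets[[id]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric term enrichment
#'
#' For each annotation term, tests over-representation of the study set by
#' the upper hypergeometric tail: with `N` population genes of which `K`
#' carry the term, and `n` study genes of which `k` carry it,
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. P-values are BH
#' corrected across terms; a term is significant iff the corrected p is
#' strictly below `alpha`. Term memberships are intersected with the
#' population before counting.
#'
#' @param study character vector of study gene ids (nonempty, must be a
#'   subset of `population`).
#' @param population character vector of background gene ids.
#' @param annotation an `annotation_sets` object.
#' @param alpha significance cutoff on the corrected p (default 0.05).
#' @return data.frame ranked by corrected p then term id: `term_id`,
#'   `term_name`, `k`, `K`, `n`, `N`, `p_value`, `corrected_p`,
#'   `significant`.
#' @examples
#' ann <- structure(list(sets = list(T1 = letters[1:5]),
#'                       descriptions = c(T1 = "demo")),
#'                  class = "annotation_sets")
#' hypergeom_enrich(letters[1:5], letters[1:20], ann)
#' @export
hypergeom_enrich <- function(study, population, annotation, alpha = 0.05) {
  stopifnot(inherits(annotation, "annotation_sets"))
  study <- unique(as.character(study))
  population <- unique(as.character(population))
  if (!length(study)) stopf("study set is empty")
  if (!length(population)) stopf("population is empty")
  stray <- setdiff(study, population)
  if (length(stray)) {
    stopf("study genes missing from population: %s%s",
          paste(utils::head(stray, 5L), collapse = ", "),
          if (length(stray) > 5L) sprintf(" (and %d more)", length(stray) - 5L) else "")
  }
  n_study <- length(study)
  n_pop <- length(population)
  rows <- lapply(names(annotation$sets), function(id) {
    members <- intersect(annotation$sets[[id]], population)
    k_pop <- length(members)
    k_study <- length(intersect(members, study))
    p <- stats::phyper(k_study - 1L, k_pop, n_pop - k_pop, n_study,
                       lower.tail = FALSE)
    data.frame(term_id = id, term_name = annotation$descriptions[[id]],
               k = k_study, K = k_pop, n = n_study, N = n_pop,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$corrected_p <- bh_fdr(out$p_value)
  out$significant <- out$corrected_p < alpha
  out <- out[order(out$corrected_p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
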