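# The seven back-splice junction candidate filters and RPM quantification
# of the surviving circRNAs.

#' Default thresholds of the seven circRNA candidate filters
#'
#' (a) exactly one clear breakpoint; (b) anchor overlap at most 2 bp;
#' (c) at most 2 bp of mismatches; (d) more than 2 unique junction reads;
#' (e) the best anchor mapping beats the runner-up by a score above 35 on at
#' least one side; (f) unique junction reads exceed `floor(n_samples / 2)`;
#' (g) spliced length under 100 kb.
#'
#' @return named list of threshold constants.
#' @export
circ_filter_defaults <- function() {
  list(breakpoint = 1L, max_anchor_overlap = 2L, max_edit_distance = 2L,
       min_uniq = 2L, min_qual = 35L, max_length = 100000L)
}

.circ_required_cols <- c("candidate_id", "chrom", "start", "end", "strand",
                         "breakpoint_count", "anchor_overlap", "edit_distance",
                         "n_uniq", "best_qual_A", "best_qual_B")

.check_candidates <- function(candidates) {
  if (!is.data.frame(candidates)) stopf("candidates must be a data.frame")
  miss <- setdiff(.circ_required_cols, names(candidates))
  if (length(miss)) stopf("candidates missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(candidates$candidate_id)) stopf("duplicate candidate_id values")
  bad <- which(candidates$end <= candidates$start)
  if (length(bad)) {
    stopf("malformed candidate(s) with end <= start: %s",
          paste(candidates$candidate_id[bad], collapse = ", "))
  }
  num <- c("breakpoint_count", "anchor_overlap", "edit_distance", "n_uniq")
  for (col in num) {
    bad <- which(!is.finite(candidates[[col]]) | candidates[[col]] < 0)
    if (length(bad)) {
      stopf("malformed candidate(s) with negative or missing %s: %s", col,
            paste(candidates$candidate_id[bad], collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Apply the seven circRNA candidate filters
#'
#' Evaluates criteria (a)-(g) (see [circ_filter_defaults()]) for every
#' candidate; a candidate passes overall iff all seven pass. Coordinates are
#' 0-based half-open (BED convention), so length = end - start. All
#' comparisons against thresholds follow their stated form: (d) and (f) are
#' strict ">", (e) is strict ">", (g) is strict "<", (b) and (c) are "<=".
#'
#' @param candidates data.frame of candidates (see
#'   [generate_circ_candidates()] for the columns).
#' @param n_samples total number of samples, used by criterion (f).
#' @param thresholds list of constants, by default [circ_filter_defaults()].
#' @return data.frame with per-criterion logicals `crit_a` .. `crit_g` and
#'   overall `pass`.
#' @export
apply_filters <- function(candidates, n_samples,
                          thresholds = circ_filter_defaults()) {
  if (!is_count1(n_samples) || n_samples < 1) {
    stopf("n_samples must be a positive integer")
  }
  .check_candidates(candidates)
  th <- thresholds
  len <- candidates$end - candidates$start
  out <- data.frame(
    candidate_id = candidates$candidate_id,
    crit_a = candidates$breakpoint_count == th$breakpoint,
    crit_b = candidates$anchor_overlap <= th$max_anchor_overlap,
    crit_c = candidates$edit_distance <= th$max_edit_distance,
    crit_d = candidates$n_uniq > th$min_uniq,
    crit_e = candidates$best_qual_A > th$min_qual |
      candidates$best_qual_B > th$min_qual,
    crit_f = candidates$n_uniq > floor(n_samples / 2),
    crit_g = len < th$max_length,
    stringsAsFactors = FALSE
  )
  out$pass <- out$crit_a & out$crit_b & out$crit_c & out$crit_d &
    out$crit_e & out$crit_f & out$crit_g
  out
}

#' Quantify passing circRNA candidates in RPM
#'
#' Restricts the candidate table to overall-passing records and converts
#' their per-sample junction-read counts to reads per million back-spliced
#' junction reads via [rpm_circ()].
#'
#' @param candidates candidate data.frame including one count column per
#'   sample named as in `junction_totals`.
#' @param verdicts output of [apply_filters()] for the same candidates.
#' @param junction_totals named positive numeric vector: total back-spliced
#'   junction reads per sample.
#' @param conditions condition label per sample (same order as
#'   `junction_totals`).
#' @return an [expression_matrix()] (layer `"circRNA"`, scale `"RPM"`) over
#'   the passing candidates; zero rows when none pass.
#' @export
quantify_rpm <- function(candidates, verdicts, junction_totals, conditions) {
  .check_candidates(candidates)
  if (!all(candidates$candidate_id %in% verdicts$candidate_id)) {
    stopf("verdicts do not cover all candidates")
  }
  samples <- names(junction_totals)
  if (is.null(samples) || !all(samples %in% names(candidates))) {
    stopf("candidates lack per-sample count columns for: %s",
          paste(setdiff(samples, names(candidates)), collapse = ", "))
  }
  if (any(junction_totals <= 0)) stopf("per-sample junction totals must be positive")
  keep <- candidates$candidate_id %in%
    verdicts$candidate_id[verdicts$pass %in% TRUE]
  sub <- candidates[keep, , drop = FALSE]
  counts <- as.matrix(sub[, samples, drop = FALSE])
  rownames(counts) <- sub$candidate_id
  rpm <- counts
  for (j in seq_along(samples)) {
    rpm[, j] <- rpm_circ(counts[, j], junction_totals[[j]])
  }
  expression_matrix(rpm, "circRNA", conditions, scale = "RPM")
}

#' Write passing circRNA candidates as BED6
#'
#' Exports the passing set in BED6 (chrom, start, end, name = candidate id,
#' score = unique junction reads, strand) through `rtracklayer`.
#'
#' @param candidates candidate data.frame.
#' @param verdicts output of [apply_filters()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_circ_bed <- function(candidates, verdicts, path) {
  .check_candidates(candidates)
  keep <- candidates$candidate_id %in%
    verdicts$candidate_id[verdicts$pass %in% TRUE]
  sub <- candidates[keep, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = sub$chrom,
    # BED is 0-based half-open; GRanges is 1-based closed
    ranges = IRanges::IRanges(start = sub$start + 1L, end = sub$end),
    strand = sub$strand
  )
  gr$name <- sub$candidate_id
  gr$score <- pmin(sub$n_uniq, 1000L)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
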