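# Abundance normalisations used by the four RNA layers, and the RT-qPCR
# 2^-ddCt relative quantitation.

#' FPKM: fragments per kilobase of transcript per million mapped fragments
#'
#' `FPKM = 1e9 * count / (length * total_fragments)`, the normalisation used
#' for mRNA and lncRNA abundance. The length is the effective transcript
#' length in bp as supplied; no fragment-length correction is applied.
#'
#' @param counts nonnegative numeric vector of fragment counts.
#' @param lengths positive numeric vector of transcript lengths in bp
#'   (length 1 or same length as `counts`).
#' @param total_fragments positive scalar, total mapped fragments in the
#'   library.
#' @return numeric vector of FPKM values.
#' @examples
#' fpkm(1000, 1000, 1e6)  # 1000
#' @export
fpkm <- function(counts, lengths, total_fragments) {
  if (any(!is.finite(counts)) || any(counts < 0)) stopf("counts must be nonnegative")
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stopf("transcript lengths must be positive")
  }
  if (!is_pos1(total_fragments)) stopf("total_fragments must be a positive scalar")
  1e9 * counts / (lengths * total_fragments)
}

#' TPM for miRNA tag counts
#'
#' Tags per million: `TPM = 1e6 * count / total_clean_tags`. The printed
#' per-million semantics (count scaled to a library of one million clean
#' tags) is the default; `literal = TRUE` instead evaluates
#' `count / (total_clean_tags * 1e6)`, a formula sometimes encountered in
#' methods text, which differs by a constant factor of 1e12 and preserves
#' all rankings and fold changes.
#'
#' @param counts nonnegative numeric vector of miRNA tag counts.
#' @param total_clean_tags positive scalar, total clean tags in the library.
#' @param literal use the literal division form (see Details).
#' @return numeric vector of TPM values.
#' @export
tpm_mirna <- function(counts, total_clean_tags, literal = FALSE) {
  if (any(!is.finite(counts)) || any(counts < 0)) stopf("counts must be nonnegative")
  if (!is_pos1(total_clean_tags)) stopf("total_clean_tags must be a positive scalar")
  if (literal) counts / (total_clean_tags * 1e6) else 1e6 * counts / total_clean_tags
}

#' RPM for circRNA back-splice junction reads
#'
#' `RPM = 1e6 * C / N` where C is the count of back-spliced junction reads
#' mapped to one circRNA and N the total back-spliced junction reads in the
#' sample. RPM removes the effect of sequencing depth so circRNA abundances
#' are comparable across samples.
#'
#' @param c_reads nonnegative numeric vector, junction reads per circRNA.
#' @param n_total positive scalar, total junction reads; every element of
#'   `c_reads` must be `<= n_total`.
#' @return numeric vector of RPM values.
#' @examples
#' rpm_circ(7, 3.5e6)  # 2
#' @export
rpm_circ <- function(c_reads, n_total) {
  if (!is_pos1(n_total)) stopf("n_total must be a positive scalar")
  if (any(!is.finite(c_reads)) || any(c_reads < 0)) stopf("c_reads must be nonnegative")
  if (any(c_reads > n_total)) stopf("c_reads cannot exceed n_total")
  1e6 * c_reads / n_total
}

#' Normalise an expression matrix on its layer's conventional scale
#'
#' mRNA and lncRNA counts are normalised to FPKM (requires per-feature
#' transcript lengths), miRNA counts to TPM, circRNA junction counts to RPM.
#' Per-sample totals default to the column sums of the count matrix.
#'
#' @param em an [expression_matrix()] on the `"counts"` scale.
#' @param totals optional per-sample totals (mapped fragments, clean tags,
#'   or junction reads); defaults to `colSums(em$values)`.
#' @return an [expression_matrix()] on the layer's normalised scale.
#' @export
normalize_layer <- function(em, totals = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$scale != "counts") stopf("matrix is already on scale %s", em$scale)
  if (is.null(totals)) totals <- colSums(em$values)
  if (length(totals) != ncol(em$values)) stopf("need one total per sample")
  if (any(totals <= 0)) stopf("per-sample totals must be positive")
  out <- em$values
  if (em$layer %in% c("mRNA", "lncRNA")) {
    if (is.null(em$lengths)) stopf("FPKM needs transcript lengths on the matrix")
    for (j in seq_len(ncol(out))) {
      out[, j] <- fpkm(em$values[, j], em$lengths, totals[j])
    }
    scale <- "FPKM"
  } else if (em$layer == "miRNA") {
    for (j in seq_len(ncol(out))) {
      out[, j] <- tpm_mirna(em$values[, j], totals[j])
    }
    scale <- "TPM"
  } else {
    for (j in seq_len(ncol(out))) {
      out[, j] <- rpm_circ(em$values[, j], totals[j])
    }
    scale <- "RPM"
  }
  expression_matrix(out, em$layer, em$conditions, scale = scale,
                    lengths = em$lengths)
}

#' RT-qPCR relative expression by the 2^-ddCt method
#'
#' Threshold-cycle (Ct) values of a target gene are normalised against the
#' mean Ct of one or more housekeeping reference genes within each condition
#' (`dCt = mean Ct(target) - mean Ct(reference)`); the relative expression of
#' the test condition against the calibrator is `2^-(dCt_test - dCt_cal)`.
#' Replicate groups whose Ct standard deviation exceeds `sd_warn` cycles are
#' flagged, the usual technical-replicate quality gate.
#'
#' @param records data.frame with columns `sample`, `condition`, `gene`,
#'   `role` (`"target"` or `"reference"`), `ct` (cycles).
#' @param target gene id of the target transcript.
#' @param test,calibrator condition labels; the result is expression of
#'   `test` relative to `calibrator`.
#' @param sd_warn replicate Ct standard deviation above which a group is
#'   flagged (default 0.5 cycles).
#' @return list with `relative_expression` (2^-ddCt), `ddct`, per-condition
#'   `dct`, and `flagged` (character vector of condition/gene groups whose
#'   replicate SD exceeded `sd_warn`).
#' @examples
#' qp <- data.frame(
#'   sample = rep(c("s1", "s2"), each = 2),
#'   condition = rep(c("GF_T", "GF_C"), each = 2),
#'   gene = rep(c("tgt", "GAPDH"), 2),
#'   role = rep(c("target", "reference"), 2),
#'   ct = c(25, 20, 26.5, 19)
#' )
#' ddct(qp, target = "tgt", test = "GF_T", calibrator = "GF_C")
#' @export
ddct <- function(records, target, test, calibrator, sd_warn = 0.5) {
  need <- c("sample", "condition", "gene", "role", "ct")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stopf("records must be a data.frame with columns %s", paste(need, collapse = ", "))
  }
  if (any(!is.finite(records$ct))) stopf("Ct values must be finite")
  if (!all(records$role %in% c("target", "reference"))) {
    stopf("role must be 'target' or 'reference'")
  }
  conds <- c(test, calibrator)
  flagged <- character()
  dct <- vapply(conds, function(cd) {
    sub <- records[records$condition == cd, , drop = FALSE]
    tg <- sub$ct[sub$role == "target" & sub$gene == target]
    rf <- sub$ct[sub$role == "reference"]
    if (!length(tg)) stopf("no target Ct values for condition %s", cd)
    if (!length(rf)) stopf("no reference-gene Ct values for condition %s", cd)
    for (g in unique(sub$gene)) {
      cts <- sub$ct[sub$gene == g]
      if (length(cts) >= 2L && stats::sd(cts) > sd_warn) {
        flagged <<- c(flagged, sprintf("%s/%s", cd, g))
      }
    }
    # multiple reference genes are combined by an arithmetic mean of Ct
    mean(tg) - mean(rf)
  }, numeric(1))
  names(dct) <- conds
  dd <- dct[[test]] - dct[[calibrator]]
  list(relative_expression = 2^(-dd), ddct = dd, dct = dct, flagged = flagged)
}
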