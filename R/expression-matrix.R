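# The per-layer expression container shared by all modules.

.layers <- c("mRNA", "lncRNA", "miRNA", "circRNA")
.scales <- c("counts", "FPKM", "TPM", "RPM")

#' Construct an expression matrix for one RNA layer
#'
#' A light container holding a feature-by-sample numeric matrix together
#' with the layer it measures, the abundance scale of its values, the
#' condition label of every sample, and (for length-normalised layers)
#' per-feature transcript lengths.
#'
#' @param values numeric matrix, features in rows (unique rownames), samples
#'   in columns (unique colnames); all values nonnegative.
#' @param layer one of `"mRNA"`, `"lncRNA"`, `"miRNA"`, `"circRNA"`.
#' @param conditions character/factor of length `ncol(values)` giving each
#'   sample's condition (two levels, e.g. `"GF_C"` large follicles and
#'   `"GF_T"` small follicles).
#' @param scale one of `"counts"`, `"FPKM"`, `"TPM"`, `"RPM"`.
#' @param lengths optional named numeric vector of transcript lengths (bp),
#'   one per feature; required for FPKM normalisation.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, layer, conditions, scale = "counts",
                              lengths = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("values must be a numeric matrix")
  }
  layer <- match.arg(layer, .layers)
  scale <- match.arg(scale, .scales)
  if (nrow(values) > 0 &&
      (is.null(rownames(values)) || anyDuplicated(rownames(values)))) {
    stopf("values must have unique feature rownames")
  }
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stopf("values must have unique sample colnames")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stopf("expression values must be finite and nonnegative")
  }
  conditions <- as.character(conditions)
  if (length(conditions) != ncol(values)) {
    stopf("conditions must have one entry per sample column")
  }
  if (!is.null(lengths)) {
    if (is.null(names(lengths)) || !all(rownames(values) %in% names(lengths))) {
      stopf("lengths must be named and cover every feature")
    }
    lengths <- lengths[rownames(values)]
    if (any(lengths <= 0)) stopf("transcript lengths must be positive")
  }
  names(conditions) <- colnames(values)
  structure(
    list(values = values, layer = layer, scale = scale,
         conditions = conditions, lengths = lengths),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %s layer, %d features x %d samples [%s]\n",
              x$layer, nrow(x$values), ncol(x$values), x$scale))
  tab <- table(x$conditions)
  cat("conditions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# split sample columns by condition; errors unless exactly two conditions
# each with >= min_rep samples
condition_split <- function(em, min_rep = 2L) {
  lv <- unique(em$conditions)
  if (length(lv) != 2L) {
    stopf("expected exactly two conditions, found: %s", paste(lv, collapse = ", "))
  }
  idx <- split(seq_along(em$conditions), factor(em$conditions, levels = lv))
  if (any(lengths(idx) < min_rep)) {
    stopf("each condition needs at least %d samples", min_rep)
  }
  idx
}

#' Write / read an expression matrix as TSV
#'
#' The TSV carries feature ids in the first column (`feature_id`) and one
#' column per sample; layer, scale and condition map travel in `#`-prefixed
#' header comment lines so a round trip preserves the object.
#'
#' @param em an [expression_matrix()].
#' @param path file path.
#' @return `write_expression_tsv` returns `path` invisibly;
#'   `read_expression_tsv` returns an [expression_matrix()].
#' @export
write_expression_tsv <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#layer=%s", em$layer),
    sprintf("#scale=%s", em$scale),
    sprintf("#conditions=%s",
            paste(sprintf("%s:%s", names(em$conditions), em$conditions),
                  collapse = ","))
  ), con)
  if (!is.null(em$lengths)) {
    writeLines(sprintf("#lengths=%s",
                       paste(sprintf("%s:%g", names(em$lengths), em$lengths),
                             collapse = ",")), con)
  }
  df <- data.frame(feature_id = rownames(em$values), em$values,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  hdr <- character()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || !startsWith(line, "#")) break
    hdr <- c(hdr, line)
  }
  close(con); on.exit()
  meta <- function(key) {
    hit <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^#", key, "="), "", hit[1L])
  }
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  values <- as.matrix(df[, -1L, drop = FALSE])
  rownames(values) <- df[[1L]]
  parse_map <- function(s, numeric = FALSE) {
    kv <- strsplit(strsplit(s, ",", fixed = TRUE)[[1L]], ":", fixed = TRUE)
    v <- vapply(kv, `[`, "", 2L)
    if (numeric) v <- as.numeric(v)
    names(v) <- vapply(kv, `[`, "", 1L)
    v
  }
  cond <- parse_map(meta("conditions"))
  lens <- if (!is.null(meta("lengths"))) parse_map(meta("lengths"), numeric = TRUE)
  expression_matrix(values, layer = meta("layer"),
                    conditions = cond[colnames(values)],
                    scale = meta("scale"), lengths = lens)
}
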