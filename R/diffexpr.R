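# Count-based differential expression: TMM scaling factors, moment
# dispersion estimation, a conditional negative-binomial exact test, BH FDR,
# and layer-specific calling thresholds (|log2FC| > 1 with FDR < 0.05 for
# mRNA/lncRNA, |log2FC| > 1 with p < 0.05 for miRNA/circRNA).

#' Trimmed mean of M-values scaling factors
#'
#' Between-sample scaling factors computed by the weighted trimmed mean of
#' log expression ratios (M-values): 30% trim on M, 5% trim on A, inverse
#' asymptotic-variance weights, against the reference sample whose
#' upper-quartile expression is closest to the mean upper quartile. Factors
#' are normalised to a geometric mean of one.
#'
#' @param x count matrix (features x samples) or an [expression_matrix()].
#' @param logratio_trim,sum_trim trim fractions for M and A values.
#' @return named numeric vector of per-sample scaling factors.
#' @export
tmm_factors <- function(x, logratio_trim = 0.3, sum_trim = 0.05) {
  if (inherits(x, "expression_matrix")) x <- x$values
  if (!is.matrix(x) || !is.numeric(x)) stopf("x must be a numeric count matrix")
  if (ncol(x) < 2L) stopf("TMM needs at least two samples")
  lib <- colSums(x)
  if (any(lib == 0)) {
    stopf("sample(s) with all-zero counts: %s",
          paste(colnames(x)[lib == 0], collapse = ", "))
  }
  uq <- apply(x, 2L, function(col) stats::quantile(col, 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(x)), function(j) {
    .tmm_pair(x[, j], x[, ref], lib[j], lib[ref],
              logratio_trim = logratio_trim, sum_trim = sum_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(x)
  f
}

.tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim) {
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  # asymptotic variance of M by the delta method
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (!length(m) || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep)) return(1)
  2^(sum(m[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE))
}

#' Estimate negative-binomial dispersion by the method of moments
#'
#' Under the parameterisation variance = mu + phi * mu^2, the pooled
#' within-condition residual moments give a common dispersion
#' `phi = sum(v - m) / sum(m^2)` over all (feature, condition) cells with
#' at least two replicates, floored at zero. Per-feature estimates are the
#' same moment ratio per feature, shrunk toward the common value with a
#' fixed prior weight.
#'
#' @param em an [expression_matrix()] of counts with two conditions.
#' @param prior_weight weight on the common dispersion when shrinking
#'   per-feature estimates (default 0.8).
#' @return a `dispersion_estimate`: list with `common_phi` and
#'   `per_feature_phi`.
#' @export
estimate_dispersion <- function(em, prior_weight = 0.8) {
  stopifnot(inherits(em, "expression_matrix"))
  x <- em$values
  idx <- split(seq_along(em$conditions), em$conditions)
  idx <- idx[lengths(idx) >= 2L]
  if (!length(idx)) {
    warnf("no condition has two replicates; estimating dispersion by pooling all samples")
    idx <- list(all = seq_len(ncol(x)))
    if (ncol(x) < 2L) stopf("dispersion estimation needs at least two samples")
  }
  num <- matrix(0, nrow(x), length(idx))
  den <- matrix(0, nrow(x), length(idx))
  for (j in seq_along(idx)) {
    sub <- x[, idx[[j]], drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1L, stats::var)
    num[, j] <- v - m
    den[, j] <- m^2
  }
  common <- max(sum(num) / max(sum(den), .Machine$double.eps), 0)
  raw <- pmax(rowSums(num) / pmax(rowSums(den), .Machine$double.eps), 0)
  per <- prior_weight * common + (1 - prior_weight) * raw
  structure(list(common_phi = common,
                 per_feature_phi = stats::setNames(per, rownames(x))),
            class = "dispersion_estimate")
}

#' Conditional negative-binomial exact test for two count sums
#'
#' Tests equality of (size-adjusted) means between two conditions from the
#' per-condition count sums, conditioning on the total `t = sum_a + sum_b`.
#' Each split (x, t - x) is scored by the product of NB probabilities with
#' means `t * r/(1+r)` and `t/(1+r)` (r = `size_ratio`, the a-side share of
#' the effective library) and common dispersion `phi`, renormalised over all
#' t + 1 splits; the two-sided p-value is the total probability of splits no
#' more likely than the observed one (relative tie tolerance 1e-7). At
#' `phi = 0` the conditional law is exactly binomial(t, r/(1+r)).
#'
#' @param sum_a,sum_b nonnegative integer count sums (not both zero).
#' @param phi common NB dispersion of the summed counts (>= 0). For n
#'   replicates per condition with per-replicate dispersion `phi_rep`, the
#'   sum has dispersion `phi_rep / n`.
#' @param size_ratio ratio of effective library sizes, side a over side b.
#' @return two-sided p-value in (0, 1].
#' @export
nb_exact_test <- function(sum_a, sum_b, phi, size_ratio = 1) {
  if (!is_count1(sum_a) || !is_count1(sum_b)) {
    stopf("sum_a and sum_b must be nonnegative integers")
  }
  if (sum_a + sum_b == 0) stopf("both sums are zero: p-value undefined")
  if (!is_nonneg1(phi)) stopf("phi must be a nonnegative scalar")
  if (!is_pos1(size_ratio)) stopf("size_ratio must be a positive scalar")
  t_total <- sum_a + sum_b
  pr <- size_ratio / (1 + size_ratio)
  x <- 0:t_total
  if (phi <= 0) {
    px <- stats::dbinom(x, t_total, pr)
  } else {
    lp <- stats::dnbinom(x, mu = t_total * pr, size = 1 / phi, log = TRUE) +
      stats::dnbinom(t_total - x, mu = t_total * (1 - pr), size = 1 / phi,
                     log = TRUE)
    lp <- lp - max(lp)
    px <- exp(lp)
    px <- px / sum(px)
  }
  p <- sum(px[px <= px[sum_a + 1L] * (1 + 1e-7)])
  min(max(p, px[sum_a + 1L]), 1)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up BH adjustment (via [stats::p.adjust()]) with input validation;
#' values are returned in the input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (NA allowed for
#'   filtered features).
#' @return numeric vector of FDR values.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially expressed features for one layer
#'
#' Library sizes are scaled by TMM factors; log2 fold change is the ratio of
#' TMM-normalised condition means with pseudocount 0.5 (treatment over
#' control). P-values come from [nb_exact_test()] on the per-condition count
#' sums with the common moment dispersion (scaled to the dispersion of
#' replicate sums) and the effective-library size ratio; FDR is BH. Calling
#' uses strict inequalities: mRNA and lncRNA are DE iff |log2FC| > `lfc` and
#' FDR < `fdr_alpha`; miRNA and circRNA iff |log2FC| > `lfc` and p <
#' `p_alpha`. Features observed in exactly one condition are flagged
#' `group_exclusive`; features with zero counts everywhere are flagged
#' `filtered` with NA p-values.
#'
#' @param em an [expression_matrix()] of counts with two conditions.
#' @param control,treatment condition labels; log2FC is treatment over
#'   control. Defaults `"GF_C"` and `"GF_T"` when present, else the two
#'   condition labels in sorted order.
#' @param lfc,fdr_alpha,p_alpha calling thresholds.
#' @param dispersion optional `dispersion_estimate` to reuse; estimated from
#'   `em` when `NULL`.
#' @return data.frame with one row per feature: `feature_id`, `layer`,
#'   `log2FC`, `p_value`, `fdr`, `direction`, `is_de`, `group_exclusive`,
#'   `filtered`.
#' @export
call_de <- function(em, control = NULL, treatment = NULL, lfc = 1,
                    fdr_alpha = 0.05, p_alpha = 0.05, dispersion = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$scale != "counts") stopf("DE calling requires raw counts, got %s", em$scale)
  lv <- sort(unique(em$conditions))
  if (length(lv) != 2L) stopf("exactly two conditions required")
  if (is.null(control)) control <- if ("GF_C" %in% lv) "GF_C" else lv[1L]
  if (is.null(treatment)) treatment <- setdiff(lv, control)
  if (!all(c(control, treatment) %in% lv) || control == treatment) {
    stopf("control/treatment must be the two condition labels")
  }
  x <- em$values
  ia <- which(em$conditions == control)
  ib <- which(em$conditions == treatment)
  if (length(ia) < 2L || length(ib) < 2L) {
    stopf("each condition needs at least two replicates")
  }
  f <- tmm_factors(x)
  eff <- colSums(x) * f
  norm <- sweep(x, 2L, eff / exp(mean(log(eff))), "/")
  mean_c <- rowMeans(norm[, ia, drop = FALSE])
  mean_t <- rowMeans(norm[, ib, drop = FALSE])
  log2fc <- log2((mean_t + 0.5) / (mean_c + 0.5))
  sum_a <- rowSums(x[, ia, drop = FALSE])
  sum_b <- rowSums(x[, ib, drop = FALSE])
  if (is.null(dispersion)) dispersion <- estimate_dispersion(em)
  # a sum of n iid NB(mu, phi) is NB(n mu, phi / n)
  phi_sum <- dispersion$common_phi * 2 / (length(ia) + length(ib))
  size_ratio <- sum(eff[ia]) / sum(eff[ib])
  filtered <- (sum_a + sum_b) == 0
  p <- rep(NA_real_, nrow(x))
  for (i in which(!filtered)) {
    p[i] <- nb_exact_test(sum_a[i], sum_b[i], phi_sum, size_ratio)
  }
  fdr <- bh_fdr(p)
  use_fdr <- em$layer %in% c("mRNA", "lncRNA")
  sig <- if (use_fdr) fdr < fdr_alpha else p < p_alpha
  is_de <- !filtered & !is.na(sig) & sig & abs(log2fc) > lfc
  data.frame(
    feature_id = rownames(x),
    layer = em$layer,
    log2FC = log2fc,
    p_value = p,
    fdr = fdr,
    direction = ifelse(log2fc > 0, "up", ifelse(log2fc < 0, "down", NA)),
    is_de = is_de,
    group_exclusive = xor(sum_a == 0, sum_b == 0),
    filtered = filtered,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
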