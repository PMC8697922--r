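# Spearman and Pearson correlation with p-values suited to very small n.
#
# The study design this package targets has six samples (three per
# condition), where the usual t approximation for correlation p-values is
# unreliable. For n <= `exact_n` (default 8) p-values are computed by full
# enumeration of all n! permutations of one margin; above that the standard
# t approximation with n - 2 degrees of freedom is used.

# cache of permutation null distributions, keyed by n and the multiset of
# ranks on each margin (ties change the attainable coefficient values)
.perm_cache <- new.env(parent = emptyenv())

# all permutations of 1..n as an n! x n integer matrix (n <= 8 in practice)
.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (k in seq_len(n)) {
    idx <- seq_len(nrow(sub)) + row
    out[idx, k] <- n
    out[idx, -k] <- sub
    row <- row + nrow(sub)
  }
  out
}

# permutation null of the correlation between fixed vector a and permuted b;
# returns sorted |r| values over all n! permutations
.perm_null_abs_r <- function(a, b) {
  n <- length(a)
  key <- paste0("n", n, ":", paste(signif(sort(a), 12), collapse = ","),
                "|", paste(signif(sort(b), 12), collapse = ","))
  hit <- .perm_cache[[key]]
  if (!is.null(hit)) return(hit)
  perms <- .all_permutations(n)
  az <- (a - mean(a))
  bz <- (b - mean(b))
  sa <- sqrt(sum(az^2))
  sb <- sqrt(sum(bz^2))
  pb <- matrix(bz[perms], nrow(perms), n)
  out <- as.numeric(abs(pb %*% az) / (sa * sb))
  .perm_cache[[key]] <- out
  out
}

# two-sided permutation p: fraction of permutations with |r| >= |r_obs|
# (small tolerance absorbs floating-point ties)
.perm_p <- function(a, b, r_obs) {
  null_abs <- .perm_null_abs_r(a, b)
  mean(null_abs >= abs(r_obs) - 1e-12)
}

.check_cor_input <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) stopf("correlation inputs must be numeric vectors")
  if (length(x) != length(y)) stopf("correlation inputs must have equal length")
  if (length(x) < 3L) stopf("correlation needs n >= 3 samples, got %d", length(x))
  if (anyNA(x) || anyNA(y)) stopf("correlation inputs must not contain NA")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("correlation undefined: at least one input vector is constant")
  }
  invisible(TRUE)
}

.correlation_result <- function(id_a, id_b, method, coefficient, p_value, n) {
  structure(
    list(id_a = id_a, id_b = id_b, method = method,
         coefficient = coefficient, p_value = p_value, n = n),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation (n = %d): r = %.4f, p = %.4g\n",
              x$method, x$n, x$coefficient, x$p_value))
  invisible(x)
}

#' Spearman rank correlation with small-sample exact permutation p-value
#'
#' Computes the Spearman coefficient as the Pearson correlation of
#' average-ranked values. The two-sided p-value is exact for small n: all n!
#' permutations of one rank vector are enumerated and the fraction with
#' |rho| at least the observed |rho| is reported. For larger n the t
#' approximation with n - 2 degrees of freedom is used.
#'
#' @param x,y numeric vectors of expression values over the same samples.
#' @param id_a,id_b optional feature identifiers carried into the result.
#' @param exact_n largest n for which the permutation enumeration is used
#'   (default 8; 8! = 40320 permutations).
#' @return a `correlation_result`: list with `id_a`, `id_b`, `method`,
#'   `coefficient`, `p_value`, `n`.
#' @examples
#' r <- spearman_test(1:6, c(6, 5, 4, 3, 2, 1))
#' r$coefficient  # -1
#' r$p_value      # 2/720: only the two extreme rankings reach |rho| = 1
#' @export
spearman_test <- function(x, y, id_a = NA_character_, id_b = NA_character_,
                          exact_n = 8L) {
  .check_cor_input(x, y)
  n <- length(x)
  rx <- rank(x) # average ranks for ties
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stopf("correlation undefined: at least one input vector is constant after ranking")
  }
  rho <- stats::cor(rx, ry)
  p <- if (n <= exact_n) {
    .perm_p(rx, ry, rho)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  .correlation_result(id_a, id_b, "spearman", rho, min(p, 1), n)
}

#' Pearson product-moment correlation
#'
#' Two-sided p-value from the t distribution with n - 2 degrees of freedom,
#' or (optionally, for n <= `exact_n`) by full permutation enumeration on the
#' raw values.
#'
#' @inheritParams spearman_test
#' @param permutation if `TRUE` and n <= `exact_n`, use the exact permutation
#'   p-value instead of the t approximation.
#' @return a `correlation_result`.
#' @export
pearson_test <- function(x, y, id_a = NA_character_, id_b = NA_character_,
                         permutation = FALSE, exact_n = 8L) {
  .check_cor_input(x, y)
  n <- length(x)
  r <- stats::cor(x, y)
  p <- if (permutation && n <= exact_n) {
    .perm_p(x, y, r)
  } else {
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  .correlation_result(id_a, id_b, "pearson", r, min(p, 1), n)
}
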