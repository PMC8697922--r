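# Shared fixtures and independent oracles used across test files.

# small, fast synthetic config for unit tests
tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_mrna = 60L, n_lncrna = 20L, n_mirna = 20L, n_circrna = 20L,
         n_triplets = 2L, n_circ_candidates = 50L, seed = seed),
    list(...)
  )
  do.call(synth_config, args)
}

# independent brute-force evaluator of the seven circRNA filters, written
# as a plain per-record loop against the stated thresholds
naive_circ_oracle <- function(candidates, n_samples) {
  out <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    r <- as.list(candidates[i, ])
    verdict <- c(
      a = (r$breakpoint_count == 1),
      b = (r$anchor_overlap <= 2),
      c = (r$edit_distance <= 2),
      d = (r$n_uniq > 2),
      e = (r$best_qual_A > 35) || (r$best_qual_B > 35),
      f = (r$n_uniq > n_samples %/% 2),
      g = ((r$end - r$start) < 100000)
    )
    out[[i]] <- c(verdict, pass = all(verdict))
  }
  m <- do.call(rbind, out)
  colnames(m) <- c("crit_a", "crit_b", "crit_c", "crit_d", "crit_e",
                   "crit_f", "crit_g", "pass")
  m
}

# independent enumeration oracle for the conditional NB exact test:
# probability of each split on the raw (non-log) scale, renormalised
naive_nb_exact_oracle <- function(sum_a, sum_b, phi, size_ratio = 1) {
  t_total <- sum_a + sum_b
  pr <- size_ratio / (1 + size_ratio)
  x <- 0:t_total
  probs <- if (phi == 0) {
    dbinom(x, t_total, pr)
  } else {
    w <- dnbinom(x, mu = t_total * pr, size = 1 / phi) *
      dnbinom(t_total - x, mu = t_total * (1 - pr), size = 1 / phi)
    w / sum(w)
  }
  sum(probs[probs <= probs[sum_a + 1] * (1 + 1e-7)])
}

# independent full-permutation Spearman p oracle, generating permutations
# by repeated column-wise expansion (a different algorithm from the
# package's recursive insertion)
naive_spearman_perm_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  r_obs <- cor(rx, ry)
  perms <- list(integer(0))
  for (k in seq_len(n)) {
    perms <- unlist(lapply(perms, function(p) {
      lapply(setdiff(seq_len(n), p), function(j) c(p, j))
    }), recursive = FALSE)
  }
  rs <- vapply(perms, function(p) cor(rx, ry[p]), numeric(1))
  mean(abs(rs) >= abs(r_obs) - 1e-12)
}

# exhaustive hypergeometric upper-tail oracle from binomial coefficients
naive_hyper_tail <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# expression matrix from a plain matrix with half/half conditions
make_em <- function(x, layer = "circRNA", lengths = NULL) {
  ns <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("GF_", seq_len(ns))
  if (is.null(rownames(x))) rownames(x) <- paste0("f", seq_len(nrow(x)))
  expression_matrix(x, layer,
                    rep(c("GF_C", "GF_T"), each = ns / 2),
                    lengths = lengths)
}

# count matrix whose TMM factors are exactly 1 and libraries exactly equal,
# carrying one feature with a chosen pair of condition means; filler
# features are constant so trimming removes the two informative rows
balanced_boundary_counts <- function(c_counts, t_counts, comp_c, comp_t,
                                     n_filler = 18L, filler = 10L) {
  x <- rbind(f1 = c(c_counts, t_counts), f2 = c(comp_c, comp_t))
  x <- rbind(x, matrix(filler, n_filler, ncol(x),
                       dimnames = list(paste0("const", seq_len(n_filler)), NULL)))
  colnames(x) <- paste0("GF_", seq_len(ncol(x)))
  x
}
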