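# TMM scaling, dispersion estimation, the conditional NB exact test, BH
# FDR, and the layer-specific DE calling rules.

test_that("TMM factors are 1 for identical columns and have unit geometric mean", {
  x <- matrix(rep(c(10, 50, 200, 5), 4), ncol = 4)
  colnames(x) <- paste0("s", 1:4)
  expect_equal(unname(tmm_factors(x)), rep(1, 4))

  set.seed(21)
  y <- matrix(rnbinom(400 * 3, mu = 50, size = 5), ncol = 3,
              dimnames = list(NULL, paste0("s", 1:3)))
  expect_equal(exp(mean(log(tmm_factors(y)))), 1)
  expect_error(tmm_factors(cbind(y, s4 = 0)), "all-zero")
})

test_that("a doubled library with no DE is restored by its TMM factor", {
  set.seed(22)
  base <- rnbinom(2000, mu = 100, size = 10)
  x <- cbind(s1 = base, s2 = base * 2L)
  f <- tmm_factors(x)
  eff <- colSums(x) * f
  expect_equal(eff[["s1"]] * 2, eff[["s2"]], tolerance = 1e-6)
})

test_that("TMM matches the reference implementation on random counts", {
  set.seed(23)
  x <- matrix(rnbinom(3000 * 5, mu = runif(3000, 5, 500), size = 3), ncol = 5)
  colnames(x) <- paste0("s", 1:5)
  ours <- unname(tmm_factors(x))
  ref <- edgeR::calcNormFactors(edgeR::DGEList(x))$samples$norm.factors
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("moment dispersion recovers the simulation truth", {
  mk <- function(phi, nfeat, nrep, seed) {
    set.seed(seed)
    mu <- runif(nfeat, 50, 500)
    draw <- function() {
      if (phi == 0) {
        matrix(rpois(nfeat * nrep, mu), nfeat)
      } else {
        matrix(rnbinom(nfeat * nrep, mu = mu, size = 1 / phi), nfeat)
      }
    }
    x <- cbind(draw(), draw())
    dimnames(x) <- list(paste0("f", 1:nfeat), paste0("GF_", 1:(2 * nrep)))
    expression_matrix(x, "mRNA", rep(c("GF_C", "GF_T"), each = nrep))
  }
  expect_lt(estimate_dispersion(mk(0, 500, 50, 31))$common_phi, 0.02)
  est <- estimate_dispersion(mk(0.2, 500, 10, 32))$common_phi
  expect_lt(abs(est - 0.2), 0.05)
  const <- make_em(matrix(7, 10, 6))
  expect_identical(estimate_dispersion(const)$common_phi, 0)
})

test_that("the exact test is symmetric-split saturating and matches enumeration", {
  expect_equal(nb_exact_test(10, 10, 0.1, 1), 1)
  expect_equal(nb_exact_test(0, 0 + 5, 0, 1), naive_nb_exact_oracle(0, 5, 0))
  # phi = 0 equals the binomial exact test
  for (case in list(c(3, 12), c(0, 9), c(40, 60))) {
    d <- dbinom(0:sum(case), sum(case), 0.5)
    p_binom <- sum(d[d <= d[case[1] + 1] * (1 + 1e-7)])
    expect_equal(nb_exact_test(case[1], case[2], 0, 1), p_binom,
                 tolerance = 1e-9)
  }
  # random cases against the independent enumeration oracle
  set.seed(33)
  for (i in 1:40) {
    t_total <- sample(1:200, 1)
    a <- sample(0:t_total, 1)
    phi <- sample(c(0, 0.05, 0.2, 1), 1)
    r <- runif(1, 0.5, 2)
    expect_equal(nb_exact_test(a, t_total - a, phi, r),
                 naive_nb_exact_oracle(a, t_total - a, phi, r),
                 tolerance = 1e-9)
  }
  expect_error(nb_exact_test(0, 0, 0.1), "both sums")
})

test_that("BH follows the hand-computed step-up", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.005, 0.9, 0.04, 0.2)
  expect_equal(bh_fdr(p), p.adjust(p, "BH"))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("DE calling applies the layer-specific strict thresholds", {
  # |log2FC| exactly 1: excluded even with no significance requirement
  x <- balanced_boundary_counts(c(1, 1), c(2, 3), c(10, 10), c(9, 8))
  d <- call_de(make_em(x), p_alpha = 1)
  expect_equal(d$log2FC[d$feature_id == "f1"], 1)
  expect_false(d$is_de[d$feature_id == "f1"])

  # strong circRNA signal: DE with direction up under the p-value rule
  y <- rbind(f1 = c(5, 5, 5, 40, 40, 40),
             matrix(20, 30, 6, dimnames = list(paste0("c", 1:30), NULL)))
  colnames(y) <- paste0("GF_", 1:6)
  d2 <- call_de(make_em(y))
  expect_true(d2$is_de[1])
  expect_identical(d2$direction[1], "up")
  expect_lt(d2$p_value[1], 0.05)

  # identical counts everywhere: log2FC 0, not DE
  expect_false(d2$is_de[2])
  expect_equal(d2$log2FC[2], 0)
})

test_that("mRNA uses the FDR rule where circRNA uses the p rule", {
  # a feature whose p is below 0.05 but FDR is not: DE as circRNA only
  set.seed(41)
  x <- matrix(rnbinom(400 * 6, mu = 100, size = 10), 400, 6,
              dimnames = list(paste0("f", 1:400), paste0("GF_", 1:6)))
  x[1, ] <- c(60, 65, 70, 130, 140, 150)
  cond <- rep(c("GF_C", "GF_T"), each = 3)
  dm <- call_de(expression_matrix(x, "mRNA",
                                  cond, lengths = setNames(rep(1000, 400),
                                                           rownames(x))))
  dc <- call_de(expression_matrix(x, "circRNA", cond))
  expect_identical(dm$p_value, dc$p_value)
  i <- which(dm$feature_id == "f1")
  if (dm$p_value[i] < 0.05 && dm$fdr[i] >= 0.05 && abs(dm$log2FC[i]) > 1) {
    expect_false(dm$is_de[i])
    expect_true(dc$is_de[i])
  }
  # group exclusivity flags features seen in exactly one condition
  y <- rbind(f1 = c(0, 0, 0, 30, 35, 40),
             matrix(20, 20, 6, dimnames = list(paste0("c", 1:20), NULL)))
  colnames(y) <- paste0("GF_", 1:6)
  dg <- call_de(make_em(y))
  expect_true(dg$group_exclusive[1])
  expect_false(any(dg$group_exclusive[-1]))
})

test_that("swapping condition labels negates log2FC and preserves p-values", {
  g <- generate_counts(tiny_config(seed = 9, n_mrna = 120L))
  em <- g$matrices$mRNA
  d1 <- call_de(em, control = "GF_C", treatment = "GF_T")
  d2 <- call_de(em, control = "GF_T", treatment = "GF_C")
  expect_equal(d1$log2FC, -d2$log2FC)
  expect_equal(d1$p_value, d2$p_value, tolerance = 1e-12)
})

test_that("planted signals are recovered with high power", {
  gen <- generate_counts(synth_config(seed = 3, n_samples_per_condition = 5,
                                      n_mrna = 600L, n_lncrna = 10L,
                                      n_mirna = 10L, n_circrna = 10L,
                                      frac_de = 0.2, log2fc_magnitude = 2,
                                      nb_dispersion = 0.1, n_triplets = 0))
  de <- call_de(gen$matrices$mRNA)
  pl <- gen$truth$planted_de[gen$truth$planted_de$layer == "mRNA", ]
  called <- de$feature_id[de$is_de]
  expect_gte(mean(pl$feature_id %in% called), 0.9)
  # directions match the planted truth for the recovered features
  hit <- pl[pl$feature_id %in% called, ]
  expect_identical(de$direction[match(hit$feature_id, de$feature_id)],
                   hit$direction)
})
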