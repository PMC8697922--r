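# Seeded synthetic multi-layer dataset generator with planted ground truth.
#
# The generator emulates the design of a two-condition follicle study: two
# pools of samples (large follicles GF_C as control, small follicles GF_T as
# treatment), four RNA layers quantified as counts, a fraction of features
# with planted fold changes, planted ceRNA triplets in which a miRNA
# suppresses both an mRNA and a ceRNA (lncRNA or circRNA) so the two targets
# positively co-vary, circRNA junction candidates with known per-criterion
# verdicts, and three miRNA target-prediction tables with tunable
# sensitivity/specificity. Every output draws from its own RNG substream of
# the root seed, so adding outputs never perturbs existing ones.

#' Configuration for the synthetic data generator
#'
#' Defaults mirror the pooled-follicle study design: three samples per
#' condition (six total), four layers with desk-scale feature counts, 10%
#' planted differential expression at two log2 units, negative-binomial
#' counts with dispersion 0.1, and ten planted ceRNA triplets.
#'
#' @param n_samples_per_condition samples per condition (>= 2; default 3).
#' @param n_mrna,n_lncrna,n_mirna,n_circrna background features per layer.
#' @param frac_de fraction of background features per layer with a planted
#'   fold change.
#' @param log2fc_magnitude planted |log2 fold change| (GF_T over GF_C).
#' @param nb_dispersion negative-binomial dispersion phi
#'   (variance = mu + phi * mu^2); 0 gives Poisson counts.
#' @param n_triplets planted ceRNA triplets (ceRNA alternates lncRNA /
#'   circRNA across triplets).
#' @param corr_noise_sd SD (log2 units) of Gaussian noise added to the
#'   latent means of planted triplet targets; 0 makes the planted
#'   correlations exact on the latent means.
#' @param pred_sensitivity probability a true miRNA-target pair appears in
#'   each prediction table.
#' @param pred_specificity 1 minus the probability a decoy pair appears in
#'   each prediction table.
#' @param n_circ_candidates circRNA junction candidates to generate.
#' @param seed integer root seed.
#' @return validated `synth_config` list.
#' @export
synth_config <- function(n_samples_per_condition = 3L,
                         n_mrna = 2000L, n_lncrna = 400L,
                         n_mirna = 300L, n_circrna = 600L,
                         frac_de = 0.1, log2fc_magnitude = 2,
                         nb_dispersion = 0.1, n_triplets = 10L,
                         corr_noise_sd = 0.1,
                         pred_sensitivity = 0.9, pred_specificity = 0.99,
                         n_circ_candidates = 200L, seed = 1L) {
  cfg <- list(
    n_samples_per_condition = n_samples_per_condition,
    n_mrna = n_mrna, n_lncrna = n_lncrna, n_mirna = n_mirna,
    n_circrna = n_circrna, frac_de = frac_de,
    log2fc_magnitude = log2fc_magnitude, nb_dispersion = nb_dispersion,
    n_triplets = n_triplets, corr_noise_sd = corr_noise_sd,
    pred_sensitivity = pred_sensitivity, pred_specificity = pred_specificity,
    n_circ_candidates = n_circ_candidates, seed = seed
  )
  checks <- list(
    n_samples_per_condition = function(v) is_count1(v) && v >= 2,
    n_mrna = is_count1, n_lncrna = is_count1, n_mirna = is_count1,
    n_circrna = is_count1, frac_de = is_frac1,
    log2fc_magnitude = is_pos1, nb_dispersion = is_nonneg1,
    n_triplets = is_count1, corr_noise_sd = is_nonneg1,
    pred_sensitivity = is_frac1, pred_specificity = is_frac1,
    n_circ_candidates = is_count1,
    seed = function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  )
  for (field in names(checks)) {
    if (!checks[[field]](cfg[[field]])) {
      stopf("invalid synth_config field '%s': %s", field,
            paste(format(cfg[[field]]), collapse = ", "))
    }
  }
  cfg$n_samples_per_condition <- as.integer(cfg$n_samples_per_condition)
  structure(cfg, class = "synth_config")
}

.synth_samples <- function(cfg) {
  n <- cfg$n_samples_per_condition
  list(
    ids = sprintf("GF_%d", seq_len(2L * n)),
    conditions = rep(c("GF_C", "GF_T"), each = n)
  )
}

.layer_spec <- function(cfg) {
  data.frame(
    layer = .layers,
    n = c(cfg$n_mrna, cfg$n_lncrna, cfg$n_mirna, cfg$n_circrna),
    prefix = c("mRNA_%04d", "lnc_%04d", "miR_%04d", "circ_%04d"),
    stringsAsFactors = FALSE
  )
}

.rcounts <- function(n, mu, phi) {
  if (phi <= 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

#' Generate four-layer count matrices with planted ground truth
#'
#' Background feature means are drawn log-uniform on \[20, 2000\]. Non-DE
#' features share their mean across conditions; planted DE features have
#' condition means separated by exactly `log2fc_magnitude` on the log2 scale
#' (split symmetrically around the baseline, alternating up/down in GF_T).
#' Counts are negative binomial with dispersion `nb_dispersion`.
#'
#' Each planted triplet adds three dedicated features. The miRNA's latent
#' log2 mean increases by one unit per sample rank (GF_T samples ranked
#' above GF_C, so the miRNA is up in GF_T); the mRNA and ceRNA latent log2
#' means are affine decreasing functions of the same rank plus Gaussian
#' noise of SD `corr_noise_sd`. With zero noise the latent means give
#' exactly Spearman -1 (miRNA vs either target) and Pearson +1 (ceRNA vs
#' mRNA), and both targets are strongly down in GF_T.
#'
#' @param config a [synth_config()].
#' @return list with `matrices` (named list of four count
#'   [expression_matrix()] objects) and `truth` (a `truth_table`: data
#'   frames `planted_de` and `planted_triplets`, per-layer feature id list
#'   `features`, and `triplet_latents`, the per-triplet latent mean
#'   profiles).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  smp <- .synth_samples(config)
  ns <- length(smp$ids)
  spec <- .layer_spec(config)
  phi <- config$nb_dispersion

  matrices <- list()
  planted_de <- list()
  features <- list()
  for (i in seq_len(nrow(spec))) {
    layer <- spec$layer[i]
    nfeat <- spec$n[i]
    ids <- sprintf(spec$prefix[i], seq_len(nfeat))
    out <- with_substream(config$seed, i, {
      base_mu <- exp(stats::runif(nfeat, log(20), log(2000)))
      n_de <- round(config$frac_de * nfeat)
      de_idx <- if (n_de > 0) sample.int(nfeat, n_de) else integer()
      dir_sign <- rep_len(c(1, -1), n_de) # +1 = up in GF_T
      mu_c <- base_mu
      mu_t <- base_mu
      mu_c[de_idx] <- base_mu[de_idx] * 2^(-dir_sign * config$log2fc_magnitude / 2)
      mu_t[de_idx] <- base_mu[de_idx] * 2^(+dir_sign * config$log2fc_magnitude / 2)
      mu <- cbind(
        matrix(rep(mu_c, config$n_samples_per_condition), nfeat),
        matrix(rep(mu_t, config$n_samples_per_condition), nfeat)
      )
      counts <- matrix(.rcounts(length(mu), as.vector(mu), phi), nfeat, ns)
      lengths <- if (layer %in% c("mRNA", "lncRNA")) {
        round(stats::runif(nfeat, 200, 10000))
      }
      list(counts = counts, de_idx = de_idx, dir_sign = dir_sign,
           lengths = lengths)
    })
    counts <- out$counts
    dimnames(counts) <- list(ids, smp$ids)
    lens <- out$lengths
    if (!is.null(lens)) names(lens) <- ids
    matrices[[layer]] <- expression_matrix(counts, layer, smp$conditions,
                                           scale = "counts", lengths = lens)
    features[[layer]] <- ids
    if (length(out$de_idx)) {
      planted_de[[layer]] <- data.frame(
        layer = layer, feature_id = ids[out$de_idx],
        direction = ifelse(out$dir_sign > 0, "up", "down"),
        stringsAsFactors = FALSE
      )
    }
  }

  # planted ceRNA triplets: dedicated features appended to three layers
  triplets <- data.frame(ceRNA_id = character(), ceRNA_layer = character(),
                         miRNA_id = character(), mRNA_id = character(),
                         stringsAsFactors = FALSE)
  triplet_latents <- list()
  if (config$n_triplets > 0) {
    ranks <- seq_len(ns) # GF_C samples rank low, GF_T high
    step <- 1 # log2 units per sample rank: wide spread keeps ranks stable
    trip <- with_substream(config$seed, 5L, {
      lapply(seq_len(config$n_triplets), function(k) {
        cer_layer <- if (k %% 2L == 1L) "lncRNA" else "circRNA"
        b_mi <- stats::runif(1, log2(30), log2(80))
        b_m <- stats::runif(1, log2(30), log2(80))
        b_c <- stats::runif(1, log2(30), log2(80))
        mi_mu <- 2^(b_mi + step * (ranks - 1))
        m_mu <- 2^(b_m + step * (ns - ranks) +
                     stats::rnorm(ns, 0, config$corr_noise_sd))
        c_mu <- 2^(b_c + step * (ns - ranks) +
                     stats::rnorm(ns, 0, config$corr_noise_sd))
        list(
          cer_layer = cer_layer,
          latents = list(miRNA = mi_mu, mRNA = m_mu, ceRNA = c_mu),
          counts = list(miRNA = .rcounts(ns, mi_mu, phi),
                        mRNA = .rcounts(ns, m_mu, phi),
                        ceRNA = .rcounts(ns, c_mu, phi))
        )
      })
    })
    for (k in seq_along(trip)) {
      tk <- trip[[k]]
      mi_id <- sprintf("miR_trip%02d", k)
      m_id <- sprintf("mRNA_trip%02d", k)
      c_id <- sprintf("%s_trip%02d",
                      if (tk$cer_layer == "lncRNA") "lnc" else "circ", k)
      add_row <- function(em, id, counts, len = NULL) {
        v <- rbind(em$values, counts)
        rownames(v) <- c(rownames(em$values), id)
        lens <- em$lengths
        if (!is.null(lens)) {
          lens <- c(lens, stats::setNames(len, id))
        }
        expression_matrix(v, em$layer, em$conditions, em$scale, lens)
      }
      matrices$miRNA <- add_row(matrices$miRNA, mi_id, tk$counts$miRNA)
      matrices$mRNA <- add_row(matrices$mRNA, m_id, tk$counts$mRNA, len = 2000)
      matrices[[tk$cer_layer]] <- add_row(
        matrices[[tk$cer_layer]], c_id, tk$counts$ceRNA,
        len = if (tk$cer_layer == "lncRNA") 1500
      )
      features$miRNA <- c(features$miRNA, mi_id)
      features$mRNA <- c(features$mRNA, m_id)
      features[[tk$cer_layer]] <- c(features[[tk$cer_layer]], c_id)
      triplets <- rbind(triplets, data.frame(
        ceRNA_id = c_id, ceRNA_layer = tk$cer_layer,
        miRNA_id = mi_id, mRNA_id = m_id, stringsAsFactors = FALSE
      ))
      triplet_latents[[k]] <- tk$latents
    }
  }

  planted_de <- if (length(planted_de)) {
    do.call(rbind, c(planted_de, list(make.row.names = FALSE)))
  } else {
    data.frame(layer = character(), feature_id = character(),
               direction = character(), stringsAsFactors = FALSE)
  }
  truth <- structure(
    list(planted_de = planted_de, planted_triplets = triplets,
         features = features, triplet_latents = triplet_latents,
         conditions = stats::setNames(smp$conditions, smp$ids)),
    class = "truth_table"
  )
  list(matrices = matrices, truth = truth)
}

#' Generate circRNA back-splice junction candidates with known verdicts
#'
#' Field distributions straddle every filter threshold so each of the seven
#' criteria is satisfied by some records and violated by others. The
#' returned truth holds the expected per-criterion verdict, computed at
#' generation time by a plain per-record predicate evaluation.
#'
#' @param config a [synth_config()].
#' @param n number of candidates (default `config$n_circ_candidates`).
#' @return list with `candidates` (data.frame: coordinates, filter fields,
#'   and one junction-read count column per sample) and `circ_truth`
#'   (data.frame of per-criterion logical verdicts and overall `pass`).
#' @export
generate_circ_candidates <- function(config, n = config$n_circ_candidates) {
  stopifnot(inherits(config, "synth_config"))
  if (!is_count1(n)) stopf("invalid synth_config field 'n_circ_candidates': %s", n)
  smp <- .synth_samples(config)
  ns <- length(smp$ids)
  if (n == 0) {
    cand <- data.frame(candidate_id = character(), chrom = character(),
                       start = integer(), end = integer(), strand = character(),
                       breakpoint_count = integer(), anchor_overlap = integer(),
                       edit_distance = integer(), n_uniq = integer(),
                       best_qual_A = integer(), best_qual_B = integer(),
                       stringsAsFactors = FALSE)
    return(list(candidates = cand,
                circ_truth = data.frame(candidate_id = character())))
  }
  cand <- with_substream(config$seed, 6L, {
    start <- sample.int(5e7, n)
    len <- round(10^stats::runif(n, 2, 5.5)) # spans the 100 kb bound
    counts <- matrix(stats::rnbinom(n * ns, mu = 8, size = 2), n, ns)
    colnames(counts) <- smp$ids
    data.frame(
      candidate_id = sprintf("cand_%05d", seq_len(n)),
      chrom = sample(sprintf("chr%d", 1:29), n, replace = TRUE),
      start = start, end = start + len,
      strand = sample(c("+", "-"), n, replace = TRUE),
      breakpoint_count = sample(0:2, n, replace = TRUE, prob = c(.1, .7, .2)),
      anchor_overlap = sample(0:4, n, replace = TRUE, prob = c(.4, .2, .2, .1, .1)),
      edit_distance = sample(0:4, n, replace = TRUE, prob = c(.4, .2, .2, .1, .1)),
      n_uniq = sample(0:10, n, replace = TRUE),
      best_qual_A = sample(20:45, n, replace = TRUE),
      best_qual_B = sample(20:45, n, replace = TRUE),
      counts,
      stringsAsFactors = FALSE, check.names = FALSE
    )
  })
  # expected verdicts by straightforward per-record predicate evaluation
  truth <- do.call(rbind, lapply(seq_len(n), function(i) {
    r <- cand[i, ]
    a <- r$breakpoint_count == 1
    b <- r$anchor_overlap <= 2
    cc <- r$edit_distance <= 2
    d <- r$n_uniq > 2
    e <- r$best_qual_A > 35 || r$best_qual_B > 35
    f <- r$n_uniq > floor(ns / 2)
    g <- (r$end - r$start) < 100000
    data.frame(candidate_id = r$candidate_id, crit_a = a, crit_b = b,
               crit_c = cc, crit_d = d, crit_e = e, crit_f = f, crit_g = g,
               pass = a && b && cc && d && e && f && g,
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  list(candidates = cand, circ_truth = truth)
}

#' Generate three miRNA target-prediction tables
#'
#' Emulates three independent sequence-based prediction sources. Every
#' planted target relation (miRNA to its mRNA target and miRNA to its ceRNA
#' target) appears in each table with probability `pred_sensitivity`; decoy
#' pairs drawn from the remaining miRNA-by-target universe appear with
#' probability `1 - pred_specificity`. The three tables use independent RNG
#' substreams of the root seed.
#'
#' @param truth a `truth_table` from [generate_counts()].
#' @param config the [synth_config()] used to generate it.
#' @return named list of three data.frames (`rnahybrid`, `miranda`,
#'   `targetscan`), each with columns `miRNA_id`, `target_id`.
#' @export
generate_prediction_tables <- function(truth, config) {
  stopifnot(inherits(truth, "truth_table"), inherits(config, "synth_config"))
  tp <- truth$planted_triplets
  true_pairs <- unique(rbind(
    data.frame(miRNA_id = tp$miRNA_id, target_id = tp$mRNA_id,
               stringsAsFactors = FALSE),
    data.frame(miRNA_id = tp$miRNA_id, target_id = tp$ceRNA_id,
               stringsAsFactors = FALSE)
  ))
  mirnas <- truth$features$miRNA
  targets <- c(truth$features$mRNA, truth$features$lncRNA,
               truth$features$circRNA)
  n_grid <- length(mirnas) * length(targets)
  true_idx <- if (nrow(true_pairs)) {
    (match(true_pairs$target_id, targets) - 1L) * length(mirnas) +
      match(true_pairs$miRNA_id, mirnas)
  } else {
    integer()
  }
  sources <- c("rnahybrid", "miranda", "targetscan")
  out <- lapply(seq_along(sources), function(s) {
    with_substream(config$seed, 10L + s, {
      keep_true <- if (nrow(true_pairs)) {
        stats::runif(nrow(true_pairs)) < config$pred_sensitivity
      } else {
        logical()
      }
      tab <- true_pairs[keep_true, , drop = FALSE]
      p_decoy <- 1 - config$pred_specificity
      n_universe <- n_grid - length(true_idx)
      if (p_decoy > 0 && n_universe > 0) {
        n_decoy <- stats::rbinom(1L, n_universe, p_decoy)
        if (n_decoy > 0) {
          # oversample then drop collisions with true pairs (rare)
          idx <- sample.int(n_grid, min(n_grid, n_decoy + length(true_idx)))
          idx <- setdiff(idx, true_idx)[seq_len(min(n_decoy, n_grid))]
          idx <- idx[!is.na(idx)]
          decoys <- data.frame(
            miRNA_id = mirnas[(idx - 1L) %% length(mirnas) + 1L],
            target_id = targets[(idx - 1L) %/% length(mirnas) + 1L],
            stringsAsFactors = FALSE
          )
          tab <- rbind(tab, decoys)
        }
      }
      tab <- tab[order(tab$miRNA_id, tab$target_id), , drop = FALSE]
      rownames(tab) <- NULL
      tab
    })
  })
  names(out) <- sources
  out
}

#' Generate synthetic annotation sets over a gene universe
#'
#' Random term memberships for exercising the enrichment stage on synthetic
#' runs; term sizes are drawn log-uniform between `size_range`.
#'
#' @param universe character vector of gene ids.
#' @param n_terms number of terms.
#' @param size_range two-element integer range of member counts.
#' @param seed integer seed.
#' @return an `annotation_sets` object (see [read_gmt()]).
#' @export
generate_annotation_sets <- function(universe, n_terms = 50L,
                                     size_range = c(10L, 100L), seed = 1L) {
  stopifnot(length(universe) >= 2L, n_terms >= 0)
  size_range <- pmin(size_range, length(universe))
  sets <- with_substream(seed, 20L, {
    lapply(seq_len(n_terms), function(k) {
      sz <- round(exp(stats::runif(1, log(size_range[1]), log(size_range[2]))))
      sort(sample(universe, min(sz, length(universe))))
    })
  })
  ids <- sprintf("TERM:%04d", seq_len(n_terms))
  names(sets) <- ids
  structure(
    list(sets = sets,
         descriptions = stats::setNames(sprintf("synthetic term %d",
                                                seq_len(n_terms)), ids)),
    class = "annotation_sets"
  )
}
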