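#' Configure the synthetic ceRNA study generator
#'
#' Builds and validates the configuration of the synthetic-data generator,
#' which emulates a two-group (HIGH vs LOW phenotype) RNA-seq study with
#' three samples per group, three RNA layers, planted differentially
#' expressed features, and planted lncRNA-miRNA-mRNA ceRNA triplets.
#'
#' Planted triplets are driven by a shared per-sample latent factor
#' `z = delta * (group - 1/2) + w`, `w ~ N(0, latent_jitter_sd^2)`: the
#' triplet's miRNAs increase with `z` while its lncRNA and mRNA decrease (or
#' the reverse, alternating per triplet), so the miRNA is anti-correlated
#' with both ceRNAs and the ceRNAs are positively correlated with each other.
#' Member noise is calibrated from `triplet_rho` and `triplet_r`: the
#' lncRNA/mRNA noise variance is set so the latent Pearson correlation of the
#' ceRNA pair equals `triplet_r`, and the miRNA noise variance so the
#' expected sample Spearman correlation at `2 * n_per_group` samples equals
#' `triplet_rho` (using the exact bivariate-normal relation between Spearman
#' and Pearson, corrected for sample size). Infeasible targets (implied
#' negative noise variance) are a hard error before any sampling.
#'
#' The moment solution is then shrunk by `calibration_margin`: planted
#' structure must survive a chain of six threshold screens at only six
#' samples, and the generator's contract is that the planted correlations
#' clear their screen thresholds for the overwhelming majority of triplets,
#' not that each sample correlation lands on the nominal target. With the
#' default margin the realized correlations overshoot the nominal targets
#' somewhat (Spearman near -0.9 against a -0.85 target) and at least 95% of
#' planted edges clear the default screens; `calibration_margin = 1` gives
#' the exact moment calibration.
#'
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param n_per_group Samples per group (default 3).
#' @param n_mrna,n_lncrna,n_mirna Features per layer.
#' @param n_de_per_layer Planted DE features per layer in addition to the
#'   planted triplet members (which are differentially expressed by
#'   construction).
#' @param planted_log2fc Absolute log2 fold change of planted DE features and
#'   of the triplet latent factor between groups (default 1.64).
#' @param nb_dispersion Negative-binomial dispersion of background counts
#'   (`variance = mu + dispersion * mu^2`).
#' @param n_triplets Number of planted ceRNA triplets.
#' @param triplet_rho Target sample Spearman correlation between a triplet's
#'   miRNAs and its ceRNAs (default -0.85).
#' @param triplet_r Target Pearson correlation between a triplet's lncRNA and
#'   mRNA on the latent log2 scale (default 0.95).
#' @param mirna_universe Number of distinct miRNAs eligible for target
#'   relations (planted plus background regulators).
#' @param shared_targets_per_triplet miRNAs shared by each planted pair
#'   (each with planted relations to both the lncRNA and the mRNA).
#' @param n_background_relations Uniformly drawn decoy relations.
#' @param latent_jitter_sd Standard deviation of the shared latent jitter `w`
#'   (log2 units).
#' @param calibration_margin Factor in (0, 1] shrinking the calibrated noise
#'   standard deviations (see Details).
#' @param n_cis_pairs Designated cis lncRNA-gene pairs placed at gaps
#'   `cis_gaps_bp` around the 10 kb boundary.
#' @param cis_gaps_bp Gaps (bp) for the designated cis pairs.
#' @param n_antisense_pairs Designated opposite-strand overlapping pairs.
#' @param base_mean_range,triplet_mean_range Log-uniform ranges for baseline
#'   negative-binomial means (background and triplet members respectively).
#' @return A list of class `sim_config` (including the derived noise
#'   calibration in `$calibration`).
#' @export
sim_config <- function(seed = 1L, n_per_group = 3L,
                       n_mrna = 400L, n_lncrna = 150L, n_mirna = 120L,
                       n_de_per_layer = 20L,
                       planted_log2fc = 1.64, nb_dispersion = 0.1,
                       n_triplets = 20L, triplet_rho = -0.85,
                       triplet_r = 0.95,
                       mirna_universe = 80L, shared_targets_per_triplet = 3L,
                       n_background_relations = 300L,
                       latent_jitter_sd = 0.2,
                       calibration_margin = 0.5,
                       n_cis_pairs = 3L,
                       cis_gaps_bp = c(9999L, 10000L, 10001L),
                       n_antisense_pairs = 3L,
                       base_mean_range = c(20, 2000),
                       triplet_mean_range = c(300, 3000)) {
  cfg <- as.list(environment())
  if (n_per_group < 2) stop_("n_per_group must be >= 2")
  if (abs(triplet_rho) > 1 || triplet_r <= -1 || triplet_r > 1) {
    stop_("correlation targets out of range")
  }
  if (nb_dispersion <= 0) stop_("nb_dispersion must be > 0")
  if (length(cis_gaps_bp) != n_cis_pairs) {
    stop_("cis_gaps_bp must have n_cis_pairs entries")
  }
  n_trip_mir <- n_triplets * shared_targets_per_triplet
  if (mirna_universe < n_trip_mir) {
    stop_("mirna_universe must cover the %d planted triplet miRNAs", n_trip_mir)
  }
  if (n_mirna < mirna_universe + n_de_per_layer) {
    stop_("n_mirna too small for the requested universe and DE extras")
  }
  if (n_lncrna < n_triplets + n_de_per_layer + n_cis_pairs + n_antisense_pairs) {
    stop_("n_lncrna too small for triplets, DE extras and designated pairs")
  }
  if (n_mrna < n_triplets + n_de_per_layer + n_cis_pairs + n_antisense_pairs) {
    stop_("n_mrna too small for triplets, DE extras and designated pairs")
  }
  if (calibration_margin <= 0 || calibration_margin > 1) {
    stop_("calibration_margin must be in (0, 1]")
  }
  cfg$calibration <- if (n_triplets > 0) {
    calibrate_triplet_noise(planted_log2fc, latent_jitter_sd,
                            abs(triplet_rho), triplet_r, 2L * n_per_group,
                            min(triplet_mean_range), calibration_margin)
  } else NULL
  structure(cfg, class = "sim_config")
}

# invert the bivariate-normal expected sample Spearman at size n
pearson_for_target_spearman <- function(rs, n) {
  f <- function(p) 6 / (pi * (n + 1)) * (asin(p) + (n - 2) * asin(p / 2)) - rs
  stats::uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
}

# moment calibration of triplet member noise on the log2 scale
calibrate_triplet_noise <- function(delta, sw, rs_target, r_target, n, mu_min,
                                    margin = 1) {
  gcent <- rep(c(0.5, -0.5), each = n / 2)
  vs <- delta^2 * var(gcent) + sw^2
  rho_mc <- pearson_for_target_spearman(rs_target, n)
  if (rho_mc^2 >= r_target) {
    stop_(paste0("infeasible correlation targets: implied miRNA noise ",
                 "variance <= 0 (Spearman target too strong for the Pearson ",
                 "target)"))
  }
  # approximate Poisson sampling noise on the log2 scale at the smallest
  # planted mean; subtracted so realized correlations land on target
  pois_var <- 1 / (mu_min * log(2)^2)
  sigma_e2 <- max(vs * (1 / r_target - 1) - pois_var, 0)
  sigma_q2 <- vs * (r_target / rho_mc^2 - 1) - pois_var
  if (sigma_q2 <= 0) {
    stop_("infeasible correlation targets at the configured baseline means")
  }
  list(delta = delta, sigma_w = sw, v_signal = vs, rho_mc = rho_mc,
       sigma_e = margin * sqrt(sigma_e2), sigma_q = margin * sqrt(sigma_q2))
}

rna_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGUT", "UGCAA", toupper(s)), "")[[1]]),
        collapse = "")
}

random_rna <- function(n_seq, len) {
  vapply(seq_len(n_seq), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate a synthetic ceRNA study
#'
#' Draws count matrices for the three RNA layers, a design table, a gene-level
#' annotation, sequence sets, a target-relation table and a truth table, with
#' the statistical structure every pipeline stage assumes: negative-binomial
#' background counts, planted DE features at the configured fold change,
#' planted ceRNA triplets driven by a shared latent factor (see
#' [sim_config()]), designated cis pairs straddling the 10 kb boundary and
#' designated antisense overlaps with exactly complementary sequence.
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `cerna_sim` with elements `config`, `counts`
#'   (list of three [expression_matrix()] objects), `design`, `annotation`,
#'   `relations`, `sequences` (lists `mirna`, `utr`, `lncrna`, `gene`) and
#'   `truth` (planted DE features with signs, planted triplets, planted
#'   relations, designated cis/antisense pairs).
#' @export
simulate_cerna_data <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_impl(config))
}

simulate_impl <- function(cfg) {
  n <- cfg$n_per_group
  samples <- c(paste0("H", seq_len(n)), paste0("L", seq_len(n)))
  is_high <- rep(c(TRUE, FALSE), each = n)
  design <- tibble::tibble(sample_id = samples,
                           group = ifelse(is_high, "HIGH", "LOW"))
  ids <- list(
    mRNA = sprintf("gene%04d", seq_len(cfg$n_mrna)),
    lncRNA = sprintf("lnc%04d", seq_len(cfg$n_lncrna)),
    miRNA = sprintf("mir%04d", seq_len(cfg$n_mirna))
  )
  tt <- cfg$n_triplets
  ss <- cfg$shared_targets_per_triplet

  trip_lnc <- ids$lncRNA[seq_len(tt)]
  trip_mrna <- ids$mRNA[seq_len(tt)]
  trip_mir <- if (tt > 0) {
    lapply(seq_len(tt), function(t) ids$miRNA[seq((t - 1) * ss + 1, t * ss)])
  } else list()
  n_trip_mir <- tt * ss
  de_extra <- list(
    mRNA = ids$mRNA[seq_len(cfg$n_de_per_layer) + tt],
    lncRNA = ids$lncRNA[seq_len(cfg$n_de_per_layer) + tt],
    miRNA = ids$miRNA[seq_len(cfg$n_de_per_layer) + n_trip_mir]
  )
  if (cfg$n_de_per_layer == 0) de_extra <- lapply(de_extra, function(x) character())

  # baseline means and background counts (negative binomial)
  draw_layer <- function(layer_ids, triplet_ids) {
    mu <- exp(runif(length(layer_ids), log(cfg$base_mean_range[1]),
                    log(cfg$base_mean_range[2])))
    names(mu) <- layer_ids
    mu[triplet_ids] <- exp(runif(length(triplet_ids),
                                 log(cfg$triplet_mean_range[1]),
                                 log(cfg$triplet_mean_range[2])))
    mu
  }
  mu <- list(
    mRNA = draw_layer(ids$mRNA, trip_mrna),
    lncRNA = draw_layer(ids$lncRNA, trip_lnc),
    miRNA = draw_layer(ids$miRNA, unlist(trip_mir))
  )

  de_sign <- function(extra_ids) {
    if (length(extra_ids) == 0) return(tibble::tibble(feature_id = character(),
                                                      sign = character()))
    tibble::tibble(feature_id = extra_ids,
                   sign = rep_len(c("up", "down"), length(extra_ids)))
  }
  extra_signs <- lapply(de_extra, de_sign)

  base_counts <- function(layer) {
    m <- matrix(0, length(ids[[layer]]), 2 * n,
                dimnames = list(ids[[layer]], samples))
    fc_mult <- rep(1, length(ids[[layer]]))
    names(fc_mult) <- ids[[layer]]
    es <- extra_signs[[layer]]
    for (i in seq_len(nrow(es))) {
      fc_mult[es$feature_id[i]] <-
        2^(ifelse(es$sign[i] == "up", 1, -1) * cfg$planted_log2fc)
    }
    for (i in seq_len(nrow(m))) {
      mu_i <- rep(mu[[layer]][i], 2 * n)
      mu_i[is_high] <- mu_i[is_high] * fc_mult[i]
      m[i, ] <- rnbinom(2 * n, mu = mu_i, size = 1 / cfg$nb_dispersion)
    }
    m
  }
  counts <- list(mRNA = base_counts("mRNA"), lncRNA = base_counts("lncRNA"),
                 miRNA = base_counts("miRNA"))

  # planted triplets: shared latent factor, calibrated noise, Poisson counts
  trip_sign <- rep_len(c(1, -1), tt) # miRNA direction in the HIGH group
  cal <- cfg$calibration
  gcent <- ifelse(is_high, 0.5, -0.5)
  triplets <- tibble::tibble(lncrna_id = character(), mirna_id = character(),
                             mrna_id = character(), primary = logical())
  for (t in seq_len(tt)) {
    z <- cal$delta * gcent + rnorm(2 * n, 0, cal$sigma_w)
    s <- trip_sign[t]
    plant <- function(layer, id, direction, sigma) {
      log2mu <- log2(mu[[layer]][id]) + direction * z +
        rnorm(2 * n, 0, sigma)
      counts[[layer]][id, ] <<- rpois(2 * n, 2^log2mu)
    }
    for (m_id in trip_mir[[t]]) plant("miRNA", m_id, s, cal$sigma_q)
    plant("lncRNA", trip_lnc[t], -s, cal$sigma_e)
    plant("mRNA", trip_mrna[t], -s, cal$sigma_e)
    triplets <- dplyr::bind_rows(triplets, tibble::tibble(
      lncrna_id = trip_lnc[t], mirna_id = trip_mir[[t]],
      mrna_id = trip_mrna[t],
      primary = seq_along(trip_mir[[t]]) == 1
    ))
  }

  trip_de <- function(layer) {
    if (tt == 0) return(tibble::tibble(feature_id = character(), sign = character()))
    switch(layer,
      miRNA = tibble::tibble(feature_id = unlist(trip_mir),
                             sign = rep(ifelse(trip_sign > 0, "up", "down"),
                                        each = ss)),
      lncRNA = tibble::tibble(feature_id = trip_lnc,
                              sign = ifelse(trip_sign > 0, "down", "up")),
      mRNA = tibble::tibble(feature_id = trip_mrna,
                            sign = ifelse(trip_sign > 0, "down", "up"))
    )
  }
  de_features <- lapply(stats::setNames(names(ids), names(ids)), function(layer) {
    dplyr::bind_rows(trip_de(layer), extra_signs[[layer]])
  })

  # target relations: planted (each shared miRNA -> both ceRNAs) + background
  planted_rel <- if (tt > 0) {
    dplyr::bind_rows(
      tibble::tibble(regulator_id = triplets$mirna_id,
                     target_id = triplets$lncrna_id,
                     mechanism = "seed_match", score = 1),
      tibble::tibble(regulator_id = triplets$mirna_id,
                     target_id = triplets$mrna_id,
                     mechanism = "seed_match", score = 1)
    )
  } else empty_relations()
  mir_pool <- ids$miRNA[seq_len(cfg$mirna_universe)]
  target_pool <- c(ids$lncRNA, ids$mRNA)
  bg <- tibble::tibble(
    regulator_id = sample(mir_pool, cfg$n_background_relations, replace = TRUE),
    target_id = sample(target_pool, cfg$n_background_relations, replace = TRUE),
    mechanism = "seed_match", score = 1
  )
  bg <- dplyr::anti_join(dplyr::distinct(bg),
                         planted_rel[, c("regulator_id", "target_id")],
                         by = c("regulator_id", "target_id"))
  relations <- dplyr::bind_rows(planted_rel, bg)

  # annotation: widely spaced loci, plus designated cis and antisense pairs
  ann <- build_sim_annotation(cfg, ids)

  # sequences
  mir_seqs <- stats::setNames(random_rna(cfg$n_mirna, 22L), ids$miRNA)
  utr_seqs <- stats::setNames(random_rna(cfg$n_mrna, 300L), ids$mRNA)
  for (t in seq_len(tt)) {
    u <- utr_seqs[[trip_mrna[t]]]
    for (j in seq_along(trip_mir[[t]])) {
      site <- rna_revcomp(substr(mir_seqs[[trip_mir[[t]][j]]], 2, 8))
      pos <- 40 + (j - 1) * 30
      substr(u, pos, pos + 6) <- site
    }
    utr_seqs[[trip_mrna[t]]] <- u
  }
  as_seqs <- antisense_sequences(ann$annotation, ann$antisense_pairs)

  truth <- structure(list(
    de_features = de_features,
    triplets = triplets,
    relations = planted_rel,
    cis_pairs = ann$cis_pairs,
    antisense_pairs = ann$antisense_pairs,
    calibration = cal
  ), class = "cerna_truth")

  to_expr <- function(m, layer) {
    df <- tibble::as_tibble(as.data.frame(m), rownames = "feature_id")
    expression_matrix(df, layer = layer, unit = "count")
  }
  structure(list(
    config = cfg,
    counts = list(mRNA = to_expr(counts$mRNA, "mRNA"),
                  lncRNA = to_expr(counts$lncRNA, "lncRNA"),
                  miRNA = to_expr(counts$miRNA, "miRNA")),
    design = design,
    annotation = ann$annotation,
    relations = relations,
    sequences = list(mirna = mir_seqs, utr = utr_seqs,
                     lncrna = as_seqs$lncrna, gene = as_seqs$gene),
    truth = truth
  ), class = "cerna_sim")
}

# place features 50 kb apart per layer chromosome; override designated pairs
build_sim_annotation <- function(cfg, ids) {
  place <- function(layer_ids, chrom, len_range, biotype) {
    k <- length(layer_ids)
    len <- round(runif(k, len_range[1], len_range[2]))
    start <- (seq_len(k) - 1L) * 50000L
    tibble::tibble(feature_id = layer_ids, chrom = chrom, start = start,
                   end = start + len,
                   strand = sample(c("+", "-"), k, replace = TRUE),
                   biotype = biotype, length_bp = len)
  }
  ann <- dplyr::bind_rows(
    place(ids$mRNA, "chr1", c(1000, 3000), "mRNA"),
    place(ids$lncRNA, "chr2", c(500, 2000), "lncRNA"),
    place(ids$miRNA, "chr3", c(70, 120), "miRNA")
  )
  nc <- cfg$n_cis_pairs
  na <- cfg$n_antisense_pairs
  cis_lnc <- rev(ids$lncRNA)[seq_len(nc)]
  cis_gene <- rev(ids$mRNA)[seq_len(nc)]
  as_lnc <- rev(ids$lncRNA)[seq_len(na) + nc]
  as_gene <- rev(ids$mRNA)[seq_len(na) + nc]

  override <- function(ann, id, chrom, start, end, strand) {
    i <- match(id, ann$feature_id)
    ann$chrom[i] <- chrom
    ann$start[i] <- start
    ann$end[i] <- end
    ann$strand[i] <- strand
    ann$length_bp[i] <- end - start
    ann
  }
  cis_pairs <- tibble::tibble(lncrna_id = character(), gene_id = character(),
                              gap_bp = integer(), expected = logical())
  for (p in seq_len(nc)) {
    base <- (p - 1L) * 100000L
    gap <- cfg$cis_gaps_bp[p]
    ann <- override(ann, cis_lnc[p], "chr_cis", base, base + 1000L, "+")
    ann <- override(ann, cis_gene[p], "chr_cis",
                    base + 1000L + gap, base + 2000L + gap, "+")
    cis_pairs <- dplyr::bind_rows(cis_pairs, tibble::tibble(
      lncrna_id = cis_lnc[p], gene_id = cis_gene[p], gap_bp = gap,
      expected = gap <= 10000L
    ))
  }
  as_pairs <- tibble::tibble(lncrna_id = character(), gene_id = character(),
                             overlap_bp = integer())
  for (p in seq_len(na)) {
    base <- (p - 1L) * 100000L
    ann <- override(ann, as_gene[p], "chr_as", base, base + 2000L, "+")
    ann <- override(ann, as_lnc[p], "chr_as", base + 500L, base + 1500L, "-")
    as_pairs <- dplyr::bind_rows(as_pairs, tibble::tibble(
      lncrna_id = as_lnc[p], gene_id = as_gene[p], overlap_bp = 1000L
    ))
  }
  list(annotation = ann, cis_pairs = cis_pairs, antisense_pairs = as_pairs)
}

# exactly complementary sequences for designated antisense pairs: both
# features read off the same genomic span on opposite strands
antisense_sequences <- function(ann, as_pairs) {
  lnc <- list(); gene <- list()
  for (p in seq_len(nrow(as_pairs))) {
    ga <- ann[ann$feature_id == as_pairs$gene_id[p], ]
    la <- ann[ann$feature_id == as_pairs$lncrna_id[p], ]
    genome <- strsplit(paste(sample(c("A", "C", "G", "U"),
                                    ga$end - min(ga$start, la$start),
                                    replace = TRUE), collapse = ""), "")[[1]]
    span <- function(a) {
      idx <- seq(a$start - min(ga$start, la$start) + 1L,
                 a$end - min(ga$start, la$start))
      s <- paste(genome[idx], collapse = "")
      if (a$strand == "+") s else rna_revcomp(s)
    }
    gene[[ga$feature_id]] <- span(ga)
    lnc[[la$feature_id]] <- span(la)
  }
  list(lncrna = unlist(lnc) %||% character(),
       gene = unlist(gene) %||% character())
}
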