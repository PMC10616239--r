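small_cfg <- function(seed = 1, ...) {
  defaults <- list(seed = seed, n_mrna = 80L, n_lncrna = 40L, n_mirna = 40L,
                   n_de_per_layer = 5L, n_triplets = 5L, mirna_universe = 20L,
                   n_background_relations = 50L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("the generator is deterministic given the seed", {
  a <- simulate_cerna_data(small_cfg(4))
  b <- simulate_cerna_data(small_cfg(4))
  expect_identical(a$counts, b$counts)
  expect_identical(a$relations, b$relations)
  expect_identical(a$truth$triplets, b$truth$triplets)
  expect_identical(a$sequences, b$sequences)
  c_ <- simulate_cerna_data(small_cfg(5))
  expect_false(identical(expr_values(a$counts$mRNA), expr_values(c_$counts$mRNA)))
})

test_that("generated matrices satisfy the expression-matrix invariants", {
  sim <- simulate_cerna_data(small_cfg(2))
  for (layer in names(sim$counts)) {
    x <- sim$counts[[layer]]
    v <- expr_values(x)
    expect_false(anyDuplicated(rownames(v)) > 0)
    expect_true(all(v >= 0 & is.finite(v)))
    expect_true(all(v == round(v)))
    expect_identical(expr_unit(x), "count")
  }
  expect_setequal(sim$design$group, c("HIGH", "LOW"))
  expect_equal(nrow(sim$annotation),
               sum(vapply(sim$counts, nrow, integer(1))))
})

test_that("zero triplets gives an empty triplet truth table", {
  sim <- simulate_cerna_data(small_cfg(3, n_triplets = 0L))
  expect_equal(nrow(sim$truth$triplets), 0)
  expect_equal(nrow(sim$truth$relations), 0)
})

test_that("planted correlations clear the screen thresholds for >= 90% of triplets", {
  rates <- vapply(1:10, function(sd) {
    sim <- simulate_cerna_data(sim_config(seed = sd))
    tr <- sim$truth$triplets
    mv <- expr_values(sim$counts$miRNA)
    lv <- expr_values(sim$counts$lncRNA)
    gv <- expr_values(sim$counts$mRNA)
    rho <- c(
      vapply(seq_len(nrow(tr)), function(i)
        cor(mv[tr$mirna_id[i], ], lv[tr$lncrna_id[i], ], method = "spearman"),
        numeric(1)),
      vapply(seq_len(nrow(tr)), function(i)
        cor(mv[tr$mirna_id[i], ], gv[tr$mrna_id[i], ], method = "spearman"),
        numeric(1))
    )
    r <- vapply(seq_len(nrow(tr)), function(i)
      cor(lv[tr$lncrna_id[i], ], gv[tr$mrna_id[i], ]), numeric(1))
    c(mean(rho <= -0.7), mean(r > 0.9))
  }, numeric(2))
  expect_gte(mean(rates[1, ]), 0.9)
  expect_gte(mean(rates[2, ]), 0.9)
})

test_that("planted shared-target relations give small hypergeometric p, decoys do not", {
  sim <- simulate_cerna_data(sim_config(seed = 6))
  rel <- sim$relations
  edges <- tibble::tibble(
    mirna_id = rel$regulator_id, cerna_id = rel$target_id,
    cerna_class = ifelse(startsWith(rel$target_id, "lnc"), "lncRNA", "mRNA"),
    spearman_rho = -1
  )
  tr <- unique(sim$truth$triplets[, c("lncrna_id", "mrna_id")])
  planted <- hypergeom_shared_test(
    tibble::tibble(lncrna_id = tr$lncrna_id, mrna_id = tr$mrna_id, pearson_r = 1),
    edges)
  expect_true(all(planted$hypergeom_p <= 0.05))
  withr::with_seed(1, {
    decoys <- tibble::tibble(
      lncrna_id = sample(unique(edges$cerna_id[edges$cerna_class == "lncRNA"]), 40,
                         replace = TRUE),
      mrna_id = sample(unique(edges$cerna_id[edges$cerna_class == "mRNA"]), 40,
                       replace = TRUE),
      pearson_r = 1
    )
    decoys <- dplyr::anti_join(decoys, tr, by = c("lncrna_id", "mrna_id"))
    dp <- hypergeom_shared_test(decoys, edges)
    expect_gte(median(dp$hypergeom_p), 0.3)
  })
})

test_that("truth-table cis labels agree with predict_cis on the generated GTF", {
  sim <- simulate_cerna_data(small_cfg(7))
  path <- tempfile(fileext = ".gtf")
  write_annotation_gtf(sim$annotation, path)
  ann <- read_annotation(path)
  got <- predict_cis(ann[ann$biotype == "lncRNA", ], ann[ann$biotype == "mRNA", ])
  key <- paste(got$regulator_id, got$target_id)
  for (i in seq_len(nrow(sim$truth$cis_pairs))) {
    pair <- sim$truth$cis_pairs[i, ]
    expect_equal(paste(pair$lncrna_id, pair$gene_id) %in% key, pair$expected,
                 info = sprintf("gap %d", pair$gap_bp))
  }
})

test_that("designated antisense pairs are recovered with perfect complementarity", {
  sim <- simulate_cerna_data(small_cfg(8))
  ann <- sim$annotation
  got <- predict_antisense(ann[ann$biotype == "lncRNA", ],
                           ann[ann$biotype == "mRNA", ],
                           sim$sequences$lncrna, sim$sequences$gene)
  expect_setequal(paste(got$regulator_id, got$target_id),
                  paste(sim$truth$antisense_pairs$lncrna_id,
                        sim$truth$antisense_pairs$gene_id))
  expect_true(all(got$score == 1))
})

test_that("planted seed sites are found in the generated miRNA/UTR sequences", {
  sim <- simulate_cerna_data(small_cfg(9))
  pred <- predict_seed_targets(sim$sequences$mirna, sim$sequences$utr)
  planted <- sim$truth$triplets
  key <- paste(pred$regulator_id, pred$target_id)
  expect_true(all(paste(planted$mirna_id, planted$mrna_id) %in% key))
})

test_that("with no planted effect the DE hit rate matches the nominal level", {
  sim <- simulate_cerna_data(sim_config(
    seed = 10, n_mrna = 2000L, n_lncrna = 30L, n_mirna = 30L,
    n_de_per_layer = 0L, n_triplets = 0L, planted_log2fc = 0,
    mirna_universe = 20L
  ))
  res <- de_screen(sim$counts$mRNA, sim$design)
  # p <= 0.05 alone (before the fold-change gate) should be ~5%
  rate <- mean(res$p_value <= 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 2000) + 0.01)
})

test_that("infeasible correlation targets error before sampling", {
  expect_error(sim_config(triplet_rho = -0.999, triplet_r = 0.9),
               "infeasible")
})

test_that("written study files are readable by the package's own readers", {
  sim <- simulate_cerna_data(small_cfg(11))
  dir <- tempfile("simdata")
  write_sim_data(sim, dir)
  mrna <- read_counts(file.path(dir, "counts_mRNA.tsv"), "mRNA")
  expect_identical(expr_values(mrna), expr_values(sim$counts$mRNA))
  ann <- read_annotation(file.path(dir, "annotation.gtf"))
  expect_equal(nrow(ann), nrow(sim$annotation))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(nrow(truth$triplets), nrow(sim$truth$triplets))
})

test_that("recovery evaluation handles perfect, empty and shuffled networks", {
  truth <- list(triplets = tibble::tibble(
    lncrna_id = c("lnc1", "lnc2"), mirna_id = c("m1", "m2"),
    mrna_id = c("g1", "g2")
  ))
  mk_net <- function(trip) {
    nodes <- tibble::tibble(
      id = unique(unlist(trip)),
      rna_class = dplyr::case_when(
        startsWith(unique(unlist(trip)), "m") ~ "miRNA",
        startsWith(unique(unlist(trip)), "lnc") ~ "lncRNA",
        .default = "mRNA"
      )
    )
    edges <- purrr::map_dfr(seq_len(nrow(trip)), function(i) {
      tibble::tibble(
        source = c(trip$mirna_id[i], trip$mirna_id[i], trip$lncrna_id[i]),
        target = c(trip$lncrna_id[i], trip$mrna_id[i], trip$mrna_id[i]),
        edge_type = c("mirna_target", "mirna_target", "cerna_pair"),
        statistic = c(-0.9, -0.9, 0.95), p_value = c(NA, NA, 0.01)
      )
    })
    cerna_network(nodes, dplyr::distinct(edges))
  }
  perfect <- evaluate_recovery(mk_net(truth$triplets), truth)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$false_discovery_proportion, 0)

  empty <- assemble_network(
    tibble::tibble(mirna_id = character(), cerna_id = character(),
                   cerna_class = character(), spearman_rho = numeric()),
    tibble::tibble(lncrna_id = character(), mrna_id = character(),
                   pearson_r = numeric(), shared_mirnas = list(),
                   k_shared = integer(), K_lnc = integer(), n_mrna = integer(),
                   N_universe = integer(), hypergeom_p = numeric())
  )
  ev0 <- evaluate_recovery(empty, truth)
  expect_equal(ev0$recall, 0)
  expect_equal(ev0$false_discovery_proportion, 0)

  wrong <- truth$triplets
  wrong$mirna_id <- rev(wrong$mirna_id)
  evw <- evaluate_recovery(mk_net(wrong), truth)
  expect_equal(evw$recall, 0)
  expect_equal(evw$false_discovery_proportion, 1)
})
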