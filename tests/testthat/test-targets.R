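test_that("cis prediction includes gap 10000 and excludes gap 10001", {
  lnc <- ann_row("lnc1", "chr1", 1000, 2000, biotype = "lncRNA")
  g_in <- ann_row("geneA", "chr1", 12000, 13000)
  g_out <- ann_row("geneB", "chr1", 12001, 13001)
  hit <- predict_cis(lnc, g_in)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$score, 10000)
  expect_equal(nrow(predict_cis(lnc, g_out)), 0)
})

test_that("cis prediction matches a quadratic all-pairs gap oracle", {
  withr::with_seed(77, {
    mk <- function(prefix, n) {
      chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
      start <- sample.int(60000, n)
      len <- sample(200:3000, n)
      ann_row(sprintf("%s%03d", prefix, seq_len(n)), chrom, start, start + len,
              strand = sample(c("+", "-"), n, replace = TRUE))
    }
    lnc <- mk("lnc", 50)
    gene <- mk("g", 50)
    got <- predict_cis(lnc, gene, radius_bp = 10000)
    # oracle: interval gap from the definition, all pairs
    oracle <- list()
    for (i in seq_len(nrow(lnc))) {
      for (j in seq_len(nrow(gene))) {
        if (lnc$chrom[i] != gene$chrom[j]) next
        gap <- max(lnc$start[i], gene$start[j]) -
          min(lnc$end[i], gene$end[j])
        gap <- max(gap, 0)
        if (gap <= 10000) {
          oracle[[length(oracle) + 1]] <-
            c(lnc$feature_id[i], gene$feature_id[j], gap)
        }
      }
    }
    oracle <- do.call(rbind, oracle)
    expect_equal(nrow(got), nrow(oracle))
    key_got <- paste(got$regulator_id, got$target_id, got$score)
    key_or <- paste(oracle[, 1], oracle[, 2], as.numeric(oracle[, 3]))
    expect_setequal(key_got, key_or)
  })
})

test_that("cis prediction is symmetric up to regulator/target relabeling", {
  withr::with_seed(9, {
    sa <- sample.int(40000, 20)
    sb <- sample.int(40000, 20)
    a <- ann_row(sprintf("a%02d", 1:20), "chr1", sa, sa + 1000)
    b <- ann_row(sprintf("b%02d", 1:20), "chr1", sb, sb + 1000)
    ab <- predict_cis(a, b)
    ba <- predict_cis(b, a)
    expect_setequal(paste(ab$regulator_id, ab$target_id, ab$score),
                    paste(ba$target_id, ba$regulator_id, ba$score))
  })
})

test_that("antisense candidates require opposite strands and overlap", {
  lnc_plus <- ann_row("lnc1", "chr1", 100, 600, "+", "lncRNA")
  gene_plus <- ann_row("g1", "chr1", 400, 900, "+")
  gene_minus <- ann_row("g2", "chr1", 400, 900, "-")
  gene_far <- ann_row("g3", "chr1", 5000, 5500, "-")
  expect_equal(nrow(predict_antisense(lnc_plus, gene_plus)), 0)
  expect_equal(nrow(predict_antisense(lnc_plus, gene_far)), 0)
  hit <- predict_antisense(lnc_plus, gene_minus)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$score, 200) # overlap length without sequences
})

test_that("exact reverse-complement overlap scores 1.0", {
  lnc <- ann_row("lnc1", "chr1", 0, 12, "+", "lncRNA")
  gene <- ann_row("g1", "chr1", 0, 12, "-")
  lseq <- c(lnc1 = "AUGGCCUUAGCA")
  gseq <- c(g1 = "UGCUAAGGCCAU") # reverse complement of lseq
  hit <- predict_antisense(lnc, gene, lseq, gseq)
  expect_equal(hit$score, 1.0)
})

test_that("partial complementarity is counted position by position", {
  # overlap of 10 bases; build gene sequence complementary at exactly 6
  lnc <- ann_row("lnc1", "chr1", 0, 10, "+", "lncRNA")
  gene <- ann_row("g1", "chr1", 0, 10, "-")
  lseq <- c(lnc1 = "AAAAAAAAAA")
  # gene 5'->3' (minus strand) pairs position i with lnc position 11-i;
  # U complements A, G does not (G-A is not a pair)
  gseq <- c(g1 = "UUUUUUGGGG")
  hit <- predict_antisense(lnc, gene, lseq, gseq, min_complementarity = 0.5)
  expect_equal(hit$score, 0.6)
  none <- predict_antisense(lnc, gene, lseq, gseq, min_complementarity = 0.7)
  expect_equal(nrow(none), 0)
})

test_that("G-U wobble pairs count only when enabled", {
  lnc <- ann_row("lnc1", "chr1", 0, 4, "+", "lncRNA")
  gene <- ann_row("g1", "chr1", 0, 4, "-")
  lseq <- c(lnc1 = "GGGG")
  gseq <- c(g1 = "UUUU")
  expect_equal(predict_antisense(lnc, gene, lseq, gseq)$score, 1)
  expect_equal(nrow(predict_antisense(lnc, gene, lseq, gseq, gu_wobble = FALSE)), 0)
})

test_that("sequences shorter than the annotated span are a hard error", {
  lnc <- ann_row("lnc1", "chr1", 0, 10, "+", "lncRNA")
  gene <- ann_row("g1", "chr1", 0, 10, "-")
  expect_error(predict_antisense(lnc, gene, c(lnc1 = "AAA"), c(g1 = "UUUUUUUUUU")),
               "shorter than")
})

test_that("trans prediction keeps |r| >= threshold and matches an all-pairs oracle", {
  samples <- sprintf("s%d", 1:6)
  lnc <- toy_counts(c(1, 2, 3, 4, 5, 6), "lnc1", samples, layer = "lncRNA")
  same <- toy_counts(c(2, 4, 6, 8, 10, 12), "g1", samples)
  hit <- predict_trans(lnc, same)
  expect_equal(hit$score, 1)

  withr::with_seed(30, {
    lv <- matrix(rpois(5 * 6, 50), 5, dimnames = list(sprintf("l%d", 1:5), samples))
    gv <- matrix(rpois(8 * 6, 50), 8, dimnames = list(sprintf("g%d", 1:8), samples))
    got <- predict_trans(make_expr(lv, "lncRNA"), make_expr(gv), 0.5, 0.3)
    oracle <- list()
    for (i in 1:5) for (j in 1:8) {
      ct <- cor.test(lv[i, ], gv[j, ])
      if (abs(ct$estimate) >= 0.5 && ct$p.value <= 0.3) {
        oracle[[length(oracle) + 1]] <- c(rownames(lv)[i], rownames(gv)[j])
      }
    }
    oracle <- do.call(rbind, oracle)
    expect_equal(nrow(got), NROW(oracle))
    if (NROW(oracle) > 0) {
      expect_setequal(paste(got$regulator_id, got$target_id),
                      paste(oracle[, 1], oracle[, 2]))
    }
  })
})

test_that("mean-centered orthogonal vectors give r = 0 and are excluded", {
  samples <- sprintf("s%d", 1:4)
  lnc <- toy_counts(c(1, 2, 1, 2), "lnc1", samples, layer = "lncRNA")
  gene <- toy_counts(c(1, 1, 2, 2), "g1", samples)
  expect_equal(nrow(predict_trans(lnc, gene)), 0)
})

test_that("constant features are excluded from trans prediction with a warning", {
  samples <- sprintf("s%d", 1:4)
  lnc <- toy_counts(c(3, 3, 3, 3), "flat", samples, layer = "lncRNA")
  gene <- toy_counts(c(1, 2, 3, 4), "g1", samples)
  expect_warning(out <- predict_trans(lnc, gene), "constant")
  expect_equal(nrow(out), 0)
})

test_that("trans with no-op thresholds returns all non-constant pairs", {
  withr::with_seed(14, {
    samples <- sprintf("s%d", 1:6)
    lv <- matrix(rpois(4 * 6, 30), 4, dimnames = list(sprintf("l%d", 1:4), samples))
    gv <- matrix(rpois(5 * 6, 30), 5, dimnames = list(sprintf("g%d", 1:5), samples))
    got <- predict_trans(make_expr(lv, "lncRNA"), make_expr(gv),
                         r_threshold = 0, p_threshold = 1)
    expect_equal(nrow(got), 20)
  })
})

test_that("seed matching finds the canonical example site", {
  mir <- c(mir1 = "UGAGGUAGUAGGUUGUAUAGUU")
  utr_hit <- c(utr1 = "GGGGCUACCUCAGGGG")
  utr_miss <- c(utr2 = "GGGGGGGGGGGGGGGG")
  hit <- predict_seed_targets(mir, utr_hit)
  expect_equal(hit$target_id, "utr1")
  expect_equal(hit$score, 1)
  expect_equal(nrow(predict_seed_targets(mir, utr_miss)), 0)
  # exhaustive substring oracle on the same sequences
  site <- "CUACCUC"
  expect_equal(
    lengths(gregexpr(gsub("U", "T", site), gsub("U", "T", utr_hit), fixed = TRUE)),
    hit$score, ignore_attr = TRUE
  )
})

test_that("duplicated target regions double the seed-site score", {
  mir <- c(mir1 = "UGAGGUAGUAGGUUGUAUAGUU")
  once <- "AAACUACCUCAAA"
  twice <- c(utr1 = paste0(once, once))
  expect_equal(predict_seed_targets(mir, twice)$score, 2)
})

test_that("seed prediction validates its inputs", {
  expect_error(predict_seed_targets(c(m = "UGAGGUA"), c(u = "AAAA")), "shorter than 8")
  expect_error(predict_seed_targets(c(m = "UGAGGUAXZ"), c(u = "AAAA")), "outside")
  expect_error(predict_seed_targets(c(m = "UGAGGUAGU"), c(u = "AAQA")), "outside")
})

test_that("intersecting predictions keeps exactly the common pairs", {
  rel <- function(r, t) tibble::tibble(regulator_id = r, target_id = t,
                                       mechanism = "seed_match", score = 1)
  a <- rel(c("m1", "m1", "m2"), c("g1", "g2", "g3"))
  b <- rel(c("m1", "m2", "m3"), c("g2", "g3", "g4"))
  both <- intersect_predictions(a, b)
  expect_equal(paste(both$regulator_id, both$target_id), c("m1 g2", "m2 g3"))
  expect_true(all(both$mechanism == "provided"))

  expect_equal(nrow(intersect_predictions(rel("m1", "g1"), rel("m2", "g2"))), 0)
  expect_equal(nrow(intersect_predictions(a, a)), nrow(a)) # idempotence

  withr::with_seed(99, {
    pool <- expand.grid(r = sprintf("m%02d", 1:30), t = sprintf("g%02d", 1:30),
                        stringsAsFactors = FALSE)
    shared <- pool[sample.int(nrow(pool), 10), ]
    only_a <- pool[sample.int(nrow(pool), 90), ]
    only_b <- pool[sample.int(nrow(pool), 90), ]
    a2 <- rel(c(shared$r, only_a$r), c(shared$t, only_a$t))
    b2 <- rel(c(shared$r, only_b$r), c(shared$t, only_b$t))
    got <- intersect_predictions(a2, b2)
    oracle <- intersect(paste(a2$regulator_id, a2$target_id),
                        paste(b2$regulator_id, b2$target_id))
    expect_setequal(paste(got$regulator_id, got$target_id), oracle)
  })
})
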