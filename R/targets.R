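#' Predict cis-acting lncRNA targets by genomic proximity
#'
#' A gene is called a cis target of a lncRNA when both lie on the same
#' chromosome and the gap between their loci is at most `radius_bp` (default
#' 10 kb). The gap is 0 for overlapping or adjacent intervals and otherwise
#' the number of bases strictly between them; a gap of exactly `radius_bp` is
#' included. Strand is ignored and the distance is measured between locus
#' boundaries, not transcription start sites.
#'
#' @param lncrnas,genes Annotation tibbles (0-based half-open, as produced by
#'   [read_annotation()]).
#' @param radius_bp Maximum gap in bases (default 10000).
#' @return A tibble of target relations with columns `regulator_id`,
#'   `target_id`, `mechanism` (`"cis"`) and `score` (the gap in bp).
#' @export
predict_cis <- function(lncrnas, genes, radius_bp = 10000L) {
  if (nrow(lncrnas) == 0 || nrow(genes) == 0) return(empty_relations())
  chroms <- union(lncrnas$chrom, genes$chrom)
  lgr <- annotation_granges(lncrnas, chroms)
  ggr <- annotation_granges(genes, chroms)
  hits <- GenomicRanges::findOverlaps(lgr, ggr, maxgap = radius_bp,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  gap <- GenomicRanges::distance(lgr[qi], ggr[si], ignore.strand = TRUE)
  keep <- !is.na(gap) & gap <= radius_bp &
    lncrnas$feature_id[qi] != genes$feature_id[si]
  rel <- tibble::tibble(
    regulator_id = lncrnas$feature_id[qi][keep],
    target_id = genes$feature_id[si][keep],
    mechanism = "cis",
    score = as.numeric(gap[keep])
  )
  dplyr::arrange(dplyr::distinct(rel), .data$regulator_id, .data$target_id)
}

#' Predict antisense lncRNA targets by opposite-strand overlap
#'
#' Candidate antisense pairs are lncRNA/gene loci that overlap by at least one
#' base on opposite strands. When both sequence sets are supplied, the
#' overlapping span of each feature is extracted (strand-aware, 5'->3'), the
#' gene span is reversed, and the score is the fraction of complementary
#' positions (Watson-Crick plus, optionally, G-U wobble); candidates scoring
#' below `min_complementarity` are dropped. Without sequences the score is the
#' overlap length in bases and all candidates pass.
#'
#' @param lncrnas,genes Annotation tibbles (0-based half-open).
#' @param lnc_seqs,gene_seqs Optional sequences: a named character vector, a
#'   `Biostrings::XStringSet`, or a FASTA file path. Names must match feature
#'   ids; each sequence must be at least as long as its annotated span.
#' @param min_complementarity Minimum complementary fraction (default 0.5).
#' @param gu_wobble Count G-U pairs as complementary (default `TRUE`).
#' @return A tibble of target relations with `mechanism = "antisense"`.
#' @export
predict_antisense <- function(lncrnas, genes, lnc_seqs = NULL, gene_seqs = NULL,
                              min_complementarity = 0.5, gu_wobble = TRUE) {
  if (nrow(lncrnas) == 0 || nrow(genes) == 0) return(empty_relations())
  chroms <- union(lncrnas$chrom, genes$chrom)
  lgr <- annotation_granges(lncrnas, chroms)
  ggr <- annotation_granges(genes, chroms)
  hits <- GenomicRanges::findOverlaps(lgr, ggr, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  opposite <- lncrnas$strand[qi] != genes$strand[si] &
    lncrnas$feature_id[qi] != genes$feature_id[si]
  qi <- qi[opposite]; si <- si[opposite]
  if (length(qi) == 0) return(empty_relations())

  ov_start <- pmax(lncrnas$start[qi], genes$start[si])
  ov_end <- pmin(lncrnas$end[qi], genes$end[si])
  ov_len <- ov_end - ov_start

  if (is.null(lnc_seqs) || is.null(gene_seqs)) {
    rel <- tibble::tibble(
      regulator_id = lncrnas$feature_id[qi],
      target_id = genes$feature_id[si],
      mechanism = "antisense",
      score = as.numeric(ov_len)
    )
    return(dplyr::arrange(dplyr::distinct(rel), .data$regulator_id, .data$target_id))
  }

  lseqs <- as_sequence_set(lnc_seqs)
  gseqs <- as_sequence_set(gene_seqs)
  score <- vapply(seq_along(qi), function(k) {
    li <- qi[k]; gi <- si[k]
    lsub <- feature_subsequence(lseqs, lncrnas[li, ], ov_start[k], ov_end[k])
    gsub <- feature_subsequence(gseqs, genes[gi, ], ov_start[k], ov_end[k])
    complementarity_fraction(lsub, rev(gsub), gu_wobble)
  }, numeric(1))
  keep <- score >= min_complementarity
  rel <- tibble::tibble(
    regulator_id = lncrnas$feature_id[qi][keep],
    target_id = genes$feature_id[si][keep],
    mechanism = "antisense",
    score = score[keep]
  )
  dplyr::arrange(dplyr::distinct(rel), .data$regulator_id, .data$target_id)
}

# extract the 5'->3' characters of `ann`'s sequence over genomic span [s, e)
feature_subsequence <- function(seqs, ann, s, e) {
  seq <- seqs[[ann$feature_id]]
  if (is.null(seq)) stop_("no sequence for feature '%s'", ann$feature_id)
  if (nchar(seq) < ann$end - ann$start) {
    stop_("sequence for '%s' (%d nt) shorter than annotated span (%d bp)",
          ann$feature_id, nchar(seq), ann$end - ann$start)
  }
  if (ann$strand == "+") {
    idx <- seq(s - ann$start + 1L, e - ann$start)
  } else {
    idx <- seq(ann$end - e + 1L, ann$end - s)
  }
  strsplit(seq, "")[[1]][idx]
}

# fraction of complementary positions between two aligned character vectors
complementarity_fraction <- function(a, b, gu_wobble = TRUE) {
  a <- toupper(a); b <- toupper(b)
  a[a == "T"] <- "U"; b[b == "T"] <- "U"
  pairs <- c("AU", "UA", "CG", "GC", if (gu_wobble) c("GU", "UG"))
  mean(paste0(a, b) %in% pairs)
}

# normalize sequence input to a named list of single character strings
as_sequence_set <- function(x) {
  if (inherits(x, "XStringSet")) {
    x <- setNames(as.character(x), names(x))
  } else if (is.character(x) && length(x) == 1 && file.exists(x) && is.null(names(x))) {
    ss <- Biostrings::readBStringSet(x)
    x <- setNames(as.character(ss), names(ss))
  }
  if (!is.character(x) || is.null(names(x))) {
    stop_("sequences must be a named character vector, XStringSet, or FASTA path")
  }
  as.list(x)
}

#' Predict trans-acting lncRNA targets by co-expression
#'
#' A gene is a trans target of a lncRNA when the two are strongly co-expressed
#' regardless of genomic location: `|Pearson r| >= r_threshold` and the
#' correlation-test p-value is at most `p_threshold`, computed over all shared
#' samples. Constant features are excluded with a warning (r is undefined).
#'
#' @param lnc_expr,gene_expr [expression_matrix()] objects over identical
#'   sample sets.
#' @param r_threshold Minimum absolute Pearson correlation (default 0.9).
#' @param p_threshold Maximum correlation-test p-value (default 0.05).
#' @return A tibble of target relations with `mechanism = "trans"` and
#'   `score` = Pearson r.
#' @export
predict_trans <- function(lnc_expr, gene_expr, r_threshold = 0.9,
                          p_threshold = 0.05) {
  lv <- expr_values(lnc_expr)
  gv <- expr_values(gene_expr)
  if (!identical(colnames(lv), colnames(gv))) {
    stop_("lnc_expr and gene_expr must share an identical sample set")
  }
  n <- ncol(lv)
  const_l <- apply(lv, 1, function(z) var(z) == 0)
  const_g <- apply(gv, 1, function(z) var(z) == 0)
  if (any(const_l) || any(const_g)) {
    warn_("%d constant feature(s) excluded from trans prediction (undefined r)",
          sum(const_l) + sum(const_g))
  }
  lv <- lv[!const_l, , drop = FALSE]
  gv <- gv[!const_g, , drop = FALSE]
  if (nrow(lv) == 0 || nrow(gv) == 0) return(empty_relations())
  r <- cor(t(lv), t(gv))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), n - 2)
  p[abs(r) >= 1] <- 0
  keep <- which(abs(r) >= r_threshold & p <= p_threshold, arr.ind = TRUE)
  rel <- tibble::tibble(
    regulator_id = rownames(lv)[keep[, 1]],
    target_id = rownames(gv)[keep[, 2]],
    mechanism = "trans",
    score = r[keep]
  )
  rel <- rel[rel$regulator_id != rel$target_id, , drop = FALSE]
  dplyr::arrange(rel, .data$regulator_id, .data$target_id)
}

#' Predict miRNA targets by 7-mer seed match
#'
#' The seed is positions 2-8 of the mature miRNA (1-based from the 5' end).
#' A target region is a predicted target when it contains at least one exact
#' occurrence of the reverse complement of the seed; the score is the
#' occurrence count (overlapping occurrences included). U and T are treated
#' equivalently.
#'
#' @param mirnas Mature miRNA sequences (named character vector, XStringSet,
#'   or FASTA path); each at least 8 nt, alphabet `A,C,G,U,T,N`.
#' @param utrs Target-region sequences in the same forms.
#' @return A tibble of target relations with `mechanism = "seed_match"` and
#'   `score` = number of seed sites.
#' @export
predict_seed_targets <- function(mirnas, utrs) {
  mirnas <- as_sequence_set(mirnas)
  utrs <- as_sequence_set(utrs)
  check_rna_alphabet <- function(seqs, what) {
    ok <- vapply(seqs, function(s) grepl("^[ACGUTNacgutn]*$", s), logical(1))
    if (any(!ok)) {
      stop_("%s sequence '%s' contains characters outside {A,C,G,U,T,N}",
            what, names(seqs)[!ok][1])
    }
  }
  check_rna_alphabet(mirnas, "miRNA")
  check_rna_alphabet(utrs, "target")
  short <- vapply(mirnas, nchar, integer(1)) < 8
  if (any(short)) {
    stop_("miRNA sequence '%s' is shorter than 8 nt", names(mirnas)[short][1])
  }
  utr_dna <- Biostrings::DNAStringSet(
    vapply(utrs, function(s) gsub("U", "T", toupper(s)), character(1))
  )
  rel <- purrr::map_dfr(names(mirnas), function(m) {
    seed <- substr(gsub("U", "T", toupper(mirnas[[m]])), 2, 8)
    site <- Biostrings::reverseComplement(Biostrings::DNAString(seed))
    counts <- Biostrings::vcountPattern(site, utr_dna)
    hit <- counts >= 1 & names(utrs) != m
    tibble::tibble(regulator_id = m, target_id = names(utrs)[hit],
                   mechanism = "seed_match", score = as.numeric(counts[hit]))
  })
  if (nrow(rel) == 0) return(empty_relations())
  dplyr::arrange(rel, .data$regulator_id, .data$target_id)
}

#' Intersect two target-prediction tables
#'
#' Keeps the (regulator, target) pairs present in both inputs — the
#' "common genes predicted by both predictors" rule used to finalize miRNA
#' target sets. The mechanism is set to `"provided"` and the output is
#' ordered by regulator, then target.
#'
#' @param pred_a,pred_b Target-relation tibbles (columns `regulator_id`,
#'   `target_id`, anything else ignored).
#' @return A tibble of target relations with `mechanism = "provided"` and
#'   `score = 0`.
#' @export
intersect_predictions <- function(pred_a, pred_b) {
  a <- dplyr::distinct(pred_a[, c("regulator_id", "target_id")])
  b <- dplyr::distinct(pred_b[, c("regulator_id", "target_id")])
  both <- dplyr::inner_join(a, b, by = c("regulator_id", "target_id"))
  out <- tibble::tibble(regulator_id = both$regulator_id,
                        target_id = both$target_id,
                        mechanism = "provided", score = 0)
  dplyr::arrange(out, .data$regulator_id, .data$target_id)
}

empty_relations <- function() {
  tibble::tibble(regulator_id = character(), target_id = character(),
                 mechanism = character(), score = numeric())
}
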