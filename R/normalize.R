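#' Tags-per-million normalization for miRNA counts
#'
#' Converts a miRNA count matrix to tags per million: for each sample,
#' `TPM_i = count_i * 1e6 / sum_j(count_j)`. The per-sample library size is
#' the column sum of the supplied matrix, so every TPM column sums to 1e6.
#'
#' @param counts An [expression_matrix()] with `unit = "count"`.
#' @return An [expression_matrix()] with `unit = "TPM"`, same dimensions and
#'   ordering.
#' @examples
#' m <- matrix(c(2L, 3L, 5L), 3, dimnames = list(c("a", "b", "c"), "s1"))
#' compute_tpm(expression_matrix(m, "miRNA", "count"))
#' @export
compute_tpm <- function(counts) {
  stopifnot(inherits(counts, "cerna_expr"))
  if (expr_unit(counts) != "count") stop_("compute_tpm expects a count matrix")
  v <- expr_values(counts)
  lib <- colSums(v)
  if (any(lib == 0)) {
    stop_("all-zero sample column: %s",
          paste(colnames(v)[lib == 0], collapse = ", "))
  }
  tpm <- sweep(v, 2, lib, "/") * 1e6
  out <- tibble::tibble(feature_id = rownames(tpm))
  out <- dplyr::bind_cols(out, tibble::as_tibble(tpm))
  expression_matrix(out, layer = expr_layer(counts), unit = "TPM")
}

#' FPKM normalization for mRNA/lncRNA counts
#'
#' Computes fragments per kilobase of transcript per million mapped reads:
#' `FPKM = count * 1e9 / (length_bp * library_size)`, with the library size
#' taken as the column sum of the supplied counts and the effective length
#' taken from the annotation's `length_bp`. FPKM is invariant under uniform
#' scaling of a sample's counts.
#'
#' @param counts An [expression_matrix()] with `unit = "count"`.
#' @param annotation Annotation tibble from [read_annotation()] (or with the
#'   same columns); every feature of `counts` must appear with
#'   `length_bp >= 1`.
#' @return An [expression_matrix()] with `unit = "FPKM"`.
#' @export
compute_fpkm <- function(counts, annotation) {
  stopifnot(inherits(counts, "cerna_expr"))
  if (expr_unit(counts) != "count") stop_("compute_fpkm expects a count matrix")
  v <- expr_values(counts)
  idx <- match(rownames(v), annotation$feature_id)
  if (anyNA(idx)) {
    stop_("features missing from annotation: %s",
          paste(rownames(v)[is.na(idx)], collapse = ", "))
  }
  len <- annotation$length_bp[idx]
  if (any(len < 1)) stop_("annotation length_bp must be >= 1")
  lib <- colSums(v)
  if (any(lib == 0)) {
    stop_("all-zero sample column: %s",
          paste(colnames(v)[lib == 0], collapse = ", "))
  }
  fpkm <- sweep(v / len, 2, lib, "/") * 1e9
  out <- tibble::tibble(feature_id = rownames(fpkm))
  out <- dplyr::bind_cols(out, tibble::as_tibble(fpkm))
  expression_matrix(out, layer = expr_layer(counts), unit = "FPKM")
}
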