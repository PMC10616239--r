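# shared fixture builders (all data generated in code)

make_expr <- function(m, layer = "mRNA", unit = "count") {
  expression_matrix(m, layer = layer, unit = unit)
}

# small count matrix with named features/samples
toy_counts <- function(values, features, samples, layer = "mRNA") {
  m <- matrix(values, nrow = length(features), byrow = TRUE,
              dimnames = list(features, samples))
  make_expr(m, layer = layer, unit = "count")
}

toy_design <- function(high, low) {
  tibble::tibble(sample_id = c(high, low),
                 group = rep(c("HIGH", "LOW"), c(length(high), length(low))))
}

# annotation row in the internal 0-based half-open convention
ann_row <- function(id, chrom, start, end, strand = "+", biotype = "mRNA") {
  tibble::tibble(feature_id = id, chrom = chrom, start = start, end = end,
                 strand = strand, biotype = biotype, length_bp = end - start)
}

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# independent oracle: upper-tail hypergeometric by exhaustive enumeration
# over all C(N, n) draws of n items from a universe with K marked items
enum_hyper_upper <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# independent oracle: permutation p-values by explicit enumeration of all
# group assignments, straight from the definition
enum_perm_p <- function(vals, n_high) {
  l <- log2(vals + 1)
  n <- length(l)
  obs <- mean(l[seq_len(n_high)]) - mean(l[-seq_len(n_high)])
  assigns <- utils::combn(n, n_high)
  diffs <- apply(assigns, 2, function(idx) mean(l[idx]) - mean(l[-idx]))
  mean(abs(diffs) >= abs(obs) - 1e-12)
}
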