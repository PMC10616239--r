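#' Write a synthetic study to disk in standard formats
#'
#' Writes the count matrices (TSV), design table (TSV), gene-level annotation
#' (GTF), target relations (TSV), sequence sets (FASTA) and truth table
#' (JSON) of a [simulate_cerna_data()] result, so the full pipeline can be
#' exercised through its file-based readers.
#'
#' @param sim A `cerna_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_data <- function(sim, dir) {
  stopifnot(inherits(sim, "cerna_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (layer in names(sim$counts)) {
    readr::write_tsv(tibble::as_tibble(sim$counts[[layer]]),
                     file.path(dir, paste0("counts_", layer, ".tsv")),
                     progress = FALSE)
  }
  readr::write_tsv(sim$design, file.path(dir, "design.tsv"), progress = FALSE)
  readr::write_tsv(sim$relations, file.path(dir, "relations.tsv"),
                   progress = FALSE)
  write_annotation_gtf(sim$annotation, file.path(dir, "annotation.gtf"))
  write_fasta <- function(seqs, path) {
    if (length(seqs) == 0) return(invisible(NULL))
    ss <- Biostrings::RNAStringSet(unlist(seqs))
    Biostrings::writeXStringSet(ss, path)
  }
  write_fasta(sim$sequences$mirna, file.path(dir, "mirna.fa"))
  write_fasta(sim$sequences$utr, file.path(dir, "utr.fa"))
  write_fasta(sim$sequences$lncrna, file.path(dir, "lncrna.fa"))
  write_fasta(sim$sequences$gene, file.path(dir, "gene.fa"))
  truth <- sim$truth
  jsonlite::write_json(
    list(de_features = truth$de_features, triplets = truth$triplets,
         relations = truth$relations, cis_pairs = truth$cis_pairs,
         antisense_pairs = truth$antisense_pairs),
    file.path(dir, "truth.json"), dataframe = "rows"
  )
  invisible(dir)
}

#' Write an annotation tibble as GTF
#'
#' Converts the internal 0-based half-open coordinates back to the 1-based
#' inclusive GTF convention at the I/O boundary.
#'
#' @param ann Annotation tibble (columns as from [read_annotation()]).
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(ann, path) {
  gr <- annotation_granges(ann)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "cernet",
    type = "gene",
    gene_id = ann$feature_id,
    gene_biotype = ann$biotype
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
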