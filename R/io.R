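#' Read a count matrix from TSV
#'
#' Reads a tab-separated count matrix whose header row carries sample ids and
#' whose first column carries feature ids. Row and column order are preserved.
#'
#' @param path Path to the TSV file.
#' @param layer RNA layer of the matrix (`"mRNA"`, `"lncRNA"` or `"miRNA"`).
#' @return A [expression_matrix()] with `unit = "count"`.
#' @export
read_counts <- function(path, layer = c("mRNA", "lncRNA", "miRNA")) {
  layer <- match.arg(layer)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        name_repair = "minimal", progress = FALSE)
  if (nrow(df) == 0) stop_("no features in '%s'", path)
  if (ncol(df) < 2) stop_("no sample columns in '%s'", path)
  names(df)[1] <- "feature_id"
  for (j in seq(2, ncol(df))) {
    num <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(num) & !is.na(df[[j]]))
    if (anyNA(df[[j]])) bad <- union(bad, which(is.na(df[[j]])))
    if (length(bad) > 0) {
      stop_("non-numeric cell in '%s' at row %d, column '%s'",
            path, bad[1], names(df)[j])
    }
    df[[j]] <- num
  }
  expression_matrix(df, layer = layer, unit = "count")
}

#' Read gene-level feature annotation from GTF/GFF3
#'
#' Imports a GTF or GFF3 file and returns one row per gene-level record with
#' coordinates converted to the package-internal 0-based half-open convention
#' (`start_internal = start_file - 1`). All downstream interval operations
#' (e.g. [predict_cis()]) consume this convention only.
#'
#' Feature ids are taken from the `gene_id` attribute when present, falling
#' back to `ID`/`Name`; biotypes from `gene_biotype`/`biotype`/`gene_type`,
#' with `protein_coding` mapped to `mRNA` and `lincRNA` to `lncRNA`.
#'
#' @param path Path to a GTF or GFF3 file.
#' @return A tibble with columns `feature_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `biotype`, `length_bp`.
#' @export
read_annotation <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path),
    error = function(e) stop_("failed to parse '%s' (invalid record?): %s",
                              path, conditionMessage(e))
  )
  md <- S4Vectors::mcols(gr)
  if ("type" %in% names(md) && any(as.character(md$type) == "gene")) {
    gr <- gr[as.character(md$type) == "gene"]
    md <- S4Vectors::mcols(gr)
  }
  if (length(gr) == 0) stop_("no gene-level records in '%s'", path)
  pick <- function(...) {
    out <- rep(NA_character_, length(gr))
    for (nm in c(...)) {
      if (nm %in% names(md)) {
        v <- as.character(md[[nm]])
        out <- ifelse(is.na(out), v, out)
      }
    }
    out
  }
  id <- pick("gene_id", "ID", "Name")
  if (anyNA(id)) stop_("record without an id attribute in '%s'", path)
  biotype <- pick("gene_biotype", "biotype", "gene_type")
  biotype <- dplyr::case_match(biotype,
    "protein_coding" ~ "mRNA",
    "lincRNA" ~ "lncRNA",
    .default = biotype
  )
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop_("unknown strand symbol '%s' for feature '%s'",
          strand[!strand %in% c("+", "-")][1], id[!strand %in% c("+", "-")][1])
  }
  tibble::tibble(
    feature_id = id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand,
    biotype = biotype,
    length_bp = BiocGenerics::width(gr)
  )
}

# annotation tibble (0-based half-open) -> GRanges (1-based inclusive);
# seqlevels can be widened so two annotations compare without warnings
annotation_granges <- function(ann, seqlevels = unique(ann$chrom)) {
  GenomicRanges::GRanges(
    seqnames = factor(ann$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand
  )
}

#' Write a ceRNA network to disk
#'
#' Supported formats: `SIF` (Cytoscape simple interaction format with
#' interaction labels `targets` for miRNA-target edges and `ceRNA` for
#' lncRNA-mRNA co-regulation edges), `TSV` (columns `source`, `target`,
#' `edge_type`, `statistic`, `p_value`) and `GraphML` (with node attribute
#' `rna_class`).
#'
#' @param network A [cerna_network()] object.
#' @param path Output file path.
#' @param format One of `"SIF"`, `"GraphML"`, `"TSV"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("SIF", "GraphML", "TSV")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "cerna_network"))
  edges <- network$edges
  if (format == "SIF") {
    label <- ifelse(edges$edge_type == "mirna_target", "targets", "ceRNA")
    out <- tryCatch(
      writeLines(paste(edges$source, label, edges$target, sep = "\t"), path),
      error = function(e) stop_("cannot write '%s': %s", path, conditionMessage(e))
    )
  } else if (format == "TSV") {
    tryCatch(readr::write_tsv(edges, path, progress = FALSE),
             error = function(e) stop_("cannot write '%s': %s", path, conditionMessage(e)))
  } else {
    g <- igraph::graph_from_data_frame(
      d = edges,
      directed = FALSE,
      vertices = data.frame(name = network$nodes$id,
                            rna_class = network$nodes$rna_class)
    )
    tryCatch(igraph::write_graph(g, path, format = "graphml"),
             error = function(e) stop_("cannot write '%s': %s", path, conditionMessage(e)))
  }
  invisible(path)
}

#' Read network edges back from the TSV export
#'
#' @param path Path written by [write_network()] with `format = "TSV"`.
#' @return A tibble with columns `source`, `target`, `edge_type`, `statistic`,
#'   `p_value`.
#' @export
read_network_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    source = readr::col_character(),
    target = readr::col_character(),
    edge_type = readr::col_character(),
    statistic = readr::col_double(),
    p_value = readr::col_double()
  ), progress = FALSE)
}
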