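#' Expression matrices
#'
#' A `cerna_expr` object is a tibble whose first column (`feature_id`) holds
#' unique feature identifiers and whose remaining columns hold non-negative
#' expression values, one column per sample. Two attributes tag the table:
#' `layer` (`"mRNA"`, `"lncRNA"` or `"miRNA"`) and `unit` (`"count"`, `"FPKM"`
#' or `"TPM"`). Count matrices must be integral; missing values are not
#' permitted (absence must be encoded as 0 by the producer).
#'
#' @param values A data frame whose first column is the feature id and whose
#'   remaining columns are numeric sample values, or a numeric matrix with
#'   feature row names and sample column names.
#' @param layer RNA layer of the matrix.
#' @param unit Expression unit of the values.
#'
#' @return A tibble of class `cerna_expr` with attributes `layer` and `unit`.
#' @examples
#' m <- matrix(c(2L, 3L, 5L, 7L), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' expression_matrix(m, layer = "mRNA", unit = "count")
#' @export
expression_matrix <- function(values,
                              layer = c("mRNA", "lncRNA", "miRNA"),
                              unit = c("count", "FPKM", "TPM")) {
  layer <- match.arg(layer)
  unit <- match.arg(unit)
  if (is.matrix(values)) {
    if (is.null(rownames(values)) || is.null(colnames(values))) {
      stop_("matrix input must carry feature row names and sample column names")
    }
    values <- tibble::as_tibble(as.data.frame(values), rownames = "feature_id")
  }
  values <- tibble::as_tibble(values)
  if (ncol(values) < 2) stop_("expression matrix needs at least one sample column")
  names(values)[1] <- "feature_id"
  values$feature_id <- as.character(values$feature_id)
  validate_expr_table(values, unit)
  structure(values,
            class = c("cerna_expr", class(tibble::tibble())),
            layer = layer, unit = unit)
}

validate_expr_table <- function(df, unit) {
  if (nrow(df) == 0) stop_("no features")
  if (anyDuplicated(df$feature_id)) {
    stop_("duplicated feature_id: %s",
          paste(unique(df$feature_id[duplicated(df$feature_id)]), collapse = ", "))
  }
  sample_ids <- names(df)[-1]
  if (anyDuplicated(sample_ids)) {
    stop_("duplicated sample id: %s",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  for (s in sample_ids) {
    v <- df[[s]]
    if (!is.numeric(v)) stop_("sample column '%s' is not numeric", s)
    if (anyNA(v) || any(!is.finite(v))) {
      stop_("sample column '%s' contains missing or non-finite values", s)
    }
    if (any(v < 0)) stop_("sample column '%s' contains negative values", s)
    if (unit == "count" && any(abs(v - round(v)) > 1e-8)) {
      stop_("count matrix has non-integral values in sample '%s'", s)
    }
  }
  invisible(df)
}

#' @rdname expression_matrix
#' @param x A `cerna_expr` object.
#' @export
expr_values <- function(x) {
  m <- as.matrix(as.data.frame(x[, -1, drop = FALSE]))
  rownames(m) <- x$feature_id
  storage.mode(m) <- "double"
  m
}

#' @rdname expression_matrix
#' @export
expr_features <- function(x) x$feature_id

#' @rdname expression_matrix
#' @export
expr_samples <- function(x) names(x)[-1]

#' @rdname expression_matrix
#' @export
expr_layer <- function(x) attr(x, "layer", exact = TRUE)

#' @rdname expression_matrix
#' @export
expr_unit <- function(x) attr(x, "unit", exact = TRUE)

#' @export
print.cerna_expr <- function(x, ...) {
  cat(sprintf("<cerna_expr> layer=%s unit=%s: %d features x %d samples\n",
              expr_layer(x), expr_unit(x), nrow(x), ncol(x) - 1L))
  NextMethod()
}
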