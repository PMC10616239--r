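# internal helpers shared across modules

# run `expr` under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_ <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- rlang::`%||%`

# validate a design table against a set of sample ids
check_design <- function(design, sample_ids) {
  if (!all(c("sample_id", "group") %in% names(design))) {
    stop_("design table must have columns 'sample_id' and 'group'")
  }
  design$group <- as.character(design$group)
  bad <- setdiff(unique(design$group), c("HIGH", "LOW"))
  if (length(bad) > 0) {
    stop_("design group must be 'HIGH' or 'LOW'; found: %s",
          paste(bad, collapse = ", "))
  }
  if (anyDuplicated(design$sample_id)) {
    stop_("duplicated sample_id in design: %s",
          paste(unique(design$sample_id[duplicated(design$sample_id)]), collapse = ", "))
  }
  missing <- setdiff(sample_ids, design$sample_id)
  if (length(missing) > 0) {
    stop_("samples absent from design: %s", paste(missing, collapse = ", "))
  }
  design <- design[match(sample_ids, design$sample_id), , drop = FALSE]
  if (!all(c("HIGH", "LOW") %in% design$group)) {
    stop_("both HIGH and LOW groups must be non-empty")
  }
  tibble::as_tibble(design)
}
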