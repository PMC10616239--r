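#' Relative expression by the Livak 2^-ddCt method
#'
#' Computes relative expression from qPCR cycle-threshold (Ct) records.
#' Replicates are first averaged on the Ct scale within each
#' (role, condition) cell; then `dCt = Ct_target - Ct_reference` per
#' condition, `ddCt = dCt_treated - dCt_control`, and the relative expression
#' is `2^-ddCt`. The reference gene is the normalization control (e.g.
#' beta-actin for mRNA/lncRNA, U6 for miRNA).
#'
#' Identities: `ddCt = 0` gives 1; swapping treated and control inverts the
#' result; adding a constant to every Ct leaves the result unchanged.
#'
#' @param records Tibble with columns `sample_id`, `gene_id`, `ct`
#'   (finite, > 0), `role` (`"target"`/`"reference"`) and `condition`
#'   (`"treated"`/`"control"`).
#' @return A one-row tibble with `delta_ct_treated`, `delta_ct_control`,
#'   `delta_delta_ct` and `relative_expression`.
#' @examples
#' recs <- tibble::tibble(
#'   sample_id = "s1", gene_id = c("g", "ref", "g", "ref"),
#'   ct = c(25, 20, 24, 20),
#'   role = c("target", "reference", "target", "reference"),
#'   condition = c("treated", "treated", "control", "control")
#' )
#' ddct(recs) # 2^-(5 - 4) = 0.5
#' @export
ddct <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("sample_id", "gene_id", "ct", "role", "condition")
  if (!all(need %in% names(records))) {
    stop_("records must have columns %s", paste(need, collapse = ", "))
  }
  if (any(!is.finite(records$ct)) || any(records$ct <= 0)) {
    stop_("ct values must be finite and > 0")
  }
  bad_role <- setdiff(unique(records$role), c("target", "reference"))
  if (length(bad_role) > 0) stop_("unknown role: %s", paste(bad_role, collapse = ", "))
  bad_cond <- setdiff(unique(records$condition), c("treated", "control"))
  if (length(bad_cond) > 0) stop_("unknown condition: %s", paste(bad_cond, collapse = ", "))

  cells <- dplyr::summarise(
    dplyr::group_by(records, .data$role, .data$condition),
    mean_ct = mean(.data$ct), .groups = "drop"
  )
  cell <- function(role, condition) {
    v <- cells$mean_ct[cells$role == role & cells$condition == condition]
    if (length(v) == 0) stop_("missing Ct cell: (%s, %s)", role, condition)
    v
  }
  dct_t <- cell("target", "treated") - cell("reference", "treated")
  dct_c <- cell("target", "control") - cell("reference", "control")
  ddct_val <- dct_t - dct_c
  tibble::tibble(delta_ct_treated = dct_t, delta_ct_control = dct_c,
                 delta_delta_ct = ddct_val,
                 relative_expression = 2^(-ddct_val))
}
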