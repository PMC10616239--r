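#' Two-group differential expression screen
#'
#' Screens every feature for differential expression between the HIGH and LOW
#' groups using the selection rule fold change strictly greater than
#' `fc_threshold` and p-value at most `p_threshold`. All statistics are
#' computed on the `log2(x + 1)` scale; the log2 fold change is the HIGH-group
#' mean minus the LOW-group mean, so up-regulated features carry positive
#' values. A feature at exactly the fold-change threshold is rejected
#' ("more than" is strict).
#'
#' Two test methods are provided as fully specified stand-ins for
#' count-model DE tools:
#' \describe{
#'   \item{`welch_log`}{Welch's two-sample t-test on the log2 scale. When both
#'     group variances are zero the p-value is 0 if the means differ and 1
#'     otherwise.}
#'   \item{`permutation`}{label-permutation null of the mean log2 difference.
#'     When the number of distinct group assignments is at most `n_perm` the
#'     null is enumerated exhaustively (for 3 vs 3 samples: all 20
#'     assignments, so p-values lie on the lattice k/20); otherwise `n_perm`
#'     random assignments are drawn under `seed` and the +1 correction is
#'     applied. Constant features get p = 1 by convention.}
#' }
#'
#' @param x An [expression_matrix()] (any unit; values are log2(x+1)
#'   transformed internally).
#' @param design Tibble with columns `sample_id` and `group`
#'   (`"HIGH"`/`"LOW"`), covering every sample of `x`; each group needs at
#'   least 2 samples.
#' @param fc_threshold Fold-change threshold on the natural scale (default 1.5).
#' @param p_threshold Significance threshold on the p-value (default 0.05).
#' @param method `"welch_log"` or `"permutation"`.
#' @param n_perm Permutation budget (>= 1000 recommended); exhaustive
#'   enumeration is used whenever it fits the budget.
#' @param adjust_p If `TRUE`, add a Benjamini-Hochberg adjusted `p_adj` column
#'   and use it for the significance call.
#' @param seed Seed for sampled (non-exhaustive) permutations.
#' @return A tibble of class `cerna_de` with columns `feature_id`, `log2fc`,
#'   `p_value` (plus `p_adj` if requested), `direction`
#'   (`"up"`/`"down"`/`"none"`) and `significant`.
#' @export
de_screen <- function(x, design, fc_threshold = 1.5, p_threshold = 0.05,
                      method = c("welch_log", "permutation"),
                      n_perm = 1000L, adjust_p = FALSE, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(x, "cerna_expr"))
  v <- expr_values(x)
  design <- check_design(design, colnames(v))
  high <- design$sample_id[design$group == "HIGH"]
  low <- design$sample_id[design$group == "LOW"]
  if (length(high) < 2 || length(low) < 2) {
    stop_("each group needs at least 2 samples (HIGH: %d, LOW: %d)",
          length(high), length(low))
  }
  l <- log2(v + 1)
  lh <- l[, high, drop = FALSE]
  ll <- l[, low, drop = FALSE]
  log2fc <- rowMeans(lh) - rowMeans(ll)

  p <- switch(method,
    welch_log = welch_p(lh, ll),
    permutation = permutation_p(l, colnames(l) %in% high, n_perm, seed)
  )

  res <- tibble::tibble(feature_id = rownames(v), log2fc = unname(log2fc),
                        p_value = p)
  p_use <- res$p_value
  if (adjust_p) {
    res$p_adj <- p.adjust(res$p_value, method = "BH")
    p_use <- res$p_adj
  }
  res$significant <- abs(res$log2fc) > log2(fc_threshold) & p_use <= p_threshold
  res$direction <- dplyr::case_when(
    res$significant & res$log2fc > 0 ~ "up",
    res$significant & res$log2fc < 0 ~ "down",
    .default = "none"
  )
  res <- res[, c("feature_id", "log2fc", "p_value",
                 if (adjust_p) "p_adj", "direction", "significant")]
  structure(res,
            class = c("cerna_de", class(tibble::tibble())),
            layer = expr_layer(x), method = method,
            fc_threshold = fc_threshold, p_threshold = p_threshold)
}

# vectorized Welch two-sample t on rows of two matrices
welch_p <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  va <- apply(a, 1, var); vb <- apply(b, 1, var)
  d <- rowMeans(a) - rowMeans(b)
  se2 <- va / na + vb / nb
  tt <- d / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tt), df)
  zero <- se2 == 0
  p[zero] <- ifelse(d[zero] == 0, 1, 0)
  unname(p)
}

# label-permutation p for |mean difference| on the log scale
permutation_p <- function(l, is_high, n_perm, seed) {
  n <- ncol(l)
  nh <- sum(is_high)
  obs <- rowMeans(l[, is_high, drop = FALSE]) - rowMeans(l[, !is_high, drop = FALSE])
  n_all <- choose(n, nh)
  if (n_all <= n_perm) {
    assigns <- combn(n, nh)
    diffs <- apply(assigns, 2, function(idx) {
      rowMeans(l[, idx, drop = FALSE]) - rowMeans(l[, -idx, drop = FALSE])
    })
    diffs <- matrix(diffs, nrow = nrow(l))
    p <- rowMeans(abs(diffs) >= abs(obs) - 1e-12)
  } else {
    p <- with_seed(seed, {
      hits <- numeric(nrow(l))
      for (b in seq_len(n_perm)) {
        idx <- sample.int(n, nh)
        d <- rowMeans(l[, idx, drop = FALSE]) - rowMeans(l[, -idx, drop = FALSE])
        hits <- hits + (abs(d) >= abs(obs) - 1e-12)
      }
      (1 + hits) / (1 + n_perm)
    })
  }
  unname(p)
}

#' Partition significant features by direction
#'
#' @param results A `cerna_de` tibble from [de_screen()].
#' @return A list with character-vector elements `up` and `down`.
#' @export
split_directions <- function(results) {
  list(up = results$feature_id[results$direction == "up"],
       down = results$feature_id[results$direction == "down"])
}
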