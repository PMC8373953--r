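#' Spearman correlation of risk score with immune-infiltration columns
#'
#' Per (cell type, method) column: Spearman rho via ranked Pearson with
#' midranks, p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`. Raw p-values are reported with a
#' BH-adjusted column alongside. Constant columns are skipped with a
#' warning.
#'
#' @param profile data.frame with `sample_id`, `risk_score`.
#' @param infil Infiltration data.frame (sample ids as row names, columns
#'   named `celltype.method`).
#' @param alpha Significance threshold on the raw p (default 0.05).
#' @return data.frame `cell_type`, `method`, `rho`, `p`, `p_adj`,
#'   `direction`, `significant`.
#' @export
spearman_risk_vs_infiltration <- function(profile, infil, alpha = 0.05) {
  ids <- intersect(profile$sample_id, rownames(infil))
  if (length(ids) < 3) stop("need at least 3 overlapping samples")
  risk <- profile$risk_score[match(ids, profile$sample_id)]
  rows <- lapply(colnames(infil), function(cn) {
    v <- infil[ids, cn]
    keep <- is.finite(v)
    if (sum(keep) < 3 || stats::sd(v[keep]) == 0) {
      warning("constant or insufficient column skipped: ", cn)
      return(NULL)
    }
    rho <- stats::cor(rank(risk[keep]), rank(v[keep]))
    n <- sum(keep)
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    parts <- strsplit(cn, ".", fixed = TRUE)[[1]]
    method <- if (length(parts) > 1) parts[length(parts)] else "unknown"
    cell <- paste(parts[-length(parts)], collapse = ".")
    if (!nzchar(cell)) cell <- cn
    data.frame(cell_type = cell, method = method, rho = rho, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) stop("no usable infiltration columns")
  out$p_adj <- benjamini_hochberg(out$p)
  out$direction <- ifelse(out$rho >= 0, "positive", "negative")
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}

#' Compare one gene's expression between risk groups
#'
#' Wilcoxon rank-sum test on `log2(x + 1)` expression of a single gene
#' (e.g. an immune-checkpoint gene such as CTLA4) between high- and low-risk
#' samples.
#'
#' @param expr An `expression_matrix`.
#' @param gene Gene id (row of `expr`); an absent gene is an error.
#' @param profile Stratified risk profile (`sample_id`, `group`).
#' @return A `wilcoxon_rank_sum` result list, plus `gene`.
#' @export
compare_gene_by_group <- function(expr, gene, profile) {
  if (!gene %in% rownames(expr$values))
    stop("gene absent from expression matrix: ", gene)
  ids <- intersect(profile$sample_id, colnames(expr$values))
  grp <- profile$group[match(ids, profile$sample_id)]
  v <- log2p1(expr$values[gene, ids])
  res <- wilcoxon_rank_sum(v, grp)
  res$gene <- gene
  res
}

#' Compare per-sample score columns between risk groups
#'
#' Per column (IPS variants, per-drug IC50 values): Wilcoxon rank-sum test
#' between high- and low-risk samples, with group medians and a direction
#' flag (`lower_in_high_risk` marks, e.g., higher drug sensitivity in the
#' high-risk group).
#'
#' @param scores Score data.frame (sample ids as row names).
#' @param profile Stratified risk profile (`sample_id`, `group`).
#' @param alpha Significance threshold (default 0.05).
#' @return data.frame `score`, `statistic`, `p`, `p_adj`, `median_low`,
#'   `median_high`, `direction`, `significant`.
#' @export
compare_scores_by_group <- function(scores, profile, alpha = 0.05) {
  ids <- intersect(profile$sample_id, rownames(scores))
  if (length(ids) == 0) stop("no overlapping samples")
  grp <- profile$group[match(ids, profile$sample_id)]
  if (any(table(grp) == 0)) stop("empty risk group")
  rows <- lapply(colnames(scores), function(cn) {
    v <- scores[ids, cn]
    res <- wilcoxon_rank_sum(v, grp)
    m_low <- unname(res$medians["low"]); m_high <- unname(res$medians["high"])
    data.frame(score = cn, statistic = res$statistic, p = res$p,
               median_low = m_low, median_high = m_high,
               direction = if (m_high < m_low) "lower_in_high_risk"
                           else if (m_high > m_low) "higher_in_high_risk"
                           else "equal",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- benjamini_hochberg(out$p)
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}
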