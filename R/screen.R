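#' Identify immune-related lncRNAs by Pearson correlation
#'
#' Correlates each candidate lncRNA with each immune gene on the
#' `log2(x + 1)` scale. A lncRNA is selected when at least one immune gene
#' reaches `|r| > r_min` with two-sided `p < p_max`, the p-value coming from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` against Student's t with `n - 2`
#' degrees of freedom.
#'
#' @param expr An `expression_matrix`.
#' @param immune_genes Character vector of immune gene ids (rows of `expr`);
#'   absent ids are skipped with a warning.
#' @param lncrnas Character vector of candidate lncRNA ids; absent ids are
#'   skipped with a warning.
#' @param r_min Correlation threshold (exclusive), default 0.5.
#' @param p_max P-value threshold (exclusive), default 0.001.
#' @param samples Optional subset of sample ids to correlate over (default:
#'   all samples).
#' @return List with `selected` (character vector of lncRNA ids) and `hits`
#'   (data.frame `lncrna_id`, `immune_gene_id`, `r`, `p` of passing couples).
#' @export
pearson_screen <- function(expr, immune_genes, lncrnas,
                           r_min = 0.5, p_max = 0.001, samples = NULL) {
  vals <- expr$values
  if (!is.null(samples)) vals <- vals[, samples, drop = FALSE]
  n <- ncol(vals)
  if (n < 3) stop("pearson_screen needs at least 3 samples")
  miss_ir <- setdiff(immune_genes, rownames(vals))
  miss_ln <- setdiff(lncrnas, rownames(vals))
  if (length(miss_ir) > 0)
    warning(length(miss_ir), " immune gene(s) absent from matrix, skipped")
  if (length(miss_ln) > 0)
    warning(length(miss_ln), " lncRNA(s) absent from matrix, skipped")
  immune_genes <- intersect(immune_genes, rownames(vals))
  lncrnas <- intersect(lncrnas, rownames(vals))
  if (length(immune_genes) == 0 || length(lncrnas) == 0)
    return(list(selected = character(0),
                hits = data.frame(lncrna_id = character(0),
                                  immune_gene_id = character(0),
                                  r = numeric(0), p = numeric(0))))
  lx <- t(log2p1(vals[lncrnas, , drop = FALSE]))
  ix <- t(log2p1(vals[immune_genes, , drop = FALSE]))
  sd_l <- apply(lx, 2, stats::sd)
  sd_i <- apply(ix, 2, stats::sd)
  if (any(sd_l == 0))
    warning(sum(sd_l == 0), " zero-variance lncRNA(s) skipped (r undefined)")
  if (any(sd_i == 0))
    warning(sum(sd_i == 0), " zero-variance immune gene(s) skipped")
  lx <- lx[, sd_l > 0, drop = FALSE]
  ix <- ix[, sd_i > 0, drop = FALSE]
  if (ncol(lx) == 0 || ncol(ix) == 0)
    return(list(selected = character(0),
                hits = data.frame(lncrna_id = character(0),
                                  immune_gene_id = character(0),
                                  r = numeric(0), p = numeric(0))))
  r <- stats::cor(lx, ix)
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  pass <- abs(r) > r_min & p < p_max
  hit_idx <- which(pass, arr.ind = TRUE)
  hits <- data.frame(lncrna_id = rownames(r)[hit_idx[, 1]],
                     immune_gene_id = colnames(r)[hit_idx[, 2]],
                     r = r[hit_idx], p = p[hit_idx],
                     stringsAsFactors = FALSE)
  hits <- hits[order(hits$p, -abs(hits$r)), , drop = FALSE]
  rownames(hits) <- NULL
  list(selected = unique(hits$lncrna_id), hits = hits)
}

#' Tumor/normal differential expression with a moderated t-statistic
#'
#' Fits a two-group linear model on `log2(x + 1)` values and moderates the
#' per-gene variances with an empirical-Bayes prior (limma's `eBayes`);
#' `method = "welch"` substitutes a plain Welch t-test. P-values are
#' BH-adjusted across all tested genes; a gene is flagged differentially
#' expressed when `|log2fc| > lfc_min` AND `p_adj < alpha`.
#'
#' @param expr An `expression_matrix` with tumor/normal groups assigned.
#' @param genes Optional subset of gene ids to test (default: all rows).
#' @param lfc_min Absolute log2 fold-change threshold (exclusive), default 2.
#' @param alpha Adjusted-p threshold (exclusive), default 0.05.
#' @param method `"moderated"` (default) or `"welch"`.
#' @return data.frame `gene_id`, `log2fc` (tumor minus normal), `p_raw`,
#'   `p_adj`, `direction`, `de`.
#' @export
differential_expression <- function(expr, genes = NULL, lfc_min = 2,
                                    alpha = 0.05,
                                    method = c("moderated", "welch")) {
  method <- match.arg(method)
  grp <- expr$sample_group
  tum <- names(grp)[grp %in% "tumor"]
  nor <- names(grp)[grp %in% "normal"]
  if (length(tum) < 2 || length(nor) < 2)
    stop("both tumor and normal groups need at least 2 samples")
  vals <- expr$values
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(vals))
    if (length(miss) > 0) stop("gene(s) absent from matrix: ",
                               paste(utils::head(miss, 5), collapse = ", "))
    vals <- vals[genes, , drop = FALSE]
  }
  lv <- log2p1(vals[, c(tum, nor), drop = FALSE])
  is_tum <- c(rep(1, length(tum)), rep(0, length(nor)))
  log2fc <- rowMeans(lv[, is_tum == 1, drop = FALSE]) -
    rowMeans(lv[, is_tum == 0, drop = FALSE])
  if (method == "moderated") {
    design <- cbind(intercept = 1, tumor = is_tum)
    fit <- limma::eBayes(limma::lmFit(lv, design))
    p_raw <- fit$p.value[, "tumor"]
  } else {
    p_raw <- apply(lv, 1, function(v) {
      a <- v[is_tum == 1]; b <- v[is_tum == 0]
      if (stats::sd(a) == 0 && stats::sd(b) == 0)
        return(if (mean(a) == mean(b)) 1 else 0)
      stats::t.test(a, b)$p.value
    })
  }
  # a gene flat in both groups with no mean difference carries no evidence
  flat <- apply(lv, 1, stats::sd) == 0 & abs(log2fc) < .Machine$double.eps
  p_raw[flat] <- 1
  p_raw[is.na(p_raw)] <- 1
  p_adj <- benjamini_hochberg(p_raw)
  out <- data.frame(gene_id = rownames(lv), log2fc = log2fc,
                    p_raw = as.numeric(p_raw), p_adj = p_adj,
                    direction = ifelse(log2fc >= 0, "up", "down"),
                    de = abs(log2fc) > lfc_min & p_adj < alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$p_adj, out$p_raw), , drop = FALSE]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order, each at least its raw value and
#'   capped at 1.
#' @export
benjamini_hochberg <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Set intersection with one-sided counts
#'
#' @param a,b Vectors treated as sets.
#' @return List with `both`, `a_only`, `b_only` and a `counts` vector.
#' @export
intersect_sets <- function(a, b) {
  a <- unique(a); b <- unique(b)
  both <- intersect(a, b)
  list(both = both, a_only = setdiff(a, b), b_only = setdiff(b, a),
       counts = c(a = length(a), b = length(b), both = length(both),
                  a_only = length(a) - length(both),
                  b_only = length(b) - length(both)))
}
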