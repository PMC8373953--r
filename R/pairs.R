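#' Build the cyclically-single-paired 0-or-1 matrix
#'
#' For an ordered list of k genes, forms all `choose(k, 2)` unordered pairs,
#' oriented so the earlier gene in the input order is `gene_a`. The entry for
#' pair `A|B` in a sample is 1 when A's expression is strictly higher than
#' B's in that sample, else 0 (ties score 0 under the strict rule). Because
#' only within-sample ranks enter, the matrix is invariant to any strictly
#' monotone per-sample transformation of expression.
#'
#' @param expr An `expression_matrix` or a plain numeric matrix with gene
#'   row names.
#' @param genes Ordered character vector of gene ids (length >= 2, no
#'   duplicates, all present in the matrix).
#' @param samples Optional subset of sample ids.
#' @return A `pair_matrix`: list with `pairs` (data.frame `gene_a`, `gene_b`,
#'   `name`), `indicator` (binary matrix pairs x samples, rownames `"A|B"`),
#'   and `ones_fraction` (named numeric).
#' @export
build_pair_matrix <- function(expr, genes, samples = NULL) {
  vals <- if (inherits(expr, "expression_matrix")) expr$values else expr
  stopifnot(is.matrix(vals))
  if (anyDuplicated(genes)) stop("duplicate gene(s) in pairing list")
  if (length(genes) < 2) stop("need at least 2 genes to build pairs")
  miss <- setdiff(genes, rownames(vals))
  if (length(miss) > 0)
    stop("gene(s) absent from matrix: ", paste(miss, collapse = ", "))
  if (!is.null(samples)) vals <- vals[, samples, drop = FALSE]
  sub <- vals[genes, , drop = FALSE]
  idx <- utils::combn(length(genes), 2)
  indicator <- (sub[idx[1, ], , drop = FALSE] >
                  sub[idx[2, ], , drop = FALSE]) + 0L
  pairs <- data.frame(gene_a = genes[idx[1, ]], gene_b = genes[idx[2, ]],
                      stringsAsFactors = FALSE)
  pairs$name <- paste(pairs$gene_a, pairs$gene_b, sep = "|")
  rownames(indicator) <- pairs$name
  structure(list(pairs = pairs, indicator = indicator,
                 ones_fraction = rowMeans(indicator)),
            class = "pair_matrix")
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("pair_matrix: %d pairs x %d samples; ones-fraction %.2f-%.2f\n",
              nrow(x$indicator), ncol(x$indicator),
              min(x$ones_fraction), max(x$ones_fraction)))
  invisible(x)
}

#' Filter pairs by indicator occupancy
#'
#' Retains pairs whose fraction of 1 entries across samples lies inside the
#' inclusive band `[low, high]`. Pairs that are (almost) always 0 or always 1
#' carry no rank information and are removed. The default 20-80% band is
#' symmetric about 0.5, so retention does not depend on pair orientation
#' (in the absence of ties `ones_fraction(A|B) = 1 - ones_fraction(B|A)`).
#'
#' @param pm A `pair_matrix`.
#' @param low,high Inclusive band endpoints, `low < high`.
#' @return Filtered `pair_matrix`.
#' @export
filter_pairs_by_occupancy <- function(pm, low = 0.20, high = 0.80) {
  stopifnot(inherits(pm, "pair_matrix"))
  if (low >= high) stop("occupancy band requires low < high")
  keep <- pm$ones_fraction >= low & pm$ones_fraction <= high
  structure(list(pairs = pm$pairs[keep, , drop = FALSE],
                 indicator = pm$indicator[keep, , drop = FALSE],
                 ones_fraction = pm$ones_fraction[keep]),
            class = "pair_matrix")
}

#' Write a pair matrix as TSV
#' @param pm A `pair_matrix`.
#' @param path Output path (first column `pair`, one 0/1 column per sample).
#' @export
write_pair_matrix <- function(pm, path) {
  df <- data.frame(pair = rownames(pm$indicator), pm$indicator,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
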