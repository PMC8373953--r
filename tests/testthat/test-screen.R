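make_expr <- function(mat, group = NULL) {
  if (is.null(group)) group <- setNames(rep("tumor", ncol(mat)), colnames(mat))
  expression_matrix(mat, group)
}

test_that("pearson screen matches direct formula and cor.test", {
  x <- 1:10
  y <- x; y[c(3, 7)] <- y[c(7, 3)]
  # the screen works on log2(x+1); invert so the correlated scale is linear
  mat <- rbind(LNC = 2^x - 1, IRG = 2^y - 1)
  colnames(mat) <- paste0("S", 1:10)
  res <- pearson_screen(make_expr(mat), "IRG", "LNC", r_min = 0.1, p_max = 1)
  ct <- stats::cor.test(x, y)
  expect_equal(res$hits$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$hits$p, ct$p.value, tolerance = 1e-12)
  # direct evaluation of the t transform
  r <- res$hits$r
  tt <- r * sqrt(8) / sqrt(1 - r^2)
  expect_equal(res$hits$p, 2 * stats::pt(-abs(tt), df = 8), tolerance = 1e-12)
})

test_that("affine copies are selected and constants are skipped", {
  set.seed(2)
  base <- stats::runif(20, 1, 100)
  mat <- rbind(LNC_copy = 2^(3 + 2 * log2(base + 1)) - 1,
               LNC_flat = rep(5, 20),
               IRG = base)
  colnames(mat) <- paste0("S", 1:20)
  expect_warning(res <- pearson_screen(make_expr(mat), "IRG",
                                       c("LNC_copy", "LNC_flat")),
                 "zero-variance")
  expect_equal(res$selected, "LNC_copy")
  expect_equal(res$hits$r, 1, tolerance = 1e-12)
})

test_that("pearson screen is invariant to sample reordering", {
  set.seed(3)
  mat <- matrix(stats::runif(60, 0, 50), nrow = 3,
                dimnames = list(c("LNC1", "LNC2", "IRG"), paste0("S", 1:20)))
  a <- pearson_screen(make_expr(mat), "IRG", c("LNC1", "LNC2"),
                      r_min = 0, p_max = 1)
  perm <- mat[, sample(20)]
  b <- pearson_screen(make_expr(perm), "IRG", c("LNC1", "LNC2"),
                      r_min = 0, p_max = 1)
  expect_equal(a$hits[order(a$hits$lncrna_id), c("r", "p")],
               b$hits[order(b$hits$lncrna_id), c("r", "p")],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("differential expression recovers planted fold changes", {
  set.seed(4)
  n <- 20
  grp <- setNames(rep(c("tumor", "normal"), each = n), paste0("S", 1:(2 * n)))
  base <- 2^10
  mat <- rbind(
    FOLD6 = c(stats::rnorm(n, 6 * base, 1), stats::rnorm(n, base, 1)),
    NULLG = stats::rnorm(2 * n, base, 50),
    FLAT = rep(100, 2 * n))
  colnames(mat) <- names(grp)
  de <- differential_expression(make_expr(abs(mat), grp))
  row6 <- de[de$gene_id == "FOLD6", ]
  expect_equal(row6$log2fc, log2(6), tolerance = 2e-3)
  expect_true(row6$de)
  expect_equal(row6$direction, "up")
  rown <- de[de$gene_id == "NULLG", ]
  expect_false(rown$de)
  expect_lt(abs(rown$log2fc), 0.5)
  flat <- de[de$gene_id == "FLAT", ]
  expect_equal(flat$p_raw, 1)  # no variance, no mean difference
  expect_false(flat$de)
})

test_that("both DE criteria are required", {
  set.seed(5)
  n <- 10
  grp <- setNames(rep(c("tumor", "normal"), each = n), paste0("S", 1:(2 * n)))
  mat <- matrix(stats::runif(4 * 2 * n, 10, 1000), nrow = 4,
                dimnames = list(paste0("G", 1:4), names(grp)))
  mat[1, 1:n] <- mat[1, 1:n] * 8   # |log2fc| > 2 guaranteed
  de <- differential_expression(make_expr(mat, grp), alpha = 1e-300)
  g1 <- de[de$gene_id == "G1", ]
  expect_gt(abs(g1$log2fc), 2)
  expect_false(g1$de)              # adjusted-p criterion fails by design
  expect_error(differential_expression(make_expr(mat)), "at least 2")
})

test_that("welch fallback agrees with t.test", {
  set.seed(6)
  grp <- setNames(rep(c("tumor", "normal"), each = 5), paste0("S", 1:10))
  mat <- matrix(stats::runif(30, 1, 100), nrow = 3,
                dimnames = list(paste0("G", 1:3), names(grp)))
  de <- differential_expression(make_expr(mat, grp), method = "welch")
  lv <- log2(mat + 1)
  p1 <- stats::t.test(lv[1, 1:5], lv[1, 6:10])$p.value
  expect_equal(de$p_raw[de$gene_id == "G1"], p1, tolerance = 1e-12)
})

test_that("BH adjustment matches the step-up recursion", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  set.seed(8)
  for (i in 1:10) {
    p <- stats::runif(sample(3:40, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, bh_stepup(p), tolerance = 1e-14)
    expect_true(all(adj >= p))             # inflation property
    expect_true(all(adj <= 1))
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= -1e-14))  # monotone in raw p
  }
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("set intersection counts are consistent", {
  a <- paste0("g", 1:91)
  b <- c(paste0("g", 1:15), paste0("h", 1:86))
  res <- intersect_sets(a, b)
  expect_equal(unname(res$counts["both"]), 15)
  expect_equal(unname(res$counts["a_only"]), 76)
  expect_equal(unname(res$counts["b_only"]), 86)
  expect_equal(intersect_sets(a, a)$both, a)
  expect_equal(length(intersect_sets(a, paste0("z", 1:5))$both), 0)
})
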