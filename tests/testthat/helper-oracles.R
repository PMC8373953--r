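# Independent oracles used across the suite. These deliberately avoid the
# code paths (and, where possible, the packages) they are checking.

# Efron-corrected Cox partial log-likelihood for a single covariate,
# written directly from the definition.
efron_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (tt in unique(time[event == 1])) {
    D <- which(time == tt & event == 1)
    R <- which(time >= tt)
    d <- length(D)
    rs <- exp(x[R] * beta)
    ds <- exp(x[D] * beta)
    ll <- ll + sum(x[D]) * beta
    for (l in 0:(d - 1)) ll <- ll - log(sum(rs) - (l / d) * sum(ds))
  }
  ll
}

# brute-force maximizer of the Efron partial likelihood (coarse grid then
# golden-section refinement of the oracle function itself)
brute_cox_beta <- function(x, time, event) {
  grid <- seq(-5, 5, by = 0.05)
  ll <- vapply(grid, efron_loglik, numeric(1), x = x, time = time,
               event = event)
  centre <- grid[which.max(ll)]
  stats::optimize(efron_loglik, c(centre - 0.1, centre + 0.1), maximum = TRUE,
                  tol = 1e-9, x = x, time = time, event = event)$maximum
}

# Benjamini-Hochberg step-up recursion written from the definition
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Mann-Whitney statistic (probability a case outranks a control, ties 0.5)
mw_stat <- function(cases, controls) {
  mean(outer(cases, controls, function(a, b) (a > b) + 0.5 * (a == b)))
}

# small random right-censored survival fixture
random_surv_fixture <- function(n, seed) {
  set.seed(seed)
  list(time = sample(1:25, n, replace = TRUE),
       event = stats::rbinom(n, 1, 0.7),
       group = sample(c("a", "b"), n, replace = TRUE))
}

# assemble a pair_matrix object directly (bypasses build_pair_matrix) so
# tests can control ones-fractions exactly
manual_pair_matrix <- function(indicator) {
  parts <- strsplit(rownames(indicator), "|", fixed = TRUE)
  structure(list(pairs = data.frame(gene_a = vapply(parts, `[`, "", 1),
                                    gene_b = vapply(parts, `[`, "", 2),
                                    name = rownames(indicator),
                                    stringsAsFactors = FALSE),
                 indicator = indicator,
                 ones_fraction = rowMeans(indicator)),
            class = "pair_matrix")
}

# quiet wrappers: these pipelines narrate via message()
quiet <- function(expr) suppressWarnings(suppressMessages(expr))
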