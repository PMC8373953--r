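test_that("fit_cox matches brute-force Efron partial-likelihood maximization", {
  fixtures <- list(
    list(time = c(1, 2, 3, 4, 5, 6, 7, 8),
         event = c(1, 1, 0, 1, 1, 0, 1, 1),
         x = c(1, 1, 0, 0, 1, 0, 0, 0)),
    list(time = c(2, 2, 4, 4, 6, 7, 9),         # tied event times
         event = c(1, 1, 1, 1, 0, 1, 0),
         x = c(1, 0, 1, 1, 0, 0, 1)),
    list(time = c(5, 1, 8, 3, 9, 2),
         event = c(1, 1, 1, 0, 1, 1),
         x = c(0.2, 1.5, -0.3, 0.8, -1.1, 0.4)))
  for (fx in fixtures) {
    fit <- fit_cox(fx$x, fx$time, fx$event)
    oracle <- brute_cox_beta(fx$x, fx$time, fx$event)
    expect_equal(fit$beta, oracle, tolerance = 1e-3)
  }
})

test_that("hazard-ratio and confidence-interval identities hold exactly", {
  fx <- random_surv_fixture(40, 31)
  x <- stats::rnorm(40)
  fit <- fit_cox(x, fx$time, fx$event)
  expect_identical(fit$hr, exp(fit$beta))
  expect_equal(sqrt(fit$ci_low * fit$ci_high), fit$hr, tolerance = 1e-14)
  expect_equal(fit$p, 2 * stats::pnorm(-abs(fit$beta / fit$se)),
               tolerance = 1e-14)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)
})

test_that("null covariates yield near-zero coefficients and calibrated p", {
  set.seed(32)
  pvals <- vapply(1:20, function(i) {
    time <- stats::rexp(100)
    event <- stats::rbinom(100, 1, 0.7)
    x <- sample(0:1, 100, replace = TRUE)
    fit_cox(x, time, event)$p
  }, numeric(1))
  expect_lte(sum(pvals < 0.05), 4)
})

test_that("fit_cox rejects degenerate inputs and flags collinearity", {
  expect_error(fit_cox(rep(1, 10), 1:10, rep(1, 10)), "constant")
  expect_error(fit_cox(stats::rnorm(10), 1:10, rep(0, 10)), "event")
  x <- cbind(a = c(0, 1, 0, 1, 1, 0, 1, 0), b = c(0, 1, 0, 1, 1, 0, 1, 0))
  expect_warning(fit <- fit_cox(x, c(3, 1, 6, 2, 4, 8, 5, 7),
                                rep(1, 8)), "collinear")
  expect_false(fit$converged[1])
})

test_that("univariate screen retains signal and respects alpha", {
  set.seed(33)
  n <- 200
  signal <- sample(0:1, n, replace = TRUE)
  noise <- matrix(sample(0:1, 5 * n, replace = TRUE), nrow = 5)
  time <- stats::rexp(n, rate = 0.01 * exp(1.0 * signal))
  event <- stats::rbinom(n, 1, 0.7)
  ind <- rbind(S = signal, noise)
  rownames(ind) <- c("A|B", paste0("N", 1:5, "|M", 1:5))
  colnames(ind) <- paste0("P", 1:n)
  pm <- manual_pair_matrix(ind)
  clinical <- data.frame(patient_id = colnames(ind), os_time_days = time,
                         event = event)
  res <- univariate_screen(pm, clinical)
  expect_true("A|B" %in% res$selected)
  expect_equal(res$selected[1], "A|B")       # sorted by p
  expect_equal(length(univariate_screen(pm, clinical, alpha = 0)$selected), 0)
  # constant pair is skipped, not fitted
  ind2 <- rbind(ind, `C|D` = rep(1L, n))
  expect_warning(univariate_screen(manual_pair_matrix(ind2), clinical),
                 "constant")
})

test_that("LASSO-Cox selects planted pairs and is seed-deterministic", {
  set.seed(34)
  n <- 300
  x <- matrix(sample(0:1, n * 30, replace = TRUE), nrow = n,
              dimnames = list(NULL, paste0("P", 1:30)))
  eta <- 1.2 * x[, 1]
  time <- stats::rexp(n, rate = 0.01 * exp(eta))
  cens <- stats::rexp(n, rate = 0.005)
  event <- as.integer(time <= cens)
  obs <- pmin(time, cens)
  res1 <- fit_lasso_cox(x, obs, event, seed = 99)
  res2 <- fit_lasso_cox(x, obs, event, seed = 99)
  expect_identical(res1$coef, res2$coef)
  expect_true("P1" %in% res1$selected)
  expect_gt(res1$coef[["P1"]], 0)
  # definition of lambda_max: active set empty at the top of the path
  expect_equal(res1$nzero[1], 0L)
  # active-set size grows from the top of the path to the bottom
  expect_lte(res1$nzero[1], res1$nzero[length(res1$nzero)])
  expect_error(fit_lasso_cox(x[, 1, drop = FALSE], obs, event), "at least 2")
})

test_that("weak penalty approaches the unpenalized multivariate fit", {
  set.seed(35)
  n <- 500
  x <- matrix(sample(0:1, n * 3, replace = TRUE), nrow = n,
              dimnames = list(NULL, c("A|B", "C|D", "E|F")))
  eta <- 0.8 * x[, 1] - 0.6 * x[, 2] + 0.4 * x[, 3]
  time <- stats::rexp(n, rate = 0.01 * exp(eta))
  event <- rep(1L, n)
  las <- fit_lasso_cox(x, time, event, seed = 7)
  ref <- fit_cox(x, time, event)
  expect_setequal(las$selected, colnames(x))
  expect_equal(unname(las$coef[ref$covariate]), ref$beta, tolerance = 0.12)
})

test_that("signature refit drops collinear pairs and scores linearly", {
  set.seed(36)
  n <- 120
  a <- sample(0:1, n, replace = TRUE)
  b <- sample(0:1, n, replace = TRUE)
  ind <- rbind(`A|B` = a, `C|D` = b, `E|F` = a)   # third duplicates first
  colnames(ind) <- paste0("P", 1:n)
  pm <- manual_pair_matrix(ind)
  clinical <- data.frame(patient_id = colnames(ind),
                         os_time_days = stats::rexp(n, 0.01 * exp(0.8 * a)),
                         event = stats::rbinom(n, 1, 0.8))
  expect_warning(sig <- build_signature(pm, c("A|B", "C|D", "E|F"), clinical),
                 "collinear")
  expect_setequal(sig$terms$pair, c("A|B", "C|D"))  # first kept by order
  profile <- compute_risk_scores(pm, sig)
  expect_equal(profile$risk_score,
               as.numeric(sig$terms$beta %*% ind[sig$terms$pair, ]))
  # linearity: doubling betas doubles every score
  sig2 <- sig; sig2$terms$beta <- 2 * sig$terms$beta
  expect_equal(compute_risk_scores(pm, sig2)$risk_score,
               2 * profile$risk_score)
  # single-pair signature: scores live on {0, beta}
  sig1 <- build_signature(pm, "A|B", clinical)
  s1 <- compute_risk_scores(pm, sig1)$risk_score
  expect_setequal(unique(round(s1, 10)),
                  round(c(0, sig1$terms$beta), 10))
  expect_error(compute_risk_scores(pm, list(terms = data.frame(
    pair = "X|Y", beta = 1))), "X\\|Y")
})

test_that("risk score of the bundled eight-pair model sums its coefficients", {
  tab <- luad_signature_table()
  ind <- matrix(1L, nrow = 8, ncol = 3,
                dimnames = list(tab$pair, paste0("P", 1:3)))
  pm <- manual_pair_matrix(ind)
  model <- list(terms = data.frame(pair = tab$pair, beta = tab$coef))
  scores <- compute_risk_scores(pm, model)$risk_score
  expect_equal(scores, rep(-0.2006424, 3), tolerance = 1e-7)
  zeros <- compute_risk_scores(manual_pair_matrix(ind * 0L), model)$risk_score
  expect_equal(zeros, rep(0, 3))
})
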