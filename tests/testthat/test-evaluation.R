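test_that("time-dependent AUC is 1 for a perfectly ranking marker", {
  time <- 1:20
  event <- rep(1, 20)
  marker <- -time          # higher marker, earlier death
  roc <- time_dependent_roc(marker, time, event, horizon = 10.5)
  expect_equal(roc$auc, 1)
})

test_that("uncensored time-dependent AUC equals the Mann-Whitney statistic", {
  set.seed(41)
  for (i in 1:10) {
    n <- 40
    marker <- stats::rnorm(n)
    time <- stats::rexp(n, rate = 0.1 * exp(0.8 * marker))
    event <- rep(1, n)
    horizon <- stats::median(time)
    roc <- time_dependent_roc(marker, time, event, horizon)
    cases <- marker[time <= horizon]
    controls <- marker[time > horizon]
    expect_equal(roc$auc, mw_stat(cases, controls), tolerance = 1e-10)
  }
})

test_that("AUC is invariant under monotone transforms of the marker", {
  fx <- random_surv_fixture(60, 42)
  marker <- stats::rnorm(60)
  a <- time_dependent_roc(marker, fx$time, fx$event, 12)$auc
  b <- time_dependent_roc(exp(marker), fx$time, fx$event, 12)$auc
  c <- time_dependent_roc(rank(marker), fx$time, fx$event, 12)$auc
  expect_equal(a, b, tolerance = 1e-12)
  expect_equal(a, c, tolerance = 1e-12)
})

test_that("degenerate ROC inputs are handled per contract", {
  expect_error(time_dependent_roc(1:5, rep(100, 5), rep(1, 5), 10),
               "no events")
  expect_warning(roc <- time_dependent_roc(rep(2, 10), 1:10,
                                           rep(1, 10), 5.5),
                 "degenerate")
  expect_equal(roc$auc, 0.5)
})

test_that("Youden cutoff matches an exhaustive double-loop maximizer", {
  set.seed(43)
  marker <- stats::rnorm(20)
  time <- stats::rexp(20, 0.1 * exp(marker))
  event <- rep(1, 20)
  roc <- time_dependent_roc(marker, time, event, stats::median(time))
  yj <- youden_cutoff(roc)
  # independent scan: empirical sens/spec at every candidate threshold
  horizon <- stats::median(time)
  cases <- marker[time <= horizon]; controls <- marker[time > horizon]
  best_j <- -Inf; best_c <- NA
  for (c0 in sort(unique(marker))) {
    j <- mean(cases > c0) - mean(controls > c0)
    if (j > best_j + 1e-12) { best_j <- j; best_c <- c0 }
  }
  expect_equal(yj$youden, best_j, tolerance = 1e-10)
  expect_equal(yj$cutoff, best_c, tolerance = 1e-10)
  # a perfect marker attains index 1
  roc2 <- time_dependent_roc(-(1:20), 1:20, rep(1, 20), 10.5)
  expect_equal(youden_cutoff(roc2)$youden, 1)
})

test_that("stratification uses the strict greater-than rule", {
  profile <- data.frame(sample_id = paste0("P", 1:10),
                        risk_score = c(1:9, 5))
  out <- quiet(stratify(profile, 5))
  expect_equal(as.character(out$group[out$risk_score == 5]),
               c("low", "low"))          # boundary goes low
  expect_equal(sum(out$group == "high"), 4)
  all_high <- quiet(stratify(profile, 0))
  expect_true(all(all_high$group == "high"))
  out2 <- quiet(stratify(data.frame(sample_id = paste0("P", 1:10),
                                    risk_score = 1:10), 5.5))
  expect_equal(unname(table(out2$group)), c(5L, 5L), ignore_attr = TRUE)
})

test_that("Kaplan-Meier matches the hand-computed product limit", {
  # times 1 (event), 2 (censored), 3 (event)
  km <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$time, c(1, 3))
  expect_equal(km$surv, c(2 / 3, 0))
  # no events: S identically 1
  km0 <- kaplan_meier(c(5, 6), c(0, 0))
  expect_equal(nrow(km0), 0)
  # no censoring: empirical survivor fraction
  t2 <- c(1, 2, 2, 4, 7)
  km2 <- kaplan_meier(t2, rep(1, 5))
  for (k in seq_len(nrow(km2)))
    expect_equal(km2$surv[k], mean(t2 > km2$time[k]))
  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), "negative")
})

test_that("KM and log-rank match the survival package on random fixtures", {
  for (s in 1:50) {
    fx <- random_surv_fixture(sample(8:30, 1), s)
    km <- kaplan_meier(fx$time, fx$event)
    sf <- survival::survfit(survival::Surv(fx$time, fx$event) ~ 1)
    ss <- summary(sf, times = km$time)
    expect_equal(km$surv, ss$surv, tolerance = 1e-10)
    if (length(unique(fx$group)) == 2 && sum(fx$event) > 0 &&
        min(table(fx$group)) > 0) {
      lr <- log_rank_test(fx$time, fx$event, fx$group)
      sd <- survival::survdiff(survival::Surv(fx$time, fx$event) ~ fx$group)
      expect_equal(lr$statistic, sd$chisq, tolerance = 1e-10)
    }
  }
})

test_that("log-rank terms match a six-patient worked example", {
  time <- c(1, 4, 6, 2, 5, 7)
  event <- c(1, 1, 0, 1, 0, 1)
  group <- c("g1", "g1", "g1", "g2", "g2", "g2")
  lr <- log_rank_test(time, event, group)
  expect_equal(lr$observed, 2)
  expect_equal(lr$expected, 0.5 + 0.4 + 0.5 + 0, tolerance = 1e-12)
  expect_equal(lr$variance, 0.25 + 0.24 + 0.25, tolerance = 1e-12)
  expect_equal(lr$statistic, (2 - 1.4)^2 / 0.74, tolerance = 1e-12)
  expect_error(log_rank_test(time, event, rep("g1", 6)), "2 groups")
})

test_that("log-rank has power on separated groups and calibrated null", {
  set.seed(44)
  p_sig <- vapply(1:10, function(i) {
    g <- rep(0:1, each = 150)
    time <- stats::rexp(300, rate = 0.01 * exp(1 * g))
    log_rank_test(time, rep(1, 300), g)$p
  }, numeric(1))
  expect_true(all(p_sig < 0.001))
  p_null <- vapply(1:20, function(i) {
    time <- stats::rexp(100, 0.01)
    log_rank_test(time, stats::rbinom(100, 1, 0.7),
                  sample(0:1, 100, replace = TRUE))$p
  }, numeric(1))
  expect_lte(sum(p_null < 0.05), 4)
})

test_that("chi-square association matches the closed form", {
  g <- rep(c("high", "low"), each = 20)
  v <- c(rep("a", 10), rep("b", 10), rep("a", 10), rep("b", 10))
  res <- chi_square_association(g, v)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  g2 <- rep(c("high", "low"), each = 40)
  v2 <- c(rep("a", 30), rep("b", 10), rep("a", 10), rep("b", 30))
  res2 <- chi_square_association(g2, v2)
  expect_equal(res2$statistic, 20, tolerance = 1e-12)  # sum (O-E)^2/E by hand
  expect_equal(res2$p, stats::pchisq(20, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res2$df, 1)
  expect_error(chi_square_association(rep("high", 5), c("a", "a", "b", "b",
                                                        "a")),
               "2 x 2")
})

test_that("wilcoxon rank-sum handles exact, tied and degenerate cases", {
  res <- wilcoxon_rank_sum(c(1, 2, 3, 4, 5, 6),
                           c("a", "a", "a", "b", "b", "b"))
  expect_equal(res$statistic, 0)          # complete separation
  expect_equal(res$p, 0.1)                # exact: 2 * 1/choose(6,3)
  allsame <- wilcoxon_rank_sum(rep(7, 10), rep(c("a", "b"), 5))
  expect_equal(allsame$p, 1)
  expect_equal(allsame$statistic, 12.5)   # n1 * n2 / 2
  expect_error(wilcoxon_rank_sum(1:3, rep("a", 3)), "2 groups")
})

test_that("independence analysis isolates a planted risk effect", {
  co <- generate_cohort(cohort_config(seed = 12))
  clinical <- quiet(filter_clinical(co$clinical))
  truth <- co$truth$true_risk[clinical$patient_id]
  profile <- data.frame(sample_id = clinical$patient_id, risk_score = truth)
  res <- quiet(independence_analysis(profile, clinical))
  mv <- res$multivariate
  expect_lt(mv$p[mv$covariate == "risk_score"], 1e-4)
  noise_p <- mv$p[mv$covariate != "risk_score"]
  expect_gte(sum(noise_p > 0.01), length(noise_p) - 1)
  uv <- res$univariate
  expect_lt(uv$p[uv$covariate == "risk_score"], 1e-4)
})

test_that("risk-stratified KM curves order as planted", {
  co <- generate_cohort(cohort_config(seed = 13))
  clinical <- quiet(filter_clinical(co$clinical))
  truth <- co$truth$true_risk[clinical$patient_id]
  grp <- ifelse(truth > stats::median(truth), "high", "low")
  km_h <- kaplan_meier(clinical$os_time_days[grp == "high"],
                       clinical$event[grp == "high"])
  km_l <- kaplan_meier(clinical$os_time_days[grp == "low"],
                       clinical$event[grp == "low"])
  grid <- seq(200, 2000, by = 200)
  s_h <- vapply(grid, function(t0) {
    i <- km_h$time <= t0
    if (any(i)) km_h$surv[max(which(i))] else 1 }, numeric(1))
  s_l <- vapply(grid, function(t0) {
    i <- km_l$time <= t0
    if (any(i)) km_l$surv[max(which(i))] else 1 }, numeric(1))
  expect_gte(mean(s_h <= s_l + 1e-12), 0.9)
})
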