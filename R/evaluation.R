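# internal: Kaplan-Meier survival probability at t0
km_surv_at <- function(time, event, t0) {
  ev_times <- sort(unique(time[event == 1 & time <= t0]))
  s <- 1
  for (tt in ev_times) {
    n_risk <- sum(time >= tt)
    d <- sum(time == tt & event == 1)
    if (n_risk > 0) s <- s * (1 - d / n_risk)
  }
  s
}

#' Cumulative/dynamic time-dependent ROC with Kaplan-Meier weighting
#'
#' Heagerty-Lumley-Pepe estimator: at horizon `t`, cases are subjects with an
#' event by `t` and controls are subjects still at risk beyond `t`; subjects
#' censored before `t` contribute through Kaplan-Meier estimates. For each
#' marker threshold `c`,
#' `sens(c) = (1 - S(t | X > c)) * P(X > c) / (1 - S(t))` and
#' `spec(c) = 1 - S(t | X > c) * P(X > c) / S(t)`, with the conditional
#' survival estimated by Kaplan-Meier within the `X > c` subgroup. The AUC
#' is the trapezoidal area over all observed thresholds. With no censoring
#' before `t` this reduces to the empirical ROC, whose AUC equals the
#' Mann-Whitney statistic.
#'
#' @param marker Numeric risk marker (higher = worse prognosis).
#' @param time,event Survival outcome.
#' @param horizon Evaluation time `t` (same units as `time`).
#' @return A `tdroc`: list with `horizon`, `cutoffs`, `tpr`, `fpr`, `auc`,
#'   `marker_median`.
#' @export
time_dependent_roc <- function(marker, time, event, horizon) {
  stopifnot(length(marker) == length(time), length(time) == length(event))
  ok <- is.finite(marker) & is.finite(time)
  marker <- marker[ok]; time <- time[ok]; event <- event[ok]
  s_t <- km_surv_at(time, event, horizon)
  if (s_t >= 1) stop("no events observed by the horizon")
  if (s_t <= 0) stop("no survivors beyond the horizon")
  if (length(unique(marker)) == 1) {
    warning("all marker values equal; degenerate ROC, AUC = 0.5")
    return(structure(list(horizon = horizon, cutoffs = c(-Inf, marker[1]),
                          tpr = c(1, 0), fpr = c(1, 0), auc = 0.5,
                          marker_median = marker[1]), class = "tdroc"))
  }
  cutoffs <- c(-Inf, sort(unique(marker)))
  tpr <- fpr <- numeric(length(cutoffs))
  for (i in seq_along(cutoffs)) {
    above <- marker > cutoffs[i]
    p_c <- mean(above)
    s_c <- if (any(above)) km_surv_at(time[above], event[above], horizon) else 1
    tpr[i] <- (1 - s_c) * p_c / (1 - s_t)
    fpr[i] <- (s_c * p_c) / s_t
  }
  tpr <- pmin(pmax(tpr, 0), 1)
  fpr <- pmin(pmax(fpr, 0), 1)
  # integrate in threshold order (decreasing cutoff <=> increasing FPR up to
  # estimator noise); signed trapezoids absorb small non-monotonicities of
  # the KM-weighted estimates
  ord <- order(cutoffs, decreasing = TRUE)
  auc <- sum(diff(fpr[ord]) * (tpr[ord][-1] + tpr[ord][-length(tpr)]) / 2)
  structure(list(horizon = horizon, cutoffs = cutoffs, tpr = tpr, fpr = fpr,
                 auc = auc, marker_median = stats::median(marker)),
            class = "tdroc")
}

#' @export
print.tdroc <- function(x, ...) {
  cat(sprintf("time-dependent ROC at t = %g: AUC = %.4f (%d thresholds)\n",
              x$horizon, x$auc, length(x$cutoffs)))
  invisible(x)
}

#' Youden-index optimal cutoff of a time-dependent ROC
#'
#' Maximizes `sensitivity + specificity - 1` over the observed thresholds;
#' ties are broken toward the smallest threshold. A degenerate curve (no
#' threshold beats chance) falls back to the marker median with a warning.
#'
#' @param roc A `tdroc`.
#' @return List with `cutoff` and `youden`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "tdroc"))
  j <- roc$tpr - roc$fpr
  finite <- is.finite(roc$cutoffs)
  if (!any(finite) || max(j[finite]) <= 0) {
    warning("degenerate ROC; using the marker median as cutoff")
    return(list(cutoff = roc$marker_median, youden = 0))
  }
  jf <- j[finite]; cf <- roc$cutoffs[finite]
  best <- which(jf == max(jf))
  pick <- best[which.min(cf[best])]
  list(cutoff = cf[pick], youden = jf[pick])
}

#' Stratify a risk profile at a cutoff
#'
#' Assigns `high` when `risk_score > cutoff` (strictly), else `low`.
#'
#' @param profile data.frame with `sample_id`, `risk_score`.
#' @param cutoff Finite numeric cutoff.
#' @return Input with added factor column `group` (levels `low`, `high`)
#'   and a `cutoff` attribute.
#' @export
stratify <- function(profile, cutoff) {
  stopifnot(is.finite(cutoff))
  profile$group <- factor(ifelse(profile$risk_score > cutoff, "high", "low"),
                          levels = c("low", "high"))
  sizes <- table(profile$group)
  message("risk groups at cutoff ", signif(cutoff, 6), ": low=",
          sizes["low"], " high=", sizes["high"])
  if (any(sizes == 0))
    warning("all samples fall in one risk group")
  attr(profile, "cutoff") <- cutoff
  profile
}

#' Kaplan-Meier product-limit estimator
#'
#' @param time Non-negative survival times.
#' @param event 0/1 event indicators (ties at common event times pooled).
#' @return A `km_curve` data.frame: `time` (distinct event times), `n_risk`,
#'   `n_event`, `surv`; `S(0) = 1` implicitly.
#' @export
kaplan_meier <- function(time, event) {
  stopifnot(length(time) >= 1, length(time) == length(event))
  if (any(time < 0)) stop("negative survival time")
  ev_times <- sort(unique(time[event == 1]))
  if (length(ev_times) == 0) {
    out <- data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), surv = numeric(0))
    class(out) <- c("km_curve", "data.frame")
    return(out)
  }
  n_risk <- vapply(ev_times, function(tt) sum(time >= tt), integer(1))
  n_event <- vapply(ev_times, function(tt) sum(time == tt & event == 1),
                    integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = ev_times, n_risk = n_risk, n_event = n_event,
                    surv = surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

# internal: evaluate a km_curve at arbitrary times (right-continuous step)
km_eval <- function(km, t0) {
  vapply(t0, function(tt) {
    below <- km$time <= tt
    if (!any(below)) 1 else km$surv[max(which(below))]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square: at each distinct event time the
#' observed events in group 1 are compared with the hypergeometric
#' expectation and variance given the risk sets.
#'
#' @param time,event Survival outcome.
#' @param group Two-level grouping (factor or character).
#' @return List with `test = "log_rank"`, `statistic`, `df`, `p`,
#'   `observed`, `expected`, `group_sizes`.
#' @export
log_rank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("log-rank test requires exactly 2 groups")
  if (any(table(group) == 0)) stop("empty group")
  g1 <- group == levels(group)[1]
  ev_times <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (tt in ev_times) {
    at_risk <- time >= tt
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & g1)
    d_j <- sum(time == tt & event == 1)
    d1_j <- sum(time == tt & event == 1 & g1)
    o1 <- o1 + d1_j
    e1 <- e1 + d_j * n1_j / n_j
    if (n_j > 1)
      v <- v + d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
  }
  stat <- if (v > 0) (o1 - e1)^2 / v else 0
  list(test = "log_rank", statistic = stat, df = 1,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = o1, expected = e1, variance = v,
       group_sizes = table(group))
}

# internal: ordinal numeric coding of clinical covariates; unknowns -> NA
code_clinical_covariates <- function(clinical,
                                     covariates = c("age", "sex", "stage",
                                                    "t", "n", "m")) {
  codes <- list(
    sex = c(male = 0, female = 1),
    stage = c(I = 1, II = 2, III = 3, IV = 4),
    t = c(T1 = 1, T2 = 2, T3 = 3, T4 = 4),
    n = c(N0 = 0, N1 = 1, N2 = 2, N3 = 3),
    m = c(M0 = 0, M1 = 1))
  out <- data.frame(row.names = seq_len(nrow(clinical)))
  for (cv in covariates) {
    if (!cv %in% colnames(clinical)) next
    v <- clinical[[cv]]
    out[[cv]] <- if (cv == "age") as.numeric(v) else
      unname(codes[[cv]][as.character(v)])
  }
  out
}

#' Univariate and multivariate Cox independence analysis
#'
#' Tests whether the risk score predicts survival independently of clinical
#' covariates: one univariate Cox model per covariate (and the risk score),
#' then one joint multivariate model. Sex, stage and T/N/M are coded as
#' ordinal integers; `unknown`/`x` levels become missing and are dropped per
#' model; degenerate covariates are dropped with a warning.
#'
#' @param profile data.frame with `sample_id`, `risk_score`.
#' @param clinical Clinical data.frame.
#' @param covariates Clinical covariates to include.
#' @return List with `univariate` and `multivariate` `fit_cox` tables.
#' @export
independence_analysis <- function(profile, clinical,
                                  covariates = c("age", "sex", "stage",
                                                 "t", "n", "m")) {
  ids <- intersect(profile$sample_id, clinical$patient_id)
  cl <- clinical[match(ids, clinical$patient_id), ]
  risk <- profile$risk_score[match(ids, profile$sample_id)]
  covs <- code_clinical_covariates(cl, covariates)
  covs$risk_score <- risk
  uni <- list()
  for (cv in colnames(covs)) {
    v <- covs[[cv]]
    keep <- !is.na(v)
    if (length(unique(v[keep])) < 2) {
      warning("degenerate covariate dropped: ", cv)
      covs[[cv]] <- NULL
      next
    }
    res <- fit_cox(stats::setNames(data.frame(v[keep]), cv),
                   cl$os_time_days[keep], cl$event[keep])
    uni[[cv]] <- res
  }
  univariate <- do.call(rbind, uni)
  rownames(univariate) <- NULL
  complete <- stats::complete.cases(covs)
  multivariate <- fit_cox(covs[complete, , drop = FALSE],
                          cl$os_time_days[complete], cl$event[complete])
  list(univariate = univariate, multivariate = multivariate,
       n_multivariate = sum(complete))
}

#' Pearson chi-square association between risk group and a categorical
#' covariate
#'
#' Plain Pearson chi-square without continuity correction,
#' `df = (r - 1)(c - 1)`; warns when any expected count is below 5.
#' `unknown`-type levels should be excluded by the caller.
#'
#' @param groups Risk-group labels.
#' @param covariate Categorical covariate, same length.
#' @return List with `test = "chi_square"`, `statistic`, `df`, `p`, `table`.
#' @export
chi_square_association <- function(groups, covariate) {
  tab <- table(factor(groups), factor(covariate))
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("contingency table must be at least 2 x 2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in contingency table")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5))
    warning("expected count(s) below 5; chi-square approximation is rough")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(test = "chi_square", statistic = unname(ct$statistic),
       df = unname(ct$parameter), p = ct$p.value, table = tab)
}

#' Wilcoxon rank-sum (Mann-Whitney) comparison of two groups
#'
#' Exact enumeration when both groups have at most 8 observations and no
#' ties; otherwise the tie-corrected normal approximation (no continuity
#' correction). When every value is identical the test is vacuous:
#' `U = n1 n2 / 2`, `p = 1`.
#'
#' @param values Numeric vector.
#' @param groups Two-level grouping of the same length.
#' @return List with `test = "wilcoxon_rank_sum"`, `statistic` (Mann-Whitney
#'   U for the first group), `p`, `medians`, `group_sizes`.
#' @export
wilcoxon_rank_sum <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly 2 groups required")
  a <- values[groups == levels(groups)[1]]
  b <- values[groups == levels(groups)[2]]
  if (length(a) == 0 || length(b) == 0) stop("empty group")
  medians <- stats::setNames(c(stats::median(a), stats::median(b)),
                             levels(groups))
  if (length(unique(values)) == 1)
    return(list(test = "wilcoxon_rank_sum",
                statistic = length(a) * length(b) / 2, p = 1,
                medians = medians,
                group_sizes = table(groups)))
  exact <- length(a) <= 8 && length(b) <= 8 && !anyDuplicated(values)
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = FALSE))
  list(test = "wilcoxon_rank_sum", statistic = unname(wt$statistic),
       p = wt$p.value, medians = medians, group_sizes = table(groups))
}
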