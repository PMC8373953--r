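#' Fit a Cox proportional-hazards model and tabulate Wald statistics
#'
#' Thin wrapper around [survival::coxph()] (Efron tie handling by default,
#' convergence tolerance 1e-9, up to 100 iterations) that returns one row per
#' covariate with the hazard ratio, a 95% Wald confidence interval built with
#' the fixed multiplier `z* = 1.959964`, and the two-sided normal p-value
#' `2 * (1 - Phi(|beta| / se))`. These identities (`hr = exp(beta)`,
#' `sqrt(ci_low * ci_high) = hr`) are exact by construction.
#'
#' @param x Covariate matrix / data.frame / vector (samples in rows).
#' @param time,event Survival time and 0/1 event indicator.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return data.frame with columns `covariate`, `beta`, `se`, `hr`,
#'   `ci_low`, `ci_high`, `wald_z`, `p`, `converged`.
#' @export
fit_cox <- function(x, time, event, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1,
                                   dimnames = list(NULL, "x"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(nrow(x) == length(time), length(time) == length(event))
  if (sum(event) < 1) stop("at least one event is required")
  const <- apply(x, 2, function(v) length(unique(v)) == 1)
  if (any(const))
    stop("constant covariate(s): ", paste(colnames(x)[const], collapse = ", "))
  orig_names <- colnames(x)
  xm <- x
  colnames(xm) <- paste0("V", seq_len(ncol(xm)))
  dat <- data.frame(.time = time, .event = event, xm, check.names = FALSE)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(colnames(xm), collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  beta <- as.numeric(stats::coef(fit))
  se <- sqrt(diag(fit$var))
  if (anyNA(beta)) {
    warning("collinear covariate(s) with undefined coefficients: ",
            paste(orig_names[is.na(beta)], collapse = ", "))
    converged <- FALSE
  }
  # monotone likelihood: cap the runaway coefficient, keep the flag
  beta[is.infinite(beta)] <- sign(beta[is.infinite(beta)]) * 20
  if (any(abs(beta) > 15, na.rm = TRUE)) converged <- FALSE
  zstar <- 1.959964
  z <- beta / se
  out <- data.frame(covariate = orig_names, beta = beta, se = se,
                    hr = exp(beta),
                    ci_low = exp(beta - zstar * se),
                    ci_high = exp(beta + zstar * se),
                    wald_z = z, p = 2 * stats::pnorm(-abs(z)),
                    converged = converged, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Univariate Cox screen over pair indicators
#'
#' Fits one single-covariate Cox model per pair and retains pairs with a
#' Wald p-value below `alpha`, sorted by p. Constant pairs (after sample
#' alignment) are skipped with a warning.
#'
#' @param pm A `pair_matrix`.
#' @param clinical Clinical data.frame (`patient_id`, `os_time_days`,
#'   `event`); samples are aligned by intersecting ids.
#' @param alpha Retention threshold on the Wald p (default 0.05).
#' @return List with `selected` (pair names ordered by p) and `table`
#'   (per-pair `fit_cox` rows, all pairs tested).
#' @export
univariate_screen <- function(pm, clinical, alpha = 0.05) {
  ids <- intersect(colnames(pm$indicator), clinical$patient_id)
  if (length(ids) == 0) stop("no overlapping samples between pairs and clinical")
  cl <- clinical[match(ids, clinical$patient_id), ]
  ind <- pm$indicator[, ids, drop = FALSE]
  keep <- apply(ind, 1, function(v) length(unique(v)) > 1)
  if (any(!keep))
    warning(sum(!keep), " constant pair(s) skipped in univariate screen")
  rows <- lapply(rownames(ind)[keep], function(pr) {
    res <- fit_cox(stats::setNames(data.frame(ind[pr, ]), pr),
                   cl$os_time_days, cl$event)
    res$covariate <- pr
    res
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$p), , drop = FALSE]
  rownames(tab) <- NULL
  list(selected = tab$covariate[tab$p < alpha], table = tab)
}

#' LASSO-penalized Cox selection of pair indicators
#'
#' Cross-validated L1-penalized Cox regression via [glmnet::cv.glmnet()]
#' (partial-likelihood deviance, features standardized internally for the
#' penalty, coefficients reported on the original 0/1 scale). The lambda
#' path holds 100 log-spaced values down to `0.01 * lambda_max`; the
#' selection rule is the CV-deviance minimum by default, with the 1-SE rule
#' available. Fold assignment is drawn deterministically from `seed`.
#'
#' @param x Binary matrix (samples x pairs) of screened pair indicators.
#' @param time,event Survival outcome.
#' @param n_folds Cross-validation folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param lambda_rule `"min"` (default) or `"1se"`.
#' @return List with `selected` (pair names with nonzero coefficients),
#'   `coef` (their penalized coefficients), `lambda` (chosen value),
#'   `lambda_path`, `nzero` (active-set size along the path), and `cvfit`.
#' @export
fit_lasso_cox <- function(x, time, event, n_folds = 10, seed = 1L,
                          lambda_rule = c("min", "1se")) {
  lambda_rule <- match.arg(lambda_rule)
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("LASSO selection needs at least 2 candidate pairs")
  if (sum(event) < n_folds)
    stop("need at least as many events as folds")
  set.seed(as.integer(seed))
  foldid <- sample(rep(seq_len(n_folds), length.out = nrow(x)))
  y <- survival::Surv(time, event)
  cvfit <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid,
                             nlambda = 100, lambda.min.ratio = 0.01,
                             standardize = TRUE)
  if (max(cvfit$nzero) == 0)
    stop("no informative pairs: all coefficients zero along the lambda path")
  lambda <- if (lambda_rule == "min") cvfit$lambda.min else cvfit$lambda.1se
  cf <- as.matrix(stats::coef(cvfit, s = lambda))[, 1]
  nz <- cf[cf != 0]
  list(selected = names(nz), coef = nz, lambda = lambda,
       lambda_path = cvfit$lambda, nzero = as.integer(cvfit$nzero),
       cvfit = cvfit)
}

#' Build the pair signature by joint multivariate Cox regression
#'
#' Refits the LASSO-selected pairs in one unpenalized Cox model; the fitted
#' coefficients are the beta_i of the risk score
#' `Riskscore = sum_i (A|B)_i * beta_i`. Collinear indicators are dropped
#' with a warning, keeping the first by input order.
#'
#' @param pm A `pair_matrix` containing the selected pairs.
#' @param selected Character vector of pair names (screen order).
#' @param clinical Clinical data.frame (`patient_id`, `os_time_days`,
#'   `event`).
#' @return A `pair_signature`: list with `terms` (data.frame `pair`, `beta`)
#'   and `fit` (full multivariate `fit_cox` table, one row per retained
#'   pair).
#' @export
build_signature <- function(pm, selected, clinical) {
  if (length(selected) == 0) stop("no pairs selected for the signature")
  miss <- setdiff(selected, rownames(pm$indicator))
  if (length(miss) > 0)
    stop("selected pair(s) absent from pair matrix: ",
         paste(miss, collapse = ", "))
  ids <- intersect(colnames(pm$indicator), clinical$patient_id)
  cl <- clinical[match(ids, clinical$patient_id), ]
  x <- t(pm$indicator[selected, ids, drop = FALSE])
  # ordered drop of linearly dependent columns (first by screen order kept)
  keep <- logical(ncol(x))
  r <- 0
  for (j in seq_len(ncol(x))) {
    cand <- cbind(1, x[, which(keep), drop = FALSE], x[, j])
    if (qr(cand)$rank > r + 1) { keep[j] <- TRUE; r <- r + 1 }
  }
  if (any(!keep))
    warning("collinear pair(s) dropped from signature: ",
            paste(colnames(x)[!keep], collapse = ", "))
  x <- x[, keep, drop = FALSE]
  fit <- fit_cox(x, cl$os_time_days, cl$event)
  structure(list(terms = data.frame(pair = fit$covariate, beta = fit$beta,
                                    stringsAsFactors = FALSE),
                 fit = fit),
            class = "pair_signature")
}

#' @export
print.pair_signature <- function(x, ...) {
  cat(sprintf("pair_signature with %d term(s):\n", nrow(x$terms)))
  print(x$fit[, c("covariate", "beta", "hr", "ci_low", "ci_high", "p")],
        digits = 4)
  invisible(x)
}

#' Compute per-sample risk scores from a pair signature
#'
#' `Riskscore(sample) = sum_i indicator_i(sample) * beta_i`.
#'
#' @param pm A `pair_matrix` covering every signature pair.
#' @param model A `pair_signature` (or any list with a `terms` data.frame).
#' @return data.frame `sample_id`, `risk_score`.
#' @export
compute_risk_scores <- function(pm, model) {
  terms <- model$terms
  miss <- setdiff(terms$pair, rownames(pm$indicator))
  if (length(miss) > 0)
    stop("signature pair(s) missing from pair matrix: ",
         paste(miss, collapse = ", "))
  scores <- as.numeric(terms$beta %*%
                         pm$indicator[terms$pair, , drop = FALSE])
  data.frame(sample_id = colnames(pm$indicator), risk_score = scores,
             stringsAsFactors = FALSE)
}

#' Internal-consistency reconstruction of a published Cox table
#'
#' Given a signature report with columns `coef`, `hr95l`, `hr95h` (and
#' optionally `hr`, `p`), rebuilds the hazard ratio as `exp(coef)`, recovers
#' the standard error from the confidence interval as
#' `se = (log(hr95h) - log(hr95l)) / (2 * 1.959964)`, and recomputes the
#' two-sided normal Wald p-value. Useful to check that a reported table is
#' internally consistent.
#'
#' @param tab data.frame with at least `coef`, `hr95l`, `hr95h`.
#' @return Input with added columns `hr_rebuilt`, `se_rebuilt`, `p_rebuilt`.
#' @export
cox_table_consistency <- function(tab) {
  stopifnot(all(c("coef", "hr95l", "hr95h") %in% colnames(tab)))
  zstar <- 1.959964
  tab$hr_rebuilt <- exp(tab$coef)
  tab$se_rebuilt <- (log(tab$hr95h) - log(tab$hr95l)) / (2 * zstar)
  tab$p_rebuilt <- 2 * stats::pnorm(-abs(tab$coef / tab$se_rebuilt))
  tab
}

#' Bundled LUAD pair-signature coefficient table
#'
#' The published eight-pair immune lncRNA signature for a TCGA LUAD cohort
#' (pair name, multivariate Cox coefficient, hazard ratio with 95% CI, and
#' p-value), bundled as reference data for internal-consistency checks such
#' as [cox_table_consistency()].
#'
#' @return data.frame with columns `pair`, `coef`, `hr`, `hr95l`, `hr95h`,
#'   `p`.
#' @export
luad_signature_table <- function() {
  utils::read.table(system.file("extdata", "luad_pair_signature.tsv",
                                package = "lncpairs"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Bundled LUAD cohort characteristics table
#'
#' Patient counts by clinicopathological characteristic for the same LUAD
#' cohort (490 tumors), used for arithmetic consistency checks on reported
#' percentages.
#'
#' @return data.frame with columns `characteristic`, `level`, `n`.
#' @export
luad_cohort_table <- function() {
  utils::read.table(system.file("extdata", "luad_cohort_characteristics.tsv",
                                package = "lncpairs"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
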