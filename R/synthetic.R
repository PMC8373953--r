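#' Configuration for the synthetic cohort generator
#'
#' Defines a tumor/normal cohort with planted structure: lncRNAs correlated
#' with immune genes, tumor/normal differential expression, and pair
#' indicators carrying proportional-hazards effects on survival.
#'
#' @param n_tumor,n_normal Sample counts.
#' @param n_lncrna Total lncRNAs generated.
#' @param n_immune_gene Immune-related protein-coding genes.
#' @param n_noise_gene Additional protein-coding genes without structure.
#' @param n_corr_lncrna lncRNAs planted with immune-gene correlation
#'   `rho_target` (may be 0).
#' @param n_de_lncrna Of the correlated lncRNAs, how many carry a planted
#'   tumor/normal log2 fold change of magnitude at least `de_lfc` (may be 0).
#' @param n_signal_pairs Disjoint pairs of planted-DE lncRNAs whose 0/1
#'   rank indicator carries a hazard coefficient (may be 0); requires
#'   `2 * n_signal_pairs <= n_de_lncrna`.
#' @param rho_target Target Pearson correlation of planted lncRNA/immune-gene
#'   couples on the log2 scale, in (0.5, 1).
#' @param de_lfc Minimum planted |log2 fold change|.
#' @param beta_range Range of |beta_true| for planted pair effects; signs
#'   alternate.
#' @param baseline_hazard Exponential event-time rate per day.
#' @param censor_rate Target censoring fraction in (0, 1).
#' @param seed Master seed; every random draw derives from it.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_tumor = 400, n_normal = 60,
                          n_lncrna = 120, n_immune_gene = 40,
                          n_noise_gene = 60,
                          n_corr_lncrna = 30, n_de_lncrna = 20,
                          n_signal_pairs = 8,
                          rho_target = 0.8, de_lfc = 2.5,
                          beta_range = c(0.4, 0.65),
                          baseline_hazard = 4.6e-4, censor_rate = 0.4,
                          seed = 1L) {
  cfg <- list(n_tumor = n_tumor, n_normal = n_normal, n_lncrna = n_lncrna,
              n_immune_gene = n_immune_gene, n_noise_gene = n_noise_gene,
              n_corr_lncrna = n_corr_lncrna, n_de_lncrna = n_de_lncrna,
              n_signal_pairs = n_signal_pairs, rho_target = rho_target,
              de_lfc = de_lfc, beta_range = sort(beta_range),
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_tumor > 0, n_normal > 0, n_lncrna > 0, n_immune_gene > 0,
              n_noise_gene >= 0, n_corr_lncrna >= 0, n_de_lncrna >= 0,
              n_signal_pairs >= 0, baseline_hazard > 0, de_lfc > 0)
    if (censor_rate <= 0 || censor_rate >= 1)
      stop("censor_rate must lie in (0, 1)")
    if (rho_target <= 0.5 || rho_target >= 1)
      stop("rho_target must lie in (0.5, 1)")
    if (n_de_lncrna > n_corr_lncrna)
      stop("n_de_lncrna cannot exceed n_corr_lncrna")
    if (n_corr_lncrna > n_lncrna)
      stop("n_corr_lncrna cannot exceed n_lncrna")
    if (n_corr_lncrna > 0 && n_corr_lncrna > n_immune_gene)
      stop("need one distinct immune gene per correlated lncRNA")
    if (2 * n_signal_pairs > n_de_lncrna)
      stop("infeasible config: n_signal_pairs requires ",
           2 * n_signal_pairs, " planted-DE lncRNAs, have ", n_de_lncrna)
  })
  class(cfg) <- "cohort_config"
  cfg
}

#' Exponential censoring rate matching a target censoring fraction
#'
#' For exponential event times with rate `baseline_hazard` (null linear
#' predictor) and independent exponential censoring with rate `c`,
#' `P(censor < event) = c / (c + lambda)`; solving for the target fraction
#' `q` gives `c = lambda * q / (1 - q)`.
#'
#' @param baseline_hazard Event rate lambda (> 0).
#' @param censor_rate Target censoring fraction q in (0, 1).
#' @return The censoring rate.
#' @export
censoring_calibration <- function(baseline_hazard, censor_rate) {
  if (censor_rate <= 0 || censor_rate >= 1)
    stop("censor_rate must lie in (0, 1)")
  stopifnot(baseline_hazard > 0)
  baseline_hazard * censor_rate / (1 - censor_rate)
}

#' Generate a synthetic tumor/normal cohort with planted structure
#'
#' Expression follows a log-normal model (Gaussian on the log2 scale,
#' exponentiated), so pair indicators are tie-free almost surely. Correlated
#' lncRNAs are linear-plus-noise functions of a distinct immune gene with
#' expected Pearson r of `rho_target` on the log2 scale. Planted-DE lncRNAs
#' receive a tumor-only mean shift of their assigned log2FC. Each planted
#' signal pair consists of two DE lncRNAs with opposite DE direction but
#' equal tumor-side mean, so its 0/1 indicator varies across tumors; event
#' times are exponential with hazard
#' `baseline_hazard * exp(true_risk - mean(true_risk))` and censoring is
#' independent exponential calibrated by [censoring_calibration()].
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `expr`
#'   (`expression_matrix`), `catalog` (`gene_catalog`), `clinical`
#'   (data.frame, tumor patients), `infiltration` and `scores` (data.frames,
#'   tumor samples), and `truth` (planted ground truth: `corr_lncrnas`,
#'   `de_lncrnas` with signed log2FC, `signal_pairs`, `true_risk`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_t <- config$n_tumor; n_n <- config$n_normal
  n <- n_t + n_n
  tumor_ids <- sprintf("TUM%04d", seq_len(n_t))
  normal_ids <- sprintf("NOR%04d", seq_len(n_n))
  sample_ids <- c(tumor_ids, normal_ids)
  is_tumor <- c(rep(TRUE, n_t), rep(FALSE, n_n))

  lnc_ids <- sprintf("LNC%04d", seq_len(config$n_lncrna))
  irg_ids <- sprintf("IRG%04d", seq_len(config$n_immune_gene))
  pcg_ids <- if (config$n_noise_gene > 0)
    sprintf("PCG%04d", seq_len(config$n_noise_gene)) else character(0)

  sd_irg <- 1.2   # log2-scale spread of immune genes
  sd_lnc <- 1.0   # log2-scale spread of unstructured lncRNAs

  # immune genes: iid log-normal rows
  mu_irg <- stats::runif(config$n_immune_gene, 3, 8)
  irg_log <- matrix(stats::rnorm(config$n_immune_gene * n, sd = sd_irg),
                    nrow = config$n_immune_gene) + mu_irg
  rownames(irg_log) <- irg_ids

  pcg_log <- if (config$n_noise_gene > 0) {
    mu <- stats::runif(config$n_noise_gene, 2, 8)
    m <- matrix(stats::rnorm(config$n_noise_gene * n, sd = 1),
                nrow = config$n_noise_gene) + mu
    rownames(m) <- pcg_ids
    m
  } else NULL

  # lncRNAs: baseline means; correlated ones inherit the immune gene's
  # centered log2 profile plus noise tuned to the target correlation
  mu_lnc <- stats::runif(config$n_lncrna, 1, 6)
  lnc_log <- matrix(stats::rnorm(config$n_lncrna * n, sd = sd_lnc),
                    nrow = config$n_lncrna) + mu_lnc
  rownames(lnc_log) <- lnc_ids
  corr_set <- lnc_ids[seq_len(config$n_corr_lncrna)]
  if (config$n_corr_lncrna > 0) {
    sd_noise <- sd_irg * sqrt(1 / config$rho_target^2 - 1)
    for (i in seq_len(config$n_corr_lncrna)) {
      z <- irg_log[i, ] - mu_irg[i]
      lnc_log[i, ] <- mu_lnc[i] + z + stats::rnorm(n, sd = sd_noise)
    }
  }

  # planted DE: tumor-only mean shift; signal-pair members get opposite
  # signs around a common tumor-side mean so the indicator stays informative
  de_set <- lnc_ids[seq_len(config$n_de_lncrna)]
  lfc <- numeric(0)
  signal_pairs <- data.frame(gene_a = character(0), gene_b = character(0),
                             beta_true = numeric(0),
                             stringsAsFactors = FALSE)
  if (config$n_de_lncrna > 0) {
    lfc <- (config$de_lfc + stats::runif(config$n_de_lncrna, 0, 1)) *
      rep_len(c(1, -1), config$n_de_lncrna)
    names(lfc) <- de_set
    n_sp <- config$n_signal_pairs
    if (n_sp > 0) {
      pair_mean <- stats::runif(n_sp, 3, 6)
      for (p in seq_len(n_sp)) {
        ia <- 2 * p - 1; ib <- 2 * p
        lfc[ia] <- abs(lfc[ia]); lfc[ib] <- -abs(lfc[ib])
        mu_lnc[ia] <- pair_mean[p] - lfc[ia]
        mu_lnc[ib] <- pair_mean[p] - lfc[ib]
        # re-center the already-drawn rows on the adjusted means
      }
      # rebuild correlated rows whose means changed
      sd_noise <- sd_irg * sqrt(1 / config$rho_target^2 - 1)
      for (i in seq_len(2 * n_sp)) {
        z <- irg_log[i, ] - mu_irg[i]
        lnc_log[i, ] <- mu_lnc[i] + z + stats::rnorm(n, sd = sd_noise)
      }
      signal_pairs <- data.frame(gene_a = de_set[seq(1, 2 * n_sp, by = 2)],
                                 gene_b = de_set[seq(2, 2 * n_sp, by = 2)],
                                 beta_true = stats::runif(n_sp,
                                                          config$beta_range[1],
                                                          config$beta_range[2]) *
                                   rep_len(c(1, -1), n_sp),
                                 stringsAsFactors = FALSE)
    }
    lnc_log[de_set, is_tumor] <- lnc_log[de_set, is_tumor] + lfc
  }

  values <- 2^rbind(lnc_log, irg_log, pcg_log)
  colnames(values) <- sample_ids
  group <- stats::setNames(ifelse(is_tumor, "tumor", "normal"), sample_ids)
  expr <- expression_matrix(values, group)

  catalog <- data.frame(
    gene_id = c(lnc_ids, irg_ids, pcg_ids),
    symbol = c(lnc_ids, irg_ids, pcg_ids),
    biotype = c(rep("lncRNA", length(lnc_ids)),
                rep("protein_coding", length(irg_ids) + length(pcg_ids))),
    stringsAsFactors = FALSE)
  class(catalog) <- c("gene_catalog", "data.frame")

  # survival on tumor samples from planted pair indicators
  true_risk <- stats::setNames(rep(0, n_t), tumor_ids)
  if (nrow(signal_pairs) > 0) {
    tum_lin <- values[, tumor_ids, drop = FALSE]
    for (p in seq_len(nrow(signal_pairs))) {
      ind <- as.numeric(tum_lin[signal_pairs$gene_a[p], ] >
                          tum_lin[signal_pairs$gene_b[p], ])
      true_risk <- true_risk + signal_pairs$beta_true[p] * ind
    }
  }
  eta <- true_risk - mean(true_risk)
  lambda <- config$baseline_hazard
  c_rate <- censoring_calibration(lambda, config$censor_rate)
  t_event <- stats::rexp(n_t, rate = lambda * exp(eta))
  t_cens <- stats::rexp(n_t, rate = c_rate)
  os_time <- pmax(1, ceiling(pmin(t_event, t_cens)))
  event <- as.integer(t_event <= t_cens)

  stage_lv <- c("I", "II", "III", "IV", "unknown")
  clinical <- data.frame(
    patient_id = tumor_ids,
    os_time_days = os_time,
    event = event,
    age = round(stats::rnorm(n_t, 65, 10)),
    sex = sample(c("male", "female"), n_t, replace = TRUE),
    stage = sample(stage_lv, n_t, replace = TRUE,
                   prob = c(0.53, 0.23, 0.16, 0.05, 0.03)),
    t = sample(c("T1", "T2", "T3", "T4", "unknown"), n_t, replace = TRUE,
               prob = c(0.33, 0.53, 0.09, 0.04, 0.01)),
    n = sample(c("N0", "N1", "N2", "N3", "unknown"), n_t, replace = TRUE,
               prob = c(0.64, 0.19, 0.14, 0.01, 0.02)),
    m = sample(c("M0", "M1", "unknown"), n_t, replace = TRUE,
               prob = c(0.66, 0.05, 0.29)),
    stringsAsFactors = FALSE)

  # infiltration scores: one column planted negative in true risk (CD8-like),
  # one positive (M0-macrophage-like), the rest pure noise
  z_risk <- if (stats::sd(true_risk) > 0) as.numeric(scale(true_risk)) else
    rep(0, n_t)
  infiltration <- data.frame(
    `CD8_T_cell.synthetic` = -z_risk + stats::rnorm(n_t, sd = 1),
    `Macrophage_M0.synthetic` = z_risk + stats::rnorm(n_t, sd = 1),
    `B_cell.synthetic` = stats::rnorm(n_t),
    `Monocyte.synthetic` = stats::rnorm(n_t),
    `NK_cell.synthetic` = stats::rnorm(n_t),
    check.names = FALSE)
  rownames(infiltration) <- tumor_ids

  scores <- data.frame(
    IPS = stats::rnorm(n_t, 7, 1),
    IPS_CTLA4_blocker = 7 - 0.6 * z_risk + stats::rnorm(n_t, sd = 1),
    paclitaxel_ic50 = 2 - 0.8 * z_risk + stats::rnorm(n_t, sd = 1),
    cisplatin_ic50 = stats::rnorm(n_t, 3, 1),
    gefitinib_ic50 = 4 + 0.8 * z_risk + stats::rnorm(n_t, sd = 1),
    check.names = FALSE)
  rownames(scores) <- tumor_ids

  structure(list(
    expr = expr, catalog = catalog, clinical = clinical,
    infiltration = infiltration, scores = scores,
    truth = list(corr_lncrnas = corr_set, de_lncrnas = lfc,
                 signal_pairs = signal_pairs, true_risk = true_risk),
    config = config), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic_cohort: %d tumor + %d normal samples, ",
                     "%d genes; %d planted signal pair(s)\n"),
              x$config$n_tumor, x$config$n_normal, nrow(x$expr$values),
              nrow(x$truth$signal_pairs)))
  invisible(x)
}

#' Write a synthetic cohort to disk in the package's file dialects
#'
#' Emits expression TSV, group map, gene catalog TSV, clinical TSV, immune
#' gene list, infiltration and score tables — the exact formats the readers
#' in this package consume, so a cohort can be round-tripped through the
#' file-based pipeline.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named vector of written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             groups = file.path(dir, "sample_groups.tsv"),
             catalog = file.path(dir, "gene_catalog.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             immune_genes = file.path(dir, "immune_genes.txt"),
             infiltration = file.path(dir, "infiltration.tsv"),
             scores = file.path(dir, "scores.tsv"))
  write_expression_matrix(cohort$expr, paths["expression"])
  utils::write.table(data.frame(sample_id = names(cohort$expr$sample_group),
                                group = cohort$expr$sample_group),
                     paths["groups"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gene_catalog(cohort$catalog, paths["catalog"])
  utils::write.table(cohort$clinical, paths["clinical"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(cohort$catalog$symbol[startsWith(cohort$catalog$gene_id, "IRG")],
             paths["immune_genes"])
  write_sample_table(cohort$infiltration, paths["infiltration"])
  write_sample_table(cohort$scores, paths["scores"])
  paths
}
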