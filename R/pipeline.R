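#' Pipeline configuration
#'
#' Collects every analysis threshold with the study defaults: correlation
#' screen `|r| > 0.5`, `p < 0.001`; differential expression `|log2FC| > 2`,
#' BH-adjusted `p < 0.05`; occupancy band `[0.20, 0.80]`; univariate Cox
#' `p < 0.05`; 10-fold LASSO-Cox with CV-minimum lambda; ROC horizons at
#' 1/3/5 years (365/1095/1825 days). Exactly one of `synthetic` (a
#' [cohort_config()]) or `inputs` (named file paths) must be supplied.
#'
#' @param synthetic A [cohort_config()], or `NULL` when reading real inputs.
#' @param inputs Named list of file paths: `expression`, `groups`,
#'   `catalog`, `clinical`, `immune_genes`, and optionally `infiltration`,
#'   `scores`.
#' @param r_min,p_corr Pearson screen thresholds.
#' @param lfc_min,de_alpha Differential-expression thresholds.
#' @param occupancy Inclusive occupancy band (length 2).
#' @param uni_alpha Univariate Cox retention threshold.
#' @param lasso_folds,lambda_rule LASSO cross-validation settings.
#' @param roc_horizons ROC horizons in days.
#' @param group_alpha Threshold for association tests.
#' @param min_followup_days Clinical exclusion rule.
#' @param seed Master seed (folds; and cohort generation when synthetic).
#' @param outdir Optional output directory for stage TSVs and the manifest.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = cohort_config(), inputs = NULL,
                            r_min = 0.5, p_corr = 0.001,
                            lfc_min = 2, de_alpha = 0.05,
                            occupancy = c(0.20, 0.80),
                            uni_alpha = 0.05,
                            lasso_folds = 10, lambda_rule = "min",
                            roc_horizons = c(365, 1095, 1825),
                            group_alpha = 0.05,
                            min_followup_days = 30,
                            seed = 1L, outdir = NULL) {
  if (is.null(synthetic) == is.null(inputs))
    stop("exactly one of 'synthetic' or 'inputs' must be supplied")
  stopifnot(r_min > 0, r_min < 1, p_corr > 0, p_corr <= 1,
            lfc_min >= 0, de_alpha > 0, de_alpha <= 1,
            length(occupancy) == 2, occupancy[1] < occupancy[2],
            occupancy[1] >= 0, occupancy[2] <= 1,
            uni_alpha >= 0, uni_alpha <= 1, lasso_folds >= 2,
            all(roc_horizons > 0))
  if (!is.null(inputs)) {
    required <- c("expression", "groups", "catalog", "clinical",
                  "immune_genes")
    miss <- setdiff(required, names(inputs))
    if (length(miss) > 0)
      stop("missing input path(s): ", paste(miss, collapse = ", "))
  }
  structure(list(synthetic = synthetic, inputs = inputs, r_min = r_min,
                 p_corr = p_corr, lfc_min = lfc_min, de_alpha = de_alpha,
                 occupancy = occupancy, uni_alpha = uni_alpha,
                 lasso_folds = lasso_folds, lambda_rule = lambda_rule,
                 roc_horizons = roc_horizons, group_alpha = group_alpha,
                 min_followup_days = min_followup_days,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key-value document; keys mirror the arguments of
#' [pipeline_config()] and [cohort_config()] (the latter nested under
#' `synthetic:`); unset keys keep their defaults.
#'
#' @param path YAML file.
#' @param seed Optional seed override.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  doc <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(doc$synthetic))
    syn <- do.call(cohort_config, doc$synthetic)
  args <- doc[setdiff(names(doc), "synthetic")]
  args$synthetic <- syn
  if (!is.null(seed)) args$seed <- seed
  if (!is.null(syn) && !is.null(args$seed)) args$synthetic$seed <-
      as.integer(args$seed)
  do.call(pipeline_config, args)
}

# internal: stage message with funnel count
stage_log <- function(stage, detail) message("[", stage, "] ", detail)

#' Run the full pair-signature pipeline
#'
#' Executes the end-to-end analysis: input (or synthetic cohort) ->
#' correlation screen -> differential expression -> pair matrix (tumor
#' samples) -> occupancy filter -> univariate Cox -> LASSO-Cox ->
#' multivariate Cox signature -> risk scores -> 1/3/5-year ROC -> Youden
#' cutoff -> stratification -> Kaplan-Meier / log-rank -> Cox independence
#' analysis -> clinical chi-square and Wilcoxon associations -> immune
#' infiltration and drug-score associations (when tables are available).
#' Every stage logs its input/output counts; the returned manifest records
#' the full filtering funnel.
#'
#' @param config A [pipeline_config()].
#' @return A manifest list: `funnel` (named counts), `signature`,
#'   `risk_profile`, `auc` (per horizon), `cutoff`, `youden`, `km`
#'   (per-group curves), `logrank_p`, `independence`, `clinical_assoc`,
#'   `immune`, `scores`, `seed`, and output `files` when `outdir` is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  funnel <- c()

  if (!is.null(config$synthetic)) {
    cohort <- generate_cohort(config$synthetic)
    expr <- cohort$expr
    catalog <- cohort$catalog
    clinical <- filter_clinical(cohort$clinical, config$min_followup_days)
    immune_symbols <- catalog$symbol[catalog$biotype == "protein_coding" &
                                       startsWith(catalog$gene_id, "IRG")]
    infiltration <- cohort$infiltration
    scores_tab <- cohort$scores
  } else {
    inp <- config$inputs
    expr <- read_expression_matrix(inp$expression, inp$groups)
    catalog <- parse_gene_catalog(inp$catalog)
    clinical <- read_clinical_table(inp$clinical, config$min_followup_days)
    immune_symbols <- read_gene_list(inp$immune_genes)
    infiltration <- if (!is.null(inp$infiltration))
      read_sample_table(inp$infiltration) else NULL
    scores_tab <- if (!is.null(inp$scores))
      read_sample_table(inp$scores) else NULL
  }

  lnc_ids <- intersect(catalog$gene_id[catalog$biotype == "lncRNA"],
                       rownames(expr$values))
  immune_ids <- catalog$gene_id[catalog$symbol %in% immune_symbols &
                                  catalog$biotype == "protein_coding"]
  immune_ids <- intersect(immune_ids, rownames(expr$values))
  funnel["lncrna_total"] <- length(lnc_ids)
  funnel["immune_genes"] <- length(immune_ids)
  stage_log("input", paste0(ncol(expr$values), " samples, ",
                            length(lnc_ids), " lncRNAs, ",
                            length(immune_ids), " immune genes"))
  if (length(lnc_ids) == 0 || length(immune_ids) == 0)
    stop("stage 'input': no lncRNAs or no immune genes in the matrix")

  scr <- pearson_screen(expr, immune_ids, lnc_ids,
                        r_min = config$r_min, p_max = config$p_corr)
  funnel["irlncrna"] <- length(scr$selected)
  stage_log("pearson_screen", paste0(length(scr$selected), " irlncRNAs"))
  if (length(scr$selected) == 0)
    stop("stage 'pearson_screen': empty funnel, no immune-related lncRNAs")

  de <- differential_expression(expr, genes = scr$selected,
                                lfc_min = config$lfc_min,
                                alpha = config$de_alpha)
  de_genes <- de$gene_id[de$de]
  funnel["de_irlncrna"] <- length(de_genes)
  stage_log("differential_expression", paste0(length(de_genes),
                                              " DEirlncRNAs"))
  if (length(de_genes) < 2)
    stop("stage 'differential_expression': fewer than 2 DEirlncRNAs")

  tumor_ids <- names(expr$sample_group)[expr$sample_group %in% "tumor"]
  pm <- build_pair_matrix(expr, de_genes, samples = tumor_ids)
  funnel["pairs_built"] <- nrow(pm$indicator)
  pm_valid <- filter_pairs_by_occupancy(pm, config$occupancy[1],
                                        config$occupancy[2])
  funnel["pairs_valid"] <- nrow(pm_valid$indicator)
  stage_log("pair_transform", paste0(nrow(pm$indicator), " built, ",
                                     nrow(pm_valid$indicator),
                                     " within occupancy band"))
  if (nrow(pm_valid$indicator) < 2)
    stop("stage 'pair_transform': fewer than 2 valid pairs")

  uni <- univariate_screen(pm_valid, clinical, alpha = config$uni_alpha)
  funnel["pairs_survival"] <- length(uni$selected)
  stage_log("univariate_screen", paste0(length(uni$selected),
                                        " survival-related pairs"))
  if (length(uni$selected) == 0)
    stop("stage 'univariate_screen': no survival-related pairs")

  ids <- intersect(colnames(pm_valid$indicator), clinical$patient_id)
  cl <- clinical[match(ids, clinical$patient_id), ]
  if (length(uni$selected) >= 2) {
    las <- fit_lasso_cox(t(pm_valid$indicator[uni$selected, ids,
                                              drop = FALSE]),
                         cl$os_time_days, cl$event,
                         n_folds = config$lasso_folds, seed = config$seed,
                         lambda_rule = config$lambda_rule)
    lasso_sel <- las$selected
  } else {
    las <- NULL
    lasso_sel <- uni$selected
  }
  funnel["pairs_lasso"] <- length(lasso_sel)
  stage_log("lasso", paste0(length(lasso_sel), " pairs with nonzero ",
                            "penalized coefficients"))
  if (length(lasso_sel) == 0)
    stop("stage 'lasso': empty selection")

  sig <- build_signature(pm_valid, lasso_sel, clinical)
  funnel["pairs_model"] <- nrow(sig$terms)
  stage_log("signature", paste0(nrow(sig$terms), " pairs in the model"))

  profile <- compute_risk_scores(pm_valid, sig)
  profile <- profile[profile$sample_id %in% clinical$patient_id, ]
  cl <- clinical[match(profile$sample_id, clinical$patient_id), ]

  roc <- lapply(config$roc_horizons, function(h)
    time_dependent_roc(profile$risk_score, cl$os_time_days, cl$event, h))
  names(roc) <- paste0("t", config$roc_horizons)
  auc <- vapply(roc, function(r) r$auc, numeric(1))
  stage_log("roc", paste(sprintf("%s: AUC=%.3f", names(auc), auc),
                         collapse = ", "))

  yj <- youden_cutoff(roc[[1]])
  profile <- stratify(profile, yj$cutoff)

  km <- lapply(split(seq_len(nrow(profile)), profile$group), function(i)
    kaplan_meier(cl$os_time_days[i], cl$event[i]))
  lr <- log_rank_test(cl$os_time_days, cl$event, profile$group)
  stage_log("km_logrank", sprintf("log-rank p = %.3g", lr$p))

  indep <- independence_analysis(profile, clinical)

  clin_assoc <- list()
  for (cv in c("sex", "stage", "t", "n", "m")) {
    v <- cl[[cv]]
    known <- !v %in% c("unknown", "Tx", "Nx", "Mx") & !is.na(v)
    if (length(unique(v[known])) >= 2 &&
        length(unique(profile$group[known])) == 2) {
      clin_assoc[[paste0("chisq_", cv)]] <-
        tryCatch(chi_square_association(profile$group[known], v[known]),
                 error = function(e) NULL)
      if (cv != "sex")
        clin_assoc[[paste0("wilcox_", cv)]] <-
          tryCatch(wilcoxon_rank_sum(profile$risk_score[known],
                                     ifelse(v[known] %in%
                                              c("I", "II", "T1", "T2",
                                                "N0", "M0"),
                                            "early", "late")),
                   error = function(e) NULL)
    }
  }

  immune_res <- if (!is.null(infiltration))
    spearman_risk_vs_infiltration(profile, infiltration,
                                  alpha = config$group_alpha) else NULL
  score_res <- if (!is.null(scores_tab))
    compare_scores_by_group(scores_tab, profile,
                            alpha = config$group_alpha) else NULL

  manifest <- list(funnel = funnel, signature = sig$fit,
                   risk_profile = profile, auc = auc, roc = roc,
                   cutoff = yj$cutoff, youden = yj$youden, km = km,
                   logrank_p = lr$p, independence = indep,
                   clinical_assoc = clin_assoc, immune = immune_res,
                   scores = score_res, seed = config$seed,
                   version = as.character(utils::packageVersion("lncpairs")))

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    f <- function(x) file.path(config$outdir, x)
    sig_tab <- data.frame(lncRNA_pair = sig$fit$covariate,
                          coef = sig$fit$beta, HR = sig$fit$hr,
                          HR.95L = sig$fit$ci_low, HR.95H = sig$fit$ci_high,
                          p_value = sig$fit$p)
    utils::write.table(sig_tab, f("signature.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(profile, f("risk_profile.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(horizon_days = config$roc_horizons,
                                  auc = unname(auc)),
                       f("auc.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(immune_res))
      utils::write.table(immune_res, f("immune_association.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(score_res))
      utils::write.table(score_res, f("score_association.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    manifest_flat <- list(funnel = as.list(funnel), auc = as.list(auc),
                          cutoff = yj$cutoff, youden = yj$youden,
                          logrank_p = lr$p, seed = config$seed,
                          version = manifest$version)
    jsonlite::write_json(manifest_flat, f("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$files <- list.files(config$outdir, full.names = TRUE)
  }
  manifest
}
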