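#' Read a gene x sample expression matrix
#'
#' Reads a TSV/CSV whose first column holds gene identifiers and whose header
#' row holds sample identifiers. Values must be non-negative normalized
#' expression (FPKM-like). Duplicate gene rows are collapsed by their mean on
#' the linear scale (with a message); duplicate sample identifiers are an
#' error.
#'
#' @param path Path to a TSV (default) or CSV file.
#' @param group_map Either a named character vector mapping sample id to
#'   `"tumor"`/`"normal"`, or the path to a two-column TSV (`sample_id`,
#'   `group`), or `NULL` to leave groups unassigned.
#' @return An object of class `expression_matrix`: a list with `values`
#'   (numeric matrix, genes in rows), and `sample_group` (named character
#'   vector, possibly `NA`).
#' @export
read_expression_matrix <- function(path, group_map = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  gene_ids <- as.character(raw[[1]])
  sample_ids <- colnames(raw)[-1]   # before [.data.frame uniquifies names
  body <- raw[, -1, drop = FALSE]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifier(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   col[bad], gene_ids[bad], sample_ids[j]))
    }
  }
  values <- as.matrix(body)
  rownames(values) <- gene_ids
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative expression value at gene '%s', sample '%s'",
                 gene_ids[neg[1, 1]], sample_ids[neg[1, 2]]))
  if (anyDuplicated(gene_ids)) {
    dups <- unique(gene_ids[duplicated(gene_ids)])
    message(length(dups), " duplicated gene id(s) collapsed by mean: ",
            paste(utils::head(dups, 5), collapse = ", "))
    values <- rowsum(values, group = gene_ids, reorder = FALSE) /
      as.vector(table(factor(gene_ids, levels = unique(gene_ids))))
  }
  group <- rep(NA_character_, ncol(values))
  names(group) <- colnames(values)
  if (!is.null(group_map)) {
    if (is.character(group_map) && length(group_map) == 1 &&
        file.exists(group_map)) {
      gm <- utils::read.table(group_map, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
      group_map <- stats::setNames(as.character(gm[[2]]), as.character(gm[[1]]))
    }
    hit <- intersect(names(group_map), names(group))
    group[hit] <- group_map[hit]
  }
  expression_matrix(values, group)
}

#' Construct an expression matrix object
#'
#' @param values Non-negative numeric matrix, genes in rows, samples in
#'   columns; dimnames required.
#' @param sample_group Named character vector (`tumor`/`normal`), aligned to
#'   the columns of `values`.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, sample_group = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values < 0)) stop("expression values must be non-negative")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (is.null(sample_group)) {
    sample_group <- rep(NA_character_, ncol(values))
    names(sample_group) <- colnames(values)
  }
  sample_group <- sample_group[colnames(values)]
  names(sample_group) <- colnames(values)
  structure(list(values = values, sample_group = sample_group),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  grp <- table(x$sample_group, useNA = "ifany")
  cat(sprintf("expression_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(names(grp), grp, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; full-precision values so that a
#' read-back reproduces the matrix.
#'
#' @param x An `expression_matrix`.
#' @param path Output TSV path.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x$values),
                   format(x$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a gene catalog from GTF or TSV
#'
#' Classifies genes into `lncRNA`, `protein_coding` or `other`. For GTF input
#' only `gene` feature rows are consulted; the biotype is read from the
#' `gene_biotype` (or `gene_type`) attribute. Ensembl consolidated several
#' historical lncRNA biotypes into "lncRNA", so an alias set is accepted and
#' configurable.
#'
#' @param path GTF file (9 tab-separated fields) or a 3-column TSV
#'   (`gene_id`, `symbol`, `biotype`).
#' @param lncrna_biotypes Biotype strings mapped to `lncRNA`.
#' @return A `gene_catalog`: data.frame with columns `gene_id`, `symbol`,
#'   `biotype`.
#' @export
parse_gene_catalog <- function(path,
                               lncrna_biotypes = c("lncRNA", "lincRNA",
                                                   "antisense",
                                                   "processed_transcript",
                                                   "sense_intronic",
                                                   "sense_overlapping")) {
  head_lines <- readLines(path, n = 50L)
  head_lines <- head_lines[!grepl("^#", head_lines) & nzchar(head_lines)]
  if (length(head_lines) == 0) stop("empty gene catalog file")
  is_gtf <- grepl("gene_id", head_lines[1], fixed = TRUE) &&
    length(strsplit(head_lines[1], "\t", fixed = TRUE)[[1]]) >= 8
  if (is_gtf) {
    gr <- rtracklayer::import(path, format = "gtf")
    meta <- as.data.frame(S4Vectors::mcols(gr))
    if ("type" %in% colnames(meta))
      meta <- meta[as.character(meta$type) == "gene", , drop = FALSE]
    if (!"gene_id" %in% colnames(meta)) meta$gene_id <- NA_character_
    missing_id <- is.na(meta$gene_id) | !nzchar(as.character(meta$gene_id))
    if (any(missing_id)) {
      warning(sum(missing_id), " gene row(s) without gene_id skipped")
      meta <- meta[!missing_id, , drop = FALSE]
    }
    biotype_col <- intersect(c("gene_biotype", "gene_type"), colnames(meta))[1]
    biotype <- if (is.na(biotype_col)) rep(NA_character_, nrow(meta)) else
      as.character(meta[[biotype_col]])
    symbol <- if ("gene_name" %in% colnames(meta))
      as.character(meta$gene_name) else as.character(meta$gene_id)
    cat_df <- data.frame(gene_id = as.character(meta$gene_id),
                         symbol = symbol, raw_biotype = biotype,
                         stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 3) stop("TSV gene catalog needs gene_id, symbol, biotype")
    cat_df <- data.frame(gene_id = as.character(tab[[1]]),
                         symbol = as.character(tab[[2]]),
                         raw_biotype = as.character(tab[[3]]),
                         stringsAsFactors = FALSE)
  }
  cat_df <- cat_df[!duplicated(cat_df$gene_id), , drop = FALSE]
  if (nrow(cat_df) == 0) stop("empty gene catalog")
  cat_df$symbol[is.na(cat_df$symbol) | !nzchar(cat_df$symbol)] <-
    cat_df$gene_id[is.na(cat_df$symbol) | !nzchar(cat_df$symbol)]
  cat_df$biotype <- ifelse(cat_df$raw_biotype %in% lncrna_biotypes, "lncRNA",
                    ifelse(cat_df$raw_biotype %in% "protein_coding",
                           "protein_coding", "other"))
  out <- cat_df[, c("gene_id", "symbol", "biotype")]
  class(out) <- c("gene_catalog", "data.frame")
  out
}

#' Write a gene catalog as 3-column TSV
#' @param catalog A `gene_catalog`.
#' @param path Output path.
#' @export
write_gene_catalog <- function(catalog, path) {
  utils::write.table(as.data.frame(catalog)[, c("gene_id", "symbol",
                                                "biotype")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table and apply the follow-up exclusion rule
#'
#' Patients with missing survival time or event, or with a survival time
#' strictly below `min_followup_days`, are excluded (a survival time of
#' exactly `min_followup_days` is retained). Removal counts are reported via
#' `message()`.
#'
#' @param path TSV with columns `patient_id`, `os_time_days`, `event`,
#'   `age`, `sex`, `stage`, `t`, `n`, `m`.
#' @param min_followup_days Minimum follow-up in days (default 30).
#' @return A data.frame of clinical records.
#' @export
read_clinical_table <- function(path, min_followup_days = 30) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("patient_id", "os_time_days", "event", "age", "sex",
                "stage", "t", "n", "m")
  missing_cols <- setdiff(required, colnames(tab))
  if (length(missing_cols) > 0)
    stop("missing required clinical column(s): ",
         paste(missing_cols, collapse = ", "))
  tab$os_time_days <- suppressWarnings(as.numeric(tab$os_time_days))
  bad_event <- !is.na(tab$event) & !(tab$event %in% c(0, 1))
  if (any(bad_event))
    stop("event indicator must be 0 (censored) or 1 (death); offending: ",
         paste(unique(tab$event[bad_event]), collapse = ", "))
  filter_clinical(tab, min_followup_days)
}

#' Apply the clinical exclusion rule
#'
#' Drops records with missing survival time/event or survival time strictly
#' below `min_followup_days`. Idempotent.
#'
#' @param clinical Clinical data.frame with `os_time_days` and `event`.
#' @param min_followup_days Minimum follow-up in days.
#' @return Filtered data.frame.
#' @export
filter_clinical <- function(clinical, min_followup_days = 30) {
  n0 <- nrow(clinical)
  keep <- !is.na(clinical$os_time_days) & !is.na(clinical$event) &
    clinical$os_time_days >= min_followup_days
  out <- clinical[keep, , drop = FALSE]
  if (n0 > nrow(out))
    message(n0 - nrow(out), " of ", n0,
            " clinical record(s) excluded (missing or short follow-up)")
  rownames(out) <- NULL
  out
}

#' Read a gene symbol list (one per line)
#' @param path Plain-text file, one symbol per line.
#' @return Deduplicated character vector.
#' @export
read_gene_list <- function(path) {
  sym <- trimws(readLines(path))
  sym <- unique(sym[nzchar(sym)])
  if (length(sym) == 0) stop("empty gene list")
  sym
}

#' Read a per-sample score table (infiltration, IPS, IC50)
#'
#' First column is the sample identifier; remaining columns are numeric
#' scores. Infiltration tables use `celltype.method` column names.
#'
#' @param path TSV path.
#' @return data.frame with sample ids as row names.
#' @export
read_sample_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in score table")
  out <- tab[, -1, drop = FALSE]
  rownames(out) <- ids
  for (j in seq_along(out)) out[[j]] <- as.numeric(out[[j]])
  out
}

#' Write a per-sample score table
#' @param x data.frame with sample ids as row names.
#' @param path Output TSV path.
#' @export
write_sample_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal: the package-wide log transform convention for FPKM-like values
log2p1 <- function(x) log2(x + 1)
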