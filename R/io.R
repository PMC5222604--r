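#' Validate a gene-by-sample expression matrix
#'
#' Checks the invariants required throughout the package: a numeric matrix
#' with unique, non-empty gene (row) and sample (column) identifiers, no
#' missing values, and no negative entries.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   `rownames` (gene ids) and `colnames` (sample ids).
#' @return The validated matrix, invisibly unchanged.
#' @export
validate_expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression matrix must be a numeric matrix")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("expression matrix must carry gene ids (rownames) and sample ids (colnames)")
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g))
    stop("duplicated gene id(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s))
    stop("duplicated sample id(s): ", paste(dup_s, collapse = ", "))
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at gene '%s', sample '%s'",
                 gene_ids[idx[1]], sample_ids[idx[2]]))
  }
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at gene '%s', sample '%s'",
                 gene_ids[idx[1]], sample_ids[idx[2]]))
  }
  invisible(values)
}

#' Read a gene-by-sample expression matrix from delimited text
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; the body must be non-negative numeric (counts or normalised
#' abundances). Input order of genes and samples is preserved.
#'
#' @param path Path to the delimited file.
#' @param delimiter Field delimiter, tab by default.
#' @return Numeric matrix (genes x samples) with gene ids as rownames and
#'   sample ids as colnames.
#' @export
read_expression_matrix <- function(path, delimiter = "\t") {
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L)
    stop("expression matrix file needs a gene-id column plus at least one sample column: ", path)
  gene_ids <- as.character(raw[[1L]])
  body <- raw[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))))[1L]
      stop(sprintf("non-numeric value at gene '%s', sample '%s'",
                   gene_ids[bad], colnames(body)[j]))
    }
  }
  m <- as.matrix(body)
  rownames(m) <- gene_ids
  validate_expression_matrix(m)
  m
}

#' Write an expression matrix as delimited text
#'
#' @param values Validated expression matrix.
#' @param path Output path.
#' @param delimiter Field delimiter, tab by default.
#' @param id_column Name of the gene-id column in the header.
#' @export
write_expression_matrix <- function(values, path, delimiter = "\t",
                                    id_column = "gene_id") {
  validate_expression_matrix(values)
  df <- data.frame(rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Validate a sample design table
#'
#' A sample design annotates each sample with its age class (months),
#' zeitgeber time (hours after lights-on, on a 24 h period), and replicate
#' index. `condition_label` defines the grouping used as the "condition" in
#' clr summaries; when absent it defaults to the age class.
#'
#' @param design data.frame with columns `sample_id`, `age_months`,
#'   `zeitgeber_time_h`, `replicate` and optionally `condition_label`.
#' @return The design with `condition_label` filled in.
#' @export
validate_sample_design <- function(design) {
  required <- c("sample_id", "age_months", "zeitgeber_time_h", "replicate")
  missing <- setdiff(required, colnames(design))
  if (length(missing))
    stop("sample design is missing column(s): ", paste(missing, collapse = ", "))
  dup <- unique(design$sample_id[duplicated(design$sample_id)])
  if (length(dup))
    stop("duplicated sample_id(s): ", paste(dup, collapse = ", "))
  if (any(design$age_months <= 0 | design$age_months != round(design$age_months)))
    stop("age_months must be positive integers")
  bad_zt <- design$zeitgeber_time_h < 0 | design$zeitgeber_time_h >= 24
  if (any(bad_zt))
    stop("zeitgeber_time_h outside [0, 24) for sample(s): ",
         paste(design$sample_id[bad_zt], collapse = ", "))
  if (any(design$replicate <= 0 | design$replicate != round(design$replicate)))
    stop("replicate must be positive integers")
  design$condition_label <- if (is.null(design$condition_label))
    as.character(design$age_months) else as.character(design$condition_label)
  design
}

#' Read a sample design from delimited text
#'
#' @inheritParams read_expression_matrix
#' @return data.frame with one row per sample (see
#'   [validate_sample_design()] for the columns).
#' @export
read_sample_design <- function(path, delimiter = "\t") {
  design <- utils::read.table(path, sep = delimiter, header = TRUE,
                              check.names = FALSE, stringsAsFactors = FALSE,
                              quote = "", comment.char = "")
  design$sample_id <- as.character(design$sample_id)
  validate_sample_design(design)
}

#' Read a candidate-gene list
#'
#' One `gene_id` column; duplicates are rejected.
#'
#' @inheritParams read_expression_matrix
#' @return Character vector of candidate gene ids.
#' @export
read_candidate_set <- function(path, delimiter = "\t") {
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (!"gene_id" %in% colnames(df))
    stop("candidate list is missing column: gene_id")
  ids <- as.character(df$gene_id)
  if (!length(ids)) stop("candidate list is empty")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicated candidate gene id(s): ", paste(dup, collapse = ", "))
  ids
}

#' Read a per-study fold-change table
#'
#' Long format with columns `gene_id`, `study_id`, `fold_change`; one row per
#' (gene, study) observation from the literature/meta-analysis export.
#'
#' @inheritParams read_expression_matrix
#' @return data.frame with validated columns.
#' @export
read_fold_change_table <- function(path, delimiter = "\t") {
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  validate_fold_change_table(df)
}

#' @rdname read_fold_change_table
#' @param table data.frame to validate in place of a file.
#' @export
validate_fold_change_table <- function(table) {
  required <- c("gene_id", "study_id", "fold_change")
  missing <- setdiff(required, colnames(table))
  if (length(missing))
    stop("fold-change table is missing column(s): ", paste(missing, collapse = ", "))
  if (any(!is.finite(table$fold_change) | table$fold_change <= 0))
    stop("fold_change must be positive and finite")
  key <- paste(table$gene_id, table$study_id, sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup))
    stop("duplicated (gene_id, study_id) pair(s): ",
         paste(gsub("\r", "/", dup), collapse = ", "))
  table
}

#' Write a bundle of result tables as delimited text
#'
#' Each element of `tables` (a named list of data.frames) is written to
#' `<dir>/<name>.tsv`. Writing is lossless for the package's result tables:
#' re-reading with [utils::read.table()] reproduces the data.frame.
#'
#' @param tables Named list of data.frames.
#' @param dir Output directory, created if needed.
#' @param delimiter Field delimiter.
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(tables, dir, delimiter = "\t") {
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("'tables' must be a named list")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], path, sep = delimiter, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

# Status codes used in assessment tables written for human consumption:
# X = passed, - = failed, ND = not detectable.
.status_to_code <- c(pass = "X", fail = "-", not_detectable = "ND")
.code_to_status <- c(X = "pass", `-` = "fail", ND = "not_detectable")

#' Read a wide pass/fail assessment table
#'
#' Wide format: first column `gene_id` (or `Gene`), one column per
#' assessment, cells coded `X` (passed), `-` (failed) or `ND` (not
#' detectable). Returns the long form used internally.
#'
#' @inheritParams read_expression_matrix
#' @return data.frame with columns `gene_id`, `assessment_id`, `status`
#'   (one of `"pass"`, `"fail"`, `"not_detectable"`).
#' @export
read_assessment_table <- function(path, delimiter = "\t") {
  wide <- utils::read.table(path, sep = delimiter, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "", comment.char = "")
  colnames(wide)[1L] <- "gene_id"
  long <- do.call(rbind, lapply(colnames(wide)[-1L], function(a) {
    data.frame(gene_id = wide$gene_id, assessment_id = a,
               status = unname(.code_to_status[as.character(wide[[a]])]),
               stringsAsFactors = FALSE)
  }))
  if (anyNA(long$status))
    stop("unknown status code(s) in assessment table; expected X, - or ND")
  validate_assessment_table(long)
}

#' Write an assessment table in the wide X/-/ND layout
#'
#' @param table Long assessment table (`gene_id`, `assessment_id`, `status`).
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @export
write_assessment_table <- function(table, path, delimiter = "\t") {
  validate_assessment_table(table)
  genes <- unique(table$gene_id)
  assessments <- unique(table$assessment_id)
  wide <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (a in assessments) {
    sub <- table[table$assessment_id == a, ]
    wide[[a]] <- unname(.status_to_code[sub$status[match(genes, sub$gene_id)]])
  }
  utils::write.table(wide, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname read_assessment_table
#' @param table Long-format assessment data.frame to validate.
#' @export
validate_assessment_table <- function(table) {
  required <- c("gene_id", "assessment_id", "status")
  missing <- setdiff(required, colnames(table))
  if (length(missing))
    stop("assessment table is missing column(s): ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(table$status), names(.status_to_code))
  if (length(bad))
    stop("invalid status value(s): ", paste(bad, collapse = ", "))
  key <- paste(table$gene_id, table$assessment_id, sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup))
    stop("duplicated (gene, assessment) entr(ies): ",
         paste(gsub("\r", "/", dup), collapse = ", "))
  table
}
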