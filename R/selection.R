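#' Expression pre-filter for count matrices
#'
#' Keeps genes observed at least `min_count` times in at least one library,
#' the usual detectability filter before stability screening.
#'
#' @param matrix Count-scale expression matrix (genes x samples).
#' @param min_count Minimum count a gene must reach in some sample (default 20).
#' @return Character vector of retained gene ids, in input order.
#' @export
expression_prefilter <- function(matrix, min_count = 20) {
  validate_expression_matrix(matrix)
  rownames(matrix)[apply(matrix, 1L, max) >= min_count]
}

.assessment_rows <- function(gene_ids, assessment_id, status) {
  data.frame(gene_id = gene_ids, assessment_id = assessment_id,
             status = status, stringsAsFactors = FALSE)
}

#' Median stability criterion against a genome-wide background
#'
#' A candidate passes when its mean clr expression is strictly above the
#' median mean clr of the background genes AND its clr variance is strictly
#' below the background's median variance — i.e. the gene is both well
#' expressed and unusually stable. Ties at either median fail. Candidates
#' absent from the assay are marked not detectable.
#'
#' The background defaults to every assayed gene, candidates included;
#' removing a handful of candidates from a genome-wide screen does not move
#' the medians, but `exclude_candidates = TRUE` gives the literal
#' "all other genes" reading.
#'
#' @param stats Per-gene clr statistics from [clr_gene_stats()] covering the
#'   whole screen.
#' @param candidates Character vector of candidate gene ids.
#' @param assessment_id Label for this assessment in the output table.
#' @param exclude_candidates Drop candidates from the background before
#'   taking medians (default `FALSE`).
#' @return Long assessment table rows (`gene_id`, `assessment_id`, `status`).
#' @export
median_criterion <- function(stats, candidates, assessment_id = "median",
                             exclude_candidates = FALSE) {
  if (!nrow(stats)) stop("empty background: no clr statistics supplied")
  background <- stats
  if (exclude_candidates)
    background <- stats[!(stats$gene_id %in% candidates), , drop = FALSE]
  if (!nrow(background)) stop("empty background after excluding candidates")
  med_mean <- stats::median(background$mean_clr)
  med_var <- stats::median(background$var_clr)
  idx <- match(candidates, stats$gene_id)
  status <- ifelse(is.na(idx), "not_detectable",
                   ifelse(stats$mean_clr[idx] > med_mean &
                          stats$var_clr[idx] < med_var, "pass", "fail"))
  .assessment_rows(candidates, assessment_id, status)
}

#' Reference-gene stability criterion
#'
#' A candidate passes when its clr variance is strictly below that of a
#' designated reference gene — in the motivating design, the least variable
#' core-clock gene (Cry2) on a targeted panel, so that "stable" means "less
#' variable than any truly rhythmic gene". Ties fail.
#'
#' @inheritParams median_criterion
#' @param reference_gene Gene id of the variance yardstick; must be present
#'   in `stats`.
#' @return Long assessment table rows.
#' @export
reference_gene_criterion <- function(stats, candidates, reference_gene,
                                     assessment_id = "reference") {
  ref_idx <- match(reference_gene, stats$gene_id)
  if (is.na(ref_idx))
    stop("reference gene '", reference_gene, "' not found in clr statistics")
  ref_var <- stats$var_clr[ref_idx]
  idx <- match(candidates, stats$gene_id)
  status <- ifelse(is.na(idx), "not_detectable",
                   ifelse(stats$var_clr[idx] < ref_var, "pass", "fail"))
  .assessment_rows(candidates, assessment_id, status)
}

#' Empirical CDF of a gene's fold-change magnitudes across studies
#'
#' Fold-changes are symmetrised to magnitudes `max(fc, 1/fc)` so that up- and
#' down-regulation count equally against stability, then summarised as a
#' right-continuous empirical cumulative distribution function.
#'
#' @param table Fold-change table (`gene_id`, `study_id`, `fold_change`).
#' @param gene_id Gene to summarise.
#' @return A function of class `ecdf`; `f(t)` is the fraction of studies with
#'   symmetrised fold-change `<= t`.
#' @export
fold_change_cdf <- function(table, gene_id) {
  validate_fold_change_table(table)
  fc <- table$fold_change[table$gene_id == gene_id]
  if (!length(fc)) stop("no studies found for gene '", gene_id, "'")
  stats::ecdf(pmax(fc, 1 / fc))
}

#' Meta-analytic stability criterion across many studies
#'
#' A candidate passes when its symmetrised fold-change magnitude is strictly
#' below `threshold` in strictly more than `required_fraction` of the studies
#' reporting it (default: below 1.2 in more than 90% of studies). Set
#' `inclusive = TRUE` to accept a fraction exactly equal to
#' `required_fraction`.
#'
#' @inheritParams fold_change_cdf
#' @param candidates Candidate gene ids.
#' @param threshold Fold-change magnitude that counts as a perturbation.
#' @param required_fraction Fraction of studies that must fall below
#'   `threshold`.
#' @param inclusive Pass at exactly `required_fraction` (default `FALSE`).
#' @param assessment_id Label for the output rows.
#' @return Long assessment table rows.
#' @export
meta_criterion <- function(table, candidates, threshold = 1.2,
                           required_fraction = 0.9, inclusive = FALSE,
                           assessment_id = "meta") {
  validate_fold_change_table(table)
  status <- vapply(candidates, function(g) {
    fc <- table$fold_change[table$gene_id == g]
    if (!length(fc)) return("not_detectable")
    frac <- mean(pmax(fc, 1 / fc) < threshold)
    ok <- if (inclusive) frac >= required_fraction else frac > required_fraction
    if (ok) "pass" else "fail"
  }, character(1L))
  .assessment_rows(candidates, assessment_id, unname(status))
}

#' Combine assessments into core and extended marker sets
#'
#' The core set contains genes that failed no assessment; the extended set
#' additionally admits genes with at most `max_fails_for_extended` failures
#' (default one). "Not detectable" entries count as neither pass nor fail, so
#' a gene with one failure and one missing assay still reaches the extended
#' set. Output gene lists are sorted, making the result invariant to row
#' permutations of the input.
#'
#' @param table Long assessment table covering every candidate in every
#'   assessment.
#' @param max_fails_for_extended Maximum failures tolerated in the extended
#'   set.
#' @return List of class `marker_sets` with elements `core` and `extended`
#'   (character vectors, `core` a subset of `extended`) and `fails`, the
#'   named per-gene failure count.
#' @export
combine_assessments <- function(table, max_fails_for_extended = 1L) {
  validate_assessment_table(table)
  genes <- sort(unique(table$gene_id))
  fails <- vapply(genes, function(g) {
    sum(table$status[table$gene_id == g] == "fail")
  }, integer(1L))
  out <- list(core = genes[fails == 0L],
              extended = genes[fails <= max_fails_for_extended],
              fails = fails)
  class(out) <- "marker_sets"
  out
}

#' @export
print.marker_sets <- function(x, ...) {
  cat("Marker sets\n")
  cat("  core     (no failed assessment): ",
      paste(x$core, collapse = ", "), "\n", sep = "")
  cat("  extended (at most one failure):  ",
      paste(x$extended, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Run the full multi-assay stability assessment of candidate genes
#'
#' Chains the assessments used to nominate normalisation genes: one median
#' criterion per genome-wide screen (e.g. the in-house age-pool RNA-seq
#' screen and public datasets), a reference-gene criterion on a targeted
#' count panel, and the meta-analytic fold-change criterion, then combines
#' them into core and extended sets.
#'
#' @param candidates Candidate gene ids.
#' @param screens Named list of genome-wide screens; each element is a list
#'   with `matrix` (counts) and optionally `grouping` (condition label per
#'   sample; default one condition per column) and `min_count` for the
#'   expression pre-filter (default 20).
#' @param panel Optional list with `matrix`, `reference_gene`, and optionally
#'   `grouping` (default: every sample its own condition).
#' @param fold_changes Optional per-study fold-change table for the meta
#'   criterion.
#' @param pseudocount Pseudocount used in all clr transforms.
#' @param meta_threshold,meta_fraction Parameters of [meta_criterion()].
#' @return List with `assessments` (long table) and `sets`
#'   ([combine_assessments()] output).
#' @export
run_selection <- function(candidates, screens = list(), panel = NULL,
                          fold_changes = NULL, pseudocount = 0.5,
                          meta_threshold = 1.2, meta_fraction = 0.9) {
  if (!length(candidates)) stop("empty candidate list")
  rows <- list()
  for (nm in names(screens)) {
    sc <- screens[[nm]]
    keep <- expression_prefilter(sc$matrix,
                                 if (is.null(sc$min_count)) 20 else sc$min_count)
    m <- sc$matrix[keep, , drop = FALSE]
    clr <- clr_transform(m, pseudocount)
    stats <- clr_gene_stats(clr, sc$grouping)
    rows[[nm]] <- median_criterion(stats, candidates, assessment_id = nm)
  }
  if (!is.null(panel)) {
    clr <- clr_transform(panel$matrix, pseudocount)
    stats <- clr_gene_stats(clr, panel$grouping)
    rows[["panel"]] <- reference_gene_criterion(stats, candidates,
                                                panel$reference_gene,
                                                assessment_id = "panel")
  }
  if (!is.null(fold_changes)) {
    rows[["meta"]] <- meta_criterion(fold_changes, candidates,
                                     threshold = meta_threshold,
                                     required_fraction = meta_fraction)
  }
  if (!length(rows)) stop("no assessments requested")
  assessments <- do.call(rbind, c(rows, make.row.names = FALSE))
  list(assessments = assessments, sets = combine_assessments(assessments))
}
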