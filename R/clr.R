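#' Geometric mean
#'
#' `exp(mean(log(x)))`; the scale-appropriate average for multiplicative
#' quantities. Scale-equivariant: `geometric_mean(k * x) == k * geometric_mean(x)`.
#'
#' @param values Positive numeric vector.
#' @return Positive scalar.
#' @export
geometric_mean <- function(values) {
  if (!length(values)) stop("geometric mean of an empty vector is undefined")
  if (any(!is.finite(values) | values <= 0))
    stop("geometric mean requires strictly positive, finite values")
  exp(mean(log(values)))
}

#' Centered log-ratio transform of an expression matrix
#'
#' For each sample (column) `x`, returns `log(x / g(x))` where `g(x)` is the
#' column's geometric mean. The clr removes per-sample compositional scale:
#' multiplying any column by a positive constant leaves its clr unchanged,
#' and every clr column sums to zero. Counts may contain zeros; a pseudocount
#' is added first (default 0.5) so the logarithm is defined.
#'
#' @param matrix Non-negative expression matrix (genes x samples).
#' @param pseudocount Non-negative value added to every entry before taking
#'   logs. Use 0 only for strictly positive matrices.
#' @return Matrix of clr values with the input dimnames.
#' @export
clr_transform <- function(matrix, pseudocount = 0.5) {
  validate_expression_matrix(matrix)
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  shifted <- matrix + pseudocount
  if (any(shifted <= 0)) {
    idx <- which(shifted <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "zero value at gene '%s', sample '%s' with pseudocount %g; clr needs positive values",
      rownames(matrix)[idx[1]], colnames(matrix)[idx[2]], pseudocount))
  }
  lg <- log(shifted)
  sweep(lg, 2L, colMeans(lg), "-")
}

#' Per-gene clr summary statistics across conditions
#'
#' Collapses clr values to one value per condition (the arithmetic mean of a
#' gene's clr over the samples in each condition group), then reports the
#' mean and the unbiased (n-1) variance of those condition-level values per
#' gene. With the default grouping every sample is its own condition.
#'
#' @param clr Matrix of clr values (genes x samples), as returned by
#'   [clr_transform()].
#' @param grouping Optional vector of condition labels, one per sample
#'   (recycled names/factors allowed). `NULL` treats each sample as its own
#'   condition.
#' @return data.frame with columns `gene_id`, `mean_clr`, `var_clr`,
#'   `n_conditions`.
#' @export
clr_gene_stats <- function(clr, grouping = NULL) {
  if (is.null(grouping)) grouping <- colnames(clr)
  if (length(grouping) != ncol(clr))
    stop("grouping must supply one condition label per sample")
  grouping <- as.character(grouping)
  groups <- unique(grouping)
  if (length(groups) < 2L)
    stop("clr summary statistics need at least 2 conditions; got ", length(groups))
  cond <- vapply(groups, function(g) {
    rowMeans(clr[, grouping == g, drop = FALSE])
  }, numeric(nrow(clr)))
  data.frame(
    gene_id = rownames(clr),
    mean_clr = rowMeans(cond),
    var_clr = apply(cond, 1L, stats::var),
    n_conditions = length(groups),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Pairwise fold-changes between conditions
#'
#' For every unordered pair of conditions, the per-gene fold-change of the
#' first condition relative to the second. In the default (reference-free)
#' mode the fold-change is computed on the clr scale, i.e. on values aligned
#' to a common per-sample geometric mean, so no normalisation genes are
#' needed: `fc = exp(clr_a - clr_b)`. With `reference_free = FALSE` the raw
#' ratio of condition means is used instead (appropriate for matrices that
#' are already normalised).
#'
#' @inheritParams clr_transform
#' @param grouping Condition label per sample; `NULL` uses each sample.
#' @param reference_free Logical; compute fold-changes after clr alignment
#'   (default) or on raw condition means.
#' @return data.frame with columns `gene_id`, `condition_a`, `condition_b`,
#'   `fold_change`, with `C (C-1) / 2` rows per gene for `C` conditions.
#' @export
pairwise_fold_changes <- function(matrix, grouping = NULL,
                                  reference_free = TRUE, pseudocount = 0.5) {
  if (is.null(grouping)) grouping <- colnames(matrix)
  grouping <- as.character(grouping)
  groups <- unique(grouping)
  if (length(groups) < 2L) stop("pairwise fold-changes need at least 2 conditions")
  if (reference_free) {
    clr <- clr_transform(matrix, pseudocount)
    cond <- vapply(groups, function(g) rowMeans(clr[, grouping == g, drop = FALSE]),
                   numeric(nrow(matrix)))
    ratio <- function(a, b) exp(cond[, a] - cond[, b])
  } else {
    cond <- vapply(groups, function(g) rowMeans(matrix[, grouping == g, drop = FALSE]),
                   numeric(nrow(matrix)))
    if (any(cond <= 0)) stop("raw fold-changes need positive condition means")
    ratio <- function(a, b) cond[, a] / cond[, b]
  }
  pairs <- utils::combn(groups, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    data.frame(gene_id = rownames(matrix),
               condition_a = pairs[1L, k], condition_b = pairs[2L, k],
               fold_change = unname(ratio(pairs[1L, k], pairs[2L, k])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pairwise Pearson correlations between genes
#'
#' Correlations across samples between all pairs of the requested genes,
#' computed on the (normalised) expression values. Genes with zero variance
#' have undefined correlations, reported as `NA`; the diagonal is 1.
#'
#' @param matrix Expression matrix (genes x samples), at least 3 samples.
#' @param gene_subset Genes to correlate; `NULL` uses all genes.
#' @return Symmetric correlation matrix.
#' @export
pairwise_correlations <- function(matrix, gene_subset = NULL) {
  if (ncol(matrix) < 3L) stop("pairwise correlations need at least 3 samples")
  if (is.null(gene_subset)) gene_subset <- rownames(matrix)
  missing <- setdiff(gene_subset, rownames(matrix))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  sub <- matrix[gene_subset, , drop = FALSE]
  cors <- suppressWarnings(stats::cor(t(sub), method = "pearson"))
  diag(cors) <- 1
  cors
}
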