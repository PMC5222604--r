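#' Per-sample normalisation constants from positive spike-in controls
#'
#' Each hybridisation carries positive controls at known input amounts. For
#' sample `s` and control `i` the constant is `c_{s,i} = expected_i /
#' observed_{s,i}`, so multiplying a sample's counts by its constant converts
#' them to the input-amount scale. The per-control constants are combined per
#' sample by their geometric mean.
#'
#' @param observed Matrix of control counts (controls x samples), rownames
#'   control ids, all strictly positive.
#' @param expected Named vector of known input amounts, one per control.
#' @return List of class `normalisation_constants` with `per_reference`
#'   (controls x samples matrix of `c_{s,i}`) and `combined` (named
#'   per-sample vector, the geometric mean over controls).
#' @export
positive_control_constants <- function(observed, expected) {
  if (!is.matrix(observed) || is.null(rownames(observed)) || is.null(colnames(observed)))
    stop("'observed' must be a controls x samples matrix with dimnames")
  missing <- setdiff(rownames(observed), names(expected))
  if (length(missing))
    stop("no expected amount for control(s): ", paste(missing, collapse = ", "))
  expected <- expected[rownames(observed)]
  if (any(expected <= 0)) stop("expected control amounts must be positive")
  if (any(observed <= 0)) {
    idx <- which(observed <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive count for control '%s' in sample '%s' (failed hybridisation?)",
                 rownames(observed)[idx[1]], colnames(observed)[idx[2]]))
  }
  per_ref <- expected / observed
  combined <- exp(colMeans(log(per_ref)))
  structure(list(per_reference = per_ref, combined = combined),
            class = "normalisation_constants")
}

#' Per-sample factors from a set of stable marker genes
#'
#' For each marker gene `g` the per-sample constant is the gene's cross-sample
#' geometric mean divided by its value in the sample; the sample's factor is
#' the geometric mean of those constants over all markers. Factors therefore
#' have geometric mean 1 across samples, and equalise the markers' geometric
#' mean across samples when applied. Anchoring each gene to its own
#' cross-sample geometric mean (rather than to one designated sample) keeps
#' the factors symmetric in the samples.
#'
#' @param matrix Positive expression matrix (genes x samples), typically
#'   already on the input-amount scale via [positive_control_constants()].
#' @param markers Marker gene ids; all must be present with strictly positive
#'   values in every sample.
#' @return Named per-sample factor vector.
#' @export
marker_normalisation_factors <- function(matrix, markers) {
  validate_expression_matrix(matrix)
  missing <- setdiff(markers, rownames(matrix))
  if (length(missing))
    stop("marker gene(s) not in matrix: ", paste(missing, collapse = ", "))
  sub <- matrix[markers, , drop = FALSE]
  if (any(sub <= 0)) {
    idx <- which(sub <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("marker '%s' has non-positive value in sample '%s'",
                 markers[idx[1]], colnames(matrix)[idx[2]]))
  }
  lg <- log(sub)
  # log c_{g,s} = mean_s' log x_{g,s'} - log x_{g,s}; factor_s = gm over g
  log_const <- sweep(-lg, 1L, rowMeans(lg), "+")
  exp(colMeans(log_const))
}

#' Apply per-sample normalisation factors to a matrix
#'
#' @param matrix Expression matrix (genes x samples).
#' @param factors Positive factor per sample; names, when present, must match
#'   the matrix's sample ids.
#' @return The rescaled matrix.
#' @export
apply_normalisation <- function(matrix, factors) {
  validate_expression_matrix(matrix)
  if (length(factors) != ncol(matrix))
    stop("need one factor per sample: got ", length(factors),
         " for ", ncol(matrix), " samples")
  if (!is.null(names(factors))) {
    if (!setequal(names(factors), colnames(matrix)))
      stop("factor names do not match sample ids")
    factors <- factors[colnames(matrix)]
  }
  if (any(!is.finite(factors) | factors <= 0))
    stop("normalisation factors must be positive and finite")
  sweep(matrix, 2L, factors, "*")
}
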