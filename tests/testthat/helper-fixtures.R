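# Shared fixtures: small matrices built in code, plus independent oracles
# used across test files.

toy_matrix <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

random_count_matrix <- function(n_genes, n_samples, seed, lambda = 50) {
  set.seed(seed)
  toy_matrix(matrix(stats::rpois(n_genes * n_samples, lambda), n_genes))
}

# Brute-force clr statistics: explicit loops, no vectorised shortcuts.
# Independent of clr_transform()/clr_gene_stats().
oracle_clr_stats <- function(matrix, grouping = NULL, pseudocount = 0) {
  if (is.null(grouping)) grouping <- colnames(matrix)
  x <- matrix + pseudocount
  clr <- x * 0
  for (j in seq_len(ncol(x))) {
    gm <- prod(x[, j])^(1 / nrow(x))
    for (i in seq_len(nrow(x))) clr[i, j] <- log(x[i, j] / gm)
  }
  groups <- unique(grouping)
  out <- data.frame(gene_id = rownames(x), mean_clr = NA_real_,
                    var_clr = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(x))) {
    cond <- numeric(length(groups))
    for (k in seq_along(groups)) {
      vals <- clr[i, grouping == groups[k]]
      cond[k] <- sum(vals) / length(vals)
    }
    mu <- sum(cond) / length(cond)
    out$mean_clr[i] <- mu
    out$var_clr[i] <- sum((cond - mu)^2) / (length(cond) - 1)
  }
  out
}

# The published six-assay stability summary of the 16 liver candidate genes,
# shipped as a plain-text fixture.
published_assessments <- function() {
  read_assessment_table(system.file("extdata", "liver_marker_assessments.tsv",
                                    package = "stabnorm"))
}

# Two-age circadian design: 12 ZT x 2 replicates per age, N = 24 per group.
two_age_design <- function(ages = c(3, 24)) panel_design(ages = ages)

# Draw one gene's young/old data frames from the panel model without
# technical factors (already-normalised scale).
draw_two_age_gene <- function(amplitude = 0.3, acrophase = 8, lfc = 0,
                              baseline = 1000, dispersion = 0.002,
                              noise_inflation = 1e-4) {
  design <- two_age_design()
  p <- gene_params("g", baseline, amplitude, acrophase, lfc,
                   dispersion, noise_inflation)
  mu <- p$baseline * exp(p$age_log_fold_change *
                           (design$age_months - 3) / 21) *
    (1 + p$circadian_amplitude *
       cos(2 * pi * (design$zeitgeber_time_h - p$acrophase_h) / 24))
  disp <- p$dispersion + p$noise_inflation_per_age * (design$age_months - 3)
  v <- stats::rnbinom(nrow(design), mu = mu, size = 1 / disp)
  young <- design$age_months == 3
  list(young = data.frame(value = v[young], zt = design$zeitgeber_time_h[young]),
       old = data.frame(value = v[!young], zt = design$zeitgeber_time_h[!young]))
}
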