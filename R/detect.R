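#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param m Number of tests in the family (positive integer).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  if (!is.numeric(m) || m < 1 || m != round(m))
    stop("m must be a positive integer")
  alpha / m
}

.check_rm_frame <- function(df, label) {
  if (!all(c("value", "zt") %in% colnames(df)))
    stop("'", label, "' must have columns 'value' and 'zt'")
  if (any(!is.finite(df$value))) stop("non-finite values in '", label, "'")
  df
}

#' Repeated-measures test for an age effect across the circadian cycle
#'
#' Compares two age groups sampled on the same zeitgeber-time grid with a
#' linear mixed model: age as fixed effect and a random intercept per time
#' point, pairing the groups through the shared times. This is the
#' repeated-measures ANOVA appropriate when samples taken at the same ZT are
#' matched across ages; with one observation per (age, time point) cell it
#' reduces exactly to a paired t-test over time points. Values are analysed
#' on the log scale by default, matching the multiplicative noise and
#' fold-change structure of expression data.
#'
#' @param young,old data.frames with columns `value` (positive when
#'   `log_scale`) and `zt` (zeitgeber time, h); both groups must cover the
#'   same set of time points.
#' @param log_scale Fit on `log(value)` (default `TRUE`).
#' @param average_replicates Average replicates within each (age, ZT) cell
#'   before fitting (default `FALSE`).
#' @return Two-sided p-value for the age effect.
#' @export
repeated_measures_anova <- function(young, old, log_scale = TRUE,
                                    average_replicates = FALSE) {
  .check_rm_frame(young, "young"); .check_rm_frame(old, "old")
  zts <- sort(unique(young$zt))
  if (!identical(zts, sort(unique(old$zt))))
    stop("young and old groups must share the same zeitgeber-time grid")
  if (length(zts) < 2L) stop("need at least 2 time points")
  df <- rbind(data.frame(value = young$value, zt = young$zt, age = "young"),
              data.frame(value = old$value, zt = old$zt, age = "old"))
  if (log_scale) {
    if (any(df$value <= 0)) stop("log-scale analysis needs positive values")
    df$value <- log(df$value)
  }
  if (average_replicates)
    df <- stats::aggregate(value ~ zt + age, data = df, FUN = mean)
  df$age <- factor(df$age, levels = c("young", "old"))
  df$zt <- factor(df$zt)
  if (stats::var(df$value) == 0) return(1)  # no variation, no effect
  # the optim-based optimizer is robust when the between-time-point variance
  # component approaches zero (flat, non-rhythmic genes)
  fit <- nlme::lme(value ~ age, random = ~ 1 | zt, data = df, method = "REML",
                   control = nlme::lmeControl(opt = "optim"))
  tab <- stats::anova(fit)
  unname(tab[["p-value"]][rownames(tab) == "age"])
}

#' Two-factor ANOVA with per-time-point Bonferroni post-tests
#'
#' Standard two-way decomposition of expression into age, time, and
#' age-by-time interaction on a balanced replicated design, followed (for two
#' age groups) by Bonferroni-corrected comparisons of the age groups at each
#' time point using the pooled residual variance.
#'
#' @param values Numeric response vector.
#' @param age Age-group label per observation.
#' @param time Time-point label per observation.
#' @return List of class `two_way_anova_result` with `p_age`, `p_time`,
#'   `p_interaction`, and `post_tests`, a data.frame per time point with the
#'   group difference, Bonferroni-adjusted p-value and a significance flag
#'   (`""`, `"*"` p<0.05, `"**"` p<0.01, `"***"` p<0.001). `post_tests` is
#'   `NULL` when there are more than two age groups.
#' @export
two_way_anova <- function(values, age, time) {
  age <- factor(age); time <- factor(time)
  cells <- table(age, time)
  if (any(cells < 2L))
    stop("unreplicated cell(s): the interaction is not estimable without replicates")
  if (stats::var(values) == 0) {
    # perfectly constant response: no term explains any variation
    res <- list(p_age = 1, p_time = 1, p_interaction = 1, post_tests = NULL)
    if (nlevels(age) == 2L)
      res$post_tests <- data.frame(time = levels(time), difference = 0,
                                   t = 0, p_adjusted = 1,
                                   signif = factor("", c("***", "**", "*", "")))
    class(res) <- "two_way_anova_result"
    return(res)
  }
  fit <- stats::aov(values ~ age * time)
  tab <- summary(fit)[[1L]]
  p <- tab[["Pr(>F)"]]
  # a term explaining no variation at all is not significant, even when the
  # residual variance is 0 and the F ratio is undefined
  p[is.nan(p) & tab[["Mean Sq"]] == 0] <- 1
  term <- trimws(rownames(tab))
  res <- list(p_age = p[term == "age"], p_time = p[term == "time"],
              p_interaction = p[term == "age:time"], post_tests = NULL)
  if (nlevels(age) == 2L) {
    mse <- tab["Residuals", "Mean Sq"]
    dfres <- tab["Residuals", "Df"]
    lv <- levels(age)
    post <- lapply(levels(time), function(tp) {
      v1 <- values[age == lv[1L] & time == tp]
      v2 <- values[age == lv[2L] & time == tp]
      diff <- mean(v2) - mean(v1)
      tstat <- diff / sqrt(mse * (1 / length(v1) + 1 / length(v2)))
      praw <- 2 * stats::pt(-abs(tstat), dfres)
      data.frame(time = tp, difference = diff, t = tstat,
                 p_adjusted = min(1, praw * nlevels(time)),
                 stringsAsFactors = FALSE)
    })
    post <- do.call(rbind, post)
    post$signif <- cut(post$p_adjusted, c(-Inf, 0.001, 0.01, 0.05, Inf),
                       labels = c("***", "**", "*", ""))
    res$post_tests <- post
  }
  class(res) <- "two_way_anova_result"
  res
}

#' Average fold-change between age groups over the circadian cycle
#'
#' The ratio of mean old to mean young expression is computed at each shared
#' time point and the ratios are averaged. The default geometric average is
#' consistent with the multiplicative model of expression changes; an
#' arithmetic average is available behind the `average` flag.
#'
#' @inheritParams repeated_measures_anova
#' @param average `"geometric"` (default) or `"arithmetic"`.
#' @return Positive fold-change, old relative to young.
#' @export
fold_change_estimate <- function(young, old, average = c("geometric", "arithmetic")) {
  average <- match.arg(average)
  .check_rm_frame(young, "young"); .check_rm_frame(old, "old")
  zts <- sort(unique(young$zt))
  if (!identical(zts, sort(unique(old$zt))))
    stop("young and old groups must share the same zeitgeber-time grid")
  ratios <- vapply(zts, function(tp) {
    my <- mean(young$value[young$zt == tp])
    mo <- mean(old$value[old$zt == tp])
    if (my <= 0 || mo <= 0)
      stop("non-positive mean at zeitgeber time ", tp)
    mo / my
  }, numeric(1L))
  if (average == "geometric") geometric_mean(ratios) else mean(ratios)
}

#' Detect age-related expression changes across a gene panel
#'
#' Runs [repeated_measures_anova()] and [fold_change_estimate()] per gene on
#' a normalised matrix, comparing two age classes over the shared
#' zeitgeber-time grid, and flags genes significant at the Bonferroni
#' threshold `alpha / family_size`.
#'
#' @param matrix Normalised expression matrix (genes x samples).
#' @param design Sample design (see [validate_sample_design()]) covering the
#'   matrix's samples.
#' @param young_age,old_age Age classes (months) to compare.
#' @param alpha Family-wise error rate (default 0.05).
#' @param family_size Number of tests for the Bonferroni correction; defaults
#'   to the number of genes tested.
#' @param genes Genes to test; `NULL` tests all rows.
#' @param exclude Genes to drop before testing (e.g. the marker genes used
#'   for normalisation, which are constant by construction).
#' @param log_scale Passed to [repeated_measures_anova()].
#' @return data.frame with columns `gene_id`, `p_value`, `fold_change`,
#'   `significant`.
#' @export
detect_age_effects <- function(matrix, design, young_age, old_age,
                               alpha = 0.05, family_size = NULL,
                               genes = NULL, exclude = NULL,
                               log_scale = TRUE) {
  validate_expression_matrix(matrix)
  design <- validate_sample_design(design)
  missing <- setdiff(colnames(matrix), design$sample_id)
  if (length(missing))
    stop("sample(s) missing from design: ", paste(missing, collapse = ", "))
  if (is.null(genes)) genes <- rownames(matrix)
  genes <- setdiff(genes, exclude)
  if (!length(genes)) stop("no genes left to test")
  design <- design[match(colnames(matrix), design$sample_id), ]
  pick <- function(age) {
    ids <- design$sample_id[design$age_months == age]
    if (!length(ids)) stop("no samples with age_months == ", age)
    ids
  }
  young_ids <- pick(young_age); old_ids <- pick(old_age)
  zt <- stats::setNames(design$zeitgeber_time_h, design$sample_id)
  if (is.null(family_size)) family_size <- length(genes)
  thr <- bonferroni_threshold(alpha, family_size)
  rows <- lapply(genes, function(g) {
    young <- data.frame(value = matrix[g, young_ids], zt = zt[young_ids])
    old <- data.frame(value = matrix[g, old_ids], zt = zt[old_ids])
    p <- repeated_measures_anova(young, old, log_scale = log_scale)
    fc <- fold_change_estimate(young, old)
    data.frame(gene_id = g, p_value = p, fold_change = fc,
               significant = p < thr, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
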