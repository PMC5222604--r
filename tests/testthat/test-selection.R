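test_that("expression pre-filter keeps genes reaching the count floor somewhere", {
  m <- toy_matrix(rbind(c(0, 19, 5), c(0, 20, 0), c(100, 0, 0)),
                  genes = c("low", "edge", "high"))
  expect_identical(expression_prefilter(m, 20), c("edge", "high"))
  expect_identical(expression_prefilter(m, 0), c("low", "edge", "high"))
})

test_that("median criterion requires strictly above-median expression and below-median variance", {
  stats <- data.frame(gene_id = sprintf("g%d", 1:5),
                      mean_clr = c(1, 2, 3, 4, 5),
                      var_clr = c(0.1, 0.2, 0.3, 0.4, 0.5),
                      n_conditions = 4L)
  rows <- median_criterion(stats, c("g4", "g3", "g2", "absent"))
  got <- setNames(rows$status, rows$gene_id)
  expect_identical(got[["g4"]], "fail")     # var above median
  expect_identical(got[["g3"]], "fail")     # sits exactly at both medians
  expect_identical(got[["g2"]], "fail")     # mean below median
  expect_identical(got[["absent"]], "not_detectable")

  # the single highest-expressed, zero-variance gene passes
  stats$mean_clr[1] <- 10; stats$var_clr[1] <- 0
  expect_identical(median_criterion(stats, "g1")$status, "pass")
  expect_error(median_criterion(stats[0, ], "g1"), "background")
})

test_that("median criterion equals a brute-force sort-and-compare oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 1001
    stats <- data.frame(gene_id = sprintf("g%04d", 1:n),
                        mean_clr = rnorm(n), var_clr = rexp(n),
                        n_conditions = 4L)
    cands <- sample(stats$gene_id, 30)
    rows <- median_criterion(stats, cands)
    # oracle: sort both measures and require the candidate strictly inside
    # the upper half by mean and the lower half by variance (n odd, ties none)
    sorted_mean <- sort(stats$mean_clr)
    sorted_var <- sort(stats$var_clr)
    mid <- (n + 1) / 2
    for (k in seq_along(cands)) {
      i <- match(cands[k], stats$gene_id)
      want <- if (which(sorted_mean == stats$mean_clr[i]) > mid &&
                  which(sorted_var == stats$var_clr[i]) < mid)
        "pass" else "fail"
      expect_identical(rows$status[k], want)
    }
  }
  # a candidate ranked 600th of 1001 by mean sits below the median: always fail
  stats <- data.frame(gene_id = sprintf("g%04d", 1:1001),
                      mean_clr = sort(rnorm(1001), decreasing = TRUE),
                      var_clr = 0, n_conditions = 4L)
  stats$var_clr <- seq(0, 1, length.out = 1001)
  expect_identical(median_criterion(stats, "g0600")$status, "fail")
})

test_that("reference-gene criterion is strict and flags missing genes", {
  stats <- data.frame(gene_id = c("ref", "a", "b", "c"),
                      mean_clr = 0, var_clr = c(0.02, 0.02, 0, 0.05),
                      n_conditions = 192L)
  rows <- reference_gene_criterion(stats, c("a", "b", "c", "z"), "ref")
  expect_identical(rows$status, c("fail", "pass", "fail", "not_detectable"))
  expect_error(reference_gene_criterion(stats, "a", "nope"), "nope")
})

test_that("a panel with 11 stable candidates yields 11 reference-criterion passes", {
  # 16 candidates of which 5 are constructed variable; the reference is the
  # least variable rhythmic gene, as in the motivating panel experiment
  stable <- sprintf("cand%02d", 1:11)
  variable <- sprintf("cand%02d", 12:16)
  params <- rbind(
    gene_params(stable, baseline = 1500, dispersion = 0.008),
    gene_params(variable, baseline = 1200, circadian_amplitude = 0.4,
                acrophase_h = seq(2, 18, length.out = 5),
                age_log_fold_change = log(1.5), dispersion = 0.02),
    gene_params("Cry2", baseline = 1000, circadian_amplitude = 0.15,
                acrophase_h = 14, dispersion = 0.008),
    gene_params(sprintf("clock%d", 1:6), baseline = 800,
                circadian_amplitude = seq(0.3, 0.6, length.out = 6),
                acrophase_h = seq(0, 20, length.out = 6), dispersion = 0.01)
  )
  sim <- simulate_panel(panel_design(), params, seed = 11)
  stats <- clr_gene_stats(clr_transform(sim$matrix))
  rows <- reference_gene_criterion(stats, c(stable, variable), "Cry2")
  expect_equal(sum(rows$status == "pass"), 11L)
  expect_identical(rows$gene_id[rows$status == "pass"], stable)
})

test_that("fold-change CDF symmetrises magnitudes and counts studies", {
  tbl <- data.frame(gene_id = "g", study_id = sprintf("s%d", 1:4),
                    fold_change = c(1.0, 1.1, 1.1, 1.3))
  cdf <- fold_change_cdf(tbl, "g")
  expect_equal(cdf(1.2), 0.75)
  expect_equal(cdf(1.3), 1)

  flat <- data.frame(gene_id = "g", study_id = sprintf("s%d", 1:5),
                     fold_change = 1)
  expect_equal(fold_change_cdf(flat, "g")(1 + 1e-9), 1)

  single <- data.frame(gene_id = "g", study_id = "s1", fold_change = 1.5)
  expect_equal(fold_change_cdf(single, "g")(1.2), 0)

  down <- data.frame(gene_id = "g", study_id = "s1", fold_change = 0.5)
  expect_equal(fold_change_cdf(down, "g")(1.9), 0)  # 0.5 counts as 2-fold
  expect_error(fold_change_cdf(tbl, "missing"), "missing")
})

test_that("meta criterion demands the threshold be beaten in >90% of studies", {
  tbl <- rbind(
    data.frame(gene_id = "borderline", study_id = sprintf("s%d", 1:4),
               fold_change = c(1.0, 1.1, 1.1, 1.3)),
    data.frame(gene_id = "quiet", study_id = sprintf("s%d", 1:100),
               fold_change = 1.05),
    data.frame(gene_id = "exact", study_id = sprintf("s%d", 1:10),
               fold_change = c(rep(1.0, 9), 1.25))
  )
  rows <- meta_criterion(tbl, c("borderline", "quiet", "exact", "gone"))
  got <- setNames(rows$status, rows$gene_id)
  expect_identical(got[["borderline"]], "fail")  # 0.75 <= 0.9
  expect_identical(got[["quiet"]], "pass")
  expect_identical(got[["exact"]], "fail")       # fraction exactly 0.9 is strict
  expect_identical(got[["gone"]], "not_detectable")
  incl <- meta_criterion(tbl, "exact", inclusive = TRUE)
  expect_identical(incl$status, "pass")
})

test_that("the published assessment summary yields the known core and extended sets", {
  sets <- combine_assessments(published_assessments())
  expect_identical(sets$core, sort(c("Atp5h", "Gsk3b", "Sirt2")))
  expect_identical(setdiff(sets$extended, sets$core),
                   sort(c("Nono", "Tprkb", "Tspo", "Ttr")))
  # two failures exclude a gene from both sets, ND entries notwithstanding
  expect_false("H3f3a" %in% sets$extended)
  expect_equal(unname(sets$fails["H3f3a"]), 2L)
  # one failure plus one not-detectable still reaches the extended set
  expect_true("Nono" %in% sets$extended)
  expect_equal(unname(sets$fails["Nono"]), 1L)
})

test_that("marker-set combination is invariant to table permutation", {
  tbl <- published_assessments()
  set.seed(9)
  shuffled <- tbl[sample(nrow(tbl)), ]
  expect_identical(combine_assessments(shuffled)[c("core", "extended")],
                   combine_assessments(tbl)[c("core", "extended")])
})
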