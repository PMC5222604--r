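test_that("Bonferroni threshold is alpha over the family size", {
  expect_equal(bonferroni_threshold(0.05, 36), 0.05 / 36)
  expect_equal(bonferroni_threshold(0.05, 36), 0.0013888, tolerance = 1e-4)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 10), 0.001)
  expect_error(bonferroni_threshold(0.05, 0), "positive integer")
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
})

test_that("repeated-measures ANOVA handles identical and extreme groups", {
  set.seed(20)
  g <- draw_two_age_gene(amplitude = 0.4)
  # comparing a group with itself: the age contrast is exactly zero
  expect_equal(repeated_measures_anova(g$young, g$young), 1, tolerance = 1e-9)
  # a clean doubling with negligible noise is overwhelmingly significant
  doubled <- g$young
  doubled$value <- g$young$value * 2 * exp(rnorm(24, 0, 1e-4))
  expect_lt(repeated_measures_anova(g$young, doubled), 1e-12)

  bad <- g$old; bad$zt <- bad$zt + 1
  expect_error(repeated_measures_anova(g$young, bad), "grid")
  one_tp <- data.frame(value = c(1, 2), zt = 0)
  expect_error(repeated_measures_anova(one_tp, one_tp), "2 time points")
})

test_that("with one replicate per time point the mixed model is a paired t-test", {
  for (seed in 1:5) {
    set.seed(seed)
    zts <- seq(0, 22, 2)
    block <- rnorm(12, 0, 1)  # shared circadian profile
    young <- data.frame(value = exp(3 + block + rnorm(12, 0, 0.2)), zt = zts)
    old <- data.frame(value = exp(3.1 + block + rnorm(12, 0, 0.2)), zt = zts)
    p_lme <- repeated_measures_anova(young, old)
    p_t <- t.test(log(old$value), log(young$value), paired = TRUE)$p.value
    expect_lt(abs(p_lme - p_t), 1e-6)
  }
})

test_that("two-way ANOVA decomposes age, time and interaction sensibly", {
  set.seed(30)
  age <- rep(c("young", "old"), each = 12)
  time <- rep(rep(c("t1", "t2", "t3"), each = 4), 2)
  # strong time effect, no age effect
  v <- rnorm(24, 0, 0.3) + rep(rep(c(0, 2, 4), each = 4), 2)
  res <- two_way_anova(v, age, time)
  expect_lt(res$p_time, 1e-6)
  expect_gt(res$p_age, 0.05)

  # all-constant data: nothing is significant
  res0 <- two_way_anova(rep(5, 24), age, time)
  expect_equal(res0$p_age, 1)
  expect_equal(res0$p_time, 1)
  expect_equal(res0$p_interaction, 1)

  expect_error(two_way_anova(v[c(1, 5, 9, 13, 17, 21)],
                             age[c(1, 5, 9, 13, 17, 21)],
                             time[c(1, 5, 9, 13, 17, 21)]), "unreplicated")
})

test_that("interaction p-value agrees with a residual-permutation oracle", {
  set.seed(31)
  age <- rep(c("young", "old"), each = 6)
  time <- rep(rep(c("t1", "t2", "t3"), each = 2), 2)
  inter <- ifelse(age == "old" & time == "t3", 1.2, 0)
  v <- rnorm(12, 0, 0.8) + inter
  res <- two_way_anova(v, age, time)

  # Freedman-Lane style: permute residuals of the additive model and rebuild
  f_stat <- function(y) {
    full <- anova(lm(y ~ factor(age) * factor(time)))
    full["factor(age):factor(time)", "F value"]
  }
  additive <- lm(v ~ factor(age) + factor(time))
  f_obs <- f_stat(v)
  perms <- replicate(2000, f_stat(fitted(additive) + sample(resid(additive))))
  p_perm <- mean(perms >= f_obs)
  expect_lt(abs(res$p_interaction - p_perm), 0.05)
})

test_that("post-tests flag the time point carrying the age difference", {
  set.seed(32)
  age <- rep(c("young", "old"), each = 12)
  time <- rep(rep(c("t1", "t2", "t3"), each = 4), 2)
  v <- rnorm(24, 10, 0.2)
  v[age == "old" & time == "t2"] <- v[age == "old" & time == "t2"] + 3
  res <- two_way_anova(v, age, time)
  post <- res$post_tests
  expect_identical(as.character(post$signif[post$time == "t2"]), "***")
  expect_identical(as.character(post$signif[post$time == "t1"]), "")
  expect_true(all(post$p_adjusted >= 0 & post$p_adjusted <= 1))
})

test_that("fold-change estimate is the geometric mean of per-ZT ratios", {
  set.seed(40)
  g <- draw_two_age_gene(amplitude = 0.3)
  expect_equal(fold_change_estimate(g$young, g$young), 1)
  scaled <- g$young
  scaled$value <- scaled$value * 1.5
  expect_equal(fold_change_estimate(g$young, scaled), 1.5, tolerance = 1e-12)
  # exact multiplicativity
  fc1 <- fold_change_estimate(g$young, g$old)
  g2 <- g$old; g2$value <- g2$value * 3
  expect_equal(fold_change_estimate(g$young, g2), 3 * fc1, tolerance = 1e-12)
  zero <- g$old; zero$value[zero$zt == 4] <- 0
  expect_error(fold_change_estimate(g$young, zero), "zeitgeber time 4")
})

test_that("a 1.52-fold age effect is estimated within 10% over 20 seeds", {
  fcs <- sapply(1:20, function(seed) {
    set.seed(seed)
    g <- draw_two_age_gene(amplitude = 0.1, lfc = log(1.52))
    fold_change_estimate(g$young, g$old)
  })
  expect_true(all(abs(fcs / 1.52 - 1) < 0.10))
})

test_that("detect_age_effects flags nothing when comparing an age with itself", {
  sim <- simulate_panel(panel_design(), seed = 50)
  markers <- c("Atp5h", "Gsk3b", "Sirt2", "Nono", "Tprkb", "Tspo", "Ttr")
  norm <- apply_normalisation(sim$matrix,
                              marker_normalisation_factors(sim$matrix, markers))
  res <- detect_age_effects(norm, sim$design, young_age = 3, old_age = 3,
                            genes = rownames(norm)[1:10])
  expect_false(any(res$significant))
  expect_true(all(abs(res$fold_change - 1) < 1e-9))
})
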