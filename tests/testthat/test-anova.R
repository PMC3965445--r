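rand_rm_table <- function(n_sub = 5, n_time = 6, seed = 1) {
  set.seed(seed)
  tps <- paste0("t", seq_len(n_time))
  grid <- expand.grid(time_point = tps, animal = seq_len(n_sub),
                      treatment = c("A", "B"), stringsAsFactors = FALSE)
  grid$animal_id <- paste(grid$treatment, grid$animal)
  grid$value <- rnorm(nrow(grid))
  grid
}

test_that("mixed-design ANOVA reproduces the study dfs (1,8) and (5,40)", {
  tab <- simulate_longitudinal_study(n_per_group = 5, seed = 3)
  an <- rm_two_way_anova(tab, "Gp", "hippocampus")
  expect_equal(an$df[an$effect == "treatment"], 1)
  expect_equal(an$df[an$effect == "subjects_error"], 8)
  expect_equal(an$df[an$effect == "time"], 5)
  expect_equal(an$df[an$effect == "treatment:time"], 5)
  expect_equal(an$df[an$effect == "within_error"], 40)
})

test_that("mixed-design SS match the direct-summation oracle to 1e-10", {
  for (cfg in list(c(2, 2, 11), c(5, 6, 12), c(4, 3, 13))) {
    tab <- rand_rm_table(cfg[1], cfg[2], cfg[3])
    an <- rm_two_way_anova(tab)
    or <- oracle_rm_ss(tab)
    expect_equal(an$ss[an$effect == "treatment"], or$treatment, tolerance = 1e-10)
    expect_equal(an$ss[an$effect == "subjects_error"], or$subjects_error, tolerance = 1e-10)
    expect_equal(an$ss[an$effect == "time"], or$time, tolerance = 1e-10)
    expect_equal(an$ss[an$effect == "treatment:time"], or$interaction, tolerance = 1e-10)
    expect_equal(an$ss[an$effect == "within_error"], or$within_error, tolerance = 1e-10)
    # F from the oracle's SS/df
    f_or <- (or$treatment / or$df[["treatment"]]) /
      (or$subjects_error / or$df[["subjects_error"]])
    expect_equal(an$f[an$effect == "treatment"], f_or, tolerance = 1e-10)
  }
})

test_that("between-subjects ANOVA matches its oracle and the (5,48) layout", {
  set.seed(21)
  tab <- data.frame(
    treatment = rep(c("CTR", "MPTP"), each = 30),
    time_point = rep(rep(paste0("d", 1:6), each = 5), 2),
    value = rnorm(60, 300, 40))
  an <- two_way_anova(tab)
  or <- oracle_between_ss(tab)
  expect_equal(an$df[an$effect == "time"], 5)
  expect_equal(an$df[an$effect == "residual_error"], 48)
  expect_equal(an$ss[an$effect == "treatment"], or$treatment, tolerance = 1e-10)
  expect_equal(an$ss[an$effect == "time"], or$time, tolerance = 1e-10)
  expect_equal(an$ss[an$effect == "treatment:time"], or$interaction, tolerance = 1e-10)
  expect_equal(an$ss[an$effect == "residual_error"], or$error, tolerance = 1e-10)
})

test_that("SS additivity per stratum and invariance to unit rescaling", {
  tab <- rand_rm_table(5, 6, 31)
  an <- rm_two_way_anova(tab)
  ss_tot <- sum((tab$value - mean(tab$value))^2)
  expect_equal(sum(an$ss), ss_tot, tolerance = 1e-8 * ss_tot)

  tab2 <- tab; tab2$value <- tab$value * 1e3  # Pa -> kPa scale change
  an2 <- rm_two_way_anova(tab2)
  expect_equal(an2$f, an$f, tolerance = 1e-10)
  expect_equal(an2$p, an$p, tolerance = 1e-10)
})

test_that("degenerate and unbalanced inputs are rejected or flagged", {
  tab <- data.frame(treatment = rep(c("A", "B"), each = 10),
                    time_point = rep(rep(c("t1", "t2"), each = 5), 2),
                    value = 7)
  expect_warning(an <- two_way_anova(tab), "zero total sum of squares")
  expect_true(all(is.na(an$f)))

  bad <- rand_rm_table(3, 4, 2)[-1, ]
  expect_error(rm_two_way_anova(bad), "unbalanced")
  expect_error(two_way_anova(bad[, c("treatment", "time_point", "value")]),
               "unbalanced")
})

test_that("Bonferroni adjustment: identity at m=1, capping, monotonicity", {
  tab <- simulate_longitudinal_study(n_per_group = 5, seed = 9)
  bp1 <- bonferroni_pairwise(tab, "Gp", "hippocampus", "group_by_time", "rm", m = 1)
  expect_equal(bp1$p_adj, pmin(1, bp1$p_raw))
  bp6 <- bonferroni_pairwise(tab, "Gp", "hippocampus", "group_by_time", "rm")
  expect_equal(bp6$m[1], 6)
  expect_true(all(bp6$p_adj >= bp6$p_raw))
  expect_true(all(bp6$p_adj <= 1))
  # capping: raw p = 0.2 at m = 6 must saturate at 1
  expect_equal(min(1, 6 * 0.2), 1)
  expect_true(all(bp6$p_adj[bp6$p_raw >= 1 / 6] == 1))
  # monotone in m
  for (mm in c(2, 4, 10)) {
    bpm <- bonferroni_pairwise(tab, "Gp", "hippocampus", "group_by_time", "rm", m = mm)
    expect_true(all(bpm$p_adj >= bp1$p_adj - 1e-12))
  }
  # within-group family size defaults to 15 time-point pairs
  bt <- bonferroni_pairwise(tab, "Gp", "hippocampus", "time_by_group", "rm")
  expect_equal(unique(bt$m), 15)
  expect_equal(nrow(bt), 30)
})

test_that("type-I error of the treatment test is calibrated at the nominal level", {
  # null world: no treatment effect, both variance components present;
  # 200 simulated studies here (the 500-seed version runs in the
  # acceptance suite)
  rej <- vapply(1:200, function(s) {
    tab <- simulate_longitudinal_study(
      effects = effect_spec(gp_mult = c(), gpp_mult = c()),
      n_per_group = 5, seed = 10000 + s)
    an <- rm_two_way_anova(tab, "Gp", "hippocampus")
    an$p[an$effect == "treatment"] < 0.05
  }, logical(1))
  ci <- qnorm(0.995) * sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(mean(rej) - 0.05), ci + 1e-9)
})
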