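test_that("cell summaries agree with an independent two-pass computation", {
  tab <- generate_cohort(cohort_effects(n_participants = 12, seed = 7))
  s <- hemifield_summary(tab)
  for (i in seq_len(nrow(s))) {
    y <- tab$threshold[tab$condition == s$condition[i] &
                         tab$hemifield == s$hemifield[i]]
    o <- oracle_mean_sem(y)
    expect_equal(s$mean[i], unname(o["mean"]), tolerance = 1e-12)
    expect_equal(s$sem[i], unname(o["sem"]), tolerance = 1e-12)
  }
  # constant table has zero SEM
  const <- tab; const$threshold <- 50
  expect_true(all(hemifield_summary(const)$sem == 0))
})

test_that("summary errors name missing design cells", {
  tab <- generate_cohort(cohort_effects(n_participants = 6, seed = 1))
  dropped <- tab[tab$condition != "hMT_sham", ]
  expect_error(hemifield_summary(dropped), "hMT_sham")
  expect_error(validate_threshold_table(tab[-1, ]), "incomplete")
})

test_that("ipsi-contra differences are linear and correctly signed", {
  tab <- generate_cohort(cohort_effects(n_participants = 12, seed = 2))
  d <- ipsi_contra_diff(tab, "hMT_active")
  sub <- tab[tab$condition == "hMT_active", ]
  expect_equal(mean(d),
               mean(sub$threshold[sub$hemifield == "ipsilateral"]) -
                 mean(sub$threshold[sub$hemifield == "contralateral"]),
               tolerance = 1e-12)
  same <- tab
  same$threshold <- ave(same$threshold,
                        paste(same$participant, same$condition))
  expect_true(all(abs(ipsi_contra_diff(same, "hMT_active")) < 1e-12))
})

test_that("one-tailed paired t reproduces the closed form and t.test", {
  d <- diff_vector(-1.17, 1.91, 42)
  res <- paired_t_one_tailed(d, "greater")
  expect_equal(round(res$statistic, 2), -0.61)
  expect_equal(res$df, 41L)
  tt <- t.test(d, alternative = "greater")
  expect_equal(res$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  # direction flip maps p to 1 - p
  res_l <- paired_t_one_tailed(d, "less")
  expect_equal(res$p + res_l$p, 1, tolerance = 1e-12)
  expect_error(paired_t_one_tailed(rep(0, 10)), "variance")
  expect_error(paired_t_one_tailed(1), "at least 2")
})

test_that("within-subject ANOVA matches aov on random tables and is zero under equality", {
  for (s in 1:5) {
    tab <- generate_cohort(cohort_effects(n_participants = 9, seed = s))
    res <- rm_anova_condition(tab)
    y <- tapply(tab$threshold, list(tab$participant, tab$condition), mean)
    long <- data.frame(y = as.vector(y),
                       subj = factor(rep(rownames(y), ncol(y))),
                       cond = factor(rep(colnames(y), each = nrow(y))))
    fit <- summary(aov(y ~ cond + Error(subj), data = long))
    ftab <- fit[["Error: Within"]][[1]]
    expect_equal(res$statistic, ftab["cond", "F value"], tolerance = 1e-10)
    expect_equal(res$p, ftab["cond", "Pr(>F)"], tolerance = 1e-10)
    expect_equal(res$df, 2L)
    expect_equal(res$df2, 16L)
  }
  flat <- generate_cohort(cohort_effects(n_participants = 6, seed = 1))
  flat$threshold <- ave(flat$threshold, flat$participant)  # no condition effect
  expect_equal(rm_anova_condition(flat)$statistic, 0)
})

test_that("effect size follows the standardised-difference definition", {
  expect_equal(round(cohens_d(10.51, 2.59, 14.8), 2), 0.54)
  expect_equal(cohens_d(5, 5, 3), 0)
  expect_equal(cohens_d(8, 3, 2), -cohens_d(3, 8, 2))
  expect_error(cohens_d(1, 0, 0), "positive")
})

test_that("noncentral-t sample size search is monotone and exact", {
  d <- cohens_d(10.51, 2.59, 14.8)
  expect_identical(required_n(d), 42L)
  # the boundary: power just misses at 41
  expect_lt(power_paired_t(41, d), 0.9)
  expect_gte(power_paired_t(42, d), 0.9)
  expect_lte(required_n(3), 4L)
  n_grid <- 2:200
  expect_true(all(diff(power_paired_t(n_grid, 0.4)) > 0))
  expect_error(required_n(-1), "positive")
})

test_that("belief report percentages round as printed", {
  expect_identical(belief_report_percent(5, 9), 36L)
  expect_identical(belief_report_percent(6, 7), 46L)
  expect_identical(belief_report_percent(0, 10), 0L)
  expect_error(belief_report_percent(0, 0), "reports")
})

test_that("the registered pipeline runs all three tests with the stated conventions", {
  tab <- generate_cohort(cohort_effects(n_participants = 12, seed = 11))
  g <- analyze_group(tab)
  expect_named(g$tests, c("hMT_ipsi_gt_contra", "hMT_vs_sham",
                          "hMT_vs_forehead"))
  expect_equal(g$tests$hMT_ipsi_gt_contra$statistic,
               paired_t_one_tailed(ipsi_contra_diff(tab, "hMT_active"),
                                   "greater")$statistic)
  d2 <- ipsi_contra_diff(tab, "hMT_active") -
    ipsi_contra_diff(tab, "hMT_sham")
  expect_equal(g$tests$hMT_vs_sham$statistic,
               paired_t_one_tailed(d2, "greater")$statistic)
  expect_equal(g$anova$df2, 22L)
  expect_output(print(g), "One-tailed paired t-tests")
})
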