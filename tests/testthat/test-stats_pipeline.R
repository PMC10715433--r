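test_that("mixed_anova matches a textbook split-plot decomposition", {
  set.seed(21)
  d <- null_trial_table(n_per_group = 2L, cond_shift = c(0, 0.8), group_shift = 0.3)
  res <- suppressMessages(mixed_anova(d, dv = "proportion",
                                      within_levels = c("WTR", "SR"),
                                      phase = "practice"))
  ref <- textbook_split_plot(d)
  for (pair in list(c("group", "group"), c("condition", "condition"),
                    c("group:condition", "interaction"))) {
    row <- res[res$effect == pair[1], ]
    e <- ref[[pair[2]]]
    expect_equal(row$SS, e$SS)
    expect_equal(row$df, e$df)
    expect_equal(row$SS_error, e$SS_err)
    expect_equal(row$df_error, e$df_err)
    expect_equal(row$`F`, (e$SS / e$df) / (e$SS_err / e$df_err))
    expect_equal(row$partial_eta_sq, e$SS / (e$SS + e$SS_err))
  }
})

test_that("degenerate structure zeroes the right sums of squares", {
  # one within level a constant shift of the other for every participant,
  # groups built identically: interaction and group SS both ~0
  ids <- sprintf("S%02d", 1:8)
  base <- rep(c(0.2, 0.4, 0.6, 0.8), times = 2)
  d <- dplyr::bind_rows(
    tibble::tibble(participant_id = ids, group = rep(c("TD", "ADHD"), each = 4),
                   condition = "WTR", phase = "practice", n_recalled = NA_integer_,
                   proportion = base, order_score = NA_real_),
    tibble::tibble(participant_id = ids, group = rep(c("TD", "ADHD"), each = 4),
                   condition = "SR", phase = "practice", n_recalled = NA_integer_,
                   proportion = base + 0.1, order_score = NA_real_)
  )
  res <- suppressMessages(mixed_anova(d, dv = "proportion",
                                      within_levels = c("WTR", "SR"),
                                      phase = "practice"))
  expect_equal(res$SS[res$effect == "group"], 0, tolerance = 1e-12)
  expect_equal(res$SS[res$effect == "group:condition"], 0, tolerance = 1e-12)
  expect_equal(res$partial_eta_sq[res$effect == "group"], 0, tolerance = 1e-10)
  expect_gt(res$`F`[res$effect == "condition"], 1e6)  # constant shift, no error
})

test_that("error degrees of freedom emerge from listwise deletion", {
  set.seed(22)
  d3 <- null_trial_table(n_per_group = 36L,
                         conditions = c("restudy", "WTR", "SR"),
                         phase = "criterion")
  res <- mixed_anova(d3, dv = "proportion", phase = "criterion")
  expect_identical(res$df_error[res$effect == "group"], 70)
  expect_identical(res$df_error[res$effect == "condition"], 140)

  # one participant loses one criterion observation -> 71 complete cases
  d3$proportion[d3$participant_id == "S001" & d3$condition == "SR"] <- NA
  res <- suppressMessages(mixed_anova(d3, dv = "proportion", phase = "criterion"))
  expect_identical(attr(res, "n_participants"), 71L)
  expect_identical(res$df_error[res$effect == "group"], 69)
  expect_identical(res$df_error[res$effect == "condition"], 138)
})

test_that("for two within levels the condition F equals the squared t on the differences", {
  # The within-effect F is tested against the condition-by-participant error
  # pooled within groups, so the matching t statistic on the paired
  # differences uses the group-centered variance: an algebraic identity,
  # recomputed here directly from the raw differences.
  set.seed(23)
  for (i in 1:5) {
    d <- null_trial_table(n_per_group = 8L, cond_shift = c(0, runif(1, -0.5, 0.5)))
    res <- mixed_anova(d, dv = "proportion", within_levels = c("WTR", "SR"),
                       phase = "practice")
    wide <- tidyr::pivot_wider(
      d[c("participant_id", "group", "condition", "proportion")],
      names_from = "condition", values_from = "proportion"
    )
    diffs <- wide$WTR - wide$SR
    grp_means <- ave(diffs, wide$group)
    n <- length(diffs)
    s2_pooled <- sum((diffs - grp_means)^2) / (n - 2)
    t_pooled <- mean(diffs) / sqrt(s2_pooled / n)
    expect_equal(res$`F`[res$effect == "condition"], t_pooled^2)
  }
})

test_that("mixed_anova rejects broken inputs", {
  set.seed(24)
  d <- null_trial_table(n_per_group = 2L)
  expect_error(mixed_anova(d[d$group == "TD", ], dv = "proportion",
                           within_levels = c("WTR", "SR"), phase = "practice"),
               class = "recallorder_analysis_error")
  dup <- dplyr::bind_rows(d, d[1, ])
  expect_error(mixed_anova(dup, dv = "proportion", within_levels = c("WTR", "SR"),
                           phase = "practice"),
               "More than one row", class = "recallorder_analysis_error")
})

test_that("Greenhouse-Geisser correction only loosens within-effect p-values", {
  set.seed(25)
  d <- null_trial_table(n_per_group = 12L, conditions = c("restudy", "WTR", "SR"),
                        phase = "criterion", cond_shift = c(0, 1, 2.5),
                        sd_noise = 0.5)
  # heterogeneous difference variances to break sphericity
  d$proportion[d$condition == "SR"] <- d$proportion[d$condition == "SR"] +
    rnorm(24, 0, 1.5)
  plain <- mixed_anova(d, dv = "proportion", phase = "criterion")
  gg <- mixed_anova(d, dv = "proportion", phase = "criterion", sphericity = "GG")
  eps <- attr(gg, "gg_epsilon")
  expect_true(eps > 0.5 && eps <= 1)
  expect_gte(gg$p[gg$effect == "condition"], plain$p[plain$effect == "condition"])
  expect_equal(gg$p[gg$effect == "group"], plain$p[plain$effect == "group"])
  expect_equal(gg$`F`, plain$`F`)  # correction adjusts dfs, not F
})

test_that("bonferroni_pairwise applies the m-fold cap and both d conventions", {
  set.seed(26)
  d <- null_trial_table(n_per_group = 10L, conditions = c("restudy", "WTR", "SR"),
                        phase = "criterion", cond_shift = c(0, 0, 0.6))
  pw <- bonferroni_pairwise(d, dv = "proportion", phase = "criterion")
  expect_identical(nrow(pw), 3L)
  expect_equal(pw$p_adj, pmin(1, 3 * pw$p_raw))

  # identical within levels: zero difference, adjusted p capped at 1
  d2 <- d[d$condition != "SR", ]
  d2$proportion[d2$condition == "WTR"] <-
    d2$proportion[d2$condition == "restudy"]
  pw2 <- bonferroni_pairwise(d2, dv = "proportion",
                             within_levels = c("restudy", "WTR"),
                             phase = "criterion")
  expect_equal(pw2$mean_diff, 0)
  expect_equal(pw2$p_adj, 1)

  # d conventions on known data
  wide <- tidyr::pivot_wider(d[c("participant_id", "condition", "proportion")],
                             names_from = "condition", values_from = "proportion")
  pw_av <- bonferroni_pairwise(d, dv = "proportion", phase = "criterion",
                               d_method = "av")
  pw_z <- bonferroni_pairwise(d, dv = "proportion", phase = "criterion",
                              d_method = "z")
  i <- which(pw_av$level_1 == "restudy" & pw_av$level_2 == "SR")
  diff <- wide$restudy - wide$SR
  expect_equal(pw_av$d[i],
               mean(diff) / sqrt((var(wide$restudy) + var(wide$SR)) / 2))
  expect_equal(pw_z$d[i], mean(diff) / sd(diff))
})

test_that("independent_t reproduces the d-from-t conversion and trivial cases", {
  expect_equal(round(cohens_d_from_t(9.29, 36, 36), 2), 2.19)
  expect_equal(round(cohens_d_from_t(1.48, 36, 36), 2), 0.35)

  vals <- c(1, 2, 3, 1, 2, 3)
  grp <- rep(c("TD", "ADHD"), each = 3)
  res <- independent_t(vals, grp)
  expect_equal(res$t, 0)
  expect_equal(res$d, 0)
  expect_equal(res$df, 4)
  expect_error(independent_t(vals, rep("TD", 6)), class = "recallorder_analysis_error")

  set.seed(27)
  x <- rnorm(36, 60.7, 9.9); y <- rnorm(36, 41.8, 7.1)
  res <- independent_t(c(x, y), rep(c("ADHD", "TD"), each = 36))
  expect_equal(res$df, 70)
  expect_equal(res$d, cohens_d_from_t(res$t, 36, 36))
})

test_that("pearson_r is the product-moment correlation with t-transform p", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_error(pearson_r(x, rep(1, 5)), class = "recallorder_analysis_error")
  expect_error(pearson_r(1:2, 2:3), class = "recallorder_analysis_error")
  # pairwise deletion of missing values
  res <- pearson_r(c(x, NA), c(2 * x + rnorm(5, 0, 0.5), 3))
  expect_identical(res$n, 5L)
})

test_that("analyze_study assembles the full battery and is deterministic", {
  study <- cached_study(42)
  scored <- suppressWarnings(score_dataset(study$outputs, roster = study$roster))
  rep1 <- suppressMessages(analyze_study(scored))
  expect_s3_class(rep1, "recall_report")
  expect_identical(nrow(rep1$correlations), 4L)
  expect_identical(nrow(rep1$criterion_proportion_pairwise), 3L)
  expect_identical(nrow(rep1$criterion_order_pairwise), 3L)
  for (nm in c("practice_proportion_anova", "criterion_proportion_anova",
               "criterion_order_anova")) {
    expect_s3_class(rep1[[nm]], "recall_anova")
    expect_true(all(rep1[[nm]]$partial_eta_sq >= 0 & rep1[[nm]]$partial_eta_sq <= 1))
  }
  expect_identical(rep1$practice_proportion_anova$df_error, c(70, 70, 70))
  rep2 <- suppressMessages(analyze_study(scored))
  expect_identical(rep1, rep2)
})
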