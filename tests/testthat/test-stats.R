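make_table <- function(n_subjects, seed, ...) {
  simulate_cohort_table(n_subjects = n_subjects, seed = seed, ...)
}

test_that("partial eta squared reproduces worked examples and edge cases", {
  expect_equal(round(partial_eta_sq(11.942, 2, 30), 3), 0.443)
  expect_equal(round(partial_eta_sq(4.650, 1, 15), 3), 0.237)
  expect_equal(partial_eta_sq(0, 2, 30), 0)
  expect_error(partial_eta_sq(-1, 2, 30), class = "emg_parameter_error")
})

test_that("ANOVA F values match the manual sums-of-squares oracle", {
  tab <- make_table(4, seed = 101)
  res <- tidy(rm_anova_2way(tab))
  oracle <- rm_anova_ss_oracle(tab)
  expect_equal(res$f[res$effect == "condition"], oracle$condition)
  expect_equal(res$f[res$effect == "time"], oracle$time)
  expect_equal(res$f[res$effect == "condition:time"], oracle$interaction)
  # a second, larger table
  tab2 <- make_table(12, seed = 102)
  res2 <- tidy(rm_anova_2way(tab2))
  oracle2 <- rm_anova_ss_oracle(tab2)
  expect_equal(res2$f, unname(unlist(oracle2[c("condition", "time", "interaction")])))
})

test_that("partial eta squared from F is consistent with the SS decomposition", {
  tab <- make_table(8, seed = 103)
  res <- tidy(rm_anova_2way(tab))
  o <- rm_anova_ss_oracle(tab)$ss
  expect_equal(res$partial_eta_sq[res$effect == "condition"],
               o$condition / (o$condition + o$err_condition))
  expect_equal(res$partial_eta_sq[res$effect == "time"],
               o$time / (o$time + o$err_time))
  expect_equal(res$partial_eta_sq[res$effect == "condition:time"],
               o$interaction / (o$interaction + o$err_interaction))
})

test_that("a two-level within factor has trivially unit epsilon", {
  tab <- make_table(6, seed = 104)
  res <- tidy(rm_anova_2way(tab))
  expect_equal(res$epsilon_gg[res$effect == "condition"], 1)
  expect_true(is.na(res$mauchly_p[res$effect == "condition"]))
  eps_t <- res$epsilon_gg[res$effect == "time"]
  expect_gte(eps_t, 0.5)   # lower bound 1/(k-1) for k = 3
  expect_lte(eps_t, 1)
})

test_that("centering the time marginal means zeroes the time effect F", {
  tab <- make_table(5, seed = 105)
  centered <- tab |>
    dplyr::group_by(time) |>
    dplyr::mutate(value = value - mean(value)) |>
    dplyr::ungroup()
  res <- tidy(rm_anova_2way(centered))
  expect_equal(res$f[res$effect == "time"], 0, tolerance = 1e-8)
  expect_gt(res$f[res$effect == "condition:time"], 0)
})

test_that("missing cells are rejected rather than imputed", {
  tab <- make_table(5, seed = 106)
  expect_error(rm_anova_2way(tab[-3, ]), class = "emg_design_error")
})

test_that("the Mauchly computation matches stats::mauchly.test", {
  tab <- make_table(10, seed = 107)
  ours <- sphericity_test(tab, factor = "time")
  marg <- dplyr::summarise(dplyr::group_by(tab, subject, time),
                           value = mean(value), .groups = "drop")
  wide <- tidyr::pivot_wider(marg, names_from = "time", values_from = "value")
  m <- as.matrix(wide[, c("BASELINE", "WARM", "STRETCH")])
  fit <- stats::lm(m ~ 1)
  ref <- stats::mauchly.test(fit, X = ~ 1)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
})

test_that("post hoc comparisons cover all pairs with Bonferroni adjustment", {
  tab <- make_table(16, seed = 108,
                    effect_map = list(y = c(WARM = 1, STRETCH = 1)))
  ph <- bonferroni_posthoc(tab, factor = "time")
  expect_equal(nrow(ph), 3)
  expect_true(all(ph$p_adjusted >= ph$p, na.rm = TRUE))
  expect_true(all(ph$p_adjusted <= 1, na.rm = TRUE))
  expect_true(all(ph$conf_low <= ph$mean_difference &
                    ph$mean_difference <= ph$conf_high))
  bw <- ph[ph$level_1 == "BASELINE" & ph$level_2 == "WARM", ]
  expect_lt(bw$p_adjusted, 0.05)
  expect_lt(bw$mean_difference, 0)  # BASELINE below shifted WARM
})

test_that("identical paired samples give zero difference and a flagged p", {
  tab <- make_table(6, seed = 109)
  wide <- tidyr::pivot_wider(tab, names_from = "time", values_from = "value")
  wide$WARM <- wide$BASELINE
  wide$STRETCH <- wide$BASELINE + 1  # constant shift: zero-variance diffs
  flat <- tidyr::pivot_longer(wide, c("BASELINE", "WARM", "STRETCH"),
                              names_to = "time", values_to = "value")
  warns <- capture_warnings(ph <- bonferroni_posthoc(flat, factor = "time"))
  expect_length(warns, 3)  # every pair has zero-variance differences
  expect_match(warns, "Zero variance", all = TRUE)
  bw <- ph[ph$level_1 == "BASELINE" & ph$level_2 == "WARM", ]
  expect_equal(bw$mean_difference, 0)
  expect_true(is.na(bw$p))
})

test_that("Cohen's d follows the printed descriptor thresholds and sign", {
  s <- c(1, 2, 3, 4, 5)
  expect_equal(cohens_d(s - mean(s) + sd(s))$d, 1)
  expect_equal(cohens_d(s - mean(s) + sd(s))$descriptor, "medium")
  expect_equal(cohens_d(c(1, -1, 2, -2, 0.5))$descriptor, "small")

  d1 <- cohens_d(c(3, 4, 5), c(1, 1, 2))
  expect_gt(d1$d, 0)
  d2 <- cohens_d(c(1, 1, 2), c(3, 4, 5))
  expect_equal(d2$d, -d1$d)
  expect_equal(cohens_d(rep(2, 5))$descriptor, "undefined")

  # descriptor boundaries: d = 0.745 medium, d = 1.211 large
  expect_equal(emgcomplexity:::d_descriptor(0.745), "medium")
  expect_equal(emgcomplexity:::d_descriptor(1.211), "large")
  expect_equal(emgcomplexity:::d_descriptor(0.466), "small")
  expect_equal(emgcomplexity:::d_descriptor(1.2), "medium")
})

test_that("normality and sphericity helpers report applicability", {
  expect_true(is.na(check_normality(c(1, 2))$statistic))
  nm <- check_normality(withr::with_seed(1, rnorm(50)))
  expect_gt(nm$p, 0.05)
  skew <- check_normality(withr::with_seed(2, rexp(50)))
  expect_lt(skew$p, 0.05)

  tab <- make_table(6, seed = 110)
  expect_true(is.na(sphericity_test(tab, factor = "condition")$p))
  expect_false(is.na(sphericity_test(tab, factor = "time")$p))
})

test_that("skewed samples are flagged by Shapiro-Wilk in most replicates", {
  rej <- sapply(1:40, function(i) {
    check_normality(withr::with_seed(300 + i, rexp(50)))$p < 0.05
  })
  expect_gt(mean(rej), 0.7)
})
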