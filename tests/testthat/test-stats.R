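fake_lag_table <- function(m) {
  conds <- c("vh_cong", "rh_cong", "vh_incong", "rh_incong")
  out <- do.call(rbind, lapply(seq_len(nrow(m)), function(i)
    data.frame(participant = sprintf("p%02d", i),
               instruction = c("VH", "RH", "VH", "RH"),
               congruence = c("cong", "cong", "incong", "incong"),
               condition = conds, n_trials = 1L,
               lag_real = as.numeric(m[i, ]),
               lag_virtual = as.numeric(m[i, ]))))
  class(out) <- c("lag_table", "data.frame")
  out
}

test_that("rm_anova_2x2 satisfies the F = t^2 contrast identity", {
  set.seed(5)
  m <- matrix(rnorm(40, mean = c(0.05, 0.05, -0.2, 0.08), sd = 0.05),
              10, 4, byrow = TRUE)
  tab <- fake_lag_table(m)
  fit <- rm_anova_2x2(tab, "lag_real")
  expect_s3_class(fit, "rm_anova")
  expect_equal(fit$effect, c("task", "congruence", "interaction"))
  expect_equal(fit$F, fit$t^2, tolerance = 1e-8)
  expect_equal(fit$df1, rep(1, 3))
  expect_equal(fit$df2, rep(9, 3))
  ## p matches the t distribution of the paired contrast
  expect_equal(fit$p, 2 * pt(-abs(fit$t), df = 9), tolerance = 1e-10)
})

test_that("identical responses give zero F and p = 1", {
  tab <- fake_lag_table(matrix(0.05, 6, 4))
  fit <- rm_anova_2x2(tab, "lag_real")
  expect_equal(fit$F, rep(0, 3))
  expect_equal(fit$p, rep(1, 3))
})

test_that("an injected interaction is detected", {
  spec <- cohort_spec("study", seed = 3L)
  tab <- draw_lag_table(spec)
  fit <- rm_anova_2x2(tab, "lag_real")
  expect_lt(fit$p[fit$effect == "interaction"], 1e-6)
  ## the virtual-hand dependent flips the congruence contrast sign
  fitv <- rm_anova_2x2(tab, "lag_virtual")
  expect_true(is.finite(fitv$F[2]))
  expect_error(rm_anova_2x2(tab[-1L, ], "lag_real"), "incomplete")
})

test_that("post-hoc t-tests are Bonferroni corrected", {
  spec <- cohort_spec("study", seed = 4L)
  tab <- draw_lag_table(spec)
  ph <- posthoc_paired_tests(tab)
  expect_equal(nrow(ph), 4L)
  expect_equal(ph$p_corrected, pmin(1, ph$p * 4))
  expect_false(any(ph$degenerate))
  ## the vh congruence comparison carries the large injected effect
  big <- ph$comparison == "vh_cong vs vh_incong"
  expect_lt(ph$p_corrected[big], 1e-6)
  ## degenerate pair: zero-variance differences are flagged
  tab0 <- fake_lag_table(matrix(0.05, 6, 4))
  ph0 <- posthoc_paired_tests(tab0)
  expect_true(all(ph0$degenerate))
  expect_equal(ph0$t, rep(0, 4))
  expect_equal(ph0$p_corrected, rep(1, 4))
})

test_that("Friedman test flags fully tied ratings", {
  spec <- cohort_spec("study", n_participants = 12L, seed = 9L)
  ratings <- generate_ratings(spec)
  ft <- friedman_test(ratings, "Q2")
  expect_equal(ft$df, 3L)
  expect_equal(ft$n, 12L)
  expect_lt(ft$p, 0.01)  # strong injected Q2 split by modality
  tied <- ratings
  tied$rating <- 4L
  expect_warning(ft0 <- friedman_test(tied, "Q1"), "tied")
  expect_equal(ft0$chi2, 0)
  expect_equal(ft0$p, 1)
})

test_that("Wilcoxon pairs recover the injected rating shifts", {
  spec <- cohort_spec("study", n_participants = 16L, seed = 10L)
  ratings <- generate_ratings(spec)
  wp <- wilcoxon_pairs(ratings, "Q1")
  expect_equal(nrow(wp), 4L)
  expect_equal(wp$p_corrected, pmin(1, wp$p * 4))
  ## Q1 latent mean is 2 points higher in vh_incong than vh_cong
  vh <- wp$pair == "vh_incong vs vh_cong"
  expect_gt(wp$z[vh], 2)
  expect_lt(wp$p_corrected[vh], 0.05)
  ## hand-rolled z agrees with the exact test away from ties
  set.seed(1)
  d <- rnorm(20, 0.8)
  r2 <- data.frame(participant = sprintf("p%02d", 1:20),
                   condition = rep(c("a", "b"), each = 20),
                   question = "Q1", rating = c(d, rep(0, 20)))
  wz <- wilcoxon_pairs(r2, "Q1", pairs = list(c("a", "b")))
  ref <- suppressWarnings(
    stats::wilcox.test(d, rep(0, 20), paired = TRUE, correct = TRUE,
                       exact = FALSE))
  expect_equal(wz$p, ref$p.value, tolerance = 1e-6)
  expect_error(wilcoxon_pairs(r2[c(1, 21), ], "Q1",
                              pairs = list(c("a", "b"))), "fewer than 2")
})
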