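test_that("cohort_spec validates design parameters", {
  expect_s3_class(cohort_spec(), "cohort_spec")
  expect_error(cohort_spec(fs = 0.9, f0 = 0.5), "fs > 2")
  expect_error(cohort_spec(visual_delay = 1.5), "half a period")
  expect_error(cohort_spec(condition_lag_means = c(vh_cong = 0.05)),
               "condition_lag_means")
  expect_error(cohort_spec(amplitude_range = c(0.9, 0.1)), "amplitude_range")
  expect_output(print(cohort_spec()), "24 participants")
})

test_that("the target size modulates 12% around its minimum", {
  tgt <- make_target(32, 0.5, 60)
  expect_equal(nrow(tgt), 1920L)
  expect_equal(max(tgt$size) / min(tgt$size), 1.12, tolerance = 1e-9)
  expect_equal(min(tgt$size), 1, tolerance = 1e-9)
  expect_equal(tgt$phase, 2 * pi * 0.5 * tgt$t)
})

test_that("cohort generation is deterministic under the spec seed", {
  spec <- cohort_spec("study", n_participants = 2L,
                      trials_per_condition = 1L, trial_duration = 16,
                      seed = 21L)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$trials, b$trials)
  expect_identical(a$truth, b$truth)
  expect_identical(a$ratings, b$ratings)
  c2 <- generate_cohort(cohort_spec("study", n_participants = 2L,
                                    trials_per_condition = 1L,
                                    trial_duration = 16, seed = 22L))
  expect_false(identical(a$trials$f2, c2$trials$f2))
})

test_that("a noiseless cohort reproduces its injected lags exactly", {
  spec <- cohort_spec("study", n_participants = 1L,
                      trials_per_condition = 1L, trial_duration = 16,
                      between_subject_sd = 0, within_trial_sd = 0,
                      noise_sd = 0, seed = 2L)
  co <- generate_cohort(spec, ratings = FALSE)
  tab <- aggregate_lags(co$trials, co$manifest)
  truth <- co$truth
  for (i in seq_len(nrow(tab))) {
    tr <- truth$lag_trial[truth$condition == tab$condition[i]]
    expect_equal(tab$lag_real[i], tr, tolerance = 1 / 60)
  }
  ## noiseless lags equal the condition means by construction
  expect_equal(sort(unique(truth$lag_participant)),
               sort(unique(unname(spec$condition_lag_means))))
})

test_that("trial channels honour gains, range and clipping", {
  spec <- cohort_spec("study", n_participants = 1L,
                      trials_per_condition = 2L, trial_duration = 16,
                      seed = 5L)
  co <- generate_cohort(spec, ratings = FALSE)
  ch <- as.matrix(co$trials[, paste0("f", 1:5)])
  expect_true(all(ch >= 0 & ch <= 1))
  ## five distinct per-finger gains: channel sds differ
  sds <- apply(ch[co$trials$trial == 1 & co$trials$congruence == "cong" &
                    co$trials$instruction == "VH", ], 2, sd)
  expect_gt(diff(range(sds)), 1e-3)
  ## design bookkeeping: 4 conditions x 2 trials, runs split 1/2
  expect_equal(nrow(co$trials), 4L * 2L * 16 * 60)
  expect_equal(sort(unique(co$trials$run)), c(1L, 2L))
  expect_equal(nrow(co$truth), 8L)
})

test_that("draw_lag_table matches the full design shape and wraps", {
  spec <- cohort_spec("study", seed = 6L)
  tab <- draw_lag_table(spec)
  expect_s3_class(tab, "lag_table")
  expect_equal(nrow(tab), 24L * 4L)
  expect_equal(unique(tab$n_trials), 6L)
  inc <- tab$congruence == "incong"
  expect_equal(tab$lag_virtual[!inc], tab$lag_real[!inc])
  period <- 1 / spec$f0
  expect_true(all(tab$lag_virtual > -period / 2 &
                    tab$lag_virtual <= period / 2))
  ## seeded determinism on the fast path too
  expect_identical(tab, draw_lag_table(spec))
  expect_false(identical(tab$lag_real,
                         draw_lag_table(spec, seed = 99L)$lag_real))
})

test_that("ratings are complete 7-point ordinals per question", {
  spec <- cohort_spec("study", n_participants = 10L, seed = 8L)
  r <- generate_ratings(spec)
  expect_equal(nrow(r), 10L * 4L * 2L)
  expect_true(all(r$rating %in% 1:7))
  expect_setequal(unique(r$question), c("Q1", "Q2"))
  ## study preset: Q1 is rated harder under vh incongruence
  mQ1 <- tapply(r$rating[r$question == "Q1"],
                r$condition[r$question == "Q1"], mean)
  expect_gt(mQ1[["vh_incong"]], mQ1[["vh_cong"]])
  ## null preset: one latent mean everywhere
  rn <- generate_ratings(cohort_spec("null", n_participants = 10L,
                                     seed = 8L))
  mn <- tapply(rn$rating, rn$condition, mean)
  expect_lt(diff(range(mn)), 1.5)
})

test_that("cohort directories include manifest, ratings and truth sidecar", {
  spec <- cohort_spec("study", n_participants = 2L,
                      trials_per_condition = 1L, trial_duration = 16,
                      seed = 31L)
  d <- file.path(tempdir(), "cohort_files")
  generate_cohort(spec, dir = d)
  expect_true(all(file.exists(file.path(
    d, c("manifest.json", "ratings.csv", "truth.csv",
         "trials_p01.csv", "trials_p02.csv")))))
  man <- read_manifest(file.path(d, "manifest.json"))
  expect_equal(man$visual_delay, 0.5)
  expect_equal(man$fs, 60)
  unlink(d, recursive = TRUE)
})
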