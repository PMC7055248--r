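test_that("the grasp signal is the mean of the four non-thumb fingers", {
  tr <- data.frame(f1 = 0, f2 = 0.2, f3 = 0.4, f4 = 0.6, f5 = 0.8)
  expect_equal(preprocess_trial(tr), 0.5)
  ## the thumb channel must not contribute
  tr$f1 <- 1
  expect_equal(preprocess_trial(tr), 0.5)
  expect_error(preprocess_trial(data.frame(f1 = 0, f2 = 0.1)),
               "finger channels")
})

test_that("display normalization cannot change the estimated phase", {
  t <- seq(0, 32 - 1 / 60, by = 1 / 60)
  ref <- sin(2 * pi * 0.5 * t)
  sig <- 0.4 + 0.2 * sin(2 * pi * 0.5 * (t - 0.3))
  raw <- cwt_phase_lag(sig, ref, 0.5, 60)
  norm <- cwt_phase_lag(normalize_trajectory(sig), ref, 0.5, 60)
  expect_equal(norm, raw, tolerance = 1e-10)
  expect_equal(normalize_trajectory(rep(2, 5)), rep(0, 5))
  expect_equal(max(abs(normalize_trajectory(sig))), 1)
})

test_that("circular lag averaging respects the period", {
  expect_equal(phasematch:::circular_mean_lag(c(0.1, 0.2), 2), 0.15)
  ## antipodal-adjacent lags average across the wrap, not through zero
  expect_equal(phasematch:::circular_mean_lag(c(0.95, -0.95), 2), 1)
  expect_equal(phasematch:::circular_mean_lag(0.4, 2), 0.4)
})

small_cohort <- function(n = 2L, trials = 1L, seed = 7L)
  generate_cohort(cohort_spec("study", n_participants = n,
                              trials_per_condition = trials,
                              trial_duration = 16, seed = seed))

test_that("aggregate_lags derives the virtual lag from the visual delay", {
  co <- small_cohort()
  tab <- aggregate_lags(co$trials, co$manifest)
  expect_s3_class(tab, "lag_table")
  expect_equal(nrow(tab), 2L * 4L)
  cong <- tab$congruence == "cong"
  expect_equal(tab$lag_real[cong], tab$lag_virtual[cong])
  inc <- !cong
  period <- 1 / co$manifest$f0
  dv <- (tab$lag_virtual - tab$lag_real)[inc]
  dv <- dv - period * round((dv - co$manifest$visual_delay) / period)
  expect_equal(dv, rep(co$manifest$visual_delay, sum(inc)),
               tolerance = 1e-9)
})

test_that("missing participant x condition cells are flagged", {
  co <- small_cohort()
  drop <- !(co$trials$participant == "p01" &
              co$trials$instruction == "VH" &
              co$trials$congruence == "incong")
  expect_warning(tab <- aggregate_lags(co$trials[drop, ], co$manifest),
                 "missing participant x condition")
  bad <- tab$participant == "p01" & tab$condition == "vh_incong"
  expect_true(is.na(tab$lag_real[bad]))
  expect_equal(tab$n_trials[bad], 0L)
  expect_true(all(!is.na(tab$lag_real[!bad])))
})

test_that("cohort directories round-trip through write/read", {
  co <- small_cohort()
  d <- file.path(tempdir(), "cohort_rt")
  write_cohort_dir(co$trials, co$manifest, d)
  back <- read_cohort_dir(d)
  expect_equal(back$manifest$f0, co$manifest$f0)
  expect_equal(back$manifest$channel_roles[["f1"]], "thumb")
  expect_equal(nrow(back$trials), nrow(co$trials))
  expect_equal(sort(unique(back$trials$participant)), c("p01", "p02"))
  ## malformed trial file is reported by name
  writeLines("participant,trial\np99,1", file.path(d, "trials_p99.csv"))
  expect_error(read_cohort_dir(d), "trials_p99")
  unlink(d, recursive = TRUE)
  expect_error(read_cohort_dir(d), "manifest")
})
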