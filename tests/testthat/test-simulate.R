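sim <- simulate_agent("vh_cong_ideal", duration = 12)

test_that("simulate_agent returns a classed simulation with methods", {
  expect_s3_class(sim, "phasematch_sim")
  expect_s3_class(sim$trace, "phasematch_trace")
  expect_equal(nrow(sim$trace), 12 * 120 + 1L)
  expect_equal(sim$order, 3L)
  expect_output(print(sim), "phase-matching simulation")
  s <- summary(sim)
  expect_s3_class(s, "summary.phasematch_sim")
  expect_output(print(s), "Phase lag vs target")
  expect_true(all(is.finite(as.matrix(as.data.frame(sim)))))
})

test_that("lag and error summaries are finite and consistent", {
  ls <- lag_summary(sim)
  expect_true(is.finite(ls$lag_real) && is.finite(ls$lag_virtual))
  ## congruent condition: seen and felt hand are one signal
  expect_equal(ls$lag_real, ls$lag_virtual, tolerance = 1e-9)
  es <- error_summary(sim)
  expect_named(es$mse, c("target", "prop", "vis"))
  expect_true(all(es$mse >= 0))
  expect_equal(es$mse_weighted,
               es$mse * exp(sim$condition$precisions$log_prec_sensory[
                 names(es$mse)]))
})

test_that("unknown condition ids are rejected by name", {
  expect_error(simulate_agent("no_such_condition"), "unknown condition")
  expect_error(run_condition_suite(c("vh_cong", "bogus")), "bogus")
})

test_that("figure-table export is byte-deterministic", {
  d1 <- file.path(tempdir(), "figtab1")
  d2 <- file.path(tempdir(), "figtab2")
  export_figure_tables(list(vh_cong_ideal = sim), d1, traces = TRUE)
  export_figure_tables(list(vh_cong_ideal = sim), d2, traces = TRUE)
  f1 <- file.path(d1, "lag_summaries.csv")
  expect_true(file.exists(f1))
  expect_true(file.exists(file.path(d1, "trace_vh_cong_ideal.csv")))
  expect_identical(readLines(f1), readLines(file.path(d2, "lag_summaries.csv")))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("traces round-trip through write_trace/read_trace", {
  f <- file.path(tempdir(), "trace_rt.csv")
  write_trace(sim, f)
  back <- read_trace(f)
  expect_s3_class(back, "phasematch_sim")
  expect_equal(as.data.frame(back$trace), as.data.frame(sim$trace),
               tolerance = 1e-12)
  expect_equal(back$condition$instruction, sim$condition$instruction)
  expect_equal(back$condition$precisions$log_prec_sensory,
               sim$condition$precisions$log_prec_sensory)
  expect_equal(back$duration, sim$duration)
  unlink(c(f, paste0(f, ".json")))
})
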