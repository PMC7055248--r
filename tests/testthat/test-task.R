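test_that("study-preset task constants are exact", {
  p <- task_params()
  expect_equal(p$t_t, 1 / 40)
  expect_equal(p$dt, 1 / 120)
  expect_equal(p$t_a, 1 / 60)
  expect_equal(p$t_a_bins, 2)
  expect_equal(p$a_rate, 0.05)
  expect_equal(p$trial_duration, 16)
  expect_equal(task_frequency(p), 3 / (2 * pi))
  expect_error(task_params(dt = 0), "positive")
})

test_that("model flow implements the instructed attractor", {
  p <- task_params()
  vh <- model_equations(p, "VH")
  rh <- model_equations(p, "RH")
  ## hand on target with believed displacement 0.35: VH keeps compensating
  expect_equal(vh$flow(c(0.5, 0.5), 0.35, NULL), c(1 / 40, 0.35))
  expect_equal(rh$flow(c(0.5, 0.5), 0.35, NULL), c(1 / 40, 0))
  ## congruent belief (v = 0): both instructions coincide
  expect_equal(vh$flow(c(0.7, 0.2), 0, NULL), rh$flow(c(0.7, 0.2), 0, NULL))
})

test_that("process sensory mapping splits seen and felt hand", {
  p <- task_params(v_true = 0.35)
  proc <- process_equations(p)
  s <- proc$obs(c(0.8, 0.35), 0.35, proc$params)
  expect_equal(s, c(sin(0.8), sin(0.35), 0))
  ## congruent process: vis and prop coincide for any posture
  proc0 <- process_equations(task_params())
  s0 <- proc0$obs(c(0.8, 0.6), 0, proc0$params)
  expect_equal(s0[2], s0[3])
})

test_that("generalized sensory embedding matches analytic derivatives", {
  p <- task_params()
  proc <- process_equations(p)
  x <- c(x_t = 0.8, x_h = 0.3)
  a <- 0.05
  smat <- proc$sens_embed(x, 0, a, proc$params, 3L)
  expect_equal(smat[1L, ], c(target = sin(0.8), prop = sin(0.3),
                             vis = sin(0.3)))
  ## order 1 is the chain rule through the true state velocities
  expect_equal(unname(smat[2L, "target"]), cos(0.8) * p$t_t)
  expect_equal(unname(smat[2L, "prop"]), cos(0.3) * a / p$t_a_bins)
  ## action sensitivity: only the hand channels respond
  da <- proc$sens_embed_da(x, 0, a, proc$params, 3L)
  expect_equal(unname(da[, "target"]), rep(0, 3L))
  expect_equal(unname(da[2L, "prop"]), cos(0.3) / p$t_a_bins,
               tolerance = 1e-9)
})

test_that("model Jacobians agree with finite differences", {
  p <- task_params()
  m <- model_equations(p, "VH")
  x0 <- c(0.4, 0.1); v0 <- 0.2
  J <- phasematch:::model_jacobians(m, x0, v0)
  Jfd <- phasematch:::fd_jacobian(function(z) m$obs(z, v0, m$params), x0)
  expect_equal(J$gx, Jfd, tolerance = 1e-8)
  expect_equal(J$fv, matrix(c(0, 1)), tolerance = 1e-8)
})

test_that("build_condition applies attention and congruence presets", {
  base <- build_condition("VH", "incong", "default")
  expect_equal(base$v_true, 0.35)
  expect_equal(base$mu_v_init, 0.35)
  expect_equal(unname(base$precisions$log_prec_sensory),
               c(4, 3, 4))  # target, prop, vis
  ha <- build_condition("VH", "incong", "HA")
  expect_equal(unname(ha$precisions$log_prec_sensory["vis"]), 5)
  hd <- build_condition("VH", "incong", "HD")
  expect_equal(unname(hd$precisions$log_prec_sensory["prop"]), 4)
  rh_ha <- build_condition("RH", "incong", "HA")
  expect_equal(unname(rh_ha$precisions$log_prec_sensory["prop"]), 4)
  ## congruent: no displacement anywhere
  cong <- build_condition("RH", "cong")
  expect_equal(cong$v_true, 0)
  expect_equal(cong$mu_v_init, 0)
  ## ideal prior matches the true displacement
  ideal <- build_condition("VH", "incong",
                           belief_preset = "ideal_incongruent_prior")
  expect_equal(ideal$precisions$log_prec_cause_prior, 3)
})

test_that("the condition registry names all twelve conditions", {
  reg <- condition_registry()
  expect_length(reg, 12L)
  expect_true(all(c("vh_cong", "rh_cong", "vh_incong", "rh_incong",
                    "vh_incong_ha", "vh_incong_hd", "rh_incong_ha",
                    "rh_incong_hd", "vh_cong_ideal", "rh_cong_ideal",
                    "vh_incong_ideal", "rh_incong_ideal") %in% names(reg)))
  expect_s3_class(reg$vh_incong_ha, "condition_spec")
})
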