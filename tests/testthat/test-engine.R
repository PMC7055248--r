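test_that("expm_ss matches known matrix exponentials", {
  ## nilpotent: exp of the 2x2 shift
  N <- rbind(c(0, 1), c(0, 0))
  expect_equal(phasematch:::expm_ss(N), rbind(c(1, 1), c(0, 1)))
  ## rotation generator
  th <- 0.7
  A <- rbind(c(0, -th), c(th, 0))
  expect_equal(phasematch:::expm_ss(A),
               rbind(c(cos(th), -sin(th)), c(sin(th), cos(th))),
               tolerance = 1e-12)
  ## large norm exercises scaling and squaring; cross-check via Matrix
  set.seed(11)
  B <- matrix(rnorm(25, sd = 4), 5, 5)
  expect_equal(phasematch:::expm_ss(B),
               as.matrix(Matrix::expm(Matrix::Matrix(B))),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("affine_step solves z' = M z + c exactly", {
  set.seed(12)
  M <- matrix(rnorm(9), 3, 3)
  cvec <- rnorm(3)
  z0 <- rnorm(3)
  h <- 0.3
  E <- phasematch:::expm_ss(M * h)
  analytic <- as.vector(E %*% z0 + solve(M, (E - diag(3)) %*% cvec))
  expect_equal(phasematch:::affine_step(z0, M, cvec, h), analytic,
               tolerance = 1e-10)
})

test_that("prediction errors vanish when sensory input equals predictions", {
  params <- task_params()
  model <- model_equations(params, "VH")
  n <- 3L
  beliefs <- agent_state(matrix(c(0.4, 0.02, 0, 0.3, 0.01, 0), n, 2L),
                         c(0.1, 0, 0))
  e0 <- prediction_errors(model, beliefs, matrix(0, n, 3L))
  e1 <- prediction_errors(model, beliefs, e0$pred)
  expect_equal(max(abs(e1$eps_v)), 0)
  expect_true(free_energy(e1, model$precision) <
                free_energy(e0, model$precision))
  expect_true(free_energy(e0, model$precision) > 0)
})

test_that("prediction_errors rejects mismatched embedding orders", {
  params <- task_params()
  model <- model_equations(params, "RH")
  beliefs <- agent_state(matrix(0, 3L, 2L), numeric(3L))
  expect_error(prediction_errors(model, beliefs, matrix(0, 4L, 3L)),
               "embedding order")
})

test_that("action_derivative is minus the free-energy gradient in action", {
  cond <- build_condition("VH", "incong")
  params <- cond$params
  process <- process_equations(params)
  model <- model_equations(params, "VH", precision = cond$precisions)
  n <- 3L
  beliefs <- agent_state(matrix(c(0.5, 0.02, 0, 0.45, 0.02, 0), n, 2L),
                         c(0.2, 0, 0))
  world <- world_state(c(x_t = 0.5, x_h = 0.4), v_true = 0.35, a = 0.03)
  f_of_a <- function(a) {
    smat <- process$sens_embed(world$x, world$v_true, a, process$params, n)
    free_energy(prediction_errors(model, beliefs, smat), model$precision)
  }
  eps <- 1e-6
  fd <- (f_of_a(world$a + eps) - f_of_a(world$a - eps)) / (2 * eps)
  smat <- process$sens_embed(world$x, world$v_true, world$a,
                             process$params, n)
  errors <- prediction_errors(model, beliefs, smat)
  expect_equal(action_derivative(process, model, errors, world), -fd,
               tolerance = 1e-6)
})

test_that("integrate_trial validates its time arguments", {
  cond <- build_condition("VH", "cong")
  params <- cond$params
  process <- process_equations(params)
  model <- model_equations(params, "VH", precision = cond$precisions)
  world <- world_state()
  agent <- agent_state(matrix(0, 3L, 2L), numeric(3L))
  expect_error(integrate_trial(process, world, model, agent,
                               duration = 1, dt = 0), "dt")
  expect_error(integrate_trial(process, world, model, agent,
                               duration = 0.0051, dt = 1 / 120), "multiple")
})
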