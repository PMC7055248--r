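## Generalized-coordinate predictive-coding engine with an action channel.
##
## The agent's beliefs evolve by a gradient descent on variational free
## energy in generalized coordinates (generalized filtering); action
## descends the same objective through the true generative process.  The
## integrator works in units of the simulation time bin; reported times
## are seconds.

#' Prediction errors of a generative model
#'
#' Computes sensory, state-motion and cause-prior prediction errors in
#' generalized coordinates.  Order 0 of each prediction is the nonlinear
#' mapping evaluated at the order-0 beliefs; higher orders use the
#' first-order chain rule (Jacobians at order 0), the standard generalized
#' filtering treatment.
#'
#' @param model a [model_spec()] (the agent's generative model).
#' @param beliefs an [agent_state()].
#' @param sensory numeric matrix, order x channel: generalized sensory
#'   input (columns target, prop, vis).
#' @return list of class `"error_set"` with elements `eps_v` (order x
#'   channel), `eps_x` (order x state), `eps_prior` (length-n vector),
#'   the predictions `pred` and `flow_pred`, and the Jacobians used.
#' @export
prediction_errors <- function(model, beliefs, sensory) {
  mu_x <- beliefs$mu_x
  mu_v <- beliefs$mu_v
  n <- nrow(mu_x)
  sensory <- as.matrix(sensory)
  if (nrow(sensory) != n)
    stop("beliefs and sensory input must share one embedding order",
         call. = FALSE)
  x0 <- mu_x[1L, ]
  v0 <- mu_v[1L]
  J <- model_jacobians(model, x0, v0)
  g0 <- model$obs(x0, v0, model$params)
  f0 <- model$flow(x0, v0, model$params)
  pred <- rbind(g0, mu_x[-1L, , drop = FALSE] %*% t(J$gx) +
                  outer(mu_v[-1L], as.vector(J$gv)))
  flow_pred <- rbind(f0, mu_x[-1L, , drop = FALSE] %*% t(J$fx) +
                       outer(mu_v[-1L], as.vector(J$fv)))
  Dmu_x <- rbind(mu_x[-1L, , drop = FALSE], 0)
  eps_prior <- mu_v - c(model$cause_prior_mean, rep(0, n - 1L))
  structure(list(
    eps_v = sensory - pred,
    eps_x = Dmu_x - flow_pred,
    eps_prior = eps_prior,
    pred = pred, flow_pred = flow_pred, J = J
  ), class = "error_set")
}

#' Time derivative of the agent's beliefs
#'
#' The generalized filtering update: the generalized motion of the beliefs
#' minus the free-energy gradient, i.e. precision-weighted prediction
#' errors passed through the (transposed) generalized Jacobians.  The
#' level-above term for the hidden cause is realized as its static
#' Gaussian prior.
#'
#' @param model a [model_spec()].
#' @param beliefs an [agent_state()].
#' @param errors an error set from [prediction_errors()].
#' @return list with `mu_x_dot` (order x state) and `mu_v_dot` (length n).
#' @export
belief_derivative <- function(model, beliefs, errors) {
  n <- nrow(beliefs$mu_x)
  m <- ncol(beliefs$mu_x)
  P <- build_precisions(model$precision, n)
  J <- errors$J
  D_n <- make_shift_operator(n)
  w_v <- P$Pi_v %*% as.vector(errors$eps_v)      # (p*n)
  w_x <- P$Pi_x %*% as.vector(errors$eps_x)      # (m*n)
  w_p <- P$Pi_p %*% errors$eps_prior             # (n)
  if (any(!is.finite(w_v)) || any(!is.finite(w_x)))
    stop("numerical failure: non-finite precision-weighted errors",
         call. = FALSE)
  A_gx <- kronecker(J$gx, diag(n))
  A_gv <- kronecker(J$gv, diag(n))
  A_fx <- kronecker(J$fx, diag(n))
  A_fv <- kronecker(J$fv, diag(n))
  D_x <- kronecker(diag(m), D_n)
  mu_x_dot <- D_x %*% as.vector(beliefs$mu_x) +
    t(A_gx) %*% w_v + t(A_fx) %*% w_x - t(D_x) %*% w_x
  mu_v_dot <- D_n %*% beliefs$mu_v +
    t(A_gv) %*% w_v + t(A_fv) %*% w_x - w_p
  list(mu_x_dot = matrix(mu_x_dot, n, m),
       mu_v_dot = as.vector(mu_v_dot))
}

#' Time derivative of action
#'
#' Action descends the free energy through the true generative process:
#' `a_dot = -(d eps_v / d a)' Pi_v eps_v`, where the sensitivity of the
#' generalized sensory input to action is computed through the process
#' (action enters the velocity order of the hand state).  Channels that do
#' not depend on the hand (the target) contribute zero.
#'
#' @param process the generative process [model_spec()] (must expose the
#'   sensory sensitivity to action, see [model_spec()]).
#' @param model the agent's generative model (supplies the precisions that
#'   weight the sensory errors).
#' @param errors current error set.
#' @param world a [world_state()].
#' @return scalar `a_dot`.
#' @export
action_derivative <- function(process, model, errors, world) {
  n <- nrow(errors$eps_v)
  P <- build_precisions(model$precision, n)
  S_a <- sens_embed_da_of(process, world, n)
  -as.numeric(crossprod(as.vector(S_a), P$Pi_v %*% as.vector(errors$eps_v)))
}

#' Variational free energy of an error set
#'
#' The sum of precision-weighted squared prediction errors,
#' `F = 1/2 sum_i eps_i' Pi_i eps_i`.  Log-determinant terms are omitted:
#' they are constant with respect to beliefs and action under fixed
#' precisions, so gradients are unaffected; consequently `F` is
#' non-negative and zero iff all errors vanish.
#'
#' @param errors an error set from [prediction_errors()].
#' @param precision a [precision_spec()] (the model's).
#' @return scalar free energy (diagnostic).
#' @export
free_energy <- function(errors, precision) {
  n <- nrow(errors$eps_v)
  P <- build_precisions(precision, n)
  ev <- as.vector(errors$eps_v)
  ex <- as.vector(errors$eps_x)
  ep <- errors$eps_prior
  0.5 * (sum(ev * (P$Pi_v %*% ev)) + sum(ex * (P$Pi_x %*% ex)) +
           sum(ep * (P$Pi_p %*% ep)))
}

## --- process-side generalized sensory input --------------------------------

sens_embed_of <- function(process, world, order) {
  if (!is.null(process$sens_embed))
    return(process$sens_embed(world$x, world$v_true, world$a,
                              process$params, order))
  ## linearized fallback: order 0 exact, order 1 via Jacobian * flow
  x <- world$x
  v <- world$v_true
  g0 <- process$obs(x, v, process$params)
  smat <- matrix(0, order, length(g0))
  smat[1L, ] <- g0
  if (order > 1L) {
    Jg <- fd_jacobian(function(z) process$obs(z, v, process$params), x)
    smat[2L, ] <- as.vector(Jg %*% process$flow(x, v, world$a, process$params))
  }
  smat
}

sens_embed_da_of <- function(process, world, order) {
  if (!is.null(process$sens_embed_da))
    return(process$sens_embed_da(world$x, world$v_true, world$a,
                                 process$params, order))
  eps <- 1e-6
  wp <- wm <- world
  wp$a <- wp$a + eps
  wm$a <- wm$a - eps
  (sens_embed_of(process, wp, order) - sens_embed_of(process, wm, order)) /
    (2 * eps)
}

## derivative of vec(generalized sensory input) wrt the world states
sens_embed_dx_of <- function(process, world, order) {
  if (!is.null(process$sens_embed_dx))
    return(process$sens_embed_dx(world$x, world$v_true, world$a,
                                 process$params, order))
  eps <- 1e-6
  m <- length(world$x)
  cols <- vector("list", m)
  for (j in seq_len(m)) {
    wp <- wm <- world
    wp$x[j] <- wp$x[j] + eps
    wm$x[j] <- wm$x[j] - eps
    cols[[j]] <- as.vector(sens_embed_of(process, wp, order) -
                             sens_embed_of(process, wm, order)) / (2 * eps)
  }
  do.call(cbind, cols)
}

## --- matrix exponential (scaling and squaring, Pade order 13) --------------

expm_ss <- function(A) {
  b <- c(64764752532480000, 32382376266240000, 7771770303897600,
         1187353796428800, 129060195264000, 10559470521600, 670442572800,
         33522128640, 1323241920, 40840800, 960960, 16380, 182, 1)
  nrm <- max(colSums(abs(A)))
  s <- if (nrm > 5.37) ceiling(log2(nrm / 5.37)) else 0L
  A <- A / 2^s
  n <- nrow(A)
  I <- diag(n)
  A2 <- A %*% A
  A4 <- A2 %*% A2
  A6 <- A2 %*% A4
  U <- A %*% (A6 %*% (b[14] * A6 + b[12] * A4 + b[10] * A2) +
                b[8] * A6 + b[6] * A4 + b[4] * A2 + b[2] * I)
  V <- A6 %*% (b[13] * A6 + b[11] * A4 + b[9] * A2) +
    b[7] * A6 + b[5] * A4 + b[3] * A2 + b[1] * I
  E <- solve(V - U, V + U)
  for (i in seq_len(s)) E <- E %*% E
  E
}

## exact update of z' = M z + c0 + c1 * tau over one step h
## (augmented exponential with a ramp state)
affine_step <- function(z, M, c0, h, c1 = NULL) {
  d <- length(z)
  if (is.null(c1)) c1 <- numeric(d)
  A <- rbind(cbind(M, c1, c0),
             c(numeric(d), 0, 1),
             numeric(d + 2L))
  Phi <- expm_ss(A * h)
  as.vector(Phi[seq_len(d), seq_len(d)] %*% z + Phi[seq_len(d), d + 2L])
}

## Assemble the locally linearized joint dynamics of the coupled
## agent/world system: z = (mu_x stacked state-major, mu_v, a, world x).
## The generalized sensory input is linearized in the world states and in
## action, so the perception-action loop is closed within each time bin.
## Frozen coefficients at the current point; returns M, c, the
## instantaneous errors and derivatives.
assemble_step <- function(model, process, beliefs, world, P) {
  n <- nrow(beliefs$mu_x)
  m <- ncol(beliefs$mu_x)
  smat <- sens_embed_of(process, world, n)
  errors <- prediction_errors(model, beliefs, smat)
  J <- errors$J
  I_n <- diag(n)
  D_n <- make_shift_operator(n)
  G <- cbind(kronecker(J$gx, I_n), kronecker(J$gv, I_n))      # (p n) x (3 n)
  Cf <- cbind(kronecker(J$fx, I_n), kronecker(J$fv, I_n))     # (m n) x (3 n)
  Dxsel <- cbind(kronecker(diag(m), D_n), matrix(0, m * n, n))
  Mx <- Dxsel - Cf
  Pv_sel <- cbind(matrix(0, n, m * n), I_n)
  D3 <- kronecker(diag(m + 1L), D_n)
  bvec <- c(as.vector(beliefs$mu_x), beliefs$mu_v)
  g_c <- as.vector(errors$pred) - G %*% bvec
  f_c <- as.vector(errors$flow_pred) - Cf %*% bvec
  S_a <- as.vector(sens_embed_da_of(process, world, n))
  S_x <- sens_embed_dx_of(process, world, n)                  # (p n) x m
  xw <- as.numeric(world$x)
  s_c <- as.vector(smat) - S_a * world$a - as.vector(S_x %*% xw)
  eta <- c(model$cause_prior_mean, rep(0, n - 1L))
  ## process flow linearized in (world x, a)
  fw0 <- process$flow(world$x, world$v_true, world$a, process$params)
  Jwx <- fd_jacobian(function(z)
    process$flow(z, world$v_true, world$a, process$params), world$x)
  Jwa <- fd_jacobian(function(z)
    process$flow(world$x, world$v_true, z, process$params), world$a)
  c_w <- fw0 - as.vector(Jwx %*% xw) - as.vector(Jwa) * world$a

  GtPv <- crossprod(G, P$Pi_v)
  MxtPx <- crossprod(Mx, P$Pi_x)
  PvtPp <- crossprod(Pv_sel, P$Pi_p)
  SatPv <- crossprod(matrix(S_a, ncol = 1L), P$Pi_v)          # 1 x (p n)

  M_bb <- D3 - GtPv %*% G - MxtPx %*% Mx - PvtPp %*% Pv_sel
  M_ba <- GtPv %*% S_a
  M_bw <- GtPv %*% S_x
  M_ab <- SatPv %*% G
  M_aa <- -as.vector(SatPv %*% S_a)
  M_aw <- -(SatPv %*% S_x)
  c_b <- GtPv %*% (s_c - g_c) + MxtPx %*% f_c + PvtPp %*% eta
  c_a <- -as.vector(SatPv %*% (s_c - g_c))

  nb <- (m + 1L) * n
  M <- rbind(cbind(M_bb, M_ba, M_bw),
             cbind(M_ab, M_aa, M_aw),
             cbind(matrix(0, m, nb), as.vector(Jwa), Jwx))
  cv <- c(as.vector(c_b), c_a, c_w)
  z <- c(bvec, world$a, xw)
  zdot <- as.vector(M %*% z + cv)
  list(M = M, c = cv, z = z, zdot = zdot, errors = errors, smat = smat,
       a_dot = zdot[nb + 1L])
}

#' Integrate one trial of the coupled world/agent system
#'
#' Integrates the coupled system of world states, beliefs and action by
#' local linearization over each time bin: the noise-free generalized
#' sensory input (simulating the average response over realizations of the
#' suppressed process fluctuations) is linearized in the world states and
#' in action, so the perception-action loop is closed within the bin, and
#' the joint affine system is advanced by one matrix-exponential step.
#'
#' @param process generative process [model_spec()]; its `flow` has
#'   signature `function(x, v, a, params)`.
#' @param world initial [world_state()].
#' @param model the agent's generative model [model_spec()].
#' @param agent initial [agent_state()].
#' @param duration trial duration in seconds (multiple of `dt`).
#' @param dt time-bin length in seconds.
#' @param method `"local_linear"` (default; matrix-exponential update) or
#'   `"euler"` (explicit Euler with `euler_substeps` substeps per bin).
#' @param euler_substeps substeps per bin for the Euler fallback.
#' @return a data frame of class `"phasematch_trace"` with one row per
#'   time bin (length `duration/dt + 1`): time, true states, action and
#'   its rate, sensory samples, predictions, order-0 prediction errors,
#'   order-0 beliefs, and free energy.
#' @export
integrate_trial <- function(process, world, model, agent, duration, dt,
                            method = c("local_linear", "euler"),
                            euler_substeps = 64L) {
  method <- match.arg(method)
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  N <- duration / dt
  if (abs(N - round(N)) > 1e-9)
    stop("'duration' must be a multiple of 'dt'", call. = FALSE)
  N <- as.integer(round(N))
  n <- nrow(agent$mu_x)
  m <- ncol(agent$mu_x)
  P <- build_precisions(model$precision, n)
  rec <- matrix(NA_real_, N + 1L, 18L)
  colnames(rec) <- c("t", "x_t", "x_h", "a", "a_dot",
                     "s_target", "s_prop", "s_vis",
                     "pred_target", "pred_prop", "pred_vis",
                     "eps_target", "eps_prop", "eps_vis",
                     "mu_xt", "mu_xh", "mu_v", "F")
  nb <- (m + 1L) * n
  unpack <- function(z) {
    list(agent = agent_state(matrix(z[seq_len(m * n)], n, m,
                                    dimnames = dimnames(agent$mu_x)),
                             z[m * n + seq_len(n)]),
         world = world_state(stats::setNames(z[nb + 1L + seq_len(m)],
                                             names(world$x)),
                             world$v_true, z[nb + 1L]))
  }
  for (i in 0:N) {
    st <- assemble_step(model, process, agent, world, P)
    rec[i + 1L, ] <- c(i * dt, world$x[1L], world$x[2L], world$a, st$a_dot,
                       st$smat[1L, ], st$errors$pred[1L, ],
                       st$errors$eps_v[1L, ],
                       agent$mu_x[1L, ], agent$mu_v[1L],
                       free_energy(st$errors, model$precision))
    if (i == N) break
    z_new <- if (method == "local_linear") {
      affine_step(st$z, st$M, st$c, 1)
    } else {
      z <- st$z
      h <- 1 / euler_substeps
      for (k in seq_len(euler_substeps)) {
        sub <- unpack(z)
        s2 <- assemble_step(model, process, sub$agent, sub$world, P)
        z <- z + h * s2$zdot
      }
      z
    }
    if (any(!is.finite(z_new)) || any(abs(z_new) > 1e6))
      stop("divergence at step ", i + 1L, " (t = ", signif(i * dt, 4),
           " s): belief/action magnitude exceeded 1e6", call. = FALSE)
    nxt <- unpack(z_new)
    world <- nxt$world
    agent <- nxt$agent
  }
  out <- as.data.frame(rec)
  attr(out, "order") <- n
  attr(out, "dt") <- dt
  class(out) <- c("phasematch_trace", "data.frame")
  out
}
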