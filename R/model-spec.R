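#' Specify a generative model (or generative process)
#'
#' A model couples a flow (equations of motion of the hidden states), an
#' observer function (sensory mapping), a static Gaussian prior on the
#' hidden cause, parameters, and a precision specification.  The same
#' structure describes the agent's generative model and the true generative
#' process; for the process, `flow` and `obs` may additionally depend on
#' action via `params`.
#'
#' Jacobians may be supplied in closed form (`jac`, a list of functions
#' `fx`, `fv`, `gx`, `gv` with the same arguments as `flow`/`obs`);
#' otherwise they are obtained by central finite differences.
#'
#' A process model may carry two optional closures used by the integrator:
#' `sens_embed(x, v, a, params, order)` returning the exact generalized
#' sensory embedding (n x p matrix), and `sens_embed_da(...)` returning its
#' derivative with respect to action.  Without them a first-order
#' (linearized) embedding is used.
#'
#' @param flow function(x, v, params) -> numeric vector of state velocities.
#' @param obs function(x, v, params) -> numeric vector of sensory values
#'   (channel order: target, prop, vis).
#' @param cause_prior_mean prior expectation of the hidden cause (radians).
#' @param params named list of model constants.
#' @param precision a [precision_spec()].
#' @param n_states,n_causes dimensions of the hidden state/cause vectors.
#' @param jac optional list of closed-form Jacobian functions.
#' @param sens_embed,sens_embed_da,sens_embed_dx optional process closures:
#'   the exact generalized sensory embedding and its derivatives with
#'   respect to action and to the world states (see above).
#' @return list of class `"model_spec"`.
#' @export
model_spec <- function(flow, obs, cause_prior_mean = 0, params = list(),
                       precision = precision_spec(),
                       n_states = 2L, n_causes = 1L, jac = NULL,
                       sens_embed = NULL, sens_embed_da = NULL,
                       sens_embed_dx = NULL) {
  stopifnot(is.function(flow), is.function(obs),
            inherits(precision, "precision_spec"))
  structure(list(flow = flow, obs = obs,
                 cause_prior_mean = cause_prior_mean,
                 params = params, precision = precision,
                 n_states = as.integer(n_states),
                 n_causes = as.integer(n_causes),
                 jac = jac,
                 sens_embed = sens_embed, sens_embed_da = sens_embed_da,
                 sens_embed_dx = sens_embed_dx),
            class = "model_spec")
}

#' Agent state: beliefs in generalized coordinates
#'
#' @param mu_x numeric matrix, order x state: beliefs about hidden states
#'   (columns `x_t`, `x_h`), rows are derivative orders 0..n-1.
#' @param mu_v numeric vector of length n: belief about the hidden cause
#'   (visuo-proprioceptive displacement), in generalized coordinates.
#' @return list of class `"agent_state"`.
#' @export
agent_state <- function(mu_x, mu_v) {
  mu_x <- as.matrix(mu_x)
  if (nrow(mu_x) != length(mu_v))
    stop("all generalized vectors must share one embedding order", call. = FALSE)
  if (!all(is.finite(mu_x)) || !all(is.finite(mu_v)))
    stop("agent state must be finite", call. = FALSE)
  structure(list(mu_x = mu_x, mu_v = as.numeric(mu_v)), class = "agent_state")
}

#' World state of the generative process
#'
#' @param x named numeric: true hidden states (radians), `x_t` (target)
#'   and `x_h` (hand).
#' @param v_true true visuo-proprioceptive displacement (radians),
#'   constant within a trial.
#' @param a action (rate of change of hand posture, model units).
#' @return list of class `"world_state"`.
#' @export
world_state <- function(x = c(x_t = 0, x_h = 0), v_true = 0, a = 0) {
  if (!all(is.finite(c(x, v_true, a))))
    stop("world state must be finite", call. = FALSE)
  structure(list(x = x, v_true = v_true, a = a), class = "world_state")
}

## central finite-difference Jacobian of f(z) wrt z (small dims only)
fd_jacobian <- function(f, z, eps = 1e-6) {
  f0 <- f(z)
  J <- matrix(0, length(f0), length(z))
  for (j in seq_along(z)) {
    zp <- zm <- z
    zp[j] <- zp[j] + eps
    zm[j] <- zm[j] - eps
    J[, j] <- (f(zp) - f(zm)) / (2 * eps)
  }
  J
}

## Jacobians of flow/obs at order-0 beliefs; closed forms when available.
model_jacobians <- function(model, x0, v0) {
  p <- model$params
  if (!is.null(model$jac)) {
    list(fx = model$jac$fx(x0, v0, p), fv = model$jac$fv(x0, v0, p),
         gx = model$jac$gx(x0, v0, p), gv = model$jac$gv(x0, v0, p))
  } else {
    list(fx = fd_jacobian(function(z) model$flow(z, v0, p), x0),
         fv = fd_jacobian(function(z) model$flow(x0, z, p), v0),
         gx = fd_jacobian(function(z) model$obs(z, v0, p), x0),
         gv = fd_jacobian(function(z) model$obs(x0, z, p), v0))
  }
}
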