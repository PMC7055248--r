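## The hand-target phase matching task: generative process, generative
## model, and the factory for all experimental conditions.

#' Task parameters of the phase-matching simulation
#'
#' Defaults are the study preset: the target state advances at a constant
#' rate of 1/40 radians per 1/120 s time bin (so one sensory oscillation
#' takes 2*pi/3 ~ 2.09 s, the task's nominal 0.5 Hz pacing), the hand
#' state is driven by action with a 16.67 ms time constant, and the
#' visuo-proprioceptive displacement is 0.35 radians (~111 ms) in
#' incongruent trials.
#'
#' @param t_t target drive rate, radians per time bin.
#' @param t_a action time constant, seconds.
#' @param dt time-bin length, seconds.
#' @param v_true true visuo-proprioceptive displacement, radians.
#' @param a_rate nominal scale of action (per time bin); used for
#'   normalizing/plotting action only, it adds no dynamical term.
#' @param trial_duration simulated trial length, seconds.
#' @return list of class `"task_params"`.
#' @export
task_params <- function(t_t = 1 / 40, t_a = 1 / 60, dt = 1 / 120,
                        v_true = 0, a_rate = 0.05, trial_duration = 16) {
  if (any(c(t_t, t_a, dt, a_rate, trial_duration) <= 0) || v_true < 0)
    stop("task parameters must be positive (v_true non-negative)",
         call. = FALSE)
  structure(list(t_t = t_t, t_a = t_a, dt = dt, v_true = v_true,
                 a_rate = a_rate, trial_duration = trial_duration,
                 t_a_bins = t_a / dt),
            class = "task_params")
}

#' Oscillation frequency implied by the task parameters
#'
#' The target's sensory oscillation frequency in Hz:
#' `t_t / (2 * pi * dt)`.
#' @param params a [task_params()].
#' @return frequency in Hz (~0.477 Hz under the study preset).
#' @export
task_frequency <- function(params) params$t_t / (2 * pi * params$dt)

#' The generative process of the phase-matching task
#'
#' True world dynamics: the target state advances at constant rate `t_t`;
#' the hand state is driven by action, `x_h' = a / t_a`.  Sensory mapping:
#' `s = (sin(x_t), sin(x_h), sin(x_h - v))` for the target, proprioceptive
#' and visual channels.  The process differentiates its sensory mappings
#' analytically (exact truncated chain rule) to supply generalized sensory
#' input and its sensitivity to action; action is treated as constant
#' within a bin, so the hand's generalized motion is truncated at the
#' velocity order.
#'
#' @param params a [task_params()].
#' @return a [model_spec()] for the process (flow signature
#'   `function(x, v, a, params)`).
#' @export
process_equations <- function(params) {
  ta <- params$t_a_bins
  tt <- params$t_t
  embed_states <- function(x, a, order) {
    list(xt = c(x[1L], tt, rep(0, order - 2L)),
         xh = c(x[2L], a / ta, rep(0, order - 2L)))
  }
  model_spec(
    flow = function(x, v, a, params) c(tt, a / ta),
    obs = function(x, v, params) c(sin(x[1L]), sin(x[2L]), sin(x[2L] - v)),
    params = unclass(params),
    sens_embed = function(x, v, a, params, order) {
      e <- embed_states(x, a, order)
      xv <- e$xh - c(v, rep(0, order - 1L))
      cbind(target = sin_embed(e$xt), prop = sin_embed(e$xh),
            vis = sin_embed(xv))
    },
    sens_embed_da = function(x, v, a, params, order) {
      e <- embed_states(x, a, order)
      xv <- e$xh - c(v, rep(0, order - 1L))
      du <- c(0, 1 / ta, rep(0, order - 2L))
      cbind(target = rep(0, order), prop = sin_embed_da(e$xh, du),
            vis = sin_embed_da(xv, du))
    },
    sens_embed_dx = function(x, v, a, params, order) {
      e <- embed_states(x, a, order)
      xv <- e$xh - c(v, rep(0, order - 1L))
      d0 <- c(1, rep(0, order - 1L))
      zero <- rep(0, order)
      cbind(c(sin_embed_da(e$xt, d0), zero, zero),
            c(zero, sin_embed_da(e$xh, d0), sin_embed_da(xv, d0)))
    }
  )
}

#' The agent's generative model of the phase-matching task
#'
#' Same sensory mapping as the process (with the believed cause in place
#' of the true displacement), no action, and a hand state driven by the
#' hand-target displacement: `x_h' = x_t - x_h` under the real-hand
#' instruction, and `x_h' = x_t - (x_h - v)` under the virtual-hand
#' instruction (the perceived visual delay must additionally be
#' compensated to keep the seen hand on the target).
#'
#' @param params a [task_params()].
#' @param instruction `"VH"` or `"RH"`.
#' @param precision a [precision_spec()].
#' @param cause_prior_mean prior expectation of the displacement cause.
#' @return a [model_spec()].
#' @export
model_equations <- function(params, instruction = c("RH", "VH"),
                            precision = precision_spec(),
                            cause_prior_mean = 0) {
  instruction <- match.arg(instruction)
  tt <- params$t_t
  vh <- instruction == "VH"
  model_spec(
    flow = function(x, v, params)
      c(tt, x[1L] - x[2L] + if (vh) v else 0),
    obs = function(x, v, params)
      c(sin(x[1L]), sin(x[2L]), sin(x[2L] - v)),
    cause_prior_mean = cause_prior_mean,
    params = unclass(params),
    precision = precision,
    jac = list(
      fx = function(x, v, params) rbind(c(0, 0), c(1, -1)),
      fv = function(x, v, params) matrix(c(0, if (vh) 1 else 0), 2L, 1L),
      gx = function(x, v, params)
        rbind(c(cos(x[1L]), 0), c(0, cos(x[2L])), c(0, cos(x[2L] - v))),
      gv = function(x, v, params) matrix(c(0, 0, -cos(x[2L] - v)), 3L, 1L)
    )
  )
}

#' Build one experimental condition
#'
#' Assembles the full parameterization of a simulated condition:
#' instruction (which modality must track the target), congruence (whether
#' the seen hand is displaced from the felt hand), attentional set
#' (which sensory log-precision is raised by 1) and prior-belief preset.
#'
#' Default hand-channel log-precisions are 3 (proprioception) and 4
#' (vision); `HA` raises the instructed modality's channel by 1, `HD` the
#' non-instructed ("distractor") channel.  The target channel keeps
#' log-precision 4 in all conditions.  Incongruent conditions have a true
#' displacement of 0.35 rad and initialize the belief about the cause at
#' 0.35; the cause-prior mean is 0 (`congruent_prior`) or equals the true
#' displacement (`ideal_incongruent_prior`).
#'
#' @param instruction `"VH"` or `"RH"`.
#' @param congruence `"cong"` or `"incong"`.
#' @param attention `"default"`, `"HA"` or `"HD"`.
#' @param belief_preset `"congruent_prior"` or `"ideal_incongruent_prior"`.
#' @param params a [task_params()] (its `v_true` is overridden by
#'   `congruence`).
#' @param log_prec_states model state-motion log-precision.
#' @param smoothness assumed fluctuation correlation length (time bins).
#' @return list of class `"condition_spec"`.
#' @export
build_condition <- function(instruction = c("VH", "RH"),
                            congruence = c("cong", "incong"),
                            attention = c("default", "HA", "HD"),
                            belief_preset = c("congruent_prior",
                                              "ideal_incongruent_prior"),
                            params = task_params(),
                            log_prec_states = 3,
                            smoothness = 0.5) {
  instruction <- match.arg(instruction)
  congruence <- match.arg(congruence)
  attention <- match.arg(attention)
  belief_preset <- match.arg(belief_preset)
  v_true <- if (congruence == "incong") 0.35 else 0
  params$v_true <- v_true
  lp <- c(target = 4, prop = 3, vis = 4)
  instructed <- if (instruction == "VH") "vis" else "prop"
  distractor <- if (instruction == "VH") "prop" else "vis"
  if (attention == "HA") lp[instructed] <- lp[instructed] + 1
  if (attention == "HD") lp[distractor] <- lp[distractor] + 1
  prior_mean <- if (belief_preset == "ideal_incongruent_prior") v_true else 0
  structure(list(
    instruction = instruction, congruence = congruence,
    attention = attention, belief_preset = belief_preset,
    params = params,
    precisions = precision_spec(log_prec_sensory = lp,
                                log_prec_states = log_prec_states,
                                log_prec_cause_prior = 3,
                                smoothness = smoothness),
    mu_v_init = if (congruence == "incong") 0.35 else 0,
    v_true = v_true
  ), class = "condition_spec")
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf("Condition: %s %s, attention %s, prior %s\n",
              x$instruction, x$congruence, x$attention, x$belief_preset))
  cat(sprintf("  v_true = %.2f rad, mu_v init = %.2f, log-precisions (target, prop, vis) = (%g, %g, %g)\n",
              x$v_true, x$mu_v_init, x$precisions$log_prec_sensory["target"],
              x$precisions$log_prec_sensory["prop"],
              x$precisions$log_prec_sensory["vis"]))
  invisible(x)
}

#' Registry of the named experimental conditions
#'
#' The conditions simulated in the study: four ideal-belief conditions
#' (prior adjusted to the true congruence), the four realistic default
#' conditions, and the incongruent high-attention (HA) / high-distraction
#' (HD) variants of both instructions.
#'
#' @param ... passed to [build_condition()] (e.g. `params`,
#'   `log_prec_states`).
#' @return named list of [build_condition()] specs.
#' @export
condition_registry <- function(...) {
  reg <- list(
    vh_cong = build_condition("VH", "cong", "default", "congruent_prior", ...),
    rh_cong = build_condition("RH", "cong", "default", "congruent_prior", ...),
    vh_incong = build_condition("VH", "incong", "default", "congruent_prior", ...),
    rh_incong = build_condition("RH", "incong", "default", "congruent_prior", ...),
    vh_incong_ha = build_condition("VH", "incong", "HA", "congruent_prior", ...),
    vh_incong_hd = build_condition("VH", "incong", "HD", "congruent_prior", ...),
    rh_incong_ha = build_condition("RH", "incong", "HA", "congruent_prior", ...),
    rh_incong_hd = build_condition("RH", "incong", "HD", "congruent_prior", ...),
    vh_cong_ideal = build_condition("VH", "cong", "default", "ideal_incongruent_prior", ...),
    rh_cong_ideal = build_condition("RH", "cong", "default", "ideal_incongruent_prior", ...),
    vh_incong_ideal = build_condition("VH", "incong", "default", "ideal_incongruent_prior", ...),
    rh_incong_ideal = build_condition("RH", "incong", "default", "ideal_incongruent_prior", ...)
  )
  reg
}
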