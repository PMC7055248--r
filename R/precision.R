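#' Precision specification for a generative model
#'
#' Precisions (inverse variances) of the assumed random fluctuations.  The
#' scalar precisions are `exp(log_prec)`; over generalized orders they are
#' expanded by the smoothness model (see [autocorr_precision()]).  The
#' sensory channel set is fixed to the three task channels: `target`
#' (visual target size), `prop` (proprioceptive hand posture) and `vis`
#' (visual hand posture).
#'
#' @param log_prec_sensory named numeric: log-precision per sensory channel;
#'   names must be exactly `target`, `prop`, `vis`.
#' @param log_prec_states log-precision of the motion of hidden states.
#' @param log_prec_cause_prior log-precision of the static prior on the
#'   hidden cause (the visuo-proprioceptive displacement).
#' @param smoothness temporal correlation length of the assumed
#'   fluctuations, in integrator time units (time bins).
#' @return list of class `"precision_spec"`.
#' @export
precision_spec <- function(log_prec_sensory = c(target = 4, prop = 3, vis = 4),
                           log_prec_states = 3,
                           log_prec_cause_prior = 3,
                           smoothness = 0.5) {
  channels <- c("target", "prop", "vis")
  if (!setequal(names(log_prec_sensory), channels))
    stop("sensory channels must be exactly: ", paste(channels, collapse = ", "),
         call. = FALSE)
  if (smoothness < 0) stop("'smoothness' must be non-negative", call. = FALSE)
  structure(list(
    log_prec_sensory = log_prec_sensory[channels],
    log_prec_states = log_prec_states,
    log_prec_cause_prior = log_prec_cause_prior,
    smoothness = smoothness
  ), class = "precision_spec")
}

#' Precision of generalized fluctuations under a Gaussian autocorrelation
#'
#' For a stationary process with Gaussian autocorrelation
#' `rho(h) = exp(-h^2 / (2 s^2))`, the covariance between derivative orders
#' i and j at one instant is `(-1)^i rho^(i+j)(0)`, which vanishes for odd
#' `i + j` and equals `(-1)^((i+j)/2 + i) (i+j-1)!! / s^(i+j)` otherwise.
#' The returned matrix is the inverse of that order-covariance; the full
#' generalized precision of a term with scalar precision `p` is
#' `p * autocorr_precision(n, s)`.
#'
#' @param order embedding order n.
#' @param smoothness correlation length s (> 0) in time units; `s = 0`
#'   returns the identity (orders treated as independent unit-precision).
#' @return an n x n positive-definite matrix.
#' @export
autocorr_precision <- function(order, smoothness) {
  if (smoothness == 0) return(diag(order))
  s <- smoothness
  C <- matrix(0, order, order)
  for (i in 0:(order - 1L)) for (j in 0:(order - 1L)) {
    k <- i + j
    if (k %% 2L == 0L) {
      m <- k %/% 2L
      ## rho^(2m)(0) = (-1)^m (2m-1)!! / s^(2m); double factorial of -1 is 1
      dfact <- if (m == 0L) 1 else prod(seq(1, 2 * m - 1, by = 2))
      C[i + 1L, j + 1L] <- (-1)^i * (-1)^m * dfact / s^k
    }
  }
  solve(C)
}

## Assemble the three generalized precision matrices used by the engine:
## block-diagonal over channels/states (variable-major stacking), each
## block p_i * R where R is the order-expansion.
build_precisions <- function(prec, order) {
  R <- autocorr_precision(order, prec$smoothness)
  kron_diag <- function(p) {
    out <- matrix(0, length(p) * order, length(p) * order)
    for (i in seq_along(p)) {
      idx <- (i - 1L) * order + seq_len(order)
      out[idx, idx] <- p[i] * R
    }
    out
  }
  list(
    Pi_v = kron_diag(exp(prec$log_prec_sensory)),
    Pi_x = kron_diag(rep(exp(prec$log_prec_states), 2L)),
    Pi_p = exp(prec$log_prec_cause_prior) * R,
    R = R
  )
}
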