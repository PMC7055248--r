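#' Generalized coordinates of motion
#'
#' A variable in generalized coordinates is represented by a plain numeric
#' vector holding its successive temporal derivative orders: position,
#' velocity, acceleration, jerk, ...  Order 0 is in task units (radians for
#' hidden states, dimensionless for sensory samples); order k is the k-th
#' temporal derivative in the integrator's time unit.
#'
#' `gen_vec()` validates and tags such a vector.  Most internal code works
#' on bare numeric vectors/matrices; the constructor exists so user-facing
#' values carry their invariants (finite entries, stated order).
#'
#' @param values numeric vector, derivative orders 0..n-1.
#' @return numeric vector of class `"gen_vec"`.
#' @examples
#' gen_vec(c(0, 1, 0, -1))  # sin(t) at t = 0, embedded to order 4
#' @export
gen_vec <- function(values) {
  if (!is.numeric(values) || length(values) < 1L)
    stop("a generalized vector needs at least one numeric entry", call. = FALSE)
  if (!all(is.finite(values)))
    stop("generalized vector entries must be finite", call. = FALSE)
  structure(as.numeric(values), class = "gen_vec")
}

#' @export
print.gen_vec <- function(x, ...) {
  cat("Generalized vector (order ", length(x), "):\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Shift (derivative) operator on generalized coordinates
#'
#' Returns the matrix `D` that maps a generalized vector onto its
#' generalized motion: `(v0, v1, ..., v_{n-1}) -> (v1, ..., v_{n-1}, 0)`.
#' `D` is nilpotent: applying it `order` times annihilates any vector.
#'
#' @param order positive integer, the embedding order n.
#' @return an `order` x `order` numeric matrix.
#' @examples
#' make_shift_operator(3) %*% c(2, 5, -1)  # (5, -1, 0)
#' @export
make_shift_operator <- function(order) {
  if (!is.numeric(order) || length(order) != 1L || is.na(order) ||
      order < 1 || order != round(order))
    stop("'order' must be a positive integer", call. = FALSE)
  order <- as.integer(order)
  D <- matrix(0, order, order)
  if (order > 1L)
    D[cbind(seq_len(order - 1L), seq_len(order - 1L) + 1L)] <- 1
  D
}

#' Embed a signal in generalized coordinates from its analytic derivatives
#'
#' Builds a generalized vector whose order-k entry is the k-th temporal
#' derivative of a scalar signal at one instant.  Derivatives beyond those
#' supplied are not invented: supplying fewer than `order` is an error,
#' so truncation is always the caller's explicit choice (pad with zeros).
#'
#' @param derivs numeric vector of derivatives, order 0 first.
#' @param order embedding order n.
#' @return a [gen_vec()] of length `order`.
#' @examples
#' embed_signal(c(0, 3), 2)        # sin(x) with x = 0 advancing at 3/s
#' embed_signal(c(5, 0, 0, 0), 4)  # a constant signal
#' @export
embed_signal <- function(derivs, order) {
  if (length(derivs) < order)
    stop("need at least 'order' derivatives to embed (pad with zeros to truncate explicitly)",
         call. = FALSE)
  gen_vec(derivs[seq_len(order)])
}

## --- truncated Taylor arithmetic -------------------------------------------
##
## Generalized vectors are Taylor jets: derivative order k corresponds to
## Taylor coefficient g_k / k!.  Products and elementary functions of
## signals are propagated exactly (to the truncation order) through these
## recurrences; the task model uses them to differentiate its sinusoidal
## sensory mappings analytically.

derivs_to_taylor <- function(g) g / factorial(seq_along(g) - 1L)
taylor_to_derivs <- function(c_) c_ * factorial(seq_along(c_) - 1L)

taylor_prod <- function(a, b) {
  n <- length(a)
  out <- numeric(n)
  for (k in seq_len(n))
    out[k] <- sum(a[seq_len(k)] * b[k:1])
  out
}

## sin/cos of a truncated Taylor series u: s' = c u', c' = -s u'.
taylor_sin_cos <- function(u) {
  n <- length(u)
  s <- c_ <- numeric(n)
  s[1] <- sin(u[1]); c_[1] <- cos(u[1])
  if (n > 1L) {
    du <- seq_len(n - 1L) * u[-1L]  # coefficients of u'
    for (k in seq_len(n - 1L)) {
      j <- seq_len(k)
      s[k + 1L] <- sum(du[j] * c_[k - j + 1L]) / k
      c_[k + 1L] <- -sum(du[j] * s[k - j + 1L]) / k
    }
  }
  list(sin = s, cos = c_)
}

#' Generalized embedding of sin(u) given the generalized embedding of u
#'
#' Propagates a generalized vector through the sine nonlinearity exactly
#' (full chain rule to the truncation order), via truncated Taylor
#' recurrences.  Used by the generative process, whose sensory mappings
#' are sines of hidden states.
#'
#' @param u numeric vector: generalized embedding of the argument.
#' @return numeric vector: generalized embedding of `sin(u(t))`.
#' @examples
#' sin_embed(c(pi / 2 - 0.35, 1, 0, 0))[1:2]  # (sin, cos) of the argument
#' @export
sin_embed <- function(u) {
  taylor_to_derivs(taylor_sin_cos(derivs_to_taylor(u))$sin)
}

## d/da of sin_embed(u(a)) given du/da in generalized form: cos(u) * du/da
## as a Taylor product (exact to truncation order).
sin_embed_da <- function(u, du_da) {
  cu <- taylor_sin_cos(derivs_to_taylor(u))$cos
  taylor_to_derivs(taylor_prod(cu, derivs_to_taylor(du_da)))
}
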