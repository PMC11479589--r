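#' Right-hand side of the three-repressor ring
#'
#' Evaluates the vector field of the protein-only repressilator,
#' \deqn{\dot x = \beta/(1+z^n) - \alpha x,\quad
#'       \dot y = \beta/(1+x^n) - \alpha y,\quad
#'       \dot z = \beta/(1+y^n) - \alpha z,}
#' with all concentrations in K-units.
#'
#' @param state Numeric vector `c(x, y, z)` of non-negative concentrations.
#' @param params A [repressilator_params()] (or [opto_params()], whose ring
#'   fields are used).
#' @return Named numeric vector of time derivatives (1/h).
#' @export
#' @examples
#' repressilator_rhs(c(0, 0, 0), repressilator_params())  # (300, 300, 300)
repressilator_rhs <- function(state, params) {
  params <- as_ring(params)
  state <- check_state(state, 3L)
  with(params, c(
    x = beta / (1 + state[[3]]^n) - alpha * state[[1]],
    y = beta / (1 + state[[1]]^n) - alpha * state[[2]],
    z = beta / (1 + state[[2]]^n) - alpha * state[[3]]
  ))
}

#' Right-hand side of the optorepressilator
#'
#' The four-variable model adds a light-inducible LacI copy `x_prime` produced
#' at rate `beta_prime` and diluted at rate `alpha`; `x` and `x_prime` add up
#' to repress `y`. The `x_prime` equation is decoupled from the ring and set
#' only by light.
#'
#' @param state Numeric vector `c(x, y, z, x_prime)`, non-negative.
#' @param params An [opto_params()] object.
#' @param beta_prime Instantaneous light-driven production rate (1/h).
#' @return Named numeric vector of time derivatives (1/h).
#' @export
#' @examples
#' optorepressilator_rhs(c(0, 0, 0, 0), opto_params(), beta_prime = 80)
optorepressilator_rhs <- function(state, params, beta_prime) {
  stopifnot(inherits(params, "opto_params"))
  state <- check_state(state, 4L)
  stopifnot(is.numeric(beta_prime), length(beta_prime) == 1L)
  if (!is.finite(beta_prime) || beta_prime < 0)
    stop("beta_prime must be finite and >= 0")
  with(params, c(
    x = beta / (1 + state[[3]]^n) - alpha * state[[1]],
    y = beta / (1 + (state[[1]] + state[[4]])^n) - alpha * state[[2]],
    z = beta / (1 + state[[2]]^n) - alpha * state[[3]],
    x_prime = beta_prime - alpha * state[[4]]
  ))
}

#' Digital-limit period and amplitude of the relaxation oscillation
#'
#' In the digital approximation (Hill coefficient n to infinity, beta/alpha
#' much larger than 1) the ring performs relaxation oscillations with
#' amplitude beta/alpha (K-units) and full-cycle period
#' \deqn{T_0 = 3\,\log(\beta/\alpha)/\alpha.}
#' At finite n the simulated period approaches this value from below as n
#' grows.
#'
#' @param params A [repressilator_params()] or [opto_params()].
#' @return `digital_period()`: period in hours; `digital_amplitude()`:
#'   amplitude in K-units.
#' @export
#' @examples
#' digital_period(repressilator_params())     # 3 log(400) / 0.75 ~ 23.97 h
#' digital_amplitude(repressilator_params())  # 400 K-units
digital_period <- function(params) {
  params <- as_ring(params)
  if (params$beta / params$alpha <= 1)
    stop("digital period requires beta/alpha > 1 (relaxation regime)")
  3 * log(params$beta / params$alpha) / params$alpha
}

#' @rdname digital_period
#' @export
digital_amplitude <- function(params) {
  params <- as_ring(params)
  if (params$beta / params$alpha < 1)
    stop("digital amplitude requires beta/alpha >= 1")
  params$beta / params$alpha
}

#' Symmetric unstable fixed point of the ring
#'
#' Solves the scalar fixed-point equation beta/(1 + s^n) = alpha s by
#' bisection on `[0, beta/alpha]`. At this point x = y = z = s and the ring
#' vector field vanishes.
#'
#' @param params A [repressilator_params()] or [opto_params()].
#' @param tol Bisection tolerance on s (K-units).
#' @return The fixed-point concentration s (K-units).
#' @export
symmetric_fixed_point <- function(params, tol = 1e-10) {
  params <- as_ring(params)
  g <- function(s) params$beta / (1 + s^params$n) - params$alpha * s
  lo <- 0
  hi <- params$beta / params$alpha
  # g(0) = beta > 0, g(beta/alpha) <= 0: a root is bracketed
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Fixed point of the optorepressilator under steady green light
#'
#' Under constant illumination the light-driven LacI relaxes to
#' x' = beta'/alpha. When beta'/alpha > 1 the extra repressor holds y at
#' zero, the limit cycle is broken, and the system collapses to
#' (x, y, z, x') = (0, 0, beta/alpha, beta'/alpha). The collapse is exact in
#' the digital limit; at finite n the x-equation retains a Hill-leak term
#' beta/(1 + (beta/alpha)^n), which is tiny for the default parameters.
#'
#' @param params An [opto_params()] with `beta_prime_on / alpha > 1`.
#' @return Named numeric vector `c(x, y, z, x_prime)` (K-units).
#' @export
#' @examples
#' green_fixed_point(opto_params())  # (0, 0, 400, 106.67)
green_fixed_point <- function(params) {
  stopifnot(inherits(params, "opto_params"))
  if (!limit_cycle_broken(params))
    stop("green light does not break the limit cycle: beta_prime_on/alpha <= 1")
  c(x = 0, y = 0, z = params$beta / params$alpha,
    x_prime = params$beta_prime_on / params$alpha)
}

#' Does steady green light break the limit cycle?
#'
#' In the digital approximation the oscillation is destroyed, and the system
#' pinned at the green fixed point, exactly when the steady light-driven LacI
#' level beta'/alpha exceeds 1 K-unit (strict inequality).
#'
#' @param params An [opto_params()].
#' @return Logical.
#' @export
limit_cycle_broken <- function(params) {
  stopifnot(inherits(params, "opto_params"))
  params$beta_prime_on / params$alpha > 1
}

# --- internal helpers ---------------------------------------------------

as_ring <- function(params) {
  if (inherits(params, "opto_params"))
    return(repressilator_params(params$alpha, params$beta, params$n))
  if (inherits(params, "repressilator_params")) return(params)
  stop("expected repressilator_params or opto_params")
}

check_state <- function(state, len) {
  if (!is.numeric(state) || length(state) != len)
    stop(sprintf("state must be a numeric vector of length %d", len))
  if (any(!is.finite(state)))
    stop("state contains non-finite values")
  if (any(state < 0))
    stop("state components must be >= 0")
  as.numeric(state)
}
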