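# Closed-form rate and drift functions of the model. Everything downstream
# (ODE limit, equilibria, PDMP event rates, fluctuation analysis) composes
# these. All functions are vectorized over x and e.

# Domain checks are strict up to an absolute slack that absorbs integrator
# round-off: values within `slack` of the boundary are clamped, values beyond
# it rejected. The box [0,1] x [l_A,l_B] is forward-invariant analytically
# but not bit-exactly under numerics.
.behenv_slack <- 1e-12

check_x <- function(x, slack = .behenv_slack) {
  if (any(!is.finite(x)) || any(x < -slack | x > 1 + slack))
    stop("frequency x outside [0, 1]", call. = FALSE)
  pmin(pmax(x, 0), 1)
}

check_e <- function(e, params, slack = .behenv_slack) {
  if (any(!is.finite(e)) || any(e < params$l_A - slack | e > params$l_B + slack))
    stop("perceived environmental state e outside [l_A, l_B]", call. = FALSE)
  pmin(pmax(e, params$l_A), params$l_B)
}

#' Social attractiveness of the two behaviors
#'
#' The rate at which an encounter converts an agent to behavior A (resp. B)
#' scales with the attractiveness `lambda_A(x) = gamma_A + delta_A * x`
#' (resp. `lambda_B(x) = gamma_B + delta_B * (1 - x)`): the payoff of the
#' target behavior plus a conformist term proportional to its current
#' frequency.
#'
#' @param x frequency of the active behavior, in \[0, 1\]. Vectorized.
#' @param params a [model_params] object.
#' @return A list with numeric components `lambda_A` and `lambda_B`.
#' @export
social_attractiveness <- function(x, params) {
  params <- validate_params(params)
  x <- check_x(x)
  list(lambda_A = params$gamma_A + params$delta_A * x,
       lambda_B = params$gamma_B + params$delta_B * (1 - x))
}

#' Assessment-driven switch rates
#'
#' An agent's own assessment of the perceived environment `e` drives switches
#' toward A at rate `tau_A(e) = tau * (e - l_A)` and toward B at rate
#' `tau_B(e) = tau * (l_B - e)`: the further `e` sits from a behavior's own
#' impact, the stronger the pull toward that behavior. Their sum is the
#' constant `tau * (l_B - l_A)` for every admissible `e`.
#'
#' @inheritParams social_attractiveness
#' @param e perceived environmental state, in \[`l_A`, `l_B`\]. Vectorized.
#' @return A list with numeric components `tau_A` and `tau_B`.
#' @export
environmental_switch_rates <- function(e, params) {
  params <- validate_params(params)
  e <- check_e(e, params)
  list(tau_A = params$tau * (e - params$l_A),
       tau_B = params$tau * (params$l_B - e))
}

#' Deterministic drift of the active-behavior frequency
#'
#' The large-population rate of change of the frequency x of the active
#' behavior,
#' `p(x, e) = kappa x (1-x) (lambda_A(x) - lambda_B(x)) +
#'  tau_A(e) (1-x) - tau_B(e) x`,
#' combining imitation dynamics with assessment-driven switching. The
#' expanded form
#' `kappa x (1-x) (beta + delta_A x - delta_B (1-x)) +
#'  tau (e - l_A (1-x) - l_B x)`
#' is algebraically identical.
#'
#' @inheritParams environmental_switch_rates
#' @return Numeric vector of drift values (1/time).
#' @export
drift_behavior <- function(x, e, params) {
  params <- validate_params(params)
  x <- check_x(x)
  e <- check_e(e, params)
  lam <- social_attractiveness(x, params)
  tsw <- environmental_switch_rates(e, params)
  params$kappa * x * (1 - x) * (lam$lambda_A - lam$lambda_B) +
    tsw$tau_A * (1 - x) - tsw$tau_B * x
}

#' Deterministic drift of the perceived environmental state
#'
#' `h(x, e) = ell * e * (l_A x + l_B (1 - x) - e)`: the perceived environment
#' relaxes logistically toward the population mean per-capita impact
#' `l_A x + l_B (1 - x)`, at a pace set by the reactivity `ell`.
#'
#' @inheritParams environmental_switch_rates
#' @return Numeric vector of drift values (1/time).
#' @export
drift_environment <- function(x, e, params) {
  params <- validate_params(params)
  x <- check_x(x)
  e <- check_e(e, params)
  params$ell * e * (params$l_A * x + params$l_B * (1 - x) - e)
}

#' Total per-capita rate of behavior switching
#'
#' `Omega(x, e) = kappa x (1-x) (lambda_A(x) + lambda_B(x)) +
#'  tau_A(e) (1-x) + tau_B(e) x` aggregates every switching channel. It is
#' the model's measure of behavioral inconsistency and, at a stable
#' equilibrium, the diffusion strength of the population-scaled fluctuations
#' (see [diffusion_coefficient]). A behavior is adopted consistently when its
#' equilibrium frequency is close to one and `Omega` at that equilibrium is
#' close to zero.
#'
#' @inheritParams environmental_switch_rates
#' @return Numeric vector of non-negative rates.
#' @export
total_switching_rate <- function(x, e, params) {
  params <- validate_params(params)
  x <- check_x(x)
  e <- check_e(e, params)
  lam <- social_attractiveness(x, params)
  tsw <- environmental_switch_rates(e, params)
  params$kappa * x * (1 - x) * (lam$lambda_A + lam$lambda_B) +
    tsw$tau_A * (1 - x) + tsw$tau_B * x
}

#' Imitation-only drift (no environmental feedback)
#'
#' With `tau = 0` the frequency equation decouples from the environment and
#' reduces to the replicator form
#' `p0(x) = kappa x (1-x) (beta + delta_A x - delta_B (1-x))`.
#'
#' @inheritParams social_attractiveness
#' @return Numeric vector of drift values (1/time).
#' @export
no_feedback_drift <- function(x, params) {
  params <- validate_params(params)
  x <- check_x(x)
  beta <- params$gamma_A - params$gamma_B
  params$kappa * x * (1 - x) *
    (beta + params$delta_A * x - params$delta_B * (1 - x))
}
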