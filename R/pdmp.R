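# Finite-population stochastic simulation. Behavior counts jump by +/-1
# at exponentially distributed candidate times drawn at a uniform dominating
# rate (thinning/uniformization); the perceived environment flows
# deterministically between candidates.

#' Uniform dominating rate for the thinning simulation
#'
#' A bound `xi_N` that strictly dominates the total event rate `N Omega(x,e)`
#' over the whole state space. Since `lambda_A + lambda_B` is affine in `x`
#' its supremum sits at an endpoint, and `tau_A + tau_B` is the constant
#' `tau (l_B - l_A)`, giving
#' `xi_N = N (kappa (gamma_A + gamma_B + max(delta_A, delta_B)) +
#'  tau (l_B - l_A))` inflated by a relative 1e-12 to make the domination
#' strict.
#'
#' @param params a [model_params] object.
#' @param N population size.
#' @return The dominating rate (events/time).
#' @export
rate_bound <- function(params, N) {
  params <- validate_params(params)
  stopifnot(N >= 1)
  N * (params$kappa * (params$gamma_A + params$gamma_B +
                         max(params$delta_A, params$delta_B)) +
         params$tau * (params$l_B - params$l_A)) * (1 + 1e-12)
}

#' Microscopic event rates of the four switching channels
#'
#' At a state with `N x` active agents the four elementary channels fire at
#' rates
#' `social B->A = N kappa x (1-x) (gamma_A + delta_A x)`,
#' `social A->B = N kappa x (1-x) (gamma_B + delta_B (1-x))`,
#' `env B->A = N (1-x) tau (e - l_A)`,
#' `env A->B = N x tau (l_B - e)`.
#' Their sum equals `N * Omega(x, e)` exactly.
#'
#' @param x frequency of the active behavior (a multiple of `1/N`).
#' @param e perceived environmental state.
#' @param params a [model_params] object.
#' @param N population size.
#' @return Named numeric vector of the four rates.
#' @export
event_rates <- function(x, e, params, N) {
  params <- validate_params(params)
  x <- check_x(x)
  e <- check_e(e, params)
  c(social_B_to_A = N * params$kappa * x * (1 - x) *
      (params$gamma_A + params$delta_A * x),
    social_A_to_B = N * params$kappa * x * (1 - x) *
      (params$gamma_B + params$delta_B * (1 - x)),
    env_B_to_A = N * (1 - x) * params$tau * (e - params$l_A),
    env_A_to_B = N * x * params$tau * (params$l_B - e))
}

#' Advance the perceived environment over a jump-free interval
#'
#' Between behavior jumps `x` is constant, so the environment obeys the
#' autonomous logistic flow `de/dt = ell e (c - e)` with
#' `c = l_A x + l_B (1 - x)`, whose exact solution is
#' `e(dt) = c e / (e + (c - e) exp(-ell c dt))`. The `"euler"` method takes
#' explicit steps capped at `euler_dt` instead, and is retained for fidelity
#' checks against integrator-free references.
#'
#' @param e current perceived environmental state.
#' @param x current frequency (held fixed over the interval).
#' @param params a [model_params] object.
#' @param dt interval length (>= 0).
#' @param method `"closed_form"` (default) or `"euler"`.
#' @param euler_dt Euler step cap.
#' @return The environment after `dt`, inside `[l_A, l_B]`.
#' @export
environment_update <- function(e, x, params, dt,
                               method = c("closed_form", "euler"),
                               euler_dt = 1e-3) {
  params <- validate_params(params)
  method <- match.arg(method)
  x <- check_x(x)
  e <- check_e(e, params)
  stopifnot(dt >= 0)
  cc <- params$l_A * x + params$l_B * (1 - x)
  out <- env_flow_cpp(e, cc, params$ell, dt, method == "closed_form",
                      euler_dt)
  min(max(out, params$l_A), params$l_B)
}

#' Simulate the finite-population process exactly by thinning
#'
#' Candidate event times are drawn from an exponential distribution at the
#' dominating rate [rate_bound]; at each candidate one of the four channels
#' of [event_rates] fires with probability `rate / xi_N` (otherwise the
#' candidate is a phantom and nothing changes). The active count moves by
#' exactly one agent per non-phantom event; the perceived environment flows
#' deterministically (and continuously across jumps) in between. The scheme
#' is exact: no time discretization error enters the law of the process.
#'
#' @param params a [model_params] object.
#' @param N population size (>= 1).
#' @param x0 initial frequency; `N * x0` must be (numerically) an integer.
#' @param e0 initial perceived environmental state.
#' @param t_end horizon (time units).
#' @param seed integer RNG seed; runs are bit-reproducible given
#'   `(seed, params, config)`.
#' @param env_update `"closed_form"` (exact logistic flow, default) or
#'   `"euler"`.
#' @param euler_dt Euler step cap when `env_update = "euler"`.
#' @param record `"grid"` stores the state sampled every `grid_dt` only;
#'   `"events"` additionally logs every non-phantom event (and phantoms too
#'   when `log_phantom = TRUE`). Event logging is refused beyond ~1e7
#'   expected candidates; use the grid for long runs.
#' @param grid_dt sampling interval of the regular grid.
#' @param log_phantom also log phantom candidates (events mode only).
#' @return A list of class `behenv_pdmp` with elements `grid` (data frame
#'   `t, x, e`), `events` (data frame `t, type, x, e` or `NULL`), `counts`
#'   (named totals of the five candidate outcomes), `x_final`, `e_final`,
#'   and `config` (all inputs, including the seed and the dominating rate).
#' @examples
#' p <- params_from_differentials(beta = -0.25, nu = 0.3, tau = 0.1,
#'                                ell = 0.1, l_A = 0.7)
#' run <- simulate_pdmp(p, N = 200, x0 = 0.05, e0 = 1, t_end = 50, seed = 1)
#' run$counts
#' @export
simulate_pdmp <- function(params, N, x0, e0, t_end, seed,
                          env_update = c("closed_form", "euler"),
                          euler_dt = 1e-3,
                          record = c("grid", "events"),
                          grid_dt = 0.1, log_phantom = FALSE) {
  params <- validate_params(params)
  env_update <- match.arg(env_update)
  record <- match.arg(record)
  stopifnot(N >= 1, t_end > 0, grid_dt > 0)
  x0 <- check_x(x0)
  e0 <- check_e(e0, params)
  nA0 <- round(N * x0)
  if (abs(N * x0 - nA0) > 1e-8)
    stop("N * x0 = ", N * x0, " is not an integer count", call. = FALSE)
  if (missing(seed) || !is.finite(seed))
    stop("an explicit integer 'seed' is required for reproducibility",
         call. = FALSE)
  xi <- rate_bound(params, N)
  log_events <- record == "events"
  if (log_events && xi * t_end > 1e7) {
    warning("expected candidate count ", format(xi * t_end, digits = 3),
            " exceeds 1e7; falling back to grid recording")
    log_events <- FALSE
  }
  set.seed(as.integer(seed))
  out <- pdmp_simulate_cpp(params$kappa, params$gamma_A, params$gamma_B,
                           params$delta_A, params$delta_B, params$tau,
                           params$ell, params$l_A, params$l_B,
                           as.integer(N), as.integer(nA0), e0, t_end, xi,
                           env_update == "closed_form", euler_dt,
                           log_events, log_phantom, grid_dt)
  out$config <- list(params = params, N = N, x0 = nA0 / N, e0 = e0,
                     t_end = t_end, seed = as.integer(seed),
                     env_update = env_update, euler_dt = euler_dt,
                     grid_dt = grid_dt, rate_bound = xi)
  class(out) <- "behenv_pdmp"
  out
}

#' @export
print.behenv_pdmp <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("PDMP run: N = %d, t_end = %g, seed = %d\n",
              cfg$N, cfg$t_end, cfg$seed))
  cat(sprintf("  final state: x = %.4f, e = %.4f\n", x$x_final, x$e_final))
  cat("  candidate outcomes:\n")
  print(x$counts)
  invisible(x)
}

#' Ensemble mean and variance of replicate runs
#'
#' Aligns replicate PDMP runs (identical parameters and configuration except
#' the seed) on their common sampling grid and returns the per-time unbiased
#' sample mean and variance of `x` and `e`.
#'
#' @param runs a list of `behenv_pdmp` objects.
#' @param times optional subset of grid times (defaults to the full grid).
#' @return A data frame `t, mean_x, var_x, mean_e, var_e` with the run count
#'   in `attr(, "n_runs")`.
#' @export
ensemble_statistics <- function(runs, times = NULL) {
  stopifnot(length(runs) >= 2)
  ref <- runs[[1]]$config
  for (r in runs[-1]) {
    cfg <- r$config
    same <- identical(unclass(cfg$params), unclass(ref$params)) &&
      cfg$N == ref$N && cfg$x0 == ref$x0 && cfg$e0 == ref$e0 &&
      cfg$t_end == ref$t_end && cfg$grid_dt == ref$grid_dt
    if (!same)
      stop("runs have mismatched parameters or configuration", call. = FALSE)
  }
  grid_t <- runs[[1]]$grid$t
  keep <- if (is.null(times)) seq_along(grid_t)
          else match(times, grid_t)
  if (anyNA(keep)) stop("requested times not on the sampling grid",
                        call. = FALSE)
  X <- vapply(runs, function(r) r$grid$x[keep], numeric(length(keep)))
  E <- vapply(runs, function(r) r$grid$e[keep], numeric(length(keep)))
  out <- data.frame(t = grid_t[keep],
                    mean_x = rowMeans(X), var_x = apply(X, 1, stats::var),
                    mean_e = rowMeans(E), var_e = apply(E, 1, stats::var))
  attr(out, "n_runs") <- length(runs)
  out
}

#' Export a PDMP run to CSV with a JSON sidecar
#'
#' Writes the sampled path (`t, x, e`) and, when present, the event log
#' (`t, type, x, e`) as CSV, plus a JSON sidecar containing the parameters
#' and configuration (including the seed).
#'
#' @param run a `behenv_pdmp` object.
#' @param path base path; files `<path>_grid.csv`, `<path>_events.csv`
#'   (if any) and `<path>.json` are produced.
#' @return `path`, invisibly.
#' @export
write_pdmp_run <- function(run, path) {
  utils::write.csv(run$grid, paste0(path, "_grid.csv"), row.names = FALSE)
  if (!is.null(run$events)) {
    ev <- run$events
    ev$type <- c("phantom", "social_B_to_A", "social_A_to_B",
                 "env_B_to_A", "env_A_to_B")[ev$type + 1L]
    utils::write.csv(ev, paste0(path, "_events.csv"), row.names = FALSE)
  }
  cfg <- run$config
  cfg$params <- lapply(unclass(cfg$params), as.numeric)
  jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}
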