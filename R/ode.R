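#' Integrate the deterministic large-population limit
#'
#' Solves the coupled system `dx/dt = p(x, e)`, `de/dt = h(x, e)`
#' ([drift_behavior], [drift_environment]) with an adaptive Runge-Kutta 4(5)
#' scheme. The box `[0, 1] x [l_A, l_B]` is forward-invariant for the exact
#' flow; states are projected back into it when round-off pushes them within
#' numerical slack of the boundary.
#'
#' @param params a [model_params] object.
#' @param x0 initial frequency of the active behavior, in \[0, 1\].
#' @param e0 initial perceived environmental state, in \[`l_A`, `l_B`\].
#' @param t_end integration horizon (time units).
#' @param dt sampling interval of the returned path (time units).
#' @param rel_tol,abs_tol integrator tolerances.
#' @param method a [deSolve::ode] method; the default `"ode45"` is an
#'   adaptive Runge-Kutta of order 4(5) (the system is smooth and non-stiff
#'   over the admissible parameter ranges).
#'
#' @return A `behenv_trajectory`: a data frame with columns `t`, `x`, `e`,
#'   carrying the parameters in `attr(, "params")` and a logical
#'   `attr(, "at_equilibrium")` which is `TRUE` when the terminal drift
#'   satisfies `max(|p|, |h|) < 1e-8`.
#' @examples
#' p <- params_from_differentials(beta = 0, nu = 0.5, tau = 0, ell = 0.1,
#'                                l_A = 0.7)
#' tr <- integrate_dynamics(p, x0 = 0.6, e0 = 1, t_end = 100)
#' tail(tr, 1)  # converges to x = 1 since x0 exceeds the norm threshold
#' @export
integrate_dynamics <- function(params, x0, e0, t_end, dt = 0.1,
                               rel_tol = 1e-8, abs_tol = 1e-10,
                               method = "ode45") {
  params <- validate_params(params)
  x0 <- check_x(x0)
  e0 <- check_e(e0, params)
  stopifnot(t_end > 0, dt > 0, rel_tol > 0, abs_tol > 0)

  deriv <- function(t, y, parms) {
    x <- min(max(y[1], 0), 1)
    e <- min(max(y[2], parms$l_A), parms$l_B)
    list(c(drift_behavior(x, e, parms), drift_environment(x, e, parms)))
  }
  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  sol <- deSolve::ode(y = c(x = x0, e = e0), times = times, func = deriv,
                      parms = params, method = method,
                      rtol = rel_tol, atol = abs_tol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed (integrator reported an error state)",
         call. = FALSE)
  traj <- data.frame(t = sol[, "time"],
                     x = pmin(pmax(sol[, "x"], 0), 1),
                     e = pmin(pmax(sol[, "e"], params$l_A), params$l_B))
  n <- nrow(traj)
  resid <- max(abs(drift_behavior(traj$x[n], traj$e[n], params)),
               abs(drift_environment(traj$x[n], traj$e[n], params)))
  structure(traj, params = params, at_equilibrium = resid < 1e-8,
            class = c("behenv_trajectory", "data.frame"))
}

#' First time the active-behavior frequency rises through a threshold
#'
#' Operationalizes the characteristic rise time of the proenvironmental
#' behavior: the first time the trajectory's `x` crosses `high`, linearly
#' interpolated between samples. The trajectory must start at or below `low`
#' (a run already past the rise would make the quantity meaningless).
#'
#' @param traj a trajectory with columns `t` and `x` (e.g. from
#'   [integrate_dynamics]).
#' @param low,high thresholds with `0 <= low < high <= 1`.
#' @return The interpolated crossing time, or `NA_real_` if `x` never
#'   reaches `high`.
#' @export
rise_time <- function(traj, low = 0.01, high = 0.95) {
  stopifnot(low >= 0, high <= 1, low < high)
  x <- traj$x
  t <- traj$t
  if (x[1] > low)
    stop("trajectory starts at x = ", signif(x[1], 4), " > low = ", low,
         call. = FALSE)
  above <- which(x >= high)
  if (length(above) == 0) return(NA_real_)
  i <- above[1]
  if (i == 1) return(t[1])
  # linear interpolation between the bracketing samples
  t[i - 1] + (high - x[i - 1]) / (x[i] - x[i - 1]) * (t[i] - t[i - 1])
}

#' Export and import trajectories
#'
#' Writes the `(t, x, e)` path as CSV with 17 significant digits plus a JSON
#' sidecar (`<path>.json`) of the parameters, so that a round trip is
#' bit-exact at the stored precision.
#'
#' @param traj a `behenv_trajectory`.
#' @param path CSV file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `behenv_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(t = sprintf("%.17g", traj$t),
                   x = sprintf("%.17g", traj$x),
                   e = sprintf("%.17g", traj$e))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  params <- attr(traj, "params")
  if (!is.null(params)) {
    jsonlite::write_json(lapply(unclass(params), as.numeric),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = I(17))
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  params <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    params <- validate_params(jsonlite::read_json(sidecar, simplifyVector = TRUE))
  }
  structure(df, params = params,
            class = c("behenv_trajectory", "data.frame"))
}
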