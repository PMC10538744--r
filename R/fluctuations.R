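# Linear-noise (Ornstein-Uhlenbeck) analysis of the population-scaled
# fluctuations (eta_A, eta_E) = sqrt(N) * ((X_N, E_N) - (x, e)) around a
# stable equilibrium. The drift of the fluctuation process is the Jacobian
# of (p, h); the noise enters the behavior coordinate only, with
# infinitesimal variance equal to the total switching rate Omega.

#' Diffusion coefficient of the fluctuation process
#'
#' The infinitesimal variance of the scaled behavior-frequency fluctuations
#' equals the total switching rate `Omega(x, e)` term by term; the Brownian
#' amplitude in [simulate_ou] is its square root. This identity is what ties
#' behavioral inconsistency (frequent switching) to large stationary
#' fluctuations.
#'
#' @inheritParams total_switching_rate
#' @return `Omega(x, e)` (numeric, vectorized).
#' @export
diffusion_coefficient <- function(x, e, params) {
  total_switching_rate(x, e, params)
}

#' Drift matrix of the fluctuation process at an equilibrium
#'
#' The linear drift of `(eta_A, eta_E)` is the Jacobian of `(p, h)` evaluated
#' at the equilibrium; in particular its `(1, 2)` entry is exactly `tau`.
#'
#' @param x_star,e_star a stable (or at least genuine) equilibrium;
#'   `e_star` defaults to the mean-impact mixture at `x_star`.
#' @param params a [model_params] object.
#' @param residual_tol maximum admissible drift residual at the point.
#' @return A 2x2 numeric matrix.
#' @export
ou_drift_matrix <- function(x_star, params, e_star = NULL,
                            residual_tol = 1e-9) {
  params <- validate_params(params)
  if (is.null(e_star))
    e_star <- params$l_A * x_star + params$l_B * (1 - x_star)
  resid <- max(abs(drift_behavior(x_star, e_star, params)),
               abs(drift_environment(x_star, e_star, params)))
  if (resid > residual_tol)
    stop("(x_star, e_star) is not an equilibrium: residual ",
         signif(resid, 3), call. = FALSE)
  jacobian_matrix(x_star, e_star, params)
}

#' Stationary covariance of the fluctuation process
#'
#' Solves the Lyapunov equation `A S + S A' + D = 0` with drift `A` the
#' Jacobian at the equilibrium and forcing `D = diag(Omega(x*, e*), 0)`
#' (rank one: noise enters the behavior coordinate only; the environment
#' coordinate inherits variance purely through the drift coupling). Requires
#' `A` Hurwitz, i.e. a stable equilibrium.
#'
#' Note that the headline scalar the consistency criterion uses is
#' `Omega(x*, e*)` itself — the diffusion strength — while the stationary
#' *variance* of `eta_A` is the Lyapunov solution's `[1, 1]` entry, which
#' rescales `Omega` by the relaxation rates. Both are reported.
#'
#' @inheritParams ou_drift_matrix
#' @return A list of class `behenv_ou` with `drift_matrix`,
#'   `diffusion_value` (`Omega(x*, e*)`), `stationary_cov` (2x2, `NULL` when
#'   invalid), and `valid` (`TRUE` iff the drift is Hurwitz).
#' @export
stationary_covariance <- function(x_star, params, e_star = NULL,
                                  residual_tol = 1e-9) {
  params <- validate_params(params)
  if (is.null(e_star))
    e_star <- params$l_A * x_star + params$l_B * (1 - x_star)
  A <- ou_drift_matrix(x_star, params, e_star, residual_tol)
  omega <- diffusion_coefficient(x_star, e_star, params)
  hurwitz <- max(Re(eigen(A, only.values = TRUE)$values)) < 0
  if (!hurwitz) {
    return(structure(list(drift_matrix = A, diffusion_value = omega,
                          stationary_cov = NULL, valid = FALSE,
                          x_star = x_star, e_star = e_star),
                     class = "behenv_ou"))
  }
  D <- diag(c(omega, 0))
  K <- kronecker(diag(2), A) + kronecker(A, diag(2))
  S <- matrix(solve(K, -as.vector(D)), 2, 2)
  S <- (S + t(S)) / 2
  dimnames(S) <- list(c("eta_A", "eta_E"), c("eta_A", "eta_E"))
  structure(list(drift_matrix = A, diffusion_value = omega,
                 stationary_cov = S, valid = TRUE,
                 x_star = x_star, e_star = e_star),
            class = "behenv_ou")
}

#' @export
print.behenv_ou <- function(x, ...) {
  cat(sprintf("OU fluctuation summary at (x*, e*) = (%.6g, %.6g)\n",
              x$x_star, x$e_star))
  cat(sprintf("  diffusion value Omega(x*, e*) = %.6g\n", x$diffusion_value))
  if (x$valid) {
    cat("  stationary covariance:\n")
    print(x$stationary_cov, digits = 6)
  } else {
    cat("  drift not Hurwitz: no stationary covariance\n")
  }
  invisible(x)
}

#' Simulate the linearized fluctuation process
#'
#' Euler-Maruyama path of the linear SDE
#' `d eta = A eta dt + (sqrt(Omega) dW, 0)` frozen at an equilibrium. The
#' noise drives the behavior coordinate only; the environment coordinate
#' evolves differentiably, forced through the drift coupling.
#'
#' @inheritParams ou_drift_matrix
#' @param t_end horizon.
#' @param dt Euler step.
#' @param seed integer RNG seed.
#' @param eta0 initial perturbation, length-2 numeric.
#' @return A data frame `t, eta_A, eta_E`.
#' @export
simulate_ou <- function(x_star, params, t_end, dt = 1e-3, seed,
                        eta0 = c(0, 0), e_star = NULL) {
  params <- validate_params(params)
  if (missing(seed) || !is.finite(seed))
    stop("an explicit integer 'seed' is required", call. = FALSE)
  stopifnot(dt > 0, t_end > 0, length(eta0) == 2)
  if (is.null(e_star))
    e_star <- params$l_A * x_star + params$l_B * (1 - x_star)
  A <- ou_drift_matrix(x_star, params, e_star)
  omega <- diffusion_coefficient(x_star, e_star, params)
  n_steps <- ceiling(t_end / dt)
  set.seed(as.integer(seed))
  path <- ou_simulate_cpp(A, sqrt(omega), eta0[1], eta0[2], dt, n_steps)
  data.frame(t = seq(0, by = dt, length.out = n_steps + 1),
             eta_A = path[, 1], eta_E = path[, 2])
}

#' Population-scaled stationary variance from PDMP ensembles
#'
#' Estimates `N * Var(X_N)` and `N * Var(E_N)` over a stationary window of
#' replicate runs initialized near an equilibrium, for comparison against
#' the central-limit prediction [stationary_covariance]. Each run
#' contributes one batch; standard errors are batch-means errors across
#' runs. Runs whose mean drifts across the window by more than twice the
#' standard error of the window mean are flagged as not equilibrated.
#'
#' @param runs list of `behenv_pdmp` objects started near the equilibrium.
#' @param window numeric length-2 time interval (after burn-in).
#' @return A list with `scaled_var_x`, `se_x`, `scaled_var_e`, `se_e`,
#'   `n_runs`, and `equilibrated` (logical).
#' @export
empirical_fluctuation_variance <- function(runs, window) {
  stopifnot(length(runs) >= 2, length(window) == 2, window[1] < window[2])
  N <- runs[[1]]$config$N
  per_run <- lapply(runs, function(r) {
    g <- r$grid
    g <- g[g$t >= window[1] & g$t <= window[2], ]
    if (nrow(g) < 10)
      stop("window contains fewer than 10 samples", call. = FALSE)
    half <- nrow(g) %/% 2
    drift <- mean(g$x[-seq_len(half)]) - mean(g$x[seq_len(half)])
    c(vx = stats::var(g$x), ve = stats::var(g$e), drift = drift)
  })
  m <- do.call(rbind, per_run)
  # systematic (ensemble-average) drift between window halves; random
  # excursions of individual runs cancel across replicates
  se_drift <- stats::sd(m[, "drift"]) / sqrt(nrow(m))
  equilibrated <- abs(mean(m[, "drift"])) <= 2 * max(se_drift, 1e-12)
  list(scaled_var_x = N * mean(m[, "vx"]),
       se_x = N * stats::sd(m[, "vx"]) / sqrt(nrow(m)),
       scaled_var_e = N * mean(m[, "ve"]),
       se_e = N * stats::sd(m[, "ve"]) / sqrt(nrow(m)),
       n_runs = length(runs), equilibrated = equilibrated)
}
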