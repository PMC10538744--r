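# Equilibria of the coupled system. At any equilibrium the environment must
# sit at the mean-impact mixture e* = l_A x* + l_B (1 - x*), so the fixed
# points are the roots in [0,1] of the reduced cubic
#   p(x, l_A x + l_B (1 - x)) = p0(x) + tau (l_B - l_A) (1 - 2x).

#' Coefficients of the reduced equilibrium polynomial
#'
#' Substituting the equilibrium environment `e = l_A x + l_B (1 - x)` into
#' the behavior drift collapses the fixed-point problem to a single cubic in
#' `x`. Coefficients are returned in increasing powers, so that
#' `sum(coef * x^(0:3))` equals [drift_behavior] evaluated on the mixture
#' line.
#'
#' @param params a [model_params] object.
#' @return Numeric vector of length 4 (constant term first).
#' @export
reduced_polynomial <- function(params) {
  params <- validate_params(params)
  a <- params$gamma_A - params$gamma_B - params$delta_B   # beta - delta_B
  b <- params$delta_A + params$delta_B
  d <- params$tau * (params$l_B - params$l_A)
  k <- params$kappa
  # kappa x (1-x) (a + b x) + d (1 - 2 x)
  c(d, k * a - 2 * d, k * (b - a), -k * b)
}

# All real roots of a polynomial (increasing coefficients) via the
# companion-matrix eigenvalues; robust to a (near-)vanishing leading
# coefficient, which occurs when kappa or the social terms vanish.
real_poly_roots <- function(coef, im_tol = 1e-8) {
  scale <- max(abs(coef))
  if (scale == 0) return(numeric(0))
  while (length(coef) > 1 && abs(coef[length(coef)]) < 1e-14 * scale)
    coef <- coef[-length(coef)]
  deg <- length(coef) - 1L
  if (deg <= 0) return(numeric(0))
  if (deg == 1) return(-coef[1] / coef[2])
  monic <- coef / coef[length(coef)]
  comp <- matrix(0, deg, deg)
  comp[cbind(2:deg, 1:(deg - 1))] <- 1
  comp[, deg] <- -monic[1:deg]
  ev <- eigen(comp, only.values = TRUE)$values
  Re(ev[abs(Im(ev)) < im_tol * max(1, abs(ev))])
}

#' Find all equilibria of the coupled system
#'
#' Computes the real roots of the reduced cubic that lie in \[0, 1\]
#' (roots within 1e-10 of the boundary are clipped onto it; roots closer
#' than 1e-8 are merged), pairs each with its equilibrium environment
#' `e* = l_A x* + l_B (1 - x*)`, and classifies local stability from the
#' Jacobian. For `tau > 0` the boundary drifts `p(0, l_B) > 0` and
#' `p(1, l_A) < 0` push every equilibrium strictly inside (0, 1).
#'
#' @param params a [model_params] object.
#' @param x_min,omega_max thresholds passed to [consistency_check] for the
#'   `consistent` flag of stable equilibria.
#' @return A data frame of class `behenv_equilibria` with one row per
#'   equilibrium and columns `x_star`, `e_star`, `eig1_re`, `eig1_im`,
#'   `eig2_re`, `eig2_im`, `stability`, `omega_star`, `consistent`, ordered
#'   by `x_star`.
#' @examples
#' p <- params_from_differentials(beta = -0.25, nu = 0.3, tau = 0.1,
#'                                ell = 0.1, l_A = 0.7)
#' find_equilibria(p)  # bistable: two stable fixed points flank an unstable one
#' @export
find_equilibria <- function(params, x_min = 0.9, omega_max = 0.05) {
  params <- validate_params(params)
  cf <- reduced_polynomial(params)
  if (params$tau == 0) {
    # p0 factorizes exactly: kappa x (1 - x) (a + b x)
    if (params$kappa == 0)
      stop("kappa = 0 and tau = 0: the drift vanishes identically and ",
           "every frequency is an equilibrium", call. = FALSE)
    b <- params$delta_A + params$delta_B
    interior <- if (b > 0)
      (params$delta_B - (params$gamma_A - params$gamma_B)) / b
    else numeric(0)
    roots <- c(0, 1, interior[interior > 0 & interior < 1])
  } else {
    roots <- real_poly_roots(cf)
    # one Newton polish per root (companion eigenvalues carry O(1e-9) error)
    dcf <- cf[-1] * (1:3)
    for (k in 1:2) {
      fv <- cf[1] + roots * (cf[2] + roots * (cf[3] + roots * cf[4]))
      dv <- dcf[1] + roots * (dcf[2] + roots * dcf[3])
      dv <- ifelse(abs(dv) < 1e-14, 1, dv)
      roots <- roots - fv / dv
    }
  }
  roots <- roots[roots >= -1e-10 & roots <= 1 + 1e-10]
  roots <- pmin(pmax(roots, 0), 1)
  roots <- sort(roots)
  if (length(roots) > 1)
    roots <- roots[c(TRUE, diff(roots) > 1e-8)]
  if (length(roots) == 0)
    stop("no equilibrium found in [0, 1]; the reduced cubic should always ",
         "have one (degenerate parameter set?)", call. = FALSE)
  rows <- lapply(roots, function(x) {
    e <- params$l_A * x + params$l_B * (1 - x)
    cls <- classify_stability(x, e, params)
    om <- total_switching_rate(x, e, params)
    data.frame(x_star = x, e_star = e,
               eig1_re = Re(cls$eigenvalues[1]), eig1_im = Im(cls$eigenvalues[1]),
               eig2_re = Re(cls$eigenvalues[2]), eig2_im = Im(cls$eigenvalues[2]),
               stability = cls$stability, omega_star = om,
               consistent = cls$stability == "stable" &&
                 consistency_check(x, om, x_min = x_min, omega_max = omega_max))
  })
  structure(do.call(rbind, rows), params = params,
            class = c("behenv_equilibria", "data.frame"))
}

#' Jacobian of the deterministic drift
#'
#' Closed-form partial derivatives of `(p, h)` at a state. The
#' environment-coupling entry is exactly `d p / d e = tau` at every state.
#'
#' @param x,e the state.
#' @param params a [model_params] object.
#' @return A 2x2 numeric matrix, rows ordered `(p, h)`, columns `(x, e)`.
#' @export
jacobian_matrix <- function(x, e, params) {
  params <- validate_params(params)
  x <- check_x(x)
  e <- check_e(e, params)
  a <- params$gamma_A - params$gamma_B - params$delta_B
  b <- params$delta_A + params$delta_B
  d <- params$tau * (params$l_B - params$l_A)
  j11 <- params$kappa * ((1 - 2 * x) * (a + b * x) + b * x * (1 - x)) - d
  j12 <- params$tau
  j21 <- params$ell * e * (params$l_A - params$l_B)
  j22 <- params$ell * (params$l_A * x + params$l_B * (1 - x) - 2 * e)
  matrix(c(j11, j12, j21, j22), 2, 2, byrow = TRUE,
         dimnames = list(c("p", "h"), c("x", "e")))
}

#' Local stability of an equilibrium point
#'
#' Computes the Jacobian eigenvalues at a fixed point and labels it
#' `stable` (max real part below `-eps_stab`), `unstable` (above
#' `+eps_stab`), or `marginal` otherwise. The input must actually be an
#' equilibrium (drift residual below `residual_tol`).
#'
#' @inheritParams jacobian_matrix
#' @param eps_stab margin on eigenvalue real parts.
#' @param residual_tol maximum admissible `max(|p|, |h|)` at the point.
#' @return A list with `stability` (character) and `eigenvalues`
#'   (complex vector of length 2, sorted by decreasing real part).
#' @export
classify_stability <- function(x, e, params, eps_stab = 1e-9,
                               residual_tol = 1e-9) {
  params <- validate_params(params)
  resid <- max(abs(drift_behavior(x, e, params)),
               abs(drift_environment(x, e, params)))
  if (resid > residual_tol)
    stop("(x, e) is not an equilibrium: drift residual ", signif(resid, 3),
         " exceeds ", residual_tol, call. = FALSE)
  ev <- eigen(jacobian_matrix(x, e, params), only.values = TRUE)$values
  ev <- as.complex(ev)
  ev <- ev[order(-Re(ev))]
  mx <- max(Re(ev))
  stability <- if (mx < -eps_stab) "stable"
    else if (mx > eps_stab) "unstable"
    else "marginal"
  list(stability = stability, eigenvalues = ev)
}

#' Consistent-adoption criterion
#'
#' A stable equilibrium counts as consistent adoption of the active behavior
#' when its frequency is high (`x_star >= x_min`) and the total switching
#' rate there is low (`omega_star <= omega_max`). The defaults operationalize
#' "close to one" and "close to zero" as 0.9 and 0.05; both are recorded in
#' sweep outputs.
#'
#' @param x_star equilibrium frequency of the active behavior.
#' @param omega_star total switching rate at the equilibrium.
#' @param x_min,omega_max thresholds.
#' @return Logical.
#' @export
consistency_check <- function(x_star, omega_star, x_min = 0.9,
                              omega_max = 0.05) {
  x_star >= x_min && omega_star <= omega_max
}

#' Detect and measure a limit cycle
#'
#' If the system's unique equilibrium is unstable, the forward-invariant box
#' `[0,1] x [l_A, l_B]` traps the flow and the Poincare-Bendixson theorem
#' guarantees an attracting periodic orbit; this function measures it from a
#' post-transient trajectory (period from successive maxima of `x`,
#' amplitude from the final cycles). When stable equilibria exist, a fan of
#' boundary-adjacent initial conditions is integrated instead, and a cycle
#' is reported only if some trajectory fails to converge to any equilibrium
#' while its peaks stabilize.
#'
#' @param params a [model_params] object.
#' @param t_window length of the post-transient measurement window; by
#'   default 30 rotation periods estimated from the imaginary part of the
#'   unstable eigenvalues (or 500 time units if they are real).
#' @param dt sampling interval of the measurement trajectory.
#' @return A list with `status` (`"cycle"`, `"none"` or `"inconclusive"`)
#'   and, for a cycle, `period`, `x_range`, `e_range`.
#' @export
detect_limit_cycle <- function(params, t_window = NULL, dt = 0.1) {
  params <- validate_params(params)
  eq <- find_equilibria(params)
  if (params$tau == 0)  # x-dynamics are one-dimensional: no cycle possible
    return(list(status = "none"))
  unstable_only <- nrow(eq) == 1 && eq$stability[1] == "unstable"
  if (!unstable_only) {
    if (any(eq$stability == "stable")) {
      conv <- limit_cycle_fan_converges(params, eq)
      return(if (conv) list(status = "none") else list(status = "inconclusive"))
    }
    return(list(status = "inconclusive"))
  }
  lam_im <- abs(eq$eig1_im[1])
  period_guess <- if (lam_im > 1e-8) 2 * pi / lam_im else 50
  if (is.null(t_window)) t_window <- max(15 * period_guess, 200)
  transient <- min(10 / max(min(abs(eq$eig1_re[1]), params$ell), 1e-3), 1000)
  x0 <- min(max(eq$x_star[1] + 0.02, 0.01), 0.99)
  tr <- integrate_dynamics(params, x0 = x0, e0 = eq$e_star[1],
                           t_end = transient + t_window, dt = dt)
  post <- tr[tr$t >= transient, ]
  measure_cycle(post)
}

# peak-based period/amplitude measurement on a post-transient path
measure_cycle <- function(post) {
  x <- post$x
  n <- length(x)
  if (n < 10) return(list(status = "inconclusive"))
  pk <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(pk) < 4) return(list(status = "inconclusive"))
  last <- utils::tail(pk, 5)
  heights <- x[last]
  if (diff(range(heights)) > 1e-3 * max(diff(range(x)), 1e-12))
    return(list(status = "inconclusive"))
  # sub-sample period refinement: quadratic interpolation of each peak
  peak_t <- vapply(last, function(i) {
    if (i <= 1 || i >= n) return(post$t[i])
    y0 <- x[i - 1]; y1 <- x[i]; y2 <- x[i + 1]
    den <- y0 - 2 * y1 + y2
    off <- if (abs(den) > 1e-15) 0.5 * (y0 - y2) / den else 0
    post$t[i] + off * (post$t[i + 1] - post$t[i])
  }, numeric(1))
  period <- mean(diff(peak_t))
  span <- post[post$t >= post$t[last[1]], ]
  list(status = "cycle", period = period,
       x_range = range(span$x), e_range = range(span$e))
}

# fan of boundary-adjacent starts: TRUE if all converge to some equilibrium
limit_cycle_fan_converges <- function(params, eq, t_end = 2000, tol = 1e-4) {
  eps <- 1e-3 * (params$l_B - params$l_A)
  starts <- list(c(0.005, params$l_B - eps), c(0.995, params$l_A + eps),
                 c(0.5, params$l_A + eps), c(0.5, params$l_B - eps))
  for (s in starts) {
    tr <- integrate_dynamics(params, s[1], s[2], t_end = t_end, dt = 0.5)
    fin <- utils::tail(tr, 1)
    dist <- min(sqrt((fin$x - eq$x_star)^2 + (fin$e - eq$e_star)^2))
    if (dist > tol) return(FALSE)
  }
  TRUE
}

#' Classify the dynamical regime
#'
#' Labels a parameter set `monostable` (one stable equilibrium),
#' `bistable` (two stable equilibria separated by an unstable threshold) or
#' `limit_cycle` (a unique unstable equilibrium, hence an attracting periodic
#' orbit by Poincare-Bendixson in the forward-invariant box). Marginal
#' equilibria are re-classified by perturbation-and-integration before
#' labelling; tangency/degenerate configurations are reported as monostable
#' with a warning.
#'
#' @param params a [model_params] object.
#' @param cycle_stats if `TRUE` and the regime is `limit_cycle`, measure the
#'   orbit with [detect_limit_cycle] (costs an integration).
#' @param ... passed to [find_equilibria].
#' @return A list of class `behenv_regime` with `equilibria` (the
#'   [find_equilibria] table, possibly with refined stability), `regime`, and
#'   `cycle` (`NULL` unless measured).
#' @export
classify_regime <- function(params, cycle_stats = FALSE, ...) {
  params <- validate_params(params)
  eq <- find_equilibria(params, ...)
  if (any(eq$stability == "marginal")) {
    for (i in which(eq$stability == "marginal"))
      eq$stability[i] <- refine_marginal(params, eq$x_star[i], eq$e_star[i])
  }
  n_stable <- sum(eq$stability == "stable")
  regime <- if (n_stable >= 2) "bistable"
    else if (n_stable == 1) "monostable"
    else if (nrow(eq) == 1 && eq$stability[1] == "unstable") "limit_cycle"
    else "monostable"
  if (n_stable == 0 && regime == "monostable")
    warning("degenerate configuration (no strictly stable equilibrium); ",
            "reported as monostable")
  if (n_stable > 2)
    warning("more than two stable equilibria; labelled bistable")
  cycle <- NULL
  if (regime == "limit_cycle" && cycle_stats) {
    det <- detect_limit_cycle(params)
    if (det$status == "cycle") cycle <- det[c("period", "x_range", "e_range")]
  }
  structure(list(equilibria = eq, regime = regime, cycle = cycle),
            class = "behenv_regime")
}

# simulation-based fallback for marginal eigenvalues: perturb and integrate
refine_marginal <- function(params, x_star, e_star, t_end = 500) {
  eps <- 1e-3
  x0 <- min(max(x_star + eps, 0), 1)
  e0 <- min(max(e_star + eps * (params$l_B - params$l_A), params$l_A),
            params$l_B)
  tr <- integrate_dynamics(params, x0, e0, t_end = t_end, dt = 0.5)
  fin <- utils::tail(tr, 1)
  back <- sqrt((fin$x - x_star)^2 + (fin$e - e_star)^2)
  if (back < 1e-3) "stable" else "marginal"
}

#' @export
print.behenv_regime <- function(x, ...) {
  cat("Regime:", x$regime, "\n")
  print.data.frame(x$equilibria, digits = 6)
  if (!is.null(x$cycle))
    cat(sprintf("Cycle: period %.4g, x in [%.4g, %.4g], e in [%.4g, %.4g]\n",
                x$cycle$period, x$cycle$x_range[1], x$cycle$x_range[2],
                x$cycle$e_range[1], x$cycle$e_range[2]))
  invisible(x)
}

#' Serialize a regime report to JSON
#'
#' @param report a `behenv_regime` object from [classify_regime].
#' @param path optional file; when omitted the JSON string is returned.
#' @return A JSON string (invisibly when written to file).
#' @export
regime_report_json <- function(report, path = NULL) {
  payload <- list(regime = report$regime,
                  equilibria = report$equilibria,
                  cycle = report$cycle,
                  params = lapply(unclass(attr(report$equilibria, "params")),
                                  as.numeric))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
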