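# Parameter-space sweeps over the payoff differential (beta) and social norm
# threshold (nu), with gamma_B, delta_B, kappa and l_B held at their anchor
# values, plus the incremental behavior-substitution scenario.

#' Default sweep axes
#'
#' Cell centers of a uniform grid: `n` cells over beta in \[-1, 1\] and `n`
#' cells over nu in (0, 1\].
#'
#' @param n number of cells per axis.
#' @return A list with numeric vectors `beta` and `nu`.
#' @export
sweep_axes <- function(n = 101) {
  list(beta = seq(-1 + 1 / n, 1 - 1 / n, length.out = n),
       nu = (seq_len(n) - 0.5) / n)
}

#' Regime map over the (beta, nu) plane
#'
#' Classifies every cell of a payoff-differential x social-norm-threshold
#' grid with [classify_regime], recording the regime, the upper and lower
#' stable equilibrium frequencies, their environments, switching rates and
#' consistency flags. Limit-cycle cells are identified analytically (unique
#' unstable equilibrium in the trapping box); no per-cell integration is
#' performed, so the sweep is deterministic and fast.
#'
#' @param beta,nu numeric axes (strictly increasing; `nu` in (0, 1\]).
#' @param tau,ell,l_A required model parameters of the sweep.
#' @param gamma_B,delta_B,kappa,l_B anchors.
#' @param x_min,omega_max consistency thresholds, recorded in the result.
#' @return A data frame of class `behenv_sweep` with one row per cell:
#'   `beta`, `nu`, `regime`, `n_equilibria`, `x_star_upper`, `x_star_lower`
#'   (stable equilibria; `NA` when absent), `e_star_upper`, `e_star_lower`,
#'   `omega_upper`, `omega_lower`, `consistent_upper`, `consistent_lower`.
#' @examples
#' ax <- sweep_axes(21)
#' sw <- sweep_phase_diagram(ax$beta, ax$nu, tau = 0, ell = 0.1, l_A = 0.7)
#' table(sw$regime)
#' @export
sweep_phase_diagram <- function(beta, nu, tau, ell, l_A,
                                gamma_B = 1, delta_B = 0.5, kappa = 1,
                                l_B = 1, x_min = 0.9, omega_max = 0.05) {
  stopifnot(length(beta) > 0, length(nu) > 0,
            !is.unsorted(beta, strictly = TRUE),
            !is.unsorted(nu, strictly = TRUE),
            all(nu > 0), all(nu <= 1))
  cells <- expand.grid(beta = beta, nu = nu, KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    p <- params_from_differentials(cells$beta[i], cells$nu[i],
                                   gamma_B = gamma_B, delta_B = delta_B,
                                   kappa = kappa, tau = tau, ell = ell,
                                   l_A = l_A, l_B = l_B)
    rep <- withCallingHandlers(
      classify_regime(p, x_min = x_min, omega_max = omega_max),
      warning = function(w) invokeRestart("muffleWarning"))
    eq <- rep$equilibria
    st <- eq[eq$stability == "stable", , drop = FALSE]
    up <- if (nrow(st) > 0) st[which.max(st$x_star), ] else NULL
    lo <- if (nrow(st) > 1) st[which.min(st$x_star), ] else NULL
    res[[i]] <- data.frame(
      beta = cells$beta[i], nu = cells$nu[i], regime = rep$regime,
      n_equilibria = nrow(eq),
      x_star_upper = if (!is.null(up)) up$x_star else NA_real_,
      x_star_lower = if (!is.null(lo)) lo$x_star else NA_real_,
      e_star_upper = if (!is.null(up)) up$e_star else NA_real_,
      e_star_lower = if (!is.null(lo)) lo$e_star else NA_real_,
      omega_upper = if (!is.null(up)) up$omega_star else NA_real_,
      omega_lower = if (!is.null(lo)) lo$omega_star else NA_real_,
      consistent_upper = if (!is.null(up)) up$consistent else NA,
      consistent_lower = if (!is.null(lo)) lo$consistent else NA)
  }
  out <- do.call(rbind, res)
  structure(out,
            anchors = list(gamma_B = gamma_B, delta_B = delta_B,
                           kappa = kappa, l_B = l_B, tau = tau, ell = ell,
                           l_A = l_A),
            thresholds = list(x_min = x_min, omega_max = omega_max),
            class = c("behenv_sweep", "data.frame"))
}

#' Closed-form bistability region without environmental feedback
#'
#' With `tau = 0` the interior equilibrium is
#' `x* = (delta_B - beta) / (delta_A + delta_B) = nu (1 - beta / delta_B)`,
#' and the system is bistable exactly when it lies in (0, 1). Used as the
#' analytic reference for sweep validation.
#'
#' @param beta,nu numeric vectors (recycled).
#' @param delta_B anchor social pressure of the baseline behavior.
#' @return Logical vector: `TRUE` where the imitation-only system is
#'   bistable.
#' @export
bistable_region_tau0 <- function(beta, nu, delta_B = 0.5) {
  x_star <- nu * (1 - beta / delta_B)
  x_star > 0 & x_star < 1
}

#' Export sweep matrices to CSV
#'
#' Writes one CSV matrix per requested quantity (rows = `nu`, columns =
#' `beta`, with axis values in the header row and first column).
#'
#' @param sweep a `behenv_sweep`.
#' @param dir output directory (created if needed).
#' @param quantities column names of `sweep` to export.
#' @return The directory, invisibly.
#' @export
write_sweep <- function(sweep, dir,
                        quantities = c("regime", "x_star_upper",
                                       "x_star_lower", "omega_upper")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  beta <- sort(unique(sweep$beta))
  nu <- sort(unique(sweep$nu))
  for (q in quantities) {
    m <- matrix(sweep[[q]][order(sweep$nu, sweep$beta)],
                nrow = length(nu), byrow = TRUE)
    df <- data.frame(nu = nu, m)
    names(df) <- c("nu_over_beta", as.character(beta))
    utils::write.csv(df, file.path(dir, paste0(q, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Incremental behavior-substitution scenario
#'
#' Once an active behavior is consistently adopted it becomes the new
#' baseline, and a yet more active (lower-impact, possibly costlier)
#' behavior can start spreading against it. Each stage `k` sets the baseline
#' impact `l_B` to the previous stage's active impact, gives the new active
#' behavior impact `l_A = stages$l_A[k]`, payoff differential
#' `stages$beta[k]` and social norm threshold `stages$nu[k]`, and integrates
#' from a rare-active start (stage 1 from `x0`; later stages from `x = 0`,
#' which the assessment channel lifts since `p(0, e) = tau (e - l_A) > 0`).
#' Each stage must settle on a stable equilibrium; the sequence of
#' equilibrium environments `e*` tracks the cumulative perceived-impact
#' reduction.
#'
#' @param stages a data frame with columns `l_A`, `beta`, `nu`, one row per
#'   stage, `l_A` strictly decreasing below the initial baseline.
#' @param tau,ell sensitivities shared across stages.
#' @param gamma_B,delta_B,kappa anchors shared across stages.
#' @param l_B0 impact of the initial baseline behavior.
#' @param x0,e0 initial state of stage 1 (defaults: active behavior rare,
#'   environment maximally degraded).
#' @param t_end per-stage integration horizon.
#' @return A data frame of class `behenv_scenario` with one row per stage:
#'   `stage`, `l_B`, `l_A`, `beta`, `nu`, `x_star`, `e_star`, `omega_star`,
#'   `consistent`.
#' @export
incremental_scenario <- function(stages, tau, ell, gamma_B = 1,
                                 delta_B = 0.5, kappa = 1, l_B0 = 1,
                                 x0 = 0.01, e0 = NULL, t_end = 2000) {
  stopifnot(is.data.frame(stages),
            all(c("l_A", "beta", "nu") %in% names(stages)),
            nrow(stages) >= 1)
  l_B <- l_B0
  if (is.null(e0)) e0 <- l_B0
  x_start <- x0
  out <- vector("list", nrow(stages))
  for (k in seq_len(nrow(stages))) {
    if (stages$l_A[k] >= l_B)
      stop("stage ", k, ": l_A = ", stages$l_A[k],
           " must be below the current baseline impact ", l_B,
           call. = FALSE)
    p <- params_from_differentials(stages$beta[k], stages$nu[k],
                                   gamma_B = gamma_B, delta_B = delta_B,
                                   kappa = kappa, tau = tau, ell = ell,
                                   l_A = stages$l_A[k], l_B = l_B)
    e_start <- min(max(e0, p$l_A), p$l_B)
    tr <- integrate_dynamics(p, x_start, e_start, t_end = t_end, dt = 0.5)
    fin <- utils::tail(tr, 1)
    eq <- find_equilibria(p)
    i <- which.min((eq$x_star - fin$x)^2 + (eq$e_star - fin$e)^2)
    dist <- sqrt((eq$x_star[i] - fin$x)^2 + (eq$e_star[i] - fin$e)^2)
    if (dist > 1e-4 || eq$stability[i] != "stable")
      stop("stage ", k, " did not settle on a stable equilibrium within ",
           "t_end = ", t_end, " (terminal state x = ", signif(fin$x, 4),
           ", e = ", signif(fin$e, 4), ")", call. = FALSE)
    out[[k]] <- data.frame(stage = k, l_B = l_B, l_A = stages$l_A[k],
                           beta = stages$beta[k], nu = stages$nu[k],
                           x_star = eq$x_star[i], e_star = eq$e_star[i],
                           omega_star = eq$omega_star[i],
                           consistent = eq$consistent[i])
    # adopted behavior becomes the baseline; the next active behavior
    # starts unexpressed, with the environment carried over
    l_B <- stages$l_A[k]
    e0 <- eq$e_star[i]
    x_start <- 0
  }
  structure(do.call(rbind, out), class = c("behenv_scenario", "data.frame"))
}
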