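#' Model parameters for the behavior-environment system
#'
#' Constructs and validates the nine structural parameters of the coupled
#' behavior-environment model. Agents switch between a baseline behavior B and
#' an active (proenvironmental) behavior A through social encounters (rate
#' scale `kappa`, payoffs `gamma_A`/`gamma_B`, social pressures
#' `delta_A`/`delta_B`) and through their own assessment of a perceived
#' environmental state (rate scale `tau`). The perceived environment relaxes,
#' with reactivity `ell`, toward the population mean per-capita impact, which
#' interpolates between `l_A` (all agents active) and `l_B` (all baseline).
#'
#' `kappa`, `gamma_B`, `delta_B` and `l_B` carry conventional defaults
#' (1, 1, 0.5 and 1). `tau` and `ell` have no meaningful default and must be
#' supplied explicitly; see [behenv_presets] for the grids used throughout the
#' package's worked examples.
#'
#' @param kappa encounter rate (1/time). Non-negative.
#' @param gamma_A payoff of the active behavior (dimensionless). Non-negative.
#' @param gamma_B payoff of the baseline behavior (dimensionless). Non-negative.
#' @param delta_A social pressure exerted by active agents (dimensionless).
#' @param delta_B social pressure exerted by baseline agents (dimensionless).
#' @param tau individual sensitivity to the environment (1/time). Non-negative.
#' @param ell environmental reactivity (1/time). Non-negative; `ell = 0`
#'   freezes the perceived environment (useful for calibration experiments).
#' @param l_A per-capita environmental impact of the active behavior. Must be
#'   strictly positive and strictly less than `l_B`.
#' @param l_B per-capita environmental impact of the baseline behavior.
#'
#' @return An object of class `behenv_params`: a named list with the nine
#'   fields above.
#'
#' @examples
#' p <- model_params(gamma_A = 0.75, delta_A = 7 / 6, tau = 0.1, ell = 0.1,
#'                   l_A = 0.7)
#' differentials_from_params(p)
#' @export
model_params <- function(kappa = 1, gamma_A, gamma_B = 1,
                         delta_A, delta_B = 0.5,
                         tau, ell, l_A, l_B = 1) {
  if (missing(tau) || missing(ell)) {
    stop("'tau' and 'ell' have no default and must be given explicitly; ",
         "the grids used in the package examples are available as ",
         "behenv_presets$tau = {0.1, 1, 10} and behenv_presets$ell = ",
         "{0.1, 0.25}.", call. = FALSE)
  }
  if (missing(gamma_A) || missing(delta_A) || missing(l_A)) {
    stop("'gamma_A', 'delta_A' and 'l_A' must be given explicitly ",
         "(no defaults); consider params_from_differentials() to set them ",
         "through the payoff differential and social norm threshold.",
         call. = FALSE)
  }
  p <- list(kappa = kappa, gamma_A = gamma_A, gamma_B = gamma_B,
            delta_A = delta_A, delta_B = delta_B, tau = tau, ell = ell,
            l_A = l_A, l_B = l_B)
  validate_params(p)
}

validate_params <- function(p) {
  num1 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  for (nm in param_names()) num1(p[[nm]], nm)
  nonneg <- c("kappa", "gamma_A", "gamma_B", "delta_A", "delta_B",
              "tau", "ell")
  for (nm in nonneg) {
    if (p[[nm]] < 0)
      stop("parameter '", nm, "' must be non-negative", call. = FALSE)
  }
  if (p$l_A <= 0) stop("'l_A' must be strictly positive", call. = FALSE)
  if (p$l_B <= p$l_A)
    stop("'l_B' must be strictly greater than 'l_A'", call. = FALSE)
  structure(p[param_names()], class = "behenv_params")
}

param_names <- function() {
  c("kappa", "gamma_A", "gamma_B", "delta_A", "delta_B",
    "tau", "ell", "l_A", "l_B")
}

#' @export
print.behenv_params <- function(x, ...) {
  d <- differentials_from_params(x)
  cat("Behavior-environment model parameters\n")
  cat(sprintf("  social:      kappa = %g, gamma_A = %g, gamma_B = %g, delta_A = %g, delta_B = %g\n",
              x$kappa, x$gamma_A, x$gamma_B, x$delta_A, x$delta_B))
  cat(sprintf("  environment: tau = %g, ell = %g, l_A = %g, l_B = %g\n",
              x$tau, x$ell, x$l_A, x$l_B))
  cat(sprintf("  derived:     beta = %g, nu (social norm threshold) = %g, tau*(l_B-l_A) = %g\n",
              d$beta, d$nu, x$tau * (x$l_B - x$l_A)))
  invisible(x)
}

#' Derived parameters: payoff differential and social norm threshold
#'
#' The dynamics depend on the payoffs and social pressures only through the
#' payoff differential `beta = gamma_A - gamma_B` and the social norm
#' threshold `nu = delta_B / (delta_A + delta_B)` (the unstable frequency that
#' social conformism must be pushed past when `beta = 0`).
#'
#' @param params a [model_params] object.
#' @return A list with components `beta` and `nu`.
#' @export
differentials_from_params <- function(params) {
  params <- validate_params(params)
  if (params$delta_A + params$delta_B <= 0)
    stop("social norm threshold undefined: delta_A + delta_B must be > 0",
         call. = FALSE)
  list(beta = params$gamma_A - params$gamma_B,
       nu = params$delta_B / (params$delta_A + params$delta_B))
}

#' Build a parameter set from (beta, nu) differentials
#'
#' Inverts the definitions `beta = gamma_A - gamma_B` and
#' `nu = delta_B / (delta_A + delta_B)` given anchor values of `gamma_B` and
#' `delta_B`, so that sweeps can be parameterized directly by the payoff
#' differential and the social norm threshold.
#'
#' @param beta payoff differential; negative `beta` means the active behavior
#'   is costly.
#' @param nu social norm threshold, in (0, 1].
#' @param gamma_B,delta_B,kappa,tau,ell,l_A,l_B anchors passed through to
#'   [model_params].
#' @return A `behenv_params` object with `gamma_A = gamma_B + beta` and
#'   `delta_A = delta_B * (1 - nu) / nu`.
#' @examples
#' p <- params_from_differentials(beta = -0.25, nu = 0.3, tau = 0.1, ell = 0.1,
#'                                l_A = 0.7)
#' p$delta_A  # 7/6
#' @export
params_from_differentials <- function(beta, nu, gamma_B = 1, delta_B = 0.5,
                                      kappa = 1, tau, ell, l_A, l_B = 1) {
  if (!is.finite(nu) || nu <= 0 || nu > 1)
    stop("'nu' must lie in (0, 1]", call. = FALSE)
  if (delta_B <= 0)
    stop("'delta_B' must be > 0 to invert the social norm threshold",
         call. = FALSE)
  gamma_A <- gamma_B + beta
  if (gamma_A < 0)
    stop("resulting gamma_A = gamma_B + beta is negative", call. = FALSE)
  delta_A <- delta_B * (1 - nu) / nu
  model_params(kappa = kappa, gamma_A = gamma_A, gamma_B = gamma_B,
               delta_A = delta_A, delta_B = delta_B, tau = tau, ell = ell,
               l_A = l_A, l_B = l_B)
}

#' Preset values for the parameters without defaults
#'
#' `tau` (individual environmental sensitivity) and `ell` (environmental
#' reactivity) carry no default; these are the grids used across the package's
#' regime maps and examples: `tau` spanning slow, matched and fast individual
#' assessment relative to a unit social encounter rate, and `ell` spanning a
#' slow and a moderately fast perceived environment.
#'
#' @format A list with numeric vectors `tau` (0.1, 1, 10) and `ell`
#'   (0.1, 0.25).
#' @export
behenv_presets <- list(tau = c(slow = 0.1, matched = 1, fast = 10),
                       ell = c(slow = 0.1, moderate = 0.25))

#' Read and write parameter sets as flat YAML mappings
#'
#' Parameter files are flat mappings whose keys are exactly the ASCII
#' parameter names (`kappa`, `gamma_A`, `gamma_B`, `delta_A`, `delta_B`,
#' `tau`, `ell`, `l_A`, `l_B`). Unknown keys are an error; a file missing
#' `tau` or `ell` is an error that names the presets.
#'
#' @param path file path.
#' @param params a [model_params] object.
#' @return `read_params` returns a `behenv_params` object; `write_params`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(names(raw)) || any(names(raw) == ""))
    stop("parameter file must be a flat named mapping", call. = FALSE)
  unknown <- setdiff(names(raw), param_names())
  if (length(unknown) > 0)
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- lapply(raw, as.numeric)
  do.call(model_params, args)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  params <- validate_params(params)
  yaml::write_yaml(lapply(unclass(params), as.numeric), path,
                   precision = 17L)
  invisible(path)
}
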