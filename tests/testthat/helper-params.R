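# Shared parameter sets for the test suite.

# bistable reference point: costly active behavior, strong-ish social
# pressure, weak environmental feedback
bistable_params <- function(tau = 0.1, ell = 0.1) {
  params_from_differentials(beta = -0.25, nu = 0.3, tau = tau, ell = ell,
                            l_A = 0.7)
}

# imitation-only symmetric point (tau = 0, beta = 0, equal pressures)
symmetric_tau0_params <- function() {
  model_params(gamma_A = 1, delta_A = 0.5, tau = 0, ell = 0.1, l_A = 0.7)
}

# assessment-only point (kappa = 0)
assessment_only_params <- function(tau = 1, ell = 0.1) {
  model_params(kappa = 0, gamma_A = 1, delta_A = 0.5, tau = tau, ell = ell,
               l_A = 0.7)
}

# strong-pressure monostable point with small impact differential: the
# active behavior spreads from rarity to a high equilibrium
strong_pressure_params <- function() {
  params_from_differentials(beta = -0.25, nu = 0.1, tau = 1, ell = 0.1,
                            l_A = 0.95)
}

# random valid parameter sets for property-style loops
random_params <- function(n, seed = 42) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      l_A <- runif(1, 0.1, 0.95)
      model_params(kappa = runif(1, 0, 2), gamma_A = runif(1, 0, 2),
                   gamma_B = runif(1, 0, 2), delta_A = runif(1, 0, 2),
                   delta_B = runif(1, 0.05, 2), tau = runif(1, 0, 2),
                   ell = runif(1, 0.01, 1), l_A = l_A,
                   l_B = l_A + runif(1, 0.05, 1))
    })
  })
}

random_states <- function(params, n, seed = 1) {
  withr::with_seed(seed, {
    data.frame(x = runif(n), e = runif(n, params$l_A, params$l_B))
  })
}
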