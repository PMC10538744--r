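test_that("the reduced cubic reproduces the drift on the impact-mixture line", {
  for (p in random_params(10)) {
    cf <- reduced_polynomial(p)
    x <- c(0.37, seq(0, 1, length.out = 11))
    mix <- p$l_A * x + p$l_B * (1 - x)
    poly_val <- cf[1] + cf[2] * x + cf[3] * x^2 + cf[4] * x^3
    expect_equal(poly_val, drift_behavior(x, mix, p), tolerance = 1e-12)
  }
})

test_that("imitation-only equilibria match the closed forms", {
  p <- symmetric_tau0_params()   # beta = 0, delta_A = delta_B = 0.5
  eq <- find_equilibria(p)
  expect_equal(eq$x_star, c(0, 0.5, 1), tolerance = 1e-10)
  expect_equal(eq$stability, c("stable", "unstable", "stable"))
  expect_equal(eq$e_star, p$l_A * eq$x_star + p$l_B * (1 - eq$x_star))
  # switching shuts off entirely at the absorbed equilibria
  expect_equal(eq$omega_star[c(1, 3)], c(0, 0))
  # random tau = 0 sets against {0, 1, (delta_B - beta)/(delta_A + delta_B)}
  for (pp in random_params(8, seed = 7)) {
    pp$tau <- 0
    pp <- behenv:::validate_params(pp)
    eq <- find_equilibria(pp)
    interior <- (pp$delta_B - (pp$gamma_A - pp$gamma_B)) /
      (pp$delta_A + pp$delta_B)
    expected <- sort(unique(c(0, 1, interior[interior > 0 & interior < 1])))
    expect_equal(eq$x_star, expected, tolerance = 1e-10)
  }
})

test_that("a dominant payoff advantage leaves only full adoption stable", {
  # beta > delta_B pushes the interior root out of (0, 1)
  p <- params_from_differentials(beta = 0.8, nu = 0.5, tau = 0, ell = 0.1,
                                 l_A = 0.7)
  eq <- find_equilibria(p)
  expect_equal(eq$x_star, c(0, 1), tolerance = 1e-10)
  expect_equal(eq$stability, c("unstable", "stable"))
})

test_that("assessment-only systems have the single half-half equilibrium", {
  p <- assessment_only_params()
  cf <- reduced_polynomial(p)
  expect_equal(cf, c(0.3, -0.6, 0, 0), tolerance = 1e-14)
  eq <- find_equilibria(p)
  expect_equal(eq$x_star, 0.5, tolerance = 1e-12)
  expect_equal(eq$e_star, 0.85, tolerance = 1e-12)
  expect_equal(eq$stability, "stable")
})

test_that("environmental feedback moves equilibria strictly inside (0, 1)", {
  for (p in random_params(10, seed = 11)) {
    if (p$tau < 0.05) p$tau <- 0.5
    p <- behenv:::validate_params(p)
    eq <- find_equilibria(p)
    expect_true(all(eq$x_star > 0 & eq$x_star < 1))
    expect_true(nrow(eq) %in% c(1, 2, 3))
    # transversal boundary signs force an odd root count away from tangencies
    resid <- max(abs(drift_behavior(eq$x_star, eq$e_star, p)))
    expect_lt(resid, 1e-9)
  }
})

test_that("the bistable reference point has two stable states flanking a threshold", {
  eq <- find_equilibria(bistable_params())
  expect_equal(nrow(eq), 3)
  expect_equal(eq$stability, c("stable", "unstable", "stable"))
  expect_lt(eq$x_star[1], 0.1)
  expect_gt(eq$x_star[3], 0.9)
})

test_that("the Jacobian matches central finite differences", {
  for (p in random_params(5, seed = 3)) {
    st <- random_states(p, 20, seed = 5)
    st$x <- 0.02 + 0.96 * st$x   # keep the FD stencil inside the domain
    st$e <- pmin(pmax(st$e, p$l_A + 1e-5), p$l_B - 1e-5)
    h <- 1e-6
    for (i in seq_len(nrow(st))) {
      x <- st$x[i]; e <- st$e[i]
      J <- jacobian_matrix(x, e, p)
      fd <- matrix(c(
        (drift_behavior(x + h, e, p) - drift_behavior(x - h, e, p)) / (2 * h),
        (drift_behavior(x, e + h, p) - drift_behavior(x, e - h, p)) / (2 * h),
        (drift_environment(x + h, e, p) - drift_environment(x - h, e, p)) / (2 * h),
        (drift_environment(x, e + h, p) - drift_environment(x, e - h, p)) / (2 * h)),
        2, 2, byrow = TRUE)
      expect_equal(unname(J), fd, tolerance = 1e-5)
      expect_identical(J[1, 2], p$tau)   # exact coupling entry
    }
  }
})

test_that("eigenvalues agree with the closed-form quadratic of a 2x2 matrix", {
  p <- bistable_params()
  eq <- find_equilibria(p)
  for (i in seq_len(nrow(eq))) {
    J <- jacobian_matrix(eq$x_star[i], eq$e_star[i], p)
    tr <- J[1, 1] + J[2, 2]
    dt <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
    disc <- as.complex(tr^2 - 4 * dt)
    lam <- sort(Re((tr + c(1, -1) * sqrt(disc)) / 2), decreasing = TRUE)
    got <- c(eq$eig1_re[i], eq$eig2_re[i])
    expect_equal(got, lam, tolerance = 1e-10)
    if (eq$stability[i] == "stable") expect_true(all(got < 0))
  }
})

test_that("classify_stability rejects non-equilibrium points", {
  p <- bistable_params()
  expect_error(classify_stability(0.5, 0.9, p), "not an equilibrium")
})

test_that("cubic equilibria coincide with long-horizon attractors", {
  p <- bistable_params()
  eq <- find_equilibria(p)
  stable <- eq[eq$stability == "stable", ]
  set.seed(20)
  found <- replicate(20, {
    tr <- integrate_dynamics(p, runif(1), runif(1, p$l_A, p$l_B),
                             t_end = 1500, dt = 1)
    unlist(tail(tr, 1)[c("x", "e")])
  })
  d <- apply(found, 2, function(f)
    min(sqrt((f[1] - stable$x_star)^2 + (f[2] - stable$e_star)^2)))
  expect_lt(max(d), 1e-4)
  # and both basins are actually reached
  near_hi <- apply(found, 2, function(f) abs(f[1] - max(stable$x_star)) < 0.05)
  expect_true(any(near_hi) && any(!near_hi))
})

test_that("regimes are labelled per the stable-equilibrium count", {
  expect_equal(classify_regime(symmetric_tau0_params())$regime, "bistable")
  expect_equal(classify_regime(assessment_only_params())$regime, "monostable")
  expect_equal(classify_regime(bistable_params())$regime, "bistable")
  # tau = 0 can never cycle
  expect_equal(detect_limit_cycle(symmetric_tau0_params())$status, "none")
})

test_that("an intermediate-feedback cell carries a measurable limit cycle", {
  p <- params_from_differentials(beta = -0.73, nu = 0.21, tau = 1, ell = 0.1,
                                 l_A = 0.7)
  reg <- classify_regime(p)
  expect_equal(reg$regime, "limit_cycle")
  det <- detect_limit_cycle(p)
  expect_equal(det$status, "cycle")
  expect_gt(diff(det$x_range), 0.1)
  expect_gt(diff(det$e_range), 0.01)
  # period is self-consistent under a finer sampling interval
  det2 <- detect_limit_cycle(p, dt = 0.05)
  expect_equal(det$period, det2$period, tolerance = 0.01)
})

test_that("consistency requires both high frequency and low switching", {
  expect_true(consistency_check(1, 0))
  expect_false(consistency_check(0.99, 0.3, omega_max = 0.05))
  expect_false(consistency_check(0.5, 0, x_min = 0.9))
  # tau = 0 full adoption is consistent for any thresholds
  eq <- find_equilibria(symmetric_tau0_params())
  expect_true(eq$consistent[eq$x_star == 1])
})

test_that("regime reports serialize to JSON with all equilibrium fields", {
  rep <- classify_regime(bistable_params())
  js <- jsonlite::fromJSON(regime_report_json(rep))
  expect_equal(js$regime, "bistable")
  expect_equal(nrow(js$equilibria), 3)
  expect_true(all(c("x_star", "e_star", "stability", "omega_star",
                    "consistent") %in% names(js$equilibria)))
})
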