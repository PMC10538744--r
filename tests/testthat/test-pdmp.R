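test_that("the dominating rate bounds the total event rate everywhere", {
  for (p in random_params(6, seed = 9)) {
    N <- 100
    xi <- rate_bound(p, N)
    st <- expand.grid(x = seq(0, 1, length.out = 100),
                      e = seq(p$l_A, p$l_B, length.out = 100))
    expect_true(all(N * total_switching_rate(st$x, st$e, p) < xi))
  }
  # endpoint evaluation of the affine supremum
  p <- model_params(gamma_A = 1, delta_A = 0.5, tau = 0, ell = 0.1,
                    l_A = 0.7)
  expect_equal(rate_bound(p, 100), 100 * 2.5 * (1 + 1e-12))
  expect_equal(rate_bound(p, 1000), 10 * rate_bound(p, 100))
})

test_that("channel rates factor correctly and sum to N * Omega", {
  p <- bistable_params()
  at0 <- event_rates(0, 0.9, p, 50)
  expect_equal(unname(at0[c("social_B_to_A", "social_A_to_B",
                            "env_A_to_B")]), c(0, 0, 0))
  expect_gt(at0[["env_B_to_A"]], 0)
  for (pp in random_params(5, seed = 13)) {
    st <- random_states(pp, 100, seed = 2)
    for (i in seq_len(nrow(st))) {
      r <- event_rates(st$x[i], st$e[i], pp, 100)
      expect_equal(sum(r), 100 * total_switching_rate(st$x[i], st$e[i], pp),
                   tolerance = 1e-12)
    }
  }
  # absorbing configuration: no channel can fire
  p0 <- symmetric_tau0_params()
  expect_equal(unname(event_rates(0, 0.9, p0, 100)), rep(0, 4))
})

test_that("runs are bit-reproducible from the seed and structurally sound", {
  p <- bistable_params()
  r1 <- simulate_pdmp(p, N = 100, x0 = 0.2, e0 = 0.9, t_end = 30, seed = 5,
                      record = "events")
  r2 <- simulate_pdmp(p, N = 100, x0 = 0.2, e0 = 0.9, t_end = 30, seed = 5,
                      record = "events")
  expect_identical(r1$events, r2$events)
  expect_identical(r1$grid, r2$grid)
  r3 <- simulate_pdmp(p, N = 100, x0 = 0.2, e0 = 0.9, t_end = 30, seed = 6,
                      record = "events")
  expect_false(identical(r1$events, r3$events))
  # x moves by exactly +/- 1/N at non-phantom events; e stays in range
  dx <- diff(c(0.2, r1$events$x))
  expect_true(all(abs(abs(dx) - 1 / 100) < 1e-12))
  expect_true(all(r1$grid$e >= p$l_A & r1$grid$e <= p$l_B))
  # grid-only recording carries no event log
  expect_null(simulate_pdmp(p, N = 100, x0 = 0.2, e0 = 0.9, t_end = 5,
                            seed = 1)$events)
  expect_error(simulate_pdmp(p, N = 100, x0 = 0.2, e0 = 0.9, t_end = 10),
               "seed")
  expect_error(simulate_pdmp(p, N = 100, x0 = 0.123, e0 = 0.9, t_end = 10,
                             seed = 1), "integer count")
})

test_that("an absorbing start produces no events at all", {
  p0 <- symmetric_tau0_params()
  r <- simulate_pdmp(p0, N = 50, x0 = 0, e0 = 1, t_end = 100, seed = 3,
                     record = "events")
  expect_equal(nrow(r$events), 0)
  expect_true(all(r$grid$x == 0))
  expect_equal(sum(r$counts[-1]), 0)
})

test_that("the phantom fraction matches one minus mean rate over the bound", {
  p <- bistable_params()
  r <- simulate_pdmp(p, N = 200, x0 = 0.5, e0 = 0.85, t_end = 500, seed = 11)
  xi <- r$config$rate_bound
  n_cand <- sum(r$counts)
  phantom_frac <- r$counts[["phantom"]] / n_cand
  mean_rate <- mean(200 * total_switching_rate(r$grid$x, r$grid$e, p))
  expected <- 1 - mean_rate / xi
  se <- sqrt(expected * (1 - expected) / n_cand)
  expect_lt(abs(phantom_frac - expected), 5 * se + 0.005)
})

test_that("closed-form and fine-Euler environment updates agree", {
  p <- bistable_params(ell = 0.25)
  set.seed(31)
  for (i in 1:20) {
    x <- runif(1)
    e <- runif(1, p$l_A, p$l_B)
    cf <- environment_update(e, x, p, dt = 1, method = "closed_form")
    eu <- environment_update(e, x, p, dt = 1, method = "euler",
                             euler_dt = 1e-4)
    expect_equal(cf, eu, tolerance = 1e-6)
  }
  # fixed point and zero-interval identities
  x <- 0.3
  cc <- p$l_A * x + p$l_B * (1 - x)
  expect_equal(environment_update(cc, x, p, dt = 7), cc)
  expect_identical(environment_update(0.8, x, p, dt = 0), 0.8)
})

test_that("frozen-environment occupancy matches the birth-death stationary law", {
  # ell = 0 freezes e, so the jump chain is a birth-death process on
  # {0, 1/N, ..., 1} whose stationary law follows from detailed balance
  p <- model_params(gamma_A = 0.75, delta_A = 7 / 6, tau = 0.5, ell = 0,
                    l_A = 0.7)
  N <- 50
  e_fix <- 0.85
  up <- sapply(0:(N - 1), function(k)
    sum(event_rates(k / N, e_fix, p, N)[c("social_B_to_A", "env_B_to_A")]))
  down <- sapply(1:N, function(k)
    sum(event_rates(k / N, e_fix, p, N)[c("social_A_to_B", "env_A_to_B")]))
  log_pi <- cumsum(c(0, log(up) - log(down)))
  pi_theory <- exp(log_pi - max(log_pi))
  pi_theory <- pi_theory / sum(pi_theory)
  r <- simulate_pdmp(p, N = N, x0 = 0.5, e0 = e_fix, t_end = 20000, seed = 17,
                     grid_dt = 0.5)
  occ <- tabulate(round(r$grid$x * N) + 1L, nbins = N + 1)
  occ <- occ / sum(occ)
  expect_lt(0.5 * sum(abs(occ - pi_theory)), 0.05)
})

test_that("ensemble statistics align runs and detect mismatched configs", {
  p <- bistable_params()
  runs <- lapply(1:4, function(s)
    simulate_pdmp(p, N = 100, x0 = 0.5, e0 = 0.85, t_end = 10, seed = s))
  st <- ensemble_statistics(runs)
  expect_equal(attr(st, "n_runs"), 4)
  expect_equal(st$t, runs[[1]]$grid$t)
  expect_equal(st$var_x[1], 0)   # common initial condition
  # duplicated seeds give zero variance everywhere
  twin <- list(runs[[1]], runs[[1]])
  st2 <- ensemble_statistics(twin)
  expect_true(all(st2$var_x == 0))
  other <- simulate_pdmp(p, N = 200, x0 = 0.5, e0 = 0.85, t_end = 10,
                         seed = 1)
  expect_error(ensemble_statistics(list(runs[[1]], other)), "mismatched")
})

test_that("the scaled stationary variance is N-independent", {
  p <- bistable_params()
  eq <- find_equilibria(p)
  xs <- eq$x_star[3]
  sv <- sapply(c(100, 1000), function(N) {
    x0 <- round(xs * N) / N
    runs <- lapply(1:6, function(s)
      simulate_pdmp(p, N = N, x0 = x0, e0 = eq$e_star[3], t_end = 300,
                    seed = 100 + s, grid_dt = 0.5))
    ev <- empirical_fluctuation_variance(runs, window = c(100, 300))
    c(ev$scaled_var_x, ev$se_x)
  })
  # slope of log(var) vs log(N) is ~0 after the 1/N rescaling
  expect_lt(abs(sv[1, 1] - sv[1, 2]) / sqrt(sum(sv[2, ]^2)), 4)
})

test_that("a PDMP run exports grid, events and config sidecar", {
  p <- bistable_params()
  r <- simulate_pdmp(p, N = 50, x0 = 0.2, e0 = 0.9, t_end = 5, seed = 2,
                     record = "events")
  base <- withr::local_tempfile()
  write_pdmp_run(r, base)
  expect_true(file.exists(paste0(base, "_grid.csv")))
  expect_true(file.exists(paste0(base, "_events.csv")))
  cfg <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  expect_equal(cfg$seed, 2)
  expect_equal(cfg$N, 50)
})
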