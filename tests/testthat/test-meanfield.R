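np <- neuron_params()

test_that("transfer function: subthreshold limit, monotonicity, grid
          convergence", {
  expect_lt(eif_rate_fp(-5, 0.25), 1e-3)
  # strictly increasing in mu at fixed s
  mus <- seq(0.8, 2, length.out = 10)
  r <- eif_rate_fp(mus, 1)
  expect_true(all(diff(r) > 0))
  # halving dV or lowering V_lb changes the rate < 0.1%
  r0 <- eif_rate_fp(1.5, 1)
  r_fine <- eif_rate_fp(1.5, 1, settings = solver_settings(dV = 0.005))
  r_deep <- eif_rate_fp(1.5, 1, settings = solver_settings(V_lb = -40))
  expect_lt(abs(r0 - r_fine) / r_fine, 1e-3)
  expect_lt(abs(r0 - r_deep) / r_deep, 1e-3)
  expect_error(eif_rate_fp(1, 0), "s must be > 0")
})

test_that("Fokker-Planck rates agree with Euler-Maruyama Monte-Carlo at
          spot-check moments", {
  for (mu in c(1.15, 1.6)) {
    for (s in c(0.8, 2.5)) {
      fp <- eif_rate_fp(mu, s)
      mc <- eif_rate_mc(mu, s, T_ms = 100000, n_rep = 8,
                        seed = round(1000 * (mu + s)))
      expect_lt(abs(fp - mc) / mc, 0.05)
    }
  }
})

test_that("population inputs reproduce a hand-evaluated toy case", {
  cfg <- meanfield_config(N_E = 200, N_I = 50, Q = 2, mu_plus = 1,
                          sigma_plus = 0.3, w_minus = 0.1)
  nu <- c(10, 5, 8)  # spikes/s
  pi <- population_inputs(nu, cfg)
  # independent term-by-term evaluation (rates in spikes/ms)
  KE <- 200 / 2 * 0.2
  mu1 <- KE * 1 * 0.010 + KE * 0.1 * 0.005 + 50 * 0.5 * (-0.34) * 0.008 + 1.5
  s1 <- KE * (1 + 0.3^2) * 0.010 + KE * 0.01 * 0.005 +
    50 * 0.5 * 0.34^2 * 0.008
  expect_equal(pi$mu[1], mu1)
  expect_equal(pi$s[1], s1)
  KI <- 200 / 2 * 0.5
  muI <- KI * 0.54 * (0.010 + 0.005) + 50 * 0.5 * (-0.46) * 0.008 + 2.19
  expect_equal(pi$mu[3], muI)
  # zero rates: only the external drive remains and the variance vanishes
  pi0 <- population_inputs(c(0, 0, 0), cfg)
  expect_equal(pi0$mu, c(1.5, 1.5, 2.19))
  expect_equal(pi0$s, c(0, 0, 0))
  # symmetric weights: cluster inputs identical under rate permutation
  cfg_s <- meanfield_config(N_E = 200, N_I = 50, Q = 2, mu_plus = 0.1,
                            sigma_plus = 0, w_minus = 0.1)
  a <- population_inputs(c(10, 5, 8), cfg_s)
  b <- population_inputs(c(5, 10, 8), cfg_s)
  expect_equal(a$mu[1], b$mu[2])
  expect_equal(a$s[1], b$s[2])
})

test_that("self-consistent solutions satisfy their own fixed-point
          equations", {
  cfg <- meanfield_config(N_E = 800, N_I = 200, Q = 10)
  sol <- solve_rates(cfg, ansatz = "uniform")
  expect_true(sol$converged)
  mom <- sol$moments
  FE <- eif_rate_fp(mom$mu[1], max(mom$s[1], 1e-9))
  FI <- eif_rate_fp(mom$mu[2], max(mom$s[2], 1e-9), tau_m = np$tau_m_I)
  expect_lt(abs(sol$nu[["E"]] - FE), 1e-4)
  expect_lt(abs(sol$nu[["I"]] - FI), 1e-4)
})

test_that("with mu_plus = w_minus the one-active solution collapses to the
          uniform one", {
  cfg <- meanfield_config(N_E = 800, N_I = 200, Q = 10, mu_plus = 0.005,
                          sigma_plus = 0, w_minus = 0.005)
  uni <- solve_rates(cfg, ansatz = "uniform")
  act <- solve_rates(cfg, ansatz = "one_active", init = c(50, 2, 10))
  expect_true(act$converged)
  expect_lt(abs(act$nu[["active"]] - act$nu[["inactive"]]), 1e-4)
  expect_lt(abs(act$nu[["active"]] - uni$nu[["E"]]), 1e-3)
})

test_that("weak clustering admits no active-cluster solution", {
  cfg <- meanfield_config(N_E = 800, N_I = 200, Q = 10, mu_plus = 0.1,
                          sigma_plus = 0.1)
  pt <- plastnet:::solve_point(cfg, solver_settings())
  expect_false(pt$active)
  # strong clustering does
  cfg2 <- meanfield_config(N_E = 800, N_I = 200, Q = 10, mu_plus = 1.5,
                           sigma_plus = 0.5)
  pt2 <- plastnet:::solve_point(cfg2, solver_settings())
  expect_true(pt2$active)
  expect_gt(pt2$active_rate, pt2$inactive_rate + 5)
})

test_that("sigma_max bound: endpoints, interior value, and the landscape
          mask", {
  expect_equal(sigma_max(0, 4), 0)
  expect_equal(sigma_max(4, 4), 0)
  expect_equal(sigma_max(2, 4), 2)
  expect_error(sigma_max(5, 4), "mu must lie")
  ls <- mf_landscape(mu_grid = c(0.2, 1, 2, 3.5),
                     sigma_grid = c(0.1, 0.9, 2),
                     cfg = meanfield_config(N_E = 800, N_I = 200, Q = 10),
                     settings = solver_settings(tol = 1e-4))
  expect_equal(ls$forbidden, ls$sigma > sigma_max(pmin(ls$mu, 4), 4) + 1e-12)
  # the low-mu corner is in the inactive phase
  corner <- ls[ls$mu == 0.2 & ls$sigma == 0.1, ]
  expect_false(corner$active)
  # active rate is nondecreasing in mu along admissible fixed-sigma rows
  row <- ls[ls$sigma == 0.9 & !ls$forbidden & ls$active, ]
  if (nrow(row) > 1) expect_true(all(diff(row$active_rate) > -1e-6))
  bd <- attr(ls, "boundary")
  expect_true(all(bd$mu_c <= 3.5))
})
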