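test_that("a closed, inert system stays at its initial state", {
  p <- plaque_params(mu_a = 0, mu_e = 0, sigma_f = 0, sigma_l = 0, sigma_e = 0)
  sim <- simulate_plaque(p, solver_config(n_cells = 32, t_end = 0.5))
  expect_equal(sim$R, rep(1, length(sim$t)), tolerance = 1e-10)
  expect_equal(max(abs(sim$f - 1)), 0, tolerance = 1e-10)
  expect_equal(max(abs(sim$l)), 0, tolerance = 1e-12)
  expect_equal(max(abs(sim$c)), 0, tolerance = 1e-12)
})

test_that("initial growth rate equals the LDL deposition rate", {
  # no modLDL at the endothelium yet, so dR/dt(0) = sigma_l exactly
  sim <- run_plaque(mu_e = 60, n_cells = 64, t_end = 0.05)
  ts <- time_series(sim)
  expect_equal(ts$dR_dt[1], 10)
  expect_equal(ts$R[1], 1)
  expect_true(all(diff(sim$t) > 0))
})

test_that("growth is monotone under net influx and totals track R", {
  sim <- run_plaque(mu_e = 60, n_cells = 64, t_end = 0.5)
  ts <- time_series(sim)
  expect_true(all(diff(ts$R) >= 0)) # sigma_e = 0: influx only
  expect_true(all(ts$mass_residual <= 1e-10))
  expect_true(all(ts$voids_residual <= 1e-4))
  # initial state is pure foam cells on a unit domain
  expect_equal(ts$total_f[1], 1)
  expect_equal(ts$total_l[1], 0)
  expect_equal(ts$total_c[1], 0)
})

test_that("medial density approaches the deep-plaque ODE steady state", {
  sim <- run_plaque(mu_e = 80, n_cells = 100, t_end = 1)
  expect_lt(abs(medial_density(sim, 1) - 0.5), 0.05)
  expect_equal(medial_density(sim, 0), 1)
  expect_error(medial_density(sim, 2), class = "plaquesim_domain_error")
})

test_that("upwind and central advection agree on bulk observables", {
  cen <- run_plaque(mu_e = 80, n_cells = 100, t_end = 0.5)
  upw <- run_plaque(mu_e = 80, n_cells = 100, t_end = 0.5,
                    advection = "upwind")
  expect_lt(abs(tail(upw$R, 1) - tail(cen$R, 1)) / tail(cen$R, 1), 0.01)
  expect_lt(abs(medial_density(upw, 0.5) - medial_density(cen, 0.5)), 0.02)
  # the consistent upwind selection preserves the no-voids constraint too
  expect_lt(max(time_series(upw)$voids_residual), 1e-8)
})

test_that("the mixture velocity field starts as plug flow at sigma_l", {
  sim <- run_plaque(mu_e = 60, n_cells = 64, t_end = 0.05)
  prof0 <- tidy(sim, times = 0)
  expect_equal(prof0$v, rep(10, nrow(prof0)))
  expect_equal(prof0$x, prof0$y) # R(0) = 1
})

test_that("invariant monitor warns past tolerance and fails past 10x", {
  sim <- run_plaque(mu_e = 60, n_cells = 32, t_end = 0.1)
  bad <- sim
  bad$f <- bad$f + 2e-4 # voids breach above tol, below 10x
  expect_warning(plaquesim:::check_invariants(bad),
                 class = "plaquesim_invariant_warning")
  worse <- sim
  worse$f <- worse$f + 2e-3
  expect_error(plaquesim:::check_invariants(worse),
               class = "plaquesim_invariant_breach")
  neg <- sim
  neg$l[1, 1] <- -2e-3
  expect_error(plaquesim:::check_invariants(neg),
               class = "plaquesim_invariant_breach")
})

test_that("solver configuration is validated", {
  expect_error(solver_config(n_cells = 8), "n_cells")
  expect_error(solver_config(rtol = 0))
  expect_error(solver_config(t_end = 1, output_times = c(0, 2)),
               class = "plaquesim_invalid_config")
  expect_error(solver_config(advection = "quick"))
  cfg <- solver_config(t_end = 0.5)
  expect_equal(cfg$output_times[1], 0)
  expect_equal(max(cfg$output_times), 0.5)
})

test_that("conservation report audits the growth law along the trajectory", {
  sim <- run_plaque(mu_e = 60, n_cells = 64, t_end = 0.3,
                    output_times = audit_times(0.3))
  cr <- conservation_report(sim)
  expect_true(all(cr$voids_residual <= 1e-4))
  expect_true(all(cr$mass_residual <= 1e-10))
  expect_lt(max(cr$growth_mismatch, na.rm = TRUE), 0.01)
})
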