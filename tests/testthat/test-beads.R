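test_that("the tagging dose is a unit-peak Gaussian summed over doses", {
  expect_equal(bead_dose(1, t_tag = 1), 1)
  expect_equal(bead_dose(1.035, t_tag = 1), exp(-0.5))
  expect_lt(bead_dose(1.35, t_tag = 1), 1e-21) # e^-50: dose over
  expect_equal(bead_dose(1, t_tag = c(1, 1.07)), 1 + exp(-2))
  expect_equal(bead_dose(0.5, t_tag = numeric(0)), 0)
})

test_that("bead kinetics conserve bead number and need a live carrier", {
  p <- plaque_params(mu_a = 40, mu_e = 80)
  s <- bead_sources(1, 0.5, 0.5, p)
  expect_equal(s$s_qf, -40 + 20)
  expect_identical(s$s_qf + s$s_qc, 0)
  # no live cells: dead-material beads cannot be recovered
  s2 <- bead_sources(0.3, 0.9, 0, p)
  expect_equal(s2$s_qf, -40 * 0.3)
  expect_equal(bead_sources(0, 0, 0.7, p)$s_qf, 0)
  set.seed(3)
  s3 <- bead_sources(runif(20), runif(20), runif(20), p)
  expect_equal(s3$s_qf + s3$s_qc, rep(0, 20))
})

test_that("bead fluxes ride the carrier phase and vanish without one", {
  bf <- bead_fluxes(q_f = 0.2, q_c = 0, f = 0.4, c = 0, J_f = -1, J_c = 5)
  expect_equal(bf$J_qf, -0.5)
  expect_equal(bf$J_qc, 0) # no dead material: no transport
  # beads mirroring their carrier inherit its flux exactly
  bf2 <- bead_fluxes(q_f = 0.4, q_c = 0.6, f = 0.4, c = 0.6,
                     J_f = -1.3, J_c = 0.7)
  expect_equal(bf2$J_qf, -1.3)
  expect_equal(bf2$J_qc, 0.7)
})

test_that("beads are conserved without emigration once dosing ends", {
  sim <- run_plaque(mu_e = 60, sigma_e = 0, n_cells = 100, t_end = 1.5,
                    bead_times = 0.3)
  qt <- total_beads(sim)
  post <- qt$Q[qt$t >= 0.3 + 10 * 0.035] # dose window closed
  expect_gt(min(post), 0)
  expect_lt((max(post) - min(post)) / max(post), 1e-3)
  # peak bounded by the time-integrated dose, 0.035 * sqrt(2*pi)
  expect_lte(max(qt$Q), 0.0878)
})

test_that("bead transport is one-way coupled to the phase dynamics", {
  plain <- run_plaque(mu_e = 80, sigma_e = 20, n_cells = 64, t_end = 0.5)
  dosed <- run_plaque(mu_e = 80, sigma_e = 20, n_cells = 64, t_end = 0.5,
                      bead_times = 0.2)
  expect_lt(max(abs(plain$f - dosed$f)), 1e-6)
  expect_lt(max(abs(plain$l - dosed$l)), 1e-6)
  expect_lt(max(abs(plain$c - dosed$c)), 1e-6)
  expect_lt(max(abs(plain$R - dosed$R)), 1e-6)
})

test_that("tracers proportional to their carriers stay proportional", {
  # closed endothelium (no LDL, no recruitment) so phagocytosis is inactive
  # and proportionality is an exact invariant of death/efferocytosis/egress
  p <- plaque_params(mu_a = 40, mu_e = 80, sigma_e = 20,
                     sigma_f = 0, sigma_l = 0)
  alpha <- 0.3
  sim <- suppressWarnings(simulate_plaque(
    p, solver_config(n_cells = 100, t_end = 0.5),
    q_f0 = rep(alpha, 101)))
  expect_lt(max(abs(sim$q_f - alpha * sim$f)), 1e-6)
  expect_lt(max(abs(sim$q_c - alpha * sim$c)), 1e-6)
})

test_that("circulation time is the FWHM with interpolated crossings", {
  tg <- seq(0, 2, by = 0.01)
  tri <- tibble::tibble(t = tg, Q = pmax(0, 1 - abs(tg - 1)))
  tc <- circulation_time(tri)
  expect_equal(tc$t_circ, 1)
  expect_equal(tc$t_lo, 0.5)
  expect_equal(tc$t_hi, 1.5)
  expect_false(tc$censored)

  rect <- tibble::tibble(t = tg, Q = as.numeric(tg >= 0.5 & tg <= 1.25))
  expect_equal(circulation_time(rect)$t_circ, 0.75, tolerance = 0.02)

  s <- 0.1
  gauss <- tibble::tibble(t = tg, Q = exp(-0.5 * ((tg - 1) / s)^2))
  expect_equal(circulation_time(gauss)$t_circ, 2 * sqrt(2 * log(2)) * s,
               tolerance = 1e-3)
})

test_that("degenerate bead series are flagged", {
  tg <- seq(0, 1, 0.01)
  expect_error(circulation_time(tibble::tibble(t = tg, Q = 0 * tg)),
               class = "plaquesim_undefined_metric")
  rising <- tibble::tibble(t = tg, Q = tg) # still at peak at t_end
  expect_warning(tc <- circulation_time(rising),
                 class = "plaquesim_censored_metric")
  expect_true(tc$censored)
  expect_equal(tc$t_hi, 1)
  # total_beads refuses a simulation run without beads
  sim <- run_plaque(mu_e = 60, n_cells = 64, t_end = 0.05)
  expect_error(total_beads(sim), class = "plaquesim_no_beads")
})
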