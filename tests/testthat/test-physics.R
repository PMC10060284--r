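test_that("kinetics vanish without foam cells and at the coexistence state", {
  p <- plaque_params(mu_a = 40, mu_e = 80)
  # every exchange term carries a factor f
  s <- source_terms(0, 0.3, 0.7, p)
  expect_equal(unlist(s), c(s_f = 0, s_l = 0, s_c = 0))
  # f = 1 - mu_a/mu_e with l = 0: deaths balance efferocytic recycling
  s2 <- source_terms(0.5, 0, 0.5, p)
  expect_equal(s2$s_f, 0)
  expect_equal(s2$s_c, 0)
  # pure foam cells only die
  s3 <- source_terms(1, 0, 0, p)
  expect_equal(unlist(s3), c(s_f = -40, s_l = 0, s_c = 40))
})

test_that("kinetics conserve mass to machine precision for arbitrary states", {
  set.seed(11)
  p <- plaque_params(mu_a = 73, mu_e = 140, sigma_e = 55)
  for (i in 1:25) {
    u <- runif(3)
    s <- source_terms(u[1], u[2], u[3], p)
    # algebraic identity; roundoff only (terms are O(100))
    expect_lt(abs(s$s_f + s$s_l + s$s_c), 1e-12)
  }
  # vectorised over nodes as used by the solver
  s <- source_terms(runif(50), runif(50), runif(50), p)
  expect_lt(max(abs(s$s_f + s$s_l + s$s_c)), 1e-12)
})

test_that("mixture velocity reduces to the boundary influx without gradients", {
  p <- plaque_params()
  expect_equal(mixture_velocity(1, 0, 0, 0, l0 = 0, params = p), 10)
  expect_equal(mixture_velocity(1, 0, 0, 0, l0 = 0.05, params = p), 15)
  p0 <- plaque_params(sigma_f = 0, sigma_l = 0)
  expect_equal(mixture_velocity(0.5, 0, 0, 0, l0 = 0.2, params = p0), 0)
})

test_that("phase fluxes follow the constitutive forms", {
  p <- plaque_params()
  # uniform state: no interphase motion, total foam-cell flux is pure advection
  fx <- phase_fluxes(1, 0, 0, 0, 0, 0, l0 = 0, params = p)
  expect_equal(unlist(fx[c("J_f", "J_l", "J_c")]), c(J_f = 0, J_l = 0, J_c = 0))
  expect_equal(fx$v, 10)
  expect_equal(fx$j_f, 10)
  # Fickian modLDL flux
  fx2 <- phase_fluxes(0.5, 0.2, 0.3, 0, 0.01, 0, l0 = 0.2, params = p)
  expect_equal(fx2$J_l, -2)
  # chemotactic attraction moves foam cells up the modLDL gradient
  expect_gt(fx2$J_f, 0)
})

test_that("total fluxes sum to the endothelial influx on the no-voids manifold", {
  # the closure identity behind the mixture velocity: whenever f+l+c = 1,
  # j_f + j_l + j_c equals sigma_f l0 + sigma_l at every node
  set.seed(7)
  p <- plaque_params(mu_a = 40, mu_e = 80, sigma_e = 20)
  for (i in 1:20) {
    f <- runif(9); l <- runif(9) * (1 - f); c <- 1 - f - l
    g <- matrix(rnorm(27, sd = 2), 9)
    l0 <- runif(1, 0, 0.3)
    fx <- phase_fluxes(f, l, c, g[, 1], g[, 2], g[, 3], l0 = l0, params = p)
    expect_equal(fx$j_f + fx$j_l + fx$j_c,
                 rep(p$sigma_f * l0 + p$sigma_l, 9), tolerance = 1e-12)
  }
})

test_that("boundary growth rate balances influx against emigration", {
  expect_equal(boundary_growth_rate(0, 0.7, plaque_params(sigma_e = 0)), 10)
  p <- plaque_params(sigma_e = 20)
  expect_equal(boundary_growth_rate(0.05, 0.5, p), 5 + 10 - 10)
  # exact balance: stabilised plaque
  expect_equal(boundary_growth_rate(0.05, 15 / 20, p), 0)
})
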