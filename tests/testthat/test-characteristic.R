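test_that("characteristic ODE right-hand side follows the logistic form", {
  expect_equal(characteristic_rhs(0, 40, 80), 0)
  expect_equal(characteristic_rhs(1 - 40 / 80, 40, 80), 0)
  expect_equal(characteristic_rhs(1, 40, 80), -40) # 80 * 1 * (0.5 - 1)
  # no efferocytic recycling: pure decay
  expect_equal(characteristic_rhs(0.6, 40, 0), -24)
})

test_that("steady states and eigenvalues across the bifurcation", {
  ss <- steady_states(40, 60)
  expect_equal(ss$F_star, c(0, 1 / 3))
  expect_equal(ss$stability, c("unstable", "stable"))
  expect_equal(ss$eigenvalue, c(20, -20))

  ss2 <- steady_states(40, 80)
  expect_equal(ss2$F_star[ss2$stability == "stable"], 0.5)

  # death outpaces efferocytosis: extinction is the only state
  ss3 <- steady_states(40, 20)
  expect_equal(nrow(ss3), 1)
  expect_equal(ss3$F_star, 0)
  expect_equal(ss3$stability, "stable")
  expect_equal(ss3$eigenvalue, -20)

  # degenerate transcritical point
  ss4 <- steady_states(40, 40)
  expect_equal(nrow(ss4), 1)
  expect_equal(ss4$eigenvalue, 0)
  expect_equal(ss4$stability, "degenerate")

  ev <- stability_eigenvalues(100, 10)
  expect_equal(unname(ev[1]), -90)
})

test_that("stability labels swap exactly at mu_e/mu_a = 1 (transcritical)", {
  mu_a <- 40
  for (r in c(0.25, 0.5, 0.75, 0.9, 1.1, 1.5, 2, 3, 4)) {
    ss <- steady_states(mu_a, r * mu_a)
    ext <- ss[ss$F_star == 0, ]
    expect_equal(ext$eigenvalue, r * mu_a - mu_a)
    if (r < 1) {
      expect_equal(nrow(ss), 1)
      expect_equal(ext$stability, "stable")
    } else {
      coex <- ss[ss$F_star > 0, ]
      expect_equal(ext$stability, "unstable")
      expect_equal(coex$F_star, 1 - 1 / r)
      expect_equal(coex$eigenvalue, mu_a - r * mu_a)
      expect_equal(coex$stability, "stable")
    }
  }
})

test_that("numerical trajectories match the closed-form logistic solution", {
  set.seed(101)
  tg <- seq(0, 1, length.out = 21)
  worst <- 0
  for (i in 1:100) {
    F0 <- runif(1, 0.05, 1)
    mu_a <- runif(1, 0, 100)
    mu_e <- runif(1, 1, 200)
    num <- solve_characteristic(F0, mu_a, mu_e, tg)$F
    cf <- logistic_characteristic(F0, mu_a, mu_e, tg)
    worst <- max(worst, max(abs(num - cf) / pmax(abs(cf), .Machine$double.xmin)))
  }
  expect_lt(worst, 1e-8)
})

test_that("starting at a steady state stays there", {
  K <- 1 - 40 / 80
  out <- solve_characteristic(K, 40, 80, seq(0, 2, 0.1))
  expect_equal(out$F, rep(K, nrow(out)), tolerance = 1e-9)
  # saturated start relaxes to the coexistence state
  out2 <- solve_characteristic(1, 40, 80, c(0, 5))
  expect_equal(out2$F[2], 0.5, tolerance = 1e-8)
})

test_that("the two-species pair conserves F + C = 1 exactly", {
  pair_rhs <- function(t, y, parms) {
    dF <- -parms[1] * y[1] + parms[2] * y[1] * y[2]
    list(c(dF, -dF))
  }
  sol <- deSolve::ode(c(F = 0.8, C = 0.2), seq(0, 1, 0.05), pair_rhs,
                      parms = c(40, 60), rtol = 1e-10, atol = 1e-12)
  expect_equal(sol[, "F"] + sol[, "C"], rep(1, nrow(sol)), tolerance = 1e-10)
  expect_equal(tail(sol[, "F"], 1), 1 / 3, tolerance = 1e-4)
})

test_that("relaxation time scales inversely with |mu_e - mu_a| at fixed ratio", {
  # linearisation: distance to the stable state decays like exp((mu_a-mu_e)t)
  hit_time <- function(mu_a, mu_e, eps = 1e-3) {
    K <- 1 - mu_a / mu_e
    tg <- seq(0, 5, length.out = 2001)
    Fv <- logistic_characteristic(0.95, mu_a, mu_e, tg)
    tg[which(abs(Fv - K) < eps)[1]]
  }
  t1 <- hit_time(40, 80)
  t2 <- hit_time(80, 160)
  t4 <- hit_time(160, 320)
  expect_equal(t1 / t2, 2, tolerance = 0.05)
  expect_equal(t2 / t4, 2, tolerance = 0.05)
})

test_that("degenerate inputs are handled as limits, not rejected", {
  expect_error(steady_states(0, 0), class = "plaquesim_invalid_parameter")
  # mu_a = 0: pure logistic growth to full occupancy
  out <- solve_characteristic(0.1, 0, 50, c(0, 1))
  expect_equal(out$F[2], 1, tolerance = 1e-6)
  expect_error(solve_characteristic(1.2, 40, 80, c(0, 1)),
               class = "plaquesim_domain_error")
  expect_error(logistic_characteristic(-0.1, 40, 80, 0.5),
               class = "plaquesim_domain_error")
})
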