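#' Deep-plaque characteristic ODE
#'
#' Away from the boundaries, transport in the plaque is dominated by bulk
#' advection, all phases move with the common mixture velocity, and modLDL is
#' negligible. Along an advection characteristic the foam-cell fraction `F`
#' (with dead material `C = 1 - F` by the no-voids condition) then obeys the
#' logistic-type equation
#' \deqn{dF/dt = \mu_e F (1 - \mu_a/\mu_e - F),}
#' with steady states at `F = 0` and the coexistence state
#' `F = 1 - mu_a/mu_e`, exchanging stability in a transcritical bifurcation
#' at `mu_a = mu_e`.
#'
#' `characteristic_rhs()` evaluates the right-hand side. When `mu_e = 0`
#' (no efferocytic recycling) the dynamics degenerate to pure exponential
#' decay `dF/dt = -mu_a F`.
#'
#' @param F Foam-cell fraction along the characteristic (vectorised).
#' @param mu_a Foam-cell death rate (>= 0).
#' @param mu_e Efferocytosis rate (>= 0).
#' @return `characteristic_rhs()`: `dF/dt`, same length as `F`.
#' @examples
#' characteristic_rhs(1, mu_a = 40, mu_e = 80)
#' steady_states(40, 60)
#' @export
characteristic_rhs <- function(F, mu_a, mu_e) {
  stopifnot(is.finite(F), mu_a >= 0, mu_e >= 0)
  if (mu_e == 0) {
    return(-mu_a * F)
  }
  mu_e * F * ((1 - mu_a / mu_e) - F)
}

#' @describeIn characteristic_rhs Non-negative steady states of the
#'   characteristic ODE with their stability. The coexistence state is
#'   reported only when strictly positive; at `mu_a = mu_e` the two states
#'   coincide in a single degenerate state at 0 with zero eigenvalue.
#'   Returns a tibble with columns `F_star`, `eigenvalue` and `stability`
#'   (`"stable"`, `"unstable"` or `"degenerate"`).
#' @export
steady_states <- function(mu_a, mu_e) {
  stopifnot(mu_a >= 0, mu_e >= 0)
  if (mu_a == 0 && mu_e == 0) {
    abort("at least one of `mu_a`, `mu_e` must be positive",
          class = "plaquesim_invalid_parameter")
  }
  label <- function(lambda) {
    if (lambda < 0) "stable" else if (lambda > 0) "unstable" else "degenerate"
  }
  lam0 <- mu_e - mu_a
  out <- tibble(F_star = 0, eigenvalue = lam0, stability = label(lam0))
  if (mu_e > 0 && 1 - mu_a / mu_e > 0) {
    lam1 <- mu_a - mu_e
    out <- dplyr::bind_rows(out, tibble(F_star = 1 - mu_a / mu_e,
                                        eigenvalue = lam1,
                                        stability = label(lam1)))
  }
  out
}

#' @describeIn characteristic_rhs Linearisation eigenvalues at the steady
#'   states: `mu_e - mu_a` at `F = 0` and `mu_a - mu_e` at the coexistence
#'   state (when it exists). Returns a named numeric vector keyed by the
#'   steady-state value.
#' @export
stability_eigenvalues <- function(mu_a, mu_e) {
  ss <- steady_states(mu_a, mu_e)
  setNames(ss$eigenvalue, format(ss$F_star, digits = 15))
}

#' Closed-form logistic solution of the characteristic ODE
#'
#' For `K = 1 - mu_a/mu_e != 0` and `F0 in (0, 1]` the characteristic ODE has
#' the explicit solution
#' \deqn{F(t) = K / (1 + ((K - F0)/F0) e^{-(\mu_e - \mu_a) t}),}
#' which also covers `K < 0` (decay to extinction). `F0 = 0` stays at 0. At
#' the bifurcation point `mu_a = mu_e` the equation is pure logistic decay
#' `dF/dt = -mu_e F^2` with solution `F0 / (1 + mu_e F0 t)`, and `mu_e = 0`
#' gives exponential decay.
#'
#' @param F0 Initial foam-cell fraction, in `[0, 1]`.
#' @param t Times at which to evaluate (numeric vector, >= 0).
#' @inheritParams characteristic_rhs
#' @return Numeric vector `F(t)`.
#' @export
logistic_characteristic <- function(F0, mu_a, mu_e, t) {
  stopifnot(mu_a >= 0, mu_e >= 0)
  if (F0 < 0 || F0 > 1) {
    abort("`F0` must lie in [0, 1]", class = "plaquesim_domain_error")
  }
  if (F0 == 0) return(rep(0, length(t)))
  if (mu_e == 0) return(F0 * exp(-mu_a * t))
  if (mu_a == mu_e) return(F0 / (1 + mu_e * F0 * t))
  K <- 1 - mu_a / mu_e
  K / (1 + ((K - F0) / F0) * exp(-(mu_e - mu_a) * t))
}

#' Integrate the characteristic ODE numerically
#'
#' Integrates the deep-plaque logistic equation with a stiff-capable
#' integrator. Kept separate from [logistic_characteristic()] so the two can
#' cross-validate each other.
#'
#' @inheritParams logistic_characteristic
#' @param t_grid Strictly increasing vector of output times starting at the
#'   initial time.
#' @param rtol,atol Integrator tolerances. The default near-zero `atol`
#'   gives pure relative error control, so even deeply decayed trajectories
#'   (foam-cell extinction over many e-foldings) keep full relative accuracy
#'   against the closed form.
#' @return A tibble with columns `t`, `F` and `C` (`= 1 - F`).
#' @examples
#' solve_characteristic(1, mu_a = 40, mu_e = 80, t_grid = seq(0, 0.5, 0.05))
#' @export
solve_characteristic <- function(F0, mu_a, mu_e, t_grid,
                                 rtol = 1e-10, atol = 1e-300) {
  stopifnot(mu_a >= 0, mu_e >= 0, length(t_grid) >= 2, !is.unsorted(t_grid))
  if (F0 < 0 || F0 > 1) {
    abort("`F0` must lie in [0, 1]", class = "plaquesim_domain_error")
  }
  sol <- deSolve::ode(
    y = c(F = F0), times = t_grid,
    func = function(t, y, parms) list(characteristic_rhs(y[[1]], mu_a, mu_e)),
    method = "lsoda", rtol = rtol, atol = atol
  )
  tibble(t = sol[, "time"], F = sol[, "F"], C = 1 - sol[, "F"])
}

#' Bifurcation table for the deep-plaque ODE
#'
#' Tabulates steady states and eigenvalues over a grid of efferocytosis/death
#' ratios, the structure behind the transcritical bifurcation diagram of the
#' deep-plaque foam-cell fraction.
#'
#' @param ratios Vector of `mu_e / mu_a` ratios (> 0).
#' @param mu_a Death rate held fixed while `mu_e = ratio * mu_a` varies.
#' @return A tibble with columns `ratio`, `mu_a`, `mu_e`, `F_star`,
#'   `eigenvalue`, `stability`.
#' @export
bifurcation_table <- function(ratios = seq(0.25, 4, by = 0.25), mu_a = 40) {
  stopifnot(all(ratios > 0), mu_a > 0)
  purrr::map_dfr(ratios, function(r) {
    dplyr::mutate(steady_states(mu_a, r * mu_a),
                  ratio = r, mu_a = mu_a, mu_e = r * mu_a,
                  .before = 1)
  })
}
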