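#' Solver configuration
#'
#' Numerical settings for [simulate_plaque()]. The growing intima `[0, R(t)]`
#' is mapped onto the fixed interval `y in [0, 1]` and discretised on a
#' uniform grid of `n_cells` intervals (`n_cells + 1` nodes, node 1 at the
#' endothelium, the last node at the medial boundary). Spatial derivatives
#' use second-order central differencing in flux form; the semi-discrete
#' system is advanced with a stiff backward differentiation formula (BDF)
#' integrator.
#'
#' @param n_cells Number of grid intervals (>= 16). Default 200, which
#'   resolves the endothelial boundary layer set up by the strong chemotactic
#'   response (`chi_l / D_f = 50`).
#' @param t_end Final time (reference timescales, i.e. weeks).
#' @param output_times Snapshot times in `[0, t_end]`. Default: uniform with
#'   at least 100 snapshots per unit time (and at least 51 overall), dense
#'   enough for time interpolation of scalar readouts and for resolving bead
#'   dose windows.
#' @param rtol,atol Integrator tolerances. Defaults `1e-8`, `1e-10`.
#' @param advection `"central"` (default; second order) or `"upwind"` (first
#'   order, monotone) discretisation of the advective face values.
#' @param tol_voids Monitoring tolerance on `max |f + l + c - 1|`. A breach
#'   warns; a breach beyond ten times this hard-fails as a model-consistency
#'   signal. Default `1e-4`.
#' @param tol_neg Monitoring tolerance for negative phase fractions and bead
#'   densities (undershoot). Default `1e-4`, sized to the dispersive
#'   undershoot of second-order central transport of the bead tagging pulse
#'   at the default grid; the phase fractions themselves stay non-negative
#'   to far tighter accuracy.
#' @param method deSolve integrator: `"lsode"` (BDF, full Jacobian; default)
#'   or `"lsodes"` (BDF, sparse Jacobian).
#' @param seed Reserved; the model is deterministic and the value is unused.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(n_cells = 200, t_end = 1, output_times = NULL,
                          rtol = 1e-8, atol = 1e-10,
                          advection = c("central", "upwind"),
                          tol_voids = 1e-4, tol_neg = 1e-4,
                          method = c("lsode", "lsodes"), seed = NULL) {
  advection <- match.arg(advection)
  method <- match.arg(method)
  stopifnot(length(n_cells) == 1L, n_cells >= 16, n_cells == round(n_cells),
            length(t_end) == 1L, t_end > 0, rtol > 0, atol > 0,
            tol_voids > 0, tol_neg > 0)
  if (is.null(output_times)) {
    n_out <- max(51, ceiling(100 * t_end) + 1)
    output_times <- seq(0, t_end, length.out = n_out)
  }
  output_times <- sort(unique(c(0, output_times)))
  if (any(output_times < 0) || any(output_times > t_end + 1e-12)) {
    abort("`output_times` must lie within [0, t_end]",
          class = "plaquesim_invalid_config")
  }
  structure(list(n_cells = as.integer(n_cells), t_end = t_end,
                 output_times = output_times, rtol = rtol, atol = atol,
                 advection = advection, tol_voids = tol_voids,
                 tol_neg = tol_neg, method = method, seed = seed),
            class = "solver_config")
}

#' @export
print.solver_config <- function(x, ...) {
  cat(sprintf(
    "<solver_config> n_cells=%d, t_end=%g, %d snapshots, rtol=%g, atol=%g, %s advection, %s\n",
    x$n_cells, x$t_end, length(x$output_times), x$rtol, x$atol,
    x$advection, x$method))
  invisible(x)
}

# Ratio guard for bead transport: below this carrier fraction the physical
# bead flux is zero (the 0/0 limit of q/u at q = u = 0).
.eps_ratio <- 1e-10

# Build the semi-discrete right-hand side on the mapped domain.
#
# With y = x / R(t), each phase obeys
#   u_t = (1/R) d/dy( R' y u - j_u ) - (R'/R) u + s_u,   j_u = J_u + v u,
# which is the transformed continuity equation with the
# mesh-advection term written conservatively. Discretisation: finite-volume
# flux differencing with half-cells at the two boundary nodes. Interior face
# fluxes use central (arithmetic-mean) face values and compact two-point
# gradients; the mixture velocity is evaluated at nodes from the closed-form
# no-voids expression and averaged to faces. Boundary faces impose the flux
# boundary conditions exactly: endothelial influx (sigma_f*l|0, sigma_l, 0)
# and, relative to the moving medial boundary, the emigration flux
# sigma_e*f|R for foam cells and zero for the passive phases. Summed over
# phases and cells this telescopes to dR/dt = sigma_f*l|0 + sigma_l -
# sigma_e*f|R, so the discrete global mass budget is exact and the no-voids
# residual is pure truncation error.
make_rhs <- function(params, cfg, beads = FALSE, dose_fun = NULL) {
  N <- cfg$n_cells + 1L
  h <- 1 / cfg$n_cells
  y_face <- seq(0, 1, length.out = N)[-1] - h / 2 # interior faces
  dy_cell <- c(h / 2, rep(h, N - 2L), h / 2)
  upwind <- cfg$advection == "upwind"
  D_f <- params$D_f; D_l <- params$D_l; D_c <- params$D_c
  chi_l <- params$chi_l; chi_c <- params$chi_c
  mu_a <- params$mu_a; mu_e <- params$mu_e; mu_p <- params$mu_p
  sigma_f <- params$sigma_f; sigma_l <- params$sigma_l; sigma_e <- params$sigma_e
  i1 <- 1:(N - 1L); i2 <- 2:N

  face_val <- function(u, w) {
    if (upwind) ifelse(w > 0, u[i1], u[i2]) else (u[i1] + u[i2]) / 2
  }

  function(t, state, parms) {
    if (any(!is.finite(state))) {
      bad <- which(!is.finite(state))[1L]
      abort(sprintf("non-finite state entry at index %d (t = %g)", bad, t),
            class = "plaquesim_integration_failure")
    }
    f <- state[1:N]; l <- state[(N + 1L):(2L * N)]; c <- state[(2L * N + 1L):(3L * N)]
    R <- state[length(state)]
    l0 <- l[1L]; fN <- f[N]
    Rp <- sigma_f * l0 + sigma_l - sigma_e * fN
    sigma0 <- sigma_f * l0 + sigma_l

    # interior face quantities; the face mixture velocity is evaluated from
    # the same compact face gradients as the fluxes, so the discrete total
    # flux J_f+J_l+J_c+v is exactly the constant sigma0 wherever f+l+c = 1
    # and the no-voids constraint is preserved by the semi-discrete system
    gf <- (f[i2] - f[i1]) / (h * R)
    gl <- (l[i2] - l[i1]) / (h * R)
    gc <- (c[i2] - c[i1]) / (h * R)
    fbar <- (f[i1] + f[i2]) / 2
    vbar <- sigma0 + D_f * gf - chi_l * fbar * gl - chi_c * fbar * gc +
      D_l * gl + D_c * gc
    # common advective coefficient (mixture velocity relative to the moving
    # mesh); upwinding, when enabled, selects the same donor node for every
    # phase, which keeps f + l + c = 1 exactly. Chemotactic drift stays in
    # central flux form.
    w <- vbar - Rp * y_face
    chemo <- (chi_l * gl + chi_c * gc) * fbar
    Phi_f <- -D_f * gf + chemo + w * face_val(f, w)
    Phi_l <- -D_l * gl + w * face_val(l, w)
    Phi_c <- -D_c * gc + w * face_val(c, w)

    # boundary faces: Phi = j_u - R' y u with y = 0 resp. 1
    Phi_f <- c(sigma_f * l0, Phi_f, sigma_e * fN)
    Phi_l <- c(sigma_l, Phi_l, 0)
    Phi_c <- c(0, Phi_c, 0)

    phag <- mu_p * f * l; eff <- mu_e * f * c; dth <- mu_a * f
    RpR <- Rp / R
    dudt_f <- -diff(Phi_f) / (R * dy_cell) - RpR * f + (phag + eff - dth)
    dudt_l <- -diff(Phi_l) / (R * dy_cell) - RpR * l - phag
    dudt_c <- -diff(Phi_c) / (R * dy_cell) - RpR * c + (dth - eff)

    if (!beads) {
      return(list(c(dudt_f, dudt_l, dudt_c, Rp)))
    }

    q_f <- state[(3L * N + 1L):(4L * N)]
    q_c <- state[(4L * N + 1L):(5L * N)]
    cbar <- (c[i1] + c[i2]) / 2
    qfbar <- (q_f[i1] + q_f[i2]) / 2; qcbar <- (q_c[i1] + q_c[i2]) / 2
    # beads ride their carrier phase: J_q = (q/u) J_u, advected with v
    Jf_face <- -D_f * gf + chi_l * fbar * gl + chi_c * fbar * gc
    Jc_face <- -D_c * gc
    rat_f <- ifelse(fbar > .eps_ratio, qfbar / fbar, 0)
    rat_c <- ifelse(cbar > .eps_ratio, qcbar / cbar, 0)
    Phi_qf <- rat_f * Jf_face + w * face_val(q_f, w)
    Phi_qc <- rat_c * Jc_face + w * face_val(q_c, w)
    Phi_qf <- c(dose_fun(t), Phi_qf, sigma_e * q_f[N])
    Phi_qc <- c(0, Phi_qc, 0)
    s_qf <- -mu_a * q_f + mu_e * f * q_c
    dudt_qf <- -diff(Phi_qf) / (R * dy_cell) - RpR * q_f + s_qf
    dudt_qc <- -diff(Phi_qc) / (R * dy_cell) - RpR * q_c - s_qf

    list(c(dudt_f, dudt_l, dudt_c, dudt_qf, dudt_qc, Rp))
  }
}

#' Simulate plaque growth
#'
#' Integrates the free-boundary multiphase system from the post-injury
#' initial state (intima of unit width populated entirely by resident
#' macrophages: `f = 1`, `l = c = 0`, `R = 1`) to `t_end`. Optionally
#' co-integrates the bead tracer pair `q_f`, `q_c` (continuum macrophage
#' tagging): beads enter with recruited monocytes as a Gaussian endothelial
#' dose of width 0.035 centred on each `bead_times` entry, are handed from
#' live foam cells to dead material at the death rate and back by
#' efferocytosis, and leave only with emigrating foam cells. The bead
#' coupling is one-way; phase dynamics are unchanged.
#'
#' @param params A [plaque_params()] object.
#' @param config A [solver_config()] object.
#' @param bead_times Optional numeric vector of bead dose centre times;
#'   enables the tracer extension.
#' @param q_f0,q_c0 Optional initial bead profiles (length `n_cells + 1`),
#'   e.g. for pre-tagged cells. Default zero.
#' @return An object of class `plaque_sim`; see [time_series()],
#'   [tidy.plaque_sim()], [glance.plaque_sim()], [conservation_report()].
#' @examples
#' \donttest{
#' sim <- simulate_plaque(plaque_params(mu_e = 80),
#'                        solver_config(n_cells = 64, t_end = 0.1))
#' glance(sim)
#' }
#' @export
simulate_plaque <- function(params, config = solver_config(),
                            bead_times = NULL, q_f0 = NULL, q_c0 = NULL) {
  stopifnot(inherits(params, "plaque_params"), inherits(config, "solver_config"))
  N <- config$n_cells + 1L
  beads <- !is.null(bead_times) || !is.null(q_f0) || !is.null(q_c0)
  dose_fun <- if (beads) bead_dose_function(bead_times %||% numeric(0)) else NULL

  y0 <- c(rep(1, N), rep(0, N), rep(0, N))
  if (beads) {
    q_f0 <- q_f0 %||% rep(0, N); q_c0 <- q_c0 %||% rep(0, N)
    stopifnot(length(q_f0) == N, length(q_c0) == N)
    y0 <- c(y0, q_f0, q_c0)
  }
  y0 <- c(y0, 1) # R(0) = 1

  rhs <- make_rhs(params, config, beads = beads, dose_fun = dose_fun)
  sol <- if (config$method == "lsodes") {
    deSolve::lsodes(y = y0, times = config$output_times, func = rhs,
                    rtol = config$rtol, atol = config$atol, maxsteps = 1e5)
  } else {
    deSolve::lsode(y = y0, times = config$output_times, func = rhs,
                   mf = 22, rtol = config$rtol, atol = config$atol,
                   maxsteps = 1e5)
  }
  istate <- attr(sol, "istate")[1L]
  if (istate < 0) {
    last <- sol[nrow(sol), ]
    abort(sprintf("stiff integration failed (istate = %d) at t = %g",
                  istate, last[[1L]]),
          class = "plaquesim_integration_failure",
          last_state = last)
  }

  times <- sol[, 1L]
  cols <- function(k) {
    m <- sol[, (k * N + 2L):((k + 1L) * N + 1L), drop = FALSE]
    dimnames(m) <- NULL
    m
  }
  out <- list(
    params = params, config = config,
    bead_times = if (beads) (bead_times %||% numeric(0)) else NULL,
    t = times, y = seq(0, 1, length.out = N),
    f = cols(0L), l = cols(1L), c = cols(2L),
    q_f = if (beads) cols(3L) else NULL,
    q_c = if (beads) cols(4L) else NULL,
    R = sol[, ncol(sol)],
    integrator = attr(sol, "istate")
  )
  class(out) <- "plaque_sim"
  check_invariants(out)
  out
}

# Invariant monitoring: warn past the configured tolerance, hard-fail past
# ten times it (a model-inconsistency signal, not a tolerance issue).
check_invariants <- function(sim) {
  cfg <- sim$config
  voids <- max(abs(sim$f + sim$l + sim$c - 1))
  neg <- -min(0, sim$f, sim$l, sim$c)
  if (!is.null(sim$q_f)) neg <- max(neg, -min(0, sim$q_f, sim$q_c))
  if (voids > 10 * cfg$tol_voids) {
    abort(sprintf("no-voids residual %.3g exceeds 10x tol_voids = %.3g",
                  voids, cfg$tol_voids),
          class = "plaquesim_invariant_breach")
  }
  if (voids > cfg$tol_voids) {
    warn(sprintf("no-voids residual %.3g exceeds tol_voids = %.3g",
                 voids, cfg$tol_voids), class = "plaquesim_invariant_warning")
  }
  if (neg > 10 * cfg$tol_neg) {
    abort(sprintf("negative phase fraction %.3g exceeds 10x tol_neg = %.3g",
                  neg, cfg$tol_neg),
          class = "plaquesim_invariant_breach")
  }
  if (neg > cfg$tol_neg) {
    warn(sprintf("negative phase fraction %.3g exceeds tol_neg = %.3g",
                 neg, cfg$tol_neg), class = "plaquesim_invariant_warning")
  }
  invisible(sim)
}

#' Mixture-velocity field of a stored snapshot
#'
#' Reconstructs the nodal mixture velocity for snapshot `i` of a simulation,
#' using the same gradient stencil as the solver.
#'
#' @param sim A `plaque_sim` object.
#' @param i Snapshot index (row of the stored arrays).
#' @return Numeric vector of `v` at the grid nodes.
#' @keywords internal
velocity_snapshot <- function(sim, i) {
  N <- length(sim$y); h <- sim$y[2L] - sim$y[1L]
  grad <- function(u) {
    g <- numeric(N)
    g[2:(N - 1L)] <- (u[3:N] - u[1:(N - 2L)]) / (2 * h)
    g[1L] <- (-3 * u[1L] + 4 * u[2L] - u[3L]) / (2 * h)
    g[N] <- (3 * u[N] - 4 * u[N - 1L] + u[N - 2L]) / (2 * h)
    g
  }
  R <- sim$R[i]
  f <- sim$f[i, ]; l <- sim$l[i, ]; c <- sim$c[i, ]
  mixture_velocity(f, grad(f) / R, grad(l) / R, grad(c) / R,
                   l0 = l[1L], params = sim$params)
}
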