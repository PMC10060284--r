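# Width (in reference timescales) of the Gaussian bead dose: counts rise and
# fall over about six hours.
.dose_width <- 0.035

#' Endothelial bead dose
#'
#' Bead-tagged monocytes are recruited over a brief window around each
#' tagging time; the endothelial bead influx is a unit-peak Gaussian of
#' width 0.035 (about six hours) per dose, summed over doses. Beads enter
#' only with live cells, so the dead-material tracer has zero endothelial
#' influx.
#'
#' @param t Time(s) at which to evaluate the influx.
#' @param t_tag Numeric vector of dose centre times.
#' @return Numeric vector of the bead influx at `t`.
#' @examples
#' bead_dose(1, t_tag = 1)            # peak of the dose
#' bead_dose(1.035, t_tag = 1)        # one width later: exp(-1/2)
#' @export
bead_dose <- function(t, t_tag) {
  vapply(t, function(ti) {
    if (length(t_tag) == 0) return(0)
    sum(exp(-0.5 * ((ti - t_tag) / .dose_width)^2))
  }, numeric(1))
}

# Closure over fixed tag times for the solver RHS.
bead_dose_function <- function(t_tag) {
  force(t_tag)
  function(t) bead_dose(t, t_tag)
}

#' Bead source terms
#'
#' Beads are handed from live foam cells to the dead-material phase when
#' their carrier dies (rate `mu_a`) and recovered by efferocytosis (rate
#' `mu_e f`, the same per-unit rate at which dead material itself is taken
#' up). The two terms cancel exactly, so bead number is locally conserved.
#'
#' @param q_f,q_c Bead densities carried by foam cells and dead material.
#' @param f Foam-cell fraction (same length).
#' @param params A [plaque_params()] object.
#' @return A tibble with columns `s_qf`, `s_qc`.
#' @export
bead_sources <- function(q_f, q_c, f, params) {
  stopifnot(inherits(params, "plaque_params"))
  s <- -params$mu_a * q_f + params$mu_e * f * q_c
  tibble(s_qf = s, s_qc = -s)
}

#' Bead interphase fluxes
#'
#' Beads move with the phase carrying them, so their interphase flux is the
#' carrier's flux scaled by the local bead load: `J_qf = (q_f / f) J_f` and
#' `J_qc = (q_c / c) J_c`. Where the carrier fraction is below `1e-10` the
#' ratio is the 0/0 limit of an absent carrier and the flux is set to zero.
#'
#' @inheritParams bead_sources
#' @param c Dead-material fraction.
#' @param J_f,J_c Interphase fluxes of the carrier phases (see
#'   [phase_fluxes()]).
#' @return A tibble with columns `J_qf`, `J_qc`.
#' @export
bead_fluxes <- function(q_f, q_c, f, c, J_f, J_c) {
  tibble(
    J_qf = ifelse(f > .eps_ratio, q_f / f, 0) * J_f,
    J_qc = ifelse(c > .eps_ratio, q_c / c, 0) * J_c
  )
}

#' Total bead quantity over time
#'
#' Integrates the two bead densities over the current domain,
#' `Q(t) = int_0^R (q_f + q_c) dx`, by the trapezoidal rule on `x = y R(t)`.
#'
#' @param sim A `plaque_sim` from [simulate_plaque()] run with beads.
#' @return A tibble with columns `t`, `Q`, `Q_f`, `Q_c`.
#' @export
total_beads <- function(sim) {
  stopifnot(inherits(sim, "plaque_sim"))
  if (is.null(sim$q_f)) {
    abort("simulation was run without beads", class = "plaquesim_no_beads")
  }
  tibble(
    t = sim$t,
    Q_f = trapz_rows(sim$q_f, sim$y) * sim$R,
    Q_c = trapz_rows(sim$q_c, sim$y) * sim$R,
    Q = .data$Q_f + .data$Q_c
  )[, c("t", "Q", "Q_f", "Q_c")]
}

# Row-wise trapezoid weights on a uniform grid in y (integral over y in
# [0,1]); multiply by R for the x-integral.
trapz_rows <- function(mat, y) {
  h <- y[2L] - y[1L]
  w <- c(h / 2, rep(h, length(y) - 2L), h / 2)
  as.numeric(mat %*% w)
}

#' Bead circulation time (FWHM of the bead pulse)
#'
#' The circulation time of a cohort of tagged cells is summarised as the
#' temporal full width at half maximum of the total bead quantity `Q(t)`:
#' the elapsed time between the first and last instants at which `Q` is at
#' least half its peak, with linear interpolation between stored samples at
#' the two crossings. If `Q` is still at or above half maximum at the end of
#' the record, the width is right-censored and the returned value is the
#' observable lower bound.
#'
#' @param Q_series A tibble/data frame with columns `t` and `Q` (e.g. from
#'   [total_beads()]), or a `plaque_sim` with beads.
#' @return A one-row tibble with columns `t_circ`, `censored` (logical),
#'   `t_lo`, `t_hi` (the two half-maximum crossings) and `Q_peak`.
#' @examples
#' tri <- tibble::tibble(t = seq(0, 2, 0.01), Q = pmax(0, 1 - abs(t - 1)))
#' circulation_time(tri) # FWHM of a unit triangular pulse = 1
#' @export
circulation_time <- function(Q_series) {
  if (inherits(Q_series, "plaque_sim")) Q_series <- total_beads(Q_series)
  t <- Q_series$t; Q <- Q_series$Q
  stopifnot(length(t) == length(Q), !is.unsorted(t))
  peak <- max(Q)
  if (peak <= 0) {
    abort("Q(t) has no positive peak; circulation time undefined",
          class = "plaquesim_undefined_metric")
  }
  half <- 0.5 * peak
  above <- Q >= half
  i_first <- which(above)[1L]
  i_last <- tail(which(above), 1L)
  cross_up <- if (i_first == 1L) t[1L] else {
    interp_crossing(t[i_first - 1L], t[i_first], Q[i_first - 1L], Q[i_first], half)
  }
  censored <- i_last == length(t)
  cross_dn <- if (censored) t[length(t)] else {
    interp_crossing(t[i_last], t[i_last + 1L], Q[i_last], Q[i_last + 1L], half)
  }
  if (censored) {
    warn("Q(t) still at or above half maximum at the end of the record; t_circ is a lower bound",
         class = "plaquesim_censored_metric")
  }
  tibble(t_circ = cross_dn - cross_up, censored = censored,
         t_lo = cross_up, t_hi = cross_dn, Q_peak = peak)
}

interp_crossing <- function(t0, t1, q0, q1, level) {
  if (q1 == q0) return(t0)
  t0 + (level - q0) / (q1 - q0) * (t1 - t0)
}
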