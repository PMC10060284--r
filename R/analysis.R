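#' Phase totals over time
#'
#' Trapezoidal integrals `int_0^R u dx` of each phase per snapshot. By the
#' no-voids condition the three totals sum to the intima width `R(t)` up to
#' the discretisation residual.
#'
#' @param sim A `plaque_sim` object.
#' @return A tibble with columns `t`, `total_f`, `total_l`, `total_c`, `R`.
#' @export
phase_totals <- function(sim) {
  ts <- time_series(sim)
  ts[, c("t", "total_f", "total_l", "total_c", "R")]
}

#' Medial foam-cell density
#'
#' Foam-cell fraction at the medial boundary `x = R(t)`, linearly
#' interpolated in time between stored snapshots. This is the quantity that
#' converges to the deep-plaque ODE steady state `1 - mu_a/mu_e` when
#' efferocytosis outpaces death.
#'
#' @param sim A `plaque_sim` object.
#' @param t Evaluation time(s) within the stored range.
#' @return Numeric vector of `f` at the medial node.
#' @export
medial_density <- function(sim, t) {
  stopifnot(inherits(sim, "plaque_sim"))
  rng <- range(sim$t)
  if (any(t < rng[1] - 1e-12) || any(t > rng[2] + 1e-12)) {
    abort(sprintf("t must lie within the stored range [%g, %g]", rng[1], rng[2]),
          class = "plaquesim_domain_error")
  }
  fR <- sim$f[, ncol(sim$f)]
  approx(sim$t, fR, xout = pmin(pmax(t, rng[1]), rng[2]))$y
}

#' Parameter sweep driver
#'
#' Runs one simulation per combination of the supplied parameter values and
#' collects scalar summaries at an evaluation time: domain width and growth
#' rate, medial foam-cell density, emigration flux and phase totals, plus
#' the bead circulation time when `bead_times` is given. Rows appear in
#' deterministic (grid expansion) order; a failed run is recorded in the
#' `error` column and the sweep continues.
#'
#' @param base A [plaque_params()] object giving the unswept values.
#' @param sweep Named list of numeric vectors, e.g.
#'   `list(mu_e = c(20, 40, 80))`. Names must be `plaque_params` fields. An
#'   empty list runs the base case once.
#' @param config A [solver_config()]; `t_end` must cover `t_eval`.
#' @param t_eval Evaluation time(s) for the scalar readouts. Default: the
#'   configured `t_end`.
#' @param bead_times Optional dose times, passed to [simulate_plaque()].
#' @param max_runs Safety cap on the number of combinations. Default 200.
#' @return A `sweep_result` tibble: one row per (combination, `t_eval`).
#' @examples
#' \donttest{
#' run_sweep(plaque_params(), list(mu_e = c(40, 80)),
#'           solver_config(n_cells = 64, t_end = 0.2))
#' }
#' @export
run_sweep <- function(base, sweep = list(), config = solver_config(),
                      t_eval = NULL, bead_times = NULL, max_runs = 200) {
  stopifnot(inherits(base, "plaque_params"), is.list(sweep))
  if (length(sweep) > 0 && (is.null(names(sweep)) || any(names(sweep) == ""))) {
    abort("`sweep` must be a named list of parameter value vectors",
          class = "plaquesim_invalid_config")
  }
  bad <- setdiff(names(sweep), names(base))
  if (length(bad) > 0) {
    abort(sprintf("unknown sweep parameter(s): %s", paste(bad, collapse = ", ")),
          class = "plaquesim_invalid_config")
  }
  t_eval <- t_eval %||% config$t_end
  stopifnot(all(t_eval >= 0), all(t_eval <= config$t_end))
  grid <- if (length(sweep) == 0) {
    tibble(.row = 1L)
  } else {
    tibble::as_tibble(expand.grid(sweep, KEEP.OUT.ATTRS = FALSE))
  }
  if (nrow(grid) > max_runs) {
    abort(sprintf("sweep would launch %d runs (cap %d)", nrow(grid), max_runs),
          class = "plaquesim_invalid_config")
  }
  rows <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    overrides <- as.list(grid[i, setdiff(names(grid), ".row"), drop = FALSE])
    res <- tryCatch({
      p <- do.call(plaque_params, modifyList(unclass(base), overrides))
      sim <- simulate_plaque(p, config, bead_times = bead_times)
      ts <- time_series(sim)
      interp <- function(col) approx(ts$t, ts[[col]], xout = t_eval)$y
      out <- tibble(
        t_eval = t_eval,
        R = interp("R"), dR_dt = interp("dR_dt"),
        f_medial = interp("f_medial"),
        emigration_flux = interp("flux_emigration"),
        total_f = interp("total_f"), total_l = interp("total_l"),
        total_c = interp("total_c"),
        error = NA_character_
      )
      if (!is.null(bead_times)) {
        tc <- suppressWarnings(circulation_time(sim))
        out$t_circ <- tc$t_circ
        out$t_circ_censored <- tc$censored
      }
      out
    }, error = function(e) {
      tibble(t_eval = t_eval, R = NA_real_, dR_dt = NA_real_,
             f_medial = NA_real_, emigration_flux = NA_real_,
             total_f = NA_real_, total_l = NA_real_, total_c = NA_real_,
             error = conditionMessage(e))
    })
    if (length(overrides) == 0) {
      res
    } else {
      dplyr::bind_cols(tibble::as_tibble(lapply(overrides, rep, nrow(res))), res)
    }
  })
  class(rows) <- c("sweep_result", class(rows))
  rows
}
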