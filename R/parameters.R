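#' Nondimensional model parameters
#'
#' Constructs the set of eleven nondimensional rate and transport constants
#' that define the multiphase plaque model. Defaults are the baseline
#' nondimensional estimates: time is measured in units of one week (the
#' timescale of murine plaque experiments), length in macrophage diameters,
#' and densities as fractions of the close-packed phase density.
#'
#' The parameters are:
#' \describe{
#'   \item{D_f, D_l, D_c}{random-motility / diffusion coefficients of foam
#'     cells, modLDL and dead material.}
#'   \item{chi_l, chi_c}{foam-cell chemotactic sensitivities towards modLDL
#'     and towards dead material.}
#'   \item{mu_a}{foam-cell death rate (apoptosis and necrosis lumped).}
#'   \item{mu_e}{efferocytosis rate per foam cell per unit dead material.}
#'   \item{mu_p}{phagocytosis rate per foam cell per unit modLDL.}
#'   \item{sigma_f}{monocyte recruitment rate per unit endothelial modLDL.}
#'   \item{sigma_l}{endothelial LDL deposition rate.}
#'   \item{sigma_e}{foam-cell egress (emigration) velocity at the medial
#'     boundary.}
#' }
#'
#' `mu_a`, `mu_e` and `sigma_e` are the biologically variable parameters
#' (plausible nondimensional ranges roughly 10--100, 10--200 and 0--100);
#' values outside those ranges are accepted with a warning.
#'
#' @param mu_a Foam-cell death rate. Default 40.
#' @param mu_e Efferocytosis rate. Default 60.
#' @param sigma_e Foam-cell egress velocity. Default 0 (no emigration).
#' @param D_f,D_l,D_c Diffusivities. Defaults 20, 200, 10.
#' @param chi_l,chi_c Chemotactic coefficients. Defaults 1000, 500.
#' @param mu_p Phagocytosis rate. Default 300.
#' @param sigma_f Monocyte recruitment rate. Default 100.
#' @param sigma_l LDL deposition rate. Default 10.
#' @return An object of class `plaque_params`: a named list of the eleven
#'   nondimensional constants.
#' @examples
#' plaque_params()
#' plaque_params(mu_e = 80, sigma_e = 20)
#' @export
plaque_params <- function(mu_a = 40, mu_e = 60, sigma_e = 0,
                          D_f = 20, D_l = 200, D_c = 10,
                          chi_l = 1000, chi_c = 500,
                          mu_p = 300, sigma_f = 100, sigma_l = 10) {
  p <- list(D_f = D_f, D_l = D_l, D_c = D_c,
            chi_l = chi_l, chi_c = chi_c,
            mu_a = mu_a, mu_e = mu_e, mu_p = mu_p,
            sigma_f = sigma_f, sigma_l = sigma_l, sigma_e = sigma_e)
  for (nm in names(p)) {
    val <- p[[nm]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
      abort(sprintf("parameter `%s` must be a single finite number", nm),
            class = "plaquesim_invalid_parameter")
    }
    if (val < 0) {
      abort(sprintf("parameter `%s` must be non-negative (got %g)", nm, val),
            class = "plaquesim_invalid_parameter")
    }
  }
  check_param_ranges(p)
  structure(p, class = "plaque_params")
}

# Plausible nondimensional ranges for the variable parameters; values outside
# are legal but flagged, since the baseline estimates lose meaning far away.
.param_ranges <- list(mu_a = c(10, 100), mu_e = c(10, 200), sigma_e = c(0, 100))

check_param_ranges <- function(p) {
  for (nm in names(.param_ranges)) {
    rng <- .param_ranges[[nm]]
    val <- p[[nm]]
    if (val > rng[2] || (val < rng[1] && val != 0)) {
      warn(sprintf(
        "parameter `%s` = %g is outside the baseline estimate range [%g, %g]",
        nm, val, rng[1], rng[2]), class = "plaquesim_range_warning")
    }
  }
  invisible(p)
}

#' @export
print.plaque_params <- function(x, ...) {
  cat("<plaque_params> nondimensional model parameters\n")
  print(tibble(parameter = names(x), value = unlist(x)), n = length(x))
  invisible(x)
}

#' Dimensional model parameters
#'
#' Holds the dimensional (SI) counterparts of [plaque_params()] together with
#' the reference scales used for nondimensionalisation: `t_S` (reference time,
#' seconds; one week for murine plaque timescales), `x_S` (reference length,
#' metres; one macrophage diameter, 16 micrometres) and `N_0` (close-packed
#' phase density, cells per unit `x_S`).
#'
#' Units: diffusivities `D_f`, `D_l`, `D_c` in m^2/s; chemotactic coefficients
#' `chi_l`, `chi_c` in m^2/s per (cell/`x_S`); `mu_a` in 1/s; `mu_e`, `mu_p`
#' in 1/s per (cell/`x_S`); `sigma_f`, `sigma_e` in m/s; `sigma_l` in
#' (cell/`x_S`) m/s.
#'
#' @param D_f,D_l,D_c,chi_l,chi_c,mu_a,mu_e,mu_p,sigma_f,sigma_l,sigma_e
#'   Dimensional rate/transport constants (see Details for units).
#' @param t_S Reference timescale in seconds (> 0). Default `6e5` (one week).
#' @param x_S Reference length in metres (> 0). Default `1.6e-5`.
#' @param N_0 Maximum phase density, cells per `x_S` (> 0). Default 1.
#' @return An object of class `plaque_dim_params`.
#' @seealso [nondimensionalise()], [redimensionalise()]
#' @export
dimensional_params <- function(D_f, D_l, D_c, chi_l, chi_c,
                               mu_a, mu_e, mu_p, sigma_f, sigma_l, sigma_e,
                               t_S = 6e5, x_S = 1.6e-5, N_0 = 1) {
  p <- list(D_f = D_f, D_l = D_l, D_c = D_c, chi_l = chi_l, chi_c = chi_c,
            mu_a = mu_a, mu_e = mu_e, mu_p = mu_p,
            sigma_f = sigma_f, sigma_l = sigma_l, sigma_e = sigma_e,
            t_S = t_S, x_S = x_S, N_0 = N_0)
  for (nm in names(p)) {
    val <- p[[nm]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
      abort(sprintf("dimensional parameter `%s` must be a single finite number", nm),
            class = "plaquesim_invalid_parameter")
    }
  }
  for (nm in c("t_S", "x_S", "N_0")) {
    if (p[[nm]] <= 0) {
      abort(sprintf("reference scale `%s` must be positive (got %g)", nm, p[[nm]]),
            class = "plaquesim_invalid_parameter")
    }
  }
  if (any(unlist(p) < 0)) {
    abort("dimensional parameters must be non-negative",
          class = "plaquesim_invalid_parameter")
  }
  structure(p, class = "plaque_dim_params")
}

# Rescaling unit for each nondimensional parameter: nondim = dim / unit.
# Rates scale with 1/t_S (linear) or 1/(N_0 t_S) (mass-action per unit
# density); diffusivities with x_S^2/t_S; chemotaxis with x_S^2/(N_0 t_S);
# boundary velocities with x_S/t_S; the LDL deposition flux with N_0 x_S/t_S.
.rescale_units <- function(t_S, x_S, N_0) {
  list(
    D_f = x_S^2 / t_S, D_l = x_S^2 / t_S, D_c = x_S^2 / t_S,
    chi_l = x_S^2 / (N_0 * t_S), chi_c = x_S^2 / (N_0 * t_S),
    mu_a = 1 / t_S,
    mu_e = 1 / (N_0 * t_S), mu_p = 1 / (N_0 * t_S),
    sigma_f = x_S / t_S, sigma_e = x_S / t_S,
    sigma_l = N_0 * x_S / t_S
  )
}

#' Nondimensionalise dimensional parameters
#'
#' Converts a [dimensional_params()] object to the nondimensional
#' [plaque_params()] used by the solver, dividing each rate by its rescaling
#' unit built from the reference time `t_S`, reference length `x_S` and
#' close-packed density `N_0`.
#'
#' @param dim A `plaque_dim_params` object.
#' @return A `plaque_params` object.
#' @examples
#' dp <- dimensional_params(
#'   D_f = 1e-14, D_l = 1e-13, D_c = 5e-15,
#'   chi_l = 4.3e-13, chi_c = 2.1e-13,
#'   mu_a = 40 / 6e5, mu_e = 60 / 6e5, mu_p = 300 / 6e5,
#'   sigma_f = 100 * 1.6e-5 / 6e5, sigma_l = 10 * 1.6e-5 / 6e5,
#'   sigma_e = 0
#' )
#' nondimensionalise(dp)
#' @export
nondimensionalise <- function(dim) {
  if (!inherits(dim, "plaque_dim_params")) {
    abort("`dim` must be a `plaque_dim_params` object",
          class = "plaquesim_invalid_parameter")
  }
  units <- .rescale_units(dim$t_S, dim$x_S, dim$N_0)
  vals <- lapply(names(units), function(nm) dim[[nm]] / units[[nm]])
  names(vals) <- names(units)
  do.call(plaque_params, vals)
}

#' Re-dimensionalise nondimensional parameters
#'
#' Inverse of [nondimensionalise()]: multiplies each nondimensional constant
#' by its rescaling unit to recover dimensional values on the stated
#' reference scales.
#'
#' @param p A `plaque_params` object.
#' @inheritParams dimensional_params
#' @return A `plaque_dim_params` object.
#' @export
redimensionalise <- function(p, t_S = 6e5, x_S = 1.6e-5, N_0 = 1) {
  if (!inherits(p, "plaque_params")) {
    abort("`p` must be a `plaque_params` object",
          class = "plaquesim_invalid_parameter")
  }
  units <- .rescale_units(t_S, x_S, N_0)
  vals <- lapply(names(units), function(nm) p[[nm]] * units[[nm]])
  names(vals) <- names(units)
  do.call(dimensional_params, c(vals, list(t_S = t_S, x_S = x_S, N_0 = N_0)))
}

#' @rdname tidy_plaque
#' @method tidy plaque_params
#' @export
tidy.plaque_params <- function(x, ...) {
  tibble(parameter = names(x), value = unname(unlist(x)))
}
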