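#' Pointwise phase kinetics
#'
#' Evaluates the interphase mass-exchange terms of the mixture model at given
#' phase fractions. Foam cells `f` gain volume by phagocytosis of modLDL
#' (`mu_p f l`) and efferocytosis of dead material (`mu_e f c`) and lose it by
#' death (`mu_a f`); each gain is the matching phase's loss, so the three
#' terms sum to zero and the kinetics conserve mass locally.
#'
#' @param f,l,c Phase fractions (numeric vectors of equal length): foam cells,
#'   modLDL, dead material.
#' @param params A [plaque_params()] object.
#' @return A tibble with columns `s_f`, `s_l`, `s_c`.
#' @examples
#' source_terms(0.5, 0, 0.5, plaque_params(mu_a = 40, mu_e = 80))
#' @export
source_terms <- function(f, l, c, params) {
  stopifnot(inherits(params, "plaque_params"))
  phag <- params$mu_p * f * l
  eff <- params$mu_e * f * c
  death <- params$mu_a * f
  tibble(s_f = phag + eff - death, s_l = -phag, s_c = -eff + death)
}

#' Mixture velocity from the no-voids closure
#'
#' The no-voids condition (phase fractions sum to one) forces the divergence
#' of the total material flux to vanish, which integrates to a closed-form
#' common advective velocity: the endothelial material influx
#' `sigma_f * l0 + sigma_l` minus the sum of the interphase (diffusive and
#' chemotactic) fluxes at each point.
#'
#' @param f Foam-cell fraction at each node.
#' @param df_dx,dl_dx,dc_dx Phase gradients with respect to physical position
#'   `x` (not the mapped coordinate).
#' @param l0 modLDL fraction at the endothelial boundary (`x = 0`).
#' @param params A [plaque_params()] object.
#' @return Numeric vector of the mixture velocity at each node.
#' @examples
#' # no gradients, no endothelial modLDL: plug flow at the deposition rate
#' mixture_velocity(1, 0, 0, 0, l0 = 0, params = plaque_params())
#' @export
mixture_velocity <- function(f, df_dx, dl_dx, dc_dx, l0, params) {
  stopifnot(inherits(params, "plaque_params"))
  params$sigma_f * l0 + params$sigma_l +
    params$D_f * df_dx -
    params$chi_l * f * dl_dx - params$chi_c * f * dc_dx +
    params$D_l * dl_dx + params$D_c * dc_dx
}

#' Interphase and total phase fluxes
#'
#' Computes the non-advective flux of each phase (`J_f`: random motility plus
#' chemotaxis towards modLDL and dead material; `J_l`, `J_c`: Fickian
#' diffusion), the mixture velocity `v` (see [mixture_velocity()]), and the
#' total flux `j_u = J_u + v u` of each phase. When the fractions sum to one,
#' the total fluxes satisfy `j_f + j_l + j_c = sigma_f * l0 + sigma_l`
#' pointwise, the flux-divergence-free identity that defines `v`.
#'
#' @inheritParams mixture_velocity
#' @param l,c modLDL and dead-material fractions at each node.
#' @return A tibble with columns `J_f`, `J_l`, `J_c`, `v`, `j_f`, `j_l`,
#'   `j_c`.
#' @export
phase_fluxes <- function(f, l, c, df_dx, dl_dx, dc_dx, l0, params) {
  stopifnot(inherits(params, "plaque_params"))
  J_f <- -params$D_f * df_dx + params$chi_l * f * dl_dx + params$chi_c * f * dc_dx
  J_l <- -params$D_l * dl_dx
  J_c <- -params$D_c * dc_dx
  v <- mixture_velocity(f, df_dx, dl_dx, dc_dx, l0, params)
  tibble(J_f = J_f, J_l = J_l, J_c = J_c, v = v,
         j_f = J_f + v * f, j_l = J_l + v * l, j_c = J_c + v * c)
}

#' Medial boundary growth rate
#'
#' The intima grows at the net rate of material exchange with its
#' surroundings: endothelial influx of monocytes (`sigma_f * l0`) and LDL
#' (`sigma_l`) minus the emigration flux of foam cells through the medial
#' boundary (`sigma_e * fR`). When the two balance the plaque stabilises.
#'
#' @param l0 modLDL fraction at the endothelium.
#' @param fR Foam-cell fraction at the medial boundary (`x = R`).
#' @param params A [plaque_params()] object.
#' @return The scalar growth rate `dR/dt`.
#' @examples
#' boundary_growth_rate(0.05, 0.5, plaque_params(sigma_e = 20))
#' @export
boundary_growth_rate <- function(l0, fR, params) {
  stopifnot(inherits(params, "plaque_params"))
  params$sigma_f * l0 + params$sigma_l - params$sigma_e * fR
}
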