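#' Plot spatial profiles of a plaque simulation
#'
#' Phase fractions (and bead densities, if present) against physical
#' position, facetted by snapshot time. The growing right-hand edge of each
#' panel is the medial boundary `x = R(t)`.
#'
#' @param object A `plaque_sim` object.
#' @param times Snapshot times to show (nearest stored snapshots). Default:
#'   four times spread over the run.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot plaque_sim
#' @export
autoplot.plaque_sim <- function(object, times = NULL, ...) {
  times <- times %||% seq(min(object$t), max(object$t), length.out = 4)[-1]
  long <- tidy(object, times = times) |>
    tidyr::pivot_longer(dplyr::any_of(c("f", "l", "c", "q_f", "q_c")),
                        names_to = "phase", values_to = "density") |>
    dplyr::mutate(phase = factor(.data$phase,
                                 levels = c("f", "l", "c", "q_f", "q_c"),
                                 labels = c("foam cells", "modLDL",
                                            "dead material", "beads (live)",
                                            "beads (dead)")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$density,
                                     colour = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(signif(.data$t, 3)), scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "position x (macrophage diameters)",
                  y = "phase fraction / bead density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a sweep result
#'
#' One panel per scalar summary against the (first) swept parameter, with
#' additional swept parameters mapped to colour.
#'
#' @param object A `sweep_result` from [run_sweep()].
#' @param y Columns to plot. Default growth rate and medial density.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, y = c("dR_dt", "f_medial"), ...) {
  meta <- c("t_eval", "R", "dR_dt", "f_medial", "emigration_flux",
            "total_f", "total_l", "total_c", "error", "t_circ",
            "t_circ_censored")
  swept <- setdiff(names(object), meta)
  stopifnot(length(swept) >= 1)
  long <- tidyr::pivot_longer(object, dplyr::all_of(y),
                              names_to = "summary", values_to = "value")
  aes <- ggplot2::aes(x = .data[[swept[1]]], y = .data$value)
  if (length(swept) > 1) {
    aes <- utils::modifyList(aes, ggplot2::aes(colour = factor(.data[[swept[2]]])))
  }
  ggplot2::ggplot(long, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$summary), scales = "free_y") +
    ggplot2::labs(x = swept[1],
                  colour = if (length(swept) > 1) swept[2] else NULL) +
    ggplot2::theme_minimal()
}

#' Plot the total bead quantity over time
#'
#' `Q(t)` with the dose windows and the full-width-at-half-maximum interval
#' used for the circulation time.
#'
#' @param sim A `plaque_sim` run with beads.
#' @return A ggplot object.
#' @export
plot_bead_series <- function(sim) {
  qt <- total_beads(sim)
  tc <- suppressWarnings(circulation_time(qt))
  ggplot2::ggplot(qt, ggplot2::aes(x = .data$t, y = .data$Q)) +
    ggplot2::geom_line() +
    ggplot2::annotate("rect", xmin = tc$t_lo, xmax = tc$t_hi,
                      ymin = 0, ymax = tc$Q_peak, alpha = 0.15) +
    ggplot2::geom_vline(xintercept = sim$bead_times, linetype = "dotted") +
    ggplot2::labs(x = "time (reference timescales)",
                  y = "total beads Q(t)") +
    ggplot2::theme_minimal()
}
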