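#' Scenario presets
#'
#' Named parameter/solver presets for the studied scenarios: a baseline
#' efferocytosis-dominant plaque, the four death/efferocytosis--emigration
#' combinations, two emigration regimes (ineffective vs stabilising), and
#' the two bead-tagging scenarios (efficient clearance vs indefinite
#' retention). Preset names index the scenario they reproduce.
#'
#' @return A tibble with columns `preset`, `description` and list-columns
#'   `parameters`, `solver`, `bead_times`.
#' @export
plaque_presets <- function() {
  pr <- list(
    fig2_base = list(
      desc = "baseline: efferocytosis outpaces death, no emigration (early evolution)",
      params = list(mu_a = 40, mu_e = 60, sigma_e = 0),
      solver = list(t_end = 0.1), beads = NULL),
    fig3a = list(
      desc = "poor efferocytosis, no emigration: dead-cell-dominated deep plaque",
      params = list(mu_a = 40, mu_e = 20, sigma_e = 0),
      solver = list(t_end = 1), beads = NULL),
    fig3b = list(
      desc = "poor efferocytosis with emigration: egress starved of live cells",
      params = list(mu_a = 40, mu_e = 20, sigma_e = 30),
      solver = list(t_end = 1), beads = NULL),
    fig3c = list(
      desc = "efficient efferocytosis, no emigration: coexistence deep plaque",
      params = list(mu_a = 40, mu_e = 80, sigma_e = 0),
      solver = list(t_end = 1), beads = NULL),
    fig3d = list(
      desc = "efficient efferocytosis with emigration",
      params = list(mu_a = 40, mu_e = 80, sigma_e = 30),
      solver = list(t_end = 1), beads = NULL),
    fig8a = list(
      desc = "emigration ineffective: few live cells reach the media",
      params = list(mu_a = 40, mu_e = 20, sigma_e = 40),
      solver = list(t_end = 3), beads = NULL),
    fig8b = list(
      desc = "emigration stabilises the plaque at high egress velocity",
      params = list(mu_a = 40, mu_e = 80, sigma_e = 80),
      solver = list(t_end = 3), beads = NULL),
    fig10_beads = list(
      desc = "bead tagging, efficient clearance: tagged cells transit and emigrate",
      params = list(mu_a = 40, mu_e = 80, sigma_e = 20),
      solver = list(t_end = 3), beads = 1.0),
    fig13_beads = list(
      desc = "bead tagging, poor efferocytosis: beads retained indefinitely",
      params = list(mu_a = 40, mu_e = 30, sigma_e = 40),
      solver = list(t_end = 3), beads = c(0.5, 1.5, 2.5))
  )
  tibble(
    preset = names(pr),
    description = vapply(pr, `[[`, character(1), "desc"),
    parameters = lapply(pr, `[[`, "params"),
    solver = lapply(pr, `[[`, "solver"),
    bead_times = lapply(pr, `[[`, "beads")
  )
}

.valid_solver_keys <- c("n_cells", "t_end", "output_times", "rtol", "atol",
                        "advection", "tol_voids", "tol_neg", "method", "seed")
.valid_scenario_keys <- c("preset", "bead_times", "run_id")

#' Load a run configuration
#'
#' Reads a YAML configuration with up to three sections -- `parameters`,
#' `solver` and `scenario` -- and merges it onto the defaults in the order
#' defaults < preset < file < `overrides`. Unknown keys in any section are
#' an error; parameter values outside the baseline estimate ranges are
#' accepted with a warning.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param overrides Named list applied last; parameter names (e.g. `mu_e`)
#'   and solver names (e.g. `n_cells`, `t_end`) are routed to their section.
#' @param preset Optional preset name (see [plaque_presets()]), used when the
#'   file does not set one.
#' @return A list with elements `params` ([plaque_params()]), `config`
#'   ([solver_config()]), `bead_times` (or `NULL`) and `run_id`.
#' @export
load_config <- function(path = NULL, overrides = list(), preset = NULL) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(sprintf("config file not found: %s", path),
            class = "plaquesim_invalid_config")
    }
    raw <- yaml::read_yaml(path) %||% list()
  }
  bad_sections <- setdiff(names(raw), c("parameters", "solver", "scenario"))
  if (length(bad_sections) > 0) {
    abort(sprintf("unknown config section(s): %s (valid: parameters, solver, scenario)",
                  paste(bad_sections, collapse = ", ")),
          class = "plaquesim_invalid_config")
  }
  check_keys <- function(section, valid, where) {
    bad <- setdiff(names(section), valid)
    if (length(bad) > 0) {
      abort(sprintf("unknown key(s) in [%s]: %s (valid: %s)", where,
                    paste(bad, collapse = ", "), paste(valid, collapse = ", ")),
            class = "plaquesim_invalid_config")
    }
  }
  par_keys <- names(formals(plaque_params))
  check_keys(raw$parameters, par_keys, "parameters")
  check_keys(raw$solver, .valid_solver_keys, "solver")
  check_keys(raw$scenario, .valid_scenario_keys, "scenario")

  preset_name <- raw$scenario$preset %||% preset
  par <- list(); slv <- list(); beads <- NULL
  if (!is.null(preset_name)) {
    tab <- plaque_presets()
    hit <- match(preset_name, tab$preset)
    if (is.na(hit)) {
      abort(sprintf("unknown preset '%s' (valid: %s)", preset_name,
                    paste(tab$preset, collapse = ", ")),
            class = "plaquesim_invalid_config")
    }
    par <- tab$parameters[[hit]]
    slv <- tab$solver[[hit]]
    beads <- tab$bead_times[[hit]]
  }
  par <- modifyList(par, raw$parameters %||% list())
  slv <- modifyList(slv, raw$solver %||% list())
  if (!is.null(raw$scenario$bead_times)) beads <- raw$scenario$bead_times

  ov_par <- overrides[intersect(names(overrides), par_keys)]
  ov_slv <- overrides[intersect(names(overrides), .valid_solver_keys)]
  ov_other <- setdiff(names(overrides), c(par_keys, .valid_solver_keys, "bead_times"))
  if (length(ov_other) > 0) {
    abort(sprintf("unknown override(s): %s", paste(ov_other, collapse = ", ")),
          class = "plaquesim_invalid_config")
  }
  par <- modifyList(par, ov_par)
  slv <- modifyList(slv, ov_slv)
  if (!is.null(overrides$bead_times)) beads <- overrides$bead_times

  list(
    params = do.call(plaque_params, par),
    config = do.call(solver_config, slv),
    bead_times = beads,
    run_id = raw$scenario$run_id %||% preset_name %||% "run"
  )
}

fmt_num <- function(x) {
  # fixed scientific formatting, 12 significant digits, for byte-stable tables
  ifelse(is.na(x), "NA", formatC(x, digits = 11, format = "e"))
}

write_table <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- fmt_num(out[[nm]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write simulation outputs
#'
#' Writes the deterministic file set for a run into `dir`:
#' `{run_id}_series.tsv` (scalar time series), `{run_id}_profiles.tsv`
#' (long-format spatial snapshots with a self-describing header) and
#' `{run_id}_config.yaml` (echo of the effective configuration). Bead runs
#' additionally produce `{run_id}_beads.tsv` (the `Q(t)` series) and
#' `{run_id}_tcirc.tsv`. Numeric columns use fixed scientific notation with
#' 12 significant digits so identical runs reproduce byte-identical tables.
#'
#' @param sim A `plaque_sim`, or a `sweep_result` (written as a single
#'   `{run_id}_sweep.tsv`).
#' @param dir Output directory (created if needed).
#' @param run_id File-name stem.
#' @param profile_times Optional snapshot times to keep in the profile table
#'   (default: all stored snapshots).
#' @return Invisibly, a tibble manifest with columns `file` and `content`.
#' @export
write_outputs <- function(sim, dir, run_id = "run", profile_times = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  add <- function(path, what) manifest[[length(manifest) + 1L]] <<- tibble(file = path, content = what)
  if (inherits(sim, "sweep_result")) {
    add(write_table(sim, file.path(dir, paste0(run_id, "_sweep.tsv"))), "sweep table")
  } else {
    stopifnot(inherits(sim, "plaque_sim"))
    add(write_table(time_series(sim), file.path(dir, paste0(run_id, "_series.tsv"))),
        "scalar time series")
    add(write_table(tidy(sim, times = profile_times),
                    file.path(dir, paste0(run_id, "_profiles.tsv"))),
        "spatial profiles")
    echo <- list(
      parameters = unclass(sim$params),
      solver = sim$config[c("n_cells", "t_end", "rtol", "atol", "advection",
                            "tol_voids", "tol_neg", "method")],
      scenario = list(run_id = run_id,
                      bead_times = if (!is.null(sim$bead_times)) as.numeric(sim$bead_times))
    )
    cfg_path <- file.path(dir, paste0(run_id, "_config.yaml"))
    yaml::write_yaml(echo, cfg_path)
    add(cfg_path, "configuration echo")
    if (!is.null(sim$q_f)) {
      add(write_table(total_beads(sim), file.path(dir, paste0(run_id, "_beads.tsv"))),
          "total bead series")
      tc <- suppressWarnings(circulation_time(sim))
      add(write_table(tc, file.path(dir, paste0(run_id, "_tcirc.tsv"))),
          "circulation time")
    }
  }
  invisible(dplyr::bind_rows(manifest))
}
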