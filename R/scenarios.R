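# Scenario registry: the named simulation cases of the study, i.e. the two
# lipid-independent base cases and every lipid-dependent row of the
# monotonic and peaked modulation tables, with their published unscaled
# steady-state G values and scaling values.

scenario_table <- function() {
  rows <- list(
    list(name = "base_rho0", behaviour = "none", form = "constant", rho = 0,
         G_unscaled = 1, scaling = 1),
    list(name = "base_rho05", behaviour = "none", form = "constant", rho = 0.5,
         G_unscaled = 1, scaling = 1),
    # monotonic (saturating) modulations
    list(name = "apoptosis_s_a15_d2", behaviour = "apoptosis", form = "saturating",
         a_half = 15, limit = 2, exponent = 2, rho = 0,
         G_unscaled = 1.188, scaling = 0.86),
    list(name = "apoptosis_s_a12_d3", behaviour = "apoptosis", form = "saturating",
         a_half = 12, limit = 3, exponent = 2, rho = 0,
         G_unscaled = 1.576, scaling = 0.72),
    list(name = "apoptosis_s_a9_d4", behaviour = "apoptosis", form = "saturating",
         a_half = 9, limit = 4, exponent = 2, rho = 0,
         G_unscaled = 2.367, scaling = 0.565),
    list(name = "apoptosis_s_a12_d3_rho05", behaviour = "apoptosis",
         form = "saturating", a_half = 12, limit = 3, exponent = 2, rho = 0.5,
         G_unscaled = 1.445, scaling = 0.76),
    list(name = "emigration_s_a12", behaviour = "emigration", form = "saturating",
         a_half = 12, limit = 0.1, exponent = 1.5, rho = 0,
         G_unscaled = 0.6902, scaling = 1.38),
    list(name = "emigration_s_a18", behaviour = "emigration", form = "saturating",
         a_half = 18, limit = 0.1, exponent = 1.5, rho = 0,
         G_unscaled = 0.7812, scaling = 1.25),
    list(name = "emigration_s_a24", behaviour = "emigration", form = "saturating",
         a_half = 24, limit = 0.1, exponent = 1.5, rho = 0,
         G_unscaled = 0.8340, scaling = 1.18),
    list(name = "emigration_s_a18_rho05", behaviour = "emigration",
         form = "saturating", a_half = 18, limit = 0.1, exponent = 1.5, rho = 0.5,
         G_unscaled = 0.7650, scaling = 1.25),
    list(name = "proliferation_s_a4", behaviour = "proliferation",
         form = "saturating", a_half = 4, limit = 0, exponent = 2, rho = 0.5,
         G_unscaled = 0.6377, scaling = 1.47),
    list(name = "proliferation_s_a9", behaviour = "proliferation",
         form = "saturating", a_half = 9, limit = 0, exponent = 2, rho = 0.5,
         G_unscaled = 0.8070, scaling = 1.22),
    list(name = "proliferation_s_a14", behaviour = "proliferation",
         form = "saturating", a_half = 14, limit = 0, exponent = 2, rho = 0.5,
         G_unscaled = 0.8675, scaling = 1.15),
    # peaked (non-monotone) emigration
    list(name = "emigration_r_b3", behaviour = "emigration", form = "peaked",
         floor = 0.1, scale_loc = 3, rise_exp = 1, fall_exp = 2, rho = 0,
         G_unscaled = 0.5736, scaling = 1.9),
    list(name = "emigration_r_b6", behaviour = "emigration", form = "peaked",
         floor = 0.1, scale_loc = 6, rise_exp = 1, fall_exp = 2, rho = 0,
         G_unscaled = 0.5418, scaling = 1.99),
    list(name = "emigration_r_b9", behaviour = "emigration", form = "peaked",
         floor = 0.1, scale_loc = 9, rise_exp = 1, fall_exp = 2, rho = 0,
         G_unscaled = 0.4964, scaling = 2.08)
  )
  names(rows) <- vapply(rows, `[[`, "", "name")
  rows
}

#' List the named scenarios
#'
#' @return data frame describing the scenario registry: the two base cases
#'   and every lipid-dependent modulation row, with the published unscaled
#'   steady-state `G` value and scaling value for each.
#' @export
list_scenarios <- function() {
  rows <- scenario_table()
  data.frame(
    name = names(rows),
    behaviour = vapply(rows, `[[`, "", "behaviour"),
    form = vapply(rows, `[[`, "", "form"),
    rho = vapply(rows, `[[`, 0, "rho"),
    G_unscaled = vapply(rows, `[[`, 0, "G_unscaled"),
    scaling = vapply(rows, `[[`, 0, "scaling"),
    row.names = NULL)
}

#' Retrieve a modulation from the scenario registry
#'
#' @param name a registry row name, e.g. `"apoptosis_s_a12_d3"`.
#' @param scaled apply the published scaling value (default `FALSE`).
#' @return a [rate_modulation()].
#' @export
scenario_modulation <- function(name, scaled = FALSE) {
  row <- scenario_table()[[name]]
  if (is.null(row)) stop(sprintf("unknown scenario '%s'", name), call. = FALSE)
  if (row$behaviour == "none")
    stop("base-case scenarios have no lipid-dependent modulation", call. = FALSE)
  scl <- if (scaled) row$scaling else 1
  if (row$form == "saturating")
    rate_modulation(row$behaviour, "saturating", a_half = row$a_half,
                    limit = row$limit, exponent = row$exponent, scaling = scl)
  else
    rate_modulation(row$behaviour, "peaked", floor = row$floor,
                    scale_loc = row$scale_loc, rise_exp = row$rise_exp,
                    fall_exp = row$fall_exp, scaling = scl)
}

#' Build a named scenario
#'
#' Assembles the full configuration for one registry entry: model
#' parameters with the (optionally scaled) modulation in place, a lipid
#' grid sized for the scenario (emigration scenarios produce heavy-tailed
#' distributions and use an extended domain), integrator settings and the
#' initial-condition width.
#'
#' @param name registry row name (see [list_scenarios()]).
#' @param scaled apply the published scaling value.
#' @param a_max,n_nodes grid overrides; defaults depend on the scenario
#'   (`a_max = 1000` for lipid-dependent emigration, 300 otherwise).
#' @param h0,a_fine grid refinement overrides (see [make_grid()]).
#' @param a_sigma initial half-normal width (default 1).
#' @param settings an [integrator_settings()]; the default horizon covers
#'   the slowest published case.
#' @return an object of class `plaque_scenario`.
#' @export
scenario <- function(name, scaled = FALSE, a_max = NULL, n_nodes = NULL,
                     h0 = NULL, a_fine = 15,
                     a_sigma = 1, settings = integrator_settings()) {
  row <- scenario_table()[[name]]
  if (is.null(row)) stop(sprintf("unknown scenario '%s'", name), call. = FALSE)
  mods <- list()
  if (row$behaviour != "none") {
    mod <- scenario_modulation(name, scaled = scaled)
    mods[[c(apoptosis = "g_beta", emigration = "g_gamma",
            proliferation = "g_rho")[[row$behaviour]]]] <- mod
  }
  params <- do.call(model_parameters, c(list(rho = row$rho), mods))
  if (is.null(a_max)) a_max <- if (row$behaviour == "emigration") 1000 else 300
  if (is.null(n_nodes)) n_nodes <- if (a_max > 500) 1600 else 1200
  # emigration scenarios have heavy tails: spend less of the node budget on
  # the boundary layer and more on the tail (see the methods vignette)
  if (is.null(h0)) h0 <- if (row$behaviour == "emigration") 0.15 else 0.05
  structure(list(name = name, scaled = scaled, params = params,
                 grid_spec = list(a_max = a_max, n_nodes = n_nodes,
                                  h0 = h0, a_fine = a_fine),
                 a_sigma = a_sigma, settings = settings,
                 G_printed = row$G_unscaled, scaling_printed = row$scaling),
            class = "plaque_scenario")
}

#' @export
print.plaque_scenario <- function(x, ...) {
  cat(sprintf("<plaque_scenario> %s%s  (a_max=%g, n=%d, a_sigma=%g)\n",
              x$name, if (x$scaled) " [scaled]" else "",
              x$grid_spec$a_max, x$grid_spec$n_nodes, x$a_sigma))
  invisible(x)
}

#' Run a scenario to steady state
#'
#' Builds the grid and initial state, checks boundedness and integrates to
#' steady state.
#'
#' @param sc a [scenario()] (or a registry name).
#' @param mode passed to [integrate_plaque()].
#' @param ... overrides passed to [scenario()] when `sc` is a name.
#' @return a `plaque_trajectory`.
#' @export
run_scenario <- function(sc, mode = "to_steady", ...) {
  if (is.character(sc)) sc <- scenario(sc, ...)
  stopifnot(inherits(sc, "plaque_scenario"))
  grid <- do.call(make_grid, sc$grid_spec)
  state <- initial_state(sc$params, grid, sc$a_sigma)
  integrate_plaque(state, sc$params, sc$settings, mode = mode)
}

#' Reproduce the published unscaled G and scaling tables
#'
#' Runs each lipid-dependent registry row to steady state with the
#' unscaled modulation and compares the computed population-averaged
#' `G(inf)` against the published value; optionally also calibrates the
#' scaling value and compares it with the published column.
#'
#' @param rows registry names (default: all lipid-dependent rows).
#' @param calibrate also recover the scaling values (slow).
#' @param n_nodes,a_max,h0 optional grid overrides applied to every row
#'   (smaller/coarser values trade accuracy for speed).
#' @param settings an [integrator_settings()].
#' @param verbose print progress.
#' @return data frame with computed and published values and relative
#'   errors.
#' @export
reproduce_tables <- function(rows = NULL, calibrate = FALSE, n_nodes = NULL,
                             a_max = NULL, h0 = 0.05,
                             settings = integrator_settings(),
                             verbose = TRUE) {
  reg <- list_scenarios()
  if (is.null(rows)) rows <- reg$name[reg$behaviour != "none"]
  out <- lapply(rows, function(nm) {
    sc <- scenario(nm, scaled = FALSE, n_nodes = n_nodes, a_max = a_max,
                   h0 = h0, settings = settings)
    if (verbose) message("running ", nm, " (unscaled) ...")
    traj <- run_scenario(sc)
    ss <- steady_state_summary(traj)
    gname <- paste0("G_", c(apoptosis = "beta", emigration = "gamma",
                            proliferation = "rho")[[reg$behaviour[reg$name == nm]]])
    Gc <- ss[[gname]]
    res <- data.frame(name = nm, G_computed = Gc, G_printed = sc$G_printed,
                      G_rel_err = Gc / sc$G_printed - 1,
                      scaling_computed = NA_real_,
                      scaling_printed = sc$scaling_printed,
                      scaling_rel_err = NA_real_)
    if (calibrate) {
      if (verbose) message("calibrating ", nm, " ...")
      grid <- do.call(make_grid, sc$grid_spec)
      cal <- calibrate_scaling(sc$params, grid, settings)
      res$scaling_computed <- cal$scaling
      res$scaling_rel_err <- cal$scaling / sc$scaling_printed - 1
    }
    res
  })
  do.call(rbind, out)
}
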