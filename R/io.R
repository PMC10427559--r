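# Structured-text (JSON) scenario configurations and run artefact writers.

mod_to_config <- function(mod) {
  keep <- setdiff(names(mod), c("behaviour", "form", "scaling"))
  c(list(behaviour = mod$behaviour, form = mod$form, scaling = mod$scaling),
    mod[keep])
}

mod_from_config <- function(cfg) {
  do.call(rate_modulation, cfg)
}

#' Write a scenario configuration file
#'
#' Serialises a [scenario()] (parameters, modulations, grid and integrator
#' settings, initial-condition width) to pretty-printed JSON. The
#' round-trip `read_scenario_config(write_scenario_config(sc))`
#' reconstructs an identical scenario.
#'
#' @param sc a [scenario()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(sc, path) {
  stopifnot(inherits(sc, "plaque_scenario"))
  p <- sc$params
  cfg <- list(
    name = sc$name, scaled = sc$scaled,
    parameters = list(gamma = p$gamma, kappa = p$kappa, rho = p$rho,
                      nu = p$nu, lam = p$lam, theta = p$theta, eta = p$eta),
    modulations = lapply(p$mods, mod_to_config),
    a_sigma = sc$a_sigma,
    grid = sc$grid_spec,
    integrator = unclass(sc$settings))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a scenario configuration file
#'
#' @param path a JSON file written by [write_scenario_config()] (or
#'   hand-edited in the same schema).
#' @return a [scenario()] object.
#' @export
read_scenario_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  mods <- lapply(cfg$modulations, mod_from_config)
  params <- do.call(model_parameters, c(cfg$parameters, mods))
  settings <- do.call(integrator_settings, cfg$integrator)
  structure(list(name = cfg$name, scaled = isTRUE(cfg$scaled), params = params,
                 grid_spec = cfg$grid, a_sigma = cfg$a_sigma,
                 settings = settings,
                 G_printed = NA_real_, scaling_printed = NA_real_),
            class = "plaque_scenario")
}

#' Write run artefacts
#'
#' Writes the scalar time series (`<prefix>_trajectory.csv`), the final
#' densities both unnormalised and as probability densities
#' (`<prefix>_distributions.csv`), and a flat summary record with
#' convergence metadata (`<prefix>_summary.json`).
#'
#' @param traj a [integrate_plaque()] trajectory.
#' @param prefix output path prefix (directories must exist).
#' @return character vector of the files written, invisibly.
#' @export
write_trajectory <- function(traj, prefix) {
  stopifnot(inherits(traj, "plaque_trajectory"))
  f_traj <- paste0(prefix, "_trajectory.csv")
  f_dist <- paste0(prefix, "_distributions.csv")
  f_summ <- paste0(prefix, "_summary.json")
  utils::write.csv(traj$summary, f_traj, row.names = FALSE)
  st <- traj$state
  momm <- moments(st$m, st$grid); momp <- moments(st$p, st$grid)
  utils::write.csv(data.frame(a = st$grid$nodes, m = st$m, p = st$p,
                              m_pdf = st$m / momm[[1]],
                              p_pdf = st$p / max(momp[[1]], .Machine$double.xmin)),
                   f_dist, row.names = FALSE)
  ss <- steady_state_summary(traj)
  rec <- unclass(ss)
  rec$G_raw <- as.list(rec$G_raw)
  rec$grid <- list(a_max = st$grid$a_max, n_nodes = length(st$grid$nodes),
                   h_min = st$grid$h_min, refinement = st$grid$refinement)
  rec$n_reject <- traj$n_reject
  jsonlite::write_json(rec, f_summ, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(f_traj, f_dist, f_summ))
}
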