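# Memoised scenario runs shared across test files (several acceptance
# criteria interrogate the same steady states; run each once per session).
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, fun) {
  if (!exists(key, envir = .run_cache)) assign(key, fun(), envir = .run_cache)
  get(key, envir = .run_cache)
}

# Steady run of a registry scenario. The shipped default resolution is
# n = 1200, h0 = 0.05; most criteria here run reduced grids (500-700
# nodes, h0 up to 0.2) to fit the test budget, which costs 1-3% accuracy
# against published values quoted at ~5% tolerance. The base cases are
# checked at the shipped defaults.
test_run <- function(name, n_nodes, a_max = NULL, h0 = 0.05,
                     steady_tol = 1e-5, t_max = 2600, a_sigma = 1) {
  key <- paste(name, n_nodes, a_max %||% "def", h0, a_sigma, sep = "_")
  cached_run(key, function() {
    sc <- scenario(name, a_max = a_max, n_nodes = n_nodes, h0 = h0,
                   a_sigma = a_sigma,
                   settings = integrator_settings(t_max = t_max,
                                                  steady_tol = steady_tol))
    run_scenario(sc)
  })
}

# the two base cases at shipped default resolution (steady_tol 1e-6)
base_run_default <- function(rho) {
  key <- paste0("base_default_rho", rho)
  cached_run(key, function() {
    params <- model_parameters(rho = rho)
    grid <- make_grid(300, 1200)
    integrate_plaque(initial_state(params, grid, 1), params,
                     integrator_settings(t_max = 600))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
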