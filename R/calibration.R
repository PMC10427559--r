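#' Calibrate a modulation scaling to a unit population-averaged rate
#'
#' Scaled scenarios multiply the lipid-dependent modulation by a constant
#' chosen so that the steady-state population-averaged rate of the
#' modulated behaviour matches the reference rate:
#' `G(inf) = integral g m da / M = 1`, accepted when within `tol`
#' (default 0.01, i.e. `G = 1 +/- 0.01`). Each trial scaling requires a
#' full integration to steady state; trials are warm-started from the
#' previous steady state, and the first guess is `1/G_unscaled`, which is
#' typically already close. The root is found by secant iteration with a
#' bisection safeguard (G is empirically monotone in the scaling).
#'
#' The behaviour-specific application of the scaling (division of the
#' emigration limit, peaked floor preservation) is handled inside
#' [eval_modulation()]; the calibration only varies the scalar.
#'
#' @param params a [model_parameters()] with exactly one non-constant
#'   modulation (the calibration target).
#' @param grid a [make_grid()] grid.
#' @param settings an [integrator_settings()].
#' @param a_sigma initial-condition width for the cold start.
#' @param tol acceptance half-width on `G` (default 0.01).
#' @param max_iter iteration cap (default 25).
#' @param bracket optional length-2 scaling bracket; default
#'   `1/G_unscaled * c(0.5, 1.5)`.
#' @param verbose print per-iteration progress.
#' @return an object of class `calibration_result`: `scaling`,
#'   `achieved_G`, `iterations`, `history` (data frame of trials),
#'   `params` with the calibrated scaling applied, and the final
#'   trajectory.
#' @export
calibrate_scaling <- function(params, grid, settings = integrator_settings(),
                              a_sigma = 1, tol = 0.01, max_iter = 25,
                              bracket = NULL, verbose = FALSE) {
  stopifnot(inherits(params, "model_parameters"))
  forms <- vapply(params$mods, function(m) m$form, "")
  target <- names(forms)[forms != "constant"]
  if (length(target) == 0) {
    # constant modulations already have unit population-averaged rate
    traj <- integrate_plaque(initial_state(params, grid, a_sigma), params,
                             settings, mode = "to_steady")
    return(structure(list(scaling = 1, achieved_G = 1, iterations = 0L,
                          history = data.frame(scaling = 1, G = 1),
                          params = params, trajectory = traj),
                     class = "calibration_result"))
  }
  if (length(target) > 1)
    stop("calibration requires exactly one non-constant modulation", call. = FALSE)
  gcol <- c(g_beta = "G_beta_norm", g_gamma = "G_gamma_norm",
            g_rho = "G_rho_norm")[[target]]

  state <- initial_state(params, grid, a_sigma)
  history <- data.frame(scaling = numeric(0), G = numeric(0))
  evalG <- function(scl, warm) {
    p2 <- params
    p2$mods[[target]]$scaling <- scl
    bd <- check_boundedness(p2, grid)
    if (!bd$ok)
      stop(sprintf("trial scaling %.4g violates the boundedness condition (min %.4g at a=%.4g)",
                   scl, bd$min_value, bd$arg_min), call. = FALSE)
    traj <- integrate_plaque(warm, p2, settings, mode = "to_steady")
    G <- traj$summary[[gcol]][nrow(traj$summary)]
    history[nrow(history) + 1L, ] <<- c(scl, G)
    if (verbose)
      message(sprintf("  scaling %.5f -> G = %.5f (t = %g)", scl, G, traj$state$t))
    list(G = G, traj = traj, params = p2)
  }

  # unscaled run gives the first guess c ~ 1/G_unscaled
  e0 <- evalG(params$mods[[target]]$scaling, state)
  c0 <- params$mods[[target]]$scaling
  if (abs(e0$G - 1) <= tol) {
    return(structure(list(scaling = c0, achieved_G = e0$G,
                          iterations = 1L, history = history,
                          params = e0$params, trajectory = e0$traj),
                     class = "calibration_result"))
  }
  if (is.null(bracket)) bracket <- (c0 / e0$G) * c(0.5, 1.5)
  c1 <- c0 / e0$G
  e1 <- evalG(c1, e0$traj$state)
  # maintain a sign-changing bracket on G - 1 when we have one
  lo <- NULL; hi <- NULL
  note <- function(scl, G) {
    if (G > 1) lo <<- c(scl, G) else hi <<- c(scl, G)
  }
  note(c0, e0$G); note(c1, e1$G)
  prev <- list(scl = c0, G = e0$G); cur <- list(scl = c1, G = e1$G)
  best <- e1
  it <- 2L
  while (abs(cur$G - 1) > tol && it < max_iter) {
    if (abs(cur$G - prev$G) > 1e-12) {
      cand <- cur$scl + (1 - cur$G) * (cur$scl - prev$scl) / (cur$G - prev$G)
    } else cand <- NA_real_
    in_bracket <- !is.na(cand) && cand > 0 &&
      (is.null(lo) || is.null(hi) ||
         (cand > min(lo[1], hi[1]) && cand < max(lo[1], hi[1])))
    if (!in_bracket) {
      if (!is.null(lo) && !is.null(hi)) cand <- (lo[1] + hi[1]) / 2
      else if (is.na(cand) || cand <= 0) cand <- cur$scl * if (cur$G > 1) 0.8 else 1.25
    }
    e <- evalG(cand, best$traj$state)
    note(cand, e$G)
    prev <- cur; cur <- list(scl = cand, G = e$G)
    best <- e
    it <- it + 1L
  }
  if (abs(cur$G - 1) > tol)
    stop(sprintf("calibration did not reach |G - 1| <= %.3g in %d iterations (last G = %.4g)",
                 tol, it, cur$G), call. = FALSE)
  structure(list(scaling = cur$scl, achieved_G = cur$G, iterations = it,
                 history = history, params = best$params,
                 trajectory = best$traj),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> scaling=%.4f, G=%.4f (%d steady-state runs)\n",
              x$scaling, x$achieved_G, nrow(x$history)))
  invisible(x)
}
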