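#' Integrator settings
#'
#' Controls for the explicit method-of-lines integrator: a Heun (RK2)
#' scheme with embedded Euler error estimate, step size capped by the
#' advective CFL condition on the finest grid spacing.
#'
#' Steady state is declared when the largest relative rate of change of the
#' scalar summaries (M, P, A_M, A_P, N) stays below `steady_tol` per unit
#' dimensionless time for a continuous span of `steady_window`, once past
#' the transient `t_min_steady`.
#'
#' @param dt_max hard cap on the time step.
#' @param cfl advective Courant factor in (0, 1].
#' @param t_max integration horizon (dimensionless time).
#' @param steady_tol relative rate-of-change threshold per unit time.
#' @param steady_window span over which the threshold must hold.
#' @param t_min_steady earliest time at which steady state may be declared.
#' @param tail_tol maximum allowed fraction of the live population M in the
#'   last 5% of the lipid domain; exceeding it indicates the domain
#'   truncation is biting.
#' @param sample_dt interval at which scalar summaries are logged.
#' @param rtol,atol relative/absolute local error tolerances for step
#'   adaptation (the CFL cap usually binds first).
#' @return an object of class `integrator_settings`.
#' @export
integrator_settings <- function(dt_max = 0.5, cfl = 0.6, t_max = 2500,
                                steady_tol = 1e-6, steady_window = 20,
                                t_min_steady = 50, tail_tol = 5e-3,
                                sample_dt = 0.5, rtol = 1e-4, atol = 1e-10) {
  vals <- c(dt_max, cfl, t_max, steady_tol, steady_window, t_min_steady,
            tail_tol, sample_dt, rtol, atol)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all integrator settings must be finite and positive", call. = FALSE)
  if (cfl > 1) stop("'cfl' must be <= 1", call. = FALSE)
  structure(list(dt_max = dt_max, cfl = cfl, t_max = t_max,
                 steady_tol = steady_tol, steady_window = steady_window,
                 t_min_steady = t_min_steady, tail_tol = tail_tol,
                 sample_dt = sample_dt, rtol = rtol, atol = atol),
            class = "integrator_settings")
}

#' Advection speed of lipid accumulation
#'
#' Live cells gain lipid by LDL ingestion distributed over the population
#' (`lam/M`) plus necrotic-lipid consumption (`theta N`); the speed is the
#' same at every lipid load.
#'
#' @param state a [plaque_state()].
#' @param params a [model_parameters()].
#' @return the positive scalar advection speed.
#' @export
advection_speed <- function(state, params) {
  M <- moments(state$m, state$grid)[[1]]
  if (M <= 0) stop("live population collapsed (M <= 0)", call. = FALSE)
  params$lam / M + params$theta * state$N
}

#' Efferocytosis convolution source
#'
#' The rate density of live cells appearing at lipid load `a` through
#' engulfment of a whole apoptotic cell:
#' `q(a) = integral_1^(a-1) m(a') p(a - a') da'`, interpreted as 0 for
#' `a <= 2` (both participants carry at least the endogenous lipid).
#' The rate factor `eta` is applied by the caller.
#'
#' Discretely the integral is evaluated by composite trapezoid over the
#' grid nodes with the second density linearly interpolated off-node
#' (direct order n-squared with a plan precomputed per grid). Events whose
#' combined load exceeds `a_max` generate no source; on domains where that
#' pair mass is non-negligible the lipid ledger reflects the truncation.
#'
#' @param m,p non-negative densities on `grid$nodes`.
#' @param grid a [make_grid()] grid.
#' @return the convolution evaluated on the grid nodes.
#' @export
efferocytosis_convolution <- function(m, p, grid) {
  stopifnot(inherits(grid, "lipid_grid"),
            length(m) == length(grid$nodes), length(p) == length(grid$nodes))
  .cpp_convolve(as.numeric(m), as.numeric(p), grid$nodes)
}

doubling_map <- function(grid) {
  a <- grid$nodes
  y <- 2 * a - 1
  n <- length(a)
  idx <- findInterval(y, a)          # a[idx] <= y < a[idx+1]
  frac <- numeric(n)
  ok <- y <= grid$a_max
  idx[!ok] <- -1L                    # parent lipid load beyond the domain
  j <- which(ok)
  jj <- pmin(idx[j], n - 1L)
  frac[j] <- (y[j] - a[jj]) / (a[jj + 1L] - a[jj])
  idx[j] <- jj
  list(idx = as.integer(idx - 1L), frac = frac, parent = y, ok = ok)
}

#' Proliferation source term
#'
#' Daughter cells with lipid load `a` are produced by parents with load
#' `2a - 1` (the parent's lipid is split equally and each daughter carries
#' one unit of endogenous lipid). Returns
#' `4 g_rho(2a - 1) m(2a - 1)` with `m` linearly interpolated and taken as
#' 0 where `2a - 1 > a_max`; the rate factor `rho` is applied by the
#' caller.
#'
#' @param m non-negative live density on `grid$nodes`.
#' @param g_rho the proliferation [rate_modulation()].
#' @param grid a [make_grid()] grid.
#' @return the source density on the grid nodes.
#' @export
proliferation_source <- function(m, g_rho, grid) {
  stopifnot(inherits(grid, "lipid_grid"), length(m) == length(grid$nodes))
  dbl <- doubling_map(grid)
  out <- numeric(length(m))
  j <- which(dbl$ok)
  k <- dbl$idx[j] + 1L
  m_par <- (1 - dbl$frac[j]) * m[k] + dbl$frac[j] * m[k + 1L]
  out[j] <- 4 * eval_modulation(dbl$parent[j], g_rho) * m_par
  out
}

#' Recruitment flux at the boundary
#'
#' The rate at which new macrophages enter at minimum lipid load, a
#' saturating function of the accumulated lipid of the live population:
#' `F = (A_M - M) / (kappa + A_M - M)`, with dimensionless maximum 1 and
#' half-maximum when `A_M - M = kappa`.
#'
#' @param M,A_M live population zeroth and first moments (`A_M >= M`).
#' @param kappa half-maximal recruitment lipid content.
#' @return the flux in `[0, 1)`.
#' @export
recruitment_flux <- function(M, A_M, kappa) {
  x <- A_M - M
  if (any(x < -1e-8 * pmax(abs(A_M), 1)))
    stop("corrupt state: A_M < M (accumulated lipid cannot be negative)",
         call. = FALSE)
  x <- pmax(x, 0)
  x / (kappa + x)
}

#' Boundary density of newly recruited cells
#'
#' The inflow value `m(1) = F / speed` implied by equating the advective
#' flux at the minimum lipid load with the recruitment flux.
#'
#' @inheritParams advection_speed
#' @return the live density at `a = 1`.
#' @export
boundary_density <- function(state, params) {
  mom <- moments(state$m, state$grid)
  recruitment_flux(mom[[1]], mom[[2]], params$kappa) /
    advection_speed(state, params)
}

modulation_vectors <- function(params, grid) {
  a <- grid$nodes
  dbl <- doubling_map(grid)
  grho2a <- numeric(length(a))
  j <- which(dbl$ok)
  grho2a[j] <- 4 * eval_modulation(dbl$parent[j], params$mods$g_rho)
  list(gb = eval_modulation(a, params$mods$g_beta),
       gg = eval_modulation(a, params$mods$g_gamma),
       gr = eval_modulation(a, params$mods$g_rho),
       grho2a = grho2a, dbl_idx = dbl$idx, dbl_frac = dbl$frac)
}

#' Time derivatives of the full state
#'
#' Evaluates the semi-discrete right-hand side: conservative upwind
#' (MUSCL-limited) advection with the recruitment flux entering as the
#' inflow at `a = 1`, the efferocytosis convolution, the proliferation
#' doubling source, the lipid-modulated sink terms, the apoptotic balance
#' `dp/dt = g_beta m - (nu + eta M) p`, and `dN/dt = nu A_P - theta M N`.
#' All modulations are evaluated with their scalings applied.
#'
#' @inheritParams advection_speed
#' @return a list with `dm`, `dp`, `dN`, the advection `speed`, the
#'   recruitment flux `F`, and the convolution `conv`.
#' @export
plaque_rhs <- function(state, params) {
  grid <- state$grid
  mv <- modulation_vectors(params, grid)
  out <- .cpp_rhs(state$m, state$p, state$N, grid$nodes, grid$weights,
                  mv$gb, mv$gg, mv$gr, mv$grho2a, mv$dbl_idx, mv$dbl_frac,
                  params$gamma, params$kappa, params$rho, params$nu,
                  params$lam, params$theta, params$eta)
  if (any(!is.finite(out$dm)) || any(!is.finite(out$dp)) || !is.finite(out$dN))
    stop("non-finite right-hand side; integration failure", call. = FALSE)
  out
}

status_labels <- c(`0` = "converged", `1` = "max_time", `2` = "collapse",
                   `3` = "negativity")

#' Integrate the plaque model
#'
#' Advances the coupled system from a given state either to a fixed time
#' (`mode = "to_time"`) or until the steady-state criterion of
#' [integrator_settings()] is met (`mode = "to_steady"`). Refuses to start
#' if the boundedness condition fails (the live population would grow
#' without bound). Scalar summaries (moments, total lipid, per-cell
#' averages, modulated-rate functionals, recruitment flux, advection speed
#' and the tail mass fraction) are logged every `sample_dt`.
#'
#' @param state initial [plaque_state()] (see [initial_state()]).
#' @param params a [model_parameters()].
#' @param settings an [integrator_settings()].
#' @param mode `"to_steady"` (default) or `"to_time"`.
#' @return an object of class `plaque_trajectory`: list with `summary`
#'   (data frame of logged scalars, including normalised per-cell
#'   `G_*_norm` columns), final `state`, `status` (`"converged"`,
#'   `"max_time"`), `dynamics` classification (see [classify_dynamics()]),
#'   and run metadata.
#' @export
integrate_plaque <- function(state, params, settings = integrator_settings(),
                             mode = c("to_steady", "to_time")) {
  mode <- match.arg(mode)
  stopifnot(inherits(state, "plaque_state"), inherits(params, "model_parameters"),
            inherits(settings, "integrator_settings"))
  grid <- state$grid
  bd <- check_boundedness(params, grid)
  if (!bd$ok)
    stop(sprintf(paste0("boundedness condition violated: g_beta + gamma*g_gamma",
                        " - rho*g_rho = %.4g <= 0 at a = %.4g; the live",
                        " population would grow without bound"),
                 bd$min_value, bd$arg_min), call. = FALSE)
  mv <- modulation_vectors(params, grid)
  res <- .cpp_integrate(state$m, state$p, state$N, state$t,
                        grid$nodes, grid$weights,
                        mv$gb, mv$gg, mv$gr, mv$grho2a, mv$dbl_idx, mv$dbl_frac,
                        params$gamma, params$kappa, params$rho, params$nu,
                        params$lam, params$theta, params$eta,
                        settings$t_max, settings$dt_max, settings$cfl,
                        settings$steady_tol, settings$steady_window,
                        settings$t_min_steady, settings$sample_dt,
                        mode == "to_steady", settings$rtol, settings$atol,
                        1e-12, 1e-8)
  if (res$status == 2)
    stop("live population collapsed (M <= 0) during integration", call. = FALSE)
  if (res$status == 3)
    stop("density became significantly negative; integration aborted", call. = FALSE)
  summ <- as.data.frame(res$summary)
  for (g in c("G_beta", "G_beta_a", "G_gamma", "G_gamma_a", "G_rho", "G_rho_a"))
    summ[[paste0(g, "_norm")]] <- summ[[g]] / summ$M
  final <- plaque_state(t = res$t, m = pmax(res$m, 0), p = pmax(res$p, 0),
                        N = max(res$N, 0), grid = grid)
  status <- status_labels[[as.character(res$status)]]
  if (mode == "to_time" && status == "converged") status <- "completed"
  traj <- structure(list(summary = summ, state = final, params = params,
                         settings = settings, mode = mode, status = status,
                         n_steps = res$n_steps, n_reject = res$n_reject),
                    class = "plaque_trajectory")
  traj$dynamics <- classify_dynamics(traj)
  tail_frac <- summ$tail_frac[nrow(summ)]
  traj$tail_frac <- tail_frac
  if (is.finite(tail_frac) && tail_frac > settings$tail_tol) {
    msg <- sprintf(paste0("tail mass fraction %.3g exceeds tail_tol %.3g: ",
                          "the lipid domain is too short; rebuild the grid ",
                          "with a larger a_max"), tail_frac, settings$tail_tol)
    if (mode == "to_steady") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  if (mode == "to_steady" && status != "converged") {
    warning(sprintf(paste0("no steady state by t = %g (status: %s, dynamics: %s);",
                           " increase t_max or inspect the trajectory"),
                    settings$t_max, status, traj$dynamics$regime), call. = FALSE)
  }
  traj
}

#' @export
print.plaque_trajectory <- function(x, ...) {
  s <- x$summary[nrow(x$summary), ]
  cat(sprintf("<plaque_trajectory> %s, status=%s, t=%g (%d samples, %g steps)\n",
              x$mode, x$status, x$state$t, nrow(x$summary), x$n_steps))
  cat(sprintf("  final: M=%.4g P=%.4g A_M=%.4g A_P=%.4g N=%.4g L=%.4g\n",
              s$M, s$P, s$A_M, s$A_P, s$N, s$L))
  cat(sprintf("  dynamics: %s (%d crossings)\n",
              x$dynamics$regime, x$dynamics$crossings))
  invisible(x)
}

#' Classify the transient dynamics of a trajectory
#'
#' Inspects the logged live-population series M(t) after the initial
#' transient: counts sign changes of dM/dt (ignoring changes below a noise
#' floor) and checks whether the oscillation envelope decays. Regimes:
#' `"monotone_settling"` (fewer than 4 crossings), `"decaying_oscillation"`
#' (at least 4 crossings with a shrinking envelope), or
#' `"sustained_oscillation"`.
#'
#' @param traj a [integrate_plaque()] trajectory.
#' @param t_transient samples before this time are ignored (default 50).
#' @return list with `regime`, `crossings`, and `envelope_ratio` (late to
#'   early oscillation amplitude; NA when not oscillatory).
#' @export
classify_dynamics <- function(traj, t_transient = 50) {
  s <- traj$summary
  s <- s[s$t >= t_transient, , drop = FALSE]
  if (nrow(s) < 5)
    return(list(regime = "monotone_settling", crossings = 0L,
                envelope_ratio = NA_real_))
  M <- s$M
  dM <- diff(M)
  # the floor separates integrator noise near the steady-state tolerance
  # (per-sample changes of order steady_tol * M) from genuine slow
  # oscillations, whose per-sample changes are far larger
  floor_noise <- max(1e-5 * max(abs(M)), 1e-12)
  sgn <- sign(dM)
  sgn[abs(dM) < floor_noise] <- 0
  sgn <- sgn[sgn != 0]
  crossings <- if (length(sgn) > 1) sum(diff(sgn) != 0) else 0L
  if (crossings < 4)
    return(list(regime = "monotone_settling", crossings = as.integer(crossings),
                envelope_ratio = NA_real_))
  # envelope: deviation from the final value at the turning points
  dev <- abs(M - M[length(M)])
  turn <- which(diff(sign(diff(M))) != 0) + 1L
  amp <- dev[turn]
  amp <- amp[amp > floor_noise]
  ratio <- if (length(amp) >= 4) {
    half <- floor(length(amp) / 2)
    mean(utils::tail(amp, half)) / mean(utils::head(amp, half))
  } else NA_real_
  regime <- if (!is.na(ratio) && ratio < 0.9) "decaying_oscillation"
            else "sustained_oscillation"
  list(regime = regime, crossings = as.integer(crossings),
       envelope_ratio = ratio)
}
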