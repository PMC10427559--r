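#' Zeroth and first moments of a density
#'
#' Trapezoidal quadrature of `density` and `a * density` over the lipid
#' grid: the population count and its total lipid content.
#'
#' @param density non-negative values on `grid$nodes`.
#' @param grid a [make_grid()] grid.
#' @return numeric vector `c(zeroth, first)`.
#' @export
moments <- function(density, grid) {
  stopifnot(inherits(grid, "lipid_grid"), length(density) == length(grid$nodes))
  c(zeroth = sum(grid$weights * density),
    first = sum(grid$weights * grid$nodes * density))
}

#' Modulated-rate functionals
#'
#' `G = integral g(a) m(a) da` and `G_a = integral g(a) a m(a) da`, with
#' the modulation's scaling applied. For a constant modulation these reduce
#' to the plain moments `(M, A_M)`. Dividing by `M` gives the
#' population-averaged rate (the quantity the scaled scenarios calibrate
#' to 1).
#'
#' @param m live density on `grid$nodes`.
#' @param mod a [rate_modulation()].
#' @param grid a [make_grid()] grid.
#' @return numeric vector `c(G, G_a)`.
#' @export
g_functionals <- function(m, mod, grid) {
  stopifnot(inherits(grid, "lipid_grid"), length(m) == length(grid$nodes))
  g <- eval_modulation(grid$nodes, mod)
  c(G = sum(grid$weights * g * m),
    G_a = sum(grid$weights * g * grid$nodes * m))
}

#' Distribution of emigration events and removed lipid
#'
#' Pointwise products `g_gamma(a) m(a)` (emigration event density) and
#' `g_gamma(a) a m(a)` (density of lipid removed by emigration); their
#' integrals are `G_gamma` and `G_gamma_a`, and the ratio
#' `G_gamma_a / G_gamma` is the average lipid removed per emigrating cell.
#'
#' @inheritParams g_functionals
#' @param mod the emigration [rate_modulation()].
#' @return list with `events`, `lipid` (densities on the grid),
#'   `G`, `G_a`, and `mean_lipid_removed`.
#' @export
emigration_profiles <- function(m, mod, grid) {
  g <- eval_modulation(grid$nodes, mod)
  events <- g * m
  lipid <- g * grid$nodes * m
  G <- sum(grid$weights * events)
  Ga <- sum(grid$weights * lipid)
  list(events = events, lipid = lipid, G = G, G_a = Ga,
       mean_lipid_removed = Ga / G)
}

#' Steady-state summary of a trajectory
#'
#' Scalar summaries at the end of a run: moments, necrotic lipid, total
#' lipid `L = A_M + A_P + N`, per-cell averages, recruitment flux, and the
#' modulated-rate functionals both unnormalised (`G_*`) and as per-cell
#' averages (`G_*_norm`, the convention of the scaled scenarios where the
#' base case value is 1).
#'
#' @param traj a [integrate_plaque()] trajectory.
#' @return an object of class `steady_state_summary`.
#' @export
steady_state_summary <- function(traj) {
  stopifnot(inherits(traj, "plaque_trajectory"))
  s <- traj$summary[nrow(traj$summary), ]
  out <- list(M = s$M, P = s$P, A_M = s$A_M, A_P = s$A_P, N = s$N, L = s$L,
              abar_M = s$Abar_M, abar_P = s$Abar_P, F = s$F,
              G_beta = s$G_beta_norm, G_beta_a = s$G_beta_a_norm,
              G_gamma = s$G_gamma_norm, G_gamma_a = s$G_gamma_a_norm,
              G_rho = s$G_rho_norm, G_rho_a = s$G_rho_a_norm,
              G_raw = c(beta = s$G_beta, beta_a = s$G_beta_a,
                        gamma = s$G_gamma, gamma_a = s$G_gamma_a,
                        rho = s$G_rho, rho_a = s$G_rho_a),
              status = if (traj$status == "converged" &&
                           traj$dynamics$regime != "monotone_settling")
                         "oscillatory-converged" else traj$status,
              dynamics = traj$dynamics$regime,
              t_final = traj$state$t, tail_frac = traj$tail_frac,
              n_steps = traj$n_steps)
  class(out) <- "steady_state_summary"
  out
}

#' @export
print.steady_state_summary <- function(x, ...) {
  cat(sprintf("<steady_state_summary> status=%s t=%g\n", x$status, x$t_final))
  cat(sprintf("  M=%.4g P=%.4g A_M=%.4g A_P=%.4g N=%.4g L=%.4g\n",
              x$M, x$P, x$A_M, x$A_P, x$N, x$L))
  cat(sprintf("  Abar_M=%.4g Abar_P=%.4g F=%.4g\n", x$abar_M, x$abar_P, x$F))
  cat(sprintf("  G (per-cell): beta=%.4g gamma=%.4g rho=%.4g\n",
              x$G_beta, x$G_gamma, x$G_rho))
  invisible(x)
}

#' Residual checks for a steady state
#'
#' Returns named residuals that should vanish at a genuine steady state:
#' the stationarity of the moment equations for M, A_M, P, A_P and N
#' (evaluated independently from the final densities, not from the
#' integrator), the apoptotic-average identity `abar_P = G_beta_a/G_beta`
#' (per-cell G), and, when `rho = 0` and emigration is unmodulated, the
#' per-cell lipid balance
#' `lam/M + theta N + eta A_P - (F/M)(abar_M - 1) + abar_M G_beta - G_beta_a = 0`
#' (per-cell G's; with unmodulated apoptosis `G_beta = 1`).
#'
#' @param traj a converged [integrate_plaque()] trajectory.
#' @return named numeric vector of residuals (relative where the quantity
#'   has a natural scale).
#' @export
steady_residuals <- function(traj) {
  stopifnot(inherits(traj, "plaque_trajectory"))
  st <- traj$state; params <- traj$params; grid <- st$grid
  w <- grid$weights; a <- grid$nodes
  momm <- moments(st$m, grid); momp <- moments(st$p, grid)
  M <- momm[[1]]; A_M <- momm[[2]]; P <- momp[[1]]; A_P <- momp[[2]]; N <- st$N
  gb <- g_functionals(st$m, params$mods$g_beta, grid)
  gg <- g_functionals(st$m, params$mods$g_gamma, grid)
  gr <- g_functionals(st$m, params$mods$g_rho, grid)
  Fl <- recruitment_flux(M, A_M, params$kappa)
  dM <- Fl + params$rho * gr[[1]] - gb[[1]] - params$gamma * gg[[1]]
  dAM <- Fl + params$lam + params$theta * M * N + params$eta * M * A_P +
    params$rho * gr[[1]] - gb[[2]] - params$gamma * gg[[2]]
  remv <- params$nu + params$eta * M
  dP <- gb[[1]] - remv * P
  dAP <- gb[[2]] - remv * A_P
  dN <- params$nu * A_P - params$theta * M * N
  res <- c(dM = dM / M, dA_M = dAM / A_M, dP = dP / P, dA_P = dAP / A_P,
           dN = dN / max(N, 1e-8),
           abar_P = (A_P / P - gb[[2]] / gb[[1]]) / (A_P / P))
  if (params$rho == 0 && params$mods$g_gamma$form == "constant") {
    bal <- params$lam / M + params$theta * N + params$eta * A_P -
      (Fl / M) * (A_M / M - 1) + (A_M / M) * (gb[[1]] / M) - gb[[2]] / M
    res <- c(res, lipid_balance = bal / (A_M / M))
  }
  res
}

#' Analytic steady state of the lipid-independent model
#'
#' When all three modulations are constant the moment equations close and
#' the steady state solves a quadratic: with survival margin
#' `s = 1 + gamma - rho`,
#' `s M^2 + (s (gamma kappa + lam) - 1) M - lam = 0`, then
#' `A_M = ((1 + gamma) M + lam)/gamma`, `P = M/(nu + eta M)`,
#' `A_P = A_M/(nu + eta M)`, `N = nu A_P/(theta M)`. Used as an
#' independent oracle for the PDE solver.
#'
#' @param params a [model_parameters()] (modulations must be constant).
#' @return named numeric vector with `M`, `P`, `A_M`, `A_P`, `N`, `L`,
#'   `abar_M`, `abar_P`, `F`.
#' @export
lipid_independent_steady <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  if (any(vapply(params$mods, function(m) m$form, "") != "constant"))
    stop("closed-form steady state requires all modulations constant", call. = FALSE)
  g <- params$gamma; k <- params$kappa; r <- params$rho
  lam <- params$lam; nu <- params$nu; eta <- params$eta; th <- params$theta
  s <- 1 + g - r
  if (s <= 0) stop("boundedness violated: 1 + gamma - rho <= 0", call. = FALSE)
  A <- s; B <- s * (g * k + lam) - 1; C <- -lam
  M <- (-B + sqrt(B^2 - 4 * A * C)) / (2 * A)
  A_M <- ((1 + g) * M + lam) / g
  P <- M / (nu + eta * M)
  A_P <- A_M / (nu + eta * M)
  N <- nu * A_P / (th * M)
  c(M = M, P = P, A_M = A_M, A_P = A_P, N = N, L = A_M + A_P + N,
    abar_M = A_M / M, abar_P = A_P / P,
    F = recruitment_flux(M, A_M, k))
}

#' Lipid-independent moment ODE system (independent oracle)
#'
#' Integrates the closed five-variable moment system
#' `dM = F + rho M - M - gamma M`,
#' `dA_M = F + lam + theta M N + eta M A_P + rho M - A_M - gamma A_M`,
#' `dP = M - (nu + eta M) P`, `dA_P = A_M - (nu + eta M) A_P`,
#' `dN = nu A_P - theta M N`
#' with classical fixed-step RK4. Valid only when all modulations are
#' constant; used to cross-check the PDE moments.
#'
#' @param params a [model_parameters()] with constant modulations.
#' @param init named vector with `M`, `P`, `A_M`, `A_P`, `N` at `t = 0`.
#' @param t_max horizon; `dt` fixed step; `sample_dt` output interval.
#' @return data frame of the sampled solution.
#' @export
lipid_independent_ode <- function(params, init, t_max = 200, dt = 0.005,
                                  sample_dt = 0.5) {
  stopifnot(inherits(params, "model_parameters"))
  if (any(vapply(params$mods, function(m) m$form, "") != "constant"))
    stop("moment closure requires constant modulations", call. = FALSE)
  g <- params$gamma; k <- params$kappa; r <- params$rho
  lam <- params$lam; nu <- params$nu; eta <- params$eta; th <- params$theta
  f <- function(y) {
    M <- y[1]; P <- y[2]; A_M <- y[3]; A_P <- y[4]; N <- y[5]
    Fl <- (A_M - M) / (k + A_M - M)
    c(Fl + r * M - M - g * M,
      M - (nu + eta * M) * P,
      Fl + lam + th * M * N + eta * M * A_P + r * M - A_M - g * A_M,
      A_M - (nu + eta * M) * A_P,
      nu * A_P - th * M * N)
  }
  y <- c(init[["M"]], init[["P"]], init[["A_M"]], init[["A_P"]], init[["N"]])
  nstep <- ceiling(t_max / dt)
  keep_every <- max(1L, round(sample_dt / dt))
  out <- matrix(NA_real_, nrow = floor(nstep / keep_every) + 1L, ncol = 6)
  out[1, ] <- c(0, y)
  row <- 1L
  for (i in seq_len(nstep)) {
    k1 <- f(y); k2 <- f(y + dt / 2 * k1); k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (i %% keep_every == 0) {
      row <- row + 1L
      out[row, ] <- c(i * dt, y)
    }
  }
  out <- out[seq_len(row), , drop = FALSE]
  colnames(out) <- c("t", "M", "P", "A_M", "A_P", "N")
  as.data.frame(out)
}

#' Lipid-ledger residual along a trajectory
#'
#' On the full lipid domain the total system lipid `L = A_M + A_P + N`
#' obeys `dL/dt = F + lam + rho G_rho - gamma G_gamma_a` (unnormalised
#' G's): recruitment and net LDL influx add lipid, emigration removes it,
#' and each division adds one unit of structural lipid. On the truncated
#' computational domain two further outflows act and are logged with the
#' trajectory: lipid advected out through `a_max`, and the lipid deficit
#' of the efferocytosis convolution (events with combined load beyond
#' `a_max` generate no source). Compares a five-point finite difference of
#' the logged `L` against the logged right-hand side including the
#' truncation fluxes, and returns the residual per sample relative to the
#' gross flux throughput.
#'
#' @param traj a [integrate_plaque()] trajectory.
#' @return data frame with `t`, `dL_dt` (finite difference), `rhs`, and
#'   `rel_residual`.
#' @export
lipid_ledger <- function(traj) {
  s <- traj$summary
  n <- nrow(s)
  if (n < 5) stop("trajectory too short for finite differencing", call. = FALSE)
  # five-point fourth-order stencil: the transient curvature of L would
  # otherwise dominate the residual through differencing error alone
  dt <- diff(s$t)
  i <- which(seq_len(n) >= 3 & seq_len(n) <= n - 2)
  uniform <- abs(dt - dt[1]) < 1e-9 * dt[1]
  i <- i[uniform[i - 2] & uniform[i - 1] & uniform[i] & uniform[i + 1]]
  h <- dt[1]
  dL <- (s$L[i - 2] - 8 * s$L[i - 1] + 8 * s$L[i + 1] - s$L[i + 2]) / (12 * h)
  rhs <- s$F[i] + traj$params$lam + traj$params$rho * s$G_rho[i] -
    traj$params$gamma * s$G_gamma_a[i] -
    s$outflow_lipid[i] + traj$params$eta * s$conv_lipid_deficit[i]
  # the identity balances fluxes of order one against each other; measure
  # the imbalance against the gross flux throughput (the natural scale,
  # and non-vanishing at steady state where both sides tend to zero)
  gross <- s$F[i] + traj$params$lam + traj$params$rho * abs(s$G_rho[i]) +
    traj$params$gamma * abs(s$G_gamma_a[i])
  scale <- pmax(abs(rhs), abs(dL), gross)
  data.frame(t = s$t[i], dL_dt = dL, rhs = rhs,
             rel_residual = (dL - rhs) / scale)
}
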