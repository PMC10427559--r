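#' Dimensionless model parameters
#'
#' Container for the dimensionless kinetic constants of the plaque model
#' together with the three lipid-dependent rate modulations. Time is
#' measured in units of the reference macrophage apoptosis timescale, lipid
#' in units of the endogenous per-cell lipid `a_0`, and cell numbers in
#' units of the maximal recruitment rate over the apoptosis rate, so the
#' dimensionless reference apoptosis rate and maximal recruitment rate are
#' both 1 and the minimum lipid load is 1.
#'
#' Defaults are the base-case parameterisation: `gamma = 0.2`,
#' `kappa = 25/6`, `rho = 0`, `nu = 1`, `lam = 0.1`, `theta = 0.6`,
#' `eta = 9.6`, with all three modulations constant.
#'
#' @param gamma reference emigration rate (relative to apoptosis).
#' @param kappa accumulated live-cell lipid `A_M - M` giving half-maximal
#'   recruitment.
#' @param rho reference proliferation rate (`rho >= 0`).
#' @param nu post-apoptotic (secondary) necrosis rate per apoptotic cell.
#' @param lam net LDL-minus-HDL lipid influx rate (`lam > 0`; a positive
#'   net influx is necessary for a plaque to form).
#' @param theta necrotic-lipid consumption rate per live cell.
#' @param eta efferocytosis rate per (live cell, apoptotic cell) pair.
#' @param g_beta,g_gamma,g_rho [rate_modulation()] objects for apoptosis,
#'   emigration and proliferation (default: constant).
#'
#' @return an object of class `model_parameters`.
#' @export
model_parameters <- function(gamma = 0.2, kappa = 25/6, rho = 0, nu = 1,
                             lam = 0.1, theta = 0.6, eta = 9.6,
                             g_beta = rate_modulation("apoptosis", "constant"),
                             g_gamma = rate_modulation("emigration", "constant"),
                             g_rho = rate_modulation("proliferation", "constant")) {
  vals <- c(gamma = gamma, kappa = kappa, nu = nu, lam = lam,
            theta = theta, eta = eta)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("gamma, kappa, nu, lam, theta, eta must all be finite and > 0",
         call. = FALSE)
  if (!is.finite(rho) || rho < 0) stop("'rho' must be >= 0", call. = FALSE)
  for (m in list(g_beta, g_gamma, g_rho))
    stopifnot(inherits(m, "rate_modulation"))
  if (g_beta$behaviour != "apoptosis" || g_gamma$behaviour != "emigration" ||
      g_rho$behaviour != "proliferation")
    stop("modulations must be assigned to their matching behaviours", call. = FALSE)
  structure(list(gamma = gamma, kappa = kappa, rho = rho, nu = nu,
                 lam = lam, theta = theta, eta = eta,
                 mods = list(g_beta = g_beta, g_gamma = g_gamma, g_rho = g_rho)),
            class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters> (dimensionless)\n")
  cat(sprintf("  gamma=%g kappa=%g rho=%g nu=%g lam=%g theta=%g eta=%g\n",
              x$gamma, x$kappa, x$rho, x$nu, x$lam, x$theta, x$eta))
  for (m in x$mods) if (m$form != "constant") print(m)
  invisible(x)
}

#' Dimensional model parameters
#'
#' Per-hour rates and per-cell quantities as estimated from the
#' experimental literature: apoptosis `beta` and secondary necrosis
#' `nu_dim` (both 0.05/h), emigration `gamma_dim` (0.01/h), maximal
#' recruitment `alpha` (1e4 cells/h), efferocytosis `eta_dim`
#' (2.4e-6 /cell/h) and necrotic consumption `theta_dim` (1.5e-7 /cell/h).
#' `a0` is the endogenous lipid per cell; `lam_dim` (lipid/h) and
#' `kappa_dim` (lipid) default to values consistent with the dimensionless
#' base case.
#'
#' @param beta apoptosis rate, per hour.
#' @param nu_dim secondary necrosis rate, per hour.
#' @param gamma_dim emigration rate, per hour.
#' @param alpha maximal recruitment rate, cells per hour.
#' @param eta_dim efferocytosis rate, per cell per hour.
#' @param theta_dim necrotic consumption rate, per cell per hour.
#' @param a0 endogenous lipid content per cell (sets the lipid unit).
#' @param lam_dim net LDL-HDL lipid influx, lipid units per hour.
#' @param kappa_dim half-maximal recruitment lipid content, lipid units.
#' @return an object of class `dimensional_parameters`.
#' @export
dimensional_parameters <- function(beta = 0.05, nu_dim = 0.05, gamma_dim = 0.01,
                                   alpha = 1e4, eta_dim = 2.4e-6,
                                   theta_dim = 1.5e-7, a0 = 1,
                                   lam_dim = 0.1 * a0 * alpha,
                                   kappa_dim = (25/6) * a0 * alpha / beta) {
  vals <- c(beta, nu_dim, gamma_dim, alpha, eta_dim, theta_dim, a0,
            lam_dim, kappa_dim)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all dimensional parameters must be finite and > 0", call. = FALSE)
  structure(list(beta = beta, nu_dim = nu_dim, gamma_dim = gamma_dim,
                 alpha = alpha, eta_dim = eta_dim, theta_dim = theta_dim,
                 a0 = a0, lam_dim = lam_dim, kappa_dim = kappa_dim),
            class = "dimensional_parameters")
}

#' Nondimensionalise dimensional parameters
#'
#' Applies the scalings `gamma = gamma_dim/beta`,
#' `kappa = kappa_dim beta/(a0 alpha)`, `rho = rho_dim/beta`,
#' `nu = nu_dim/beta`, `lam = lam_dim/(a0 alpha)`,
#' `theta = theta_dim alpha/beta^2`, `eta = eta_dim alpha/beta^2`.
#'
#' @param dim a [dimensional_parameters()] object.
#' @param rho_dim dimensional proliferation rate, per hour (default 0).
#' @param ... modulations passed on to [model_parameters()].
#' @return a [model_parameters()] object.
#' @export
nondimensionalise <- function(dim, rho_dim = 0, ...) {
  stopifnot(inherits(dim, "dimensional_parameters"))
  b <- dim$beta
  model_parameters(gamma = dim$gamma_dim / b,
                   kappa = dim$kappa_dim * b / (dim$a0 * dim$alpha),
                   rho = rho_dim / b,
                   nu = dim$nu_dim / b,
                   lam = dim$lam_dim / (dim$a0 * dim$alpha),
                   theta = dim$theta_dim * dim$alpha / b^2,
                   eta = dim$eta_dim * dim$alpha / b^2,
                   ...)
}

#' Construct a lipid grid
#'
#' Builds a strictly increasing grid of dimensionless lipid loads on
#' `[1, a_max]` with trapezoidal quadrature weights. The default
#' `"stretched"` refinement keeps a uniform fine spacing `h0` on
#' `[1, a_fine]` (where the density varies fastest and the inflow boundary
#' sits) and coarsens geometrically towards `a_max`; `"uniform"` spaces all
#' nodes equally.
#'
#' @param a_max right edge of the truncated lipid domain (`>= 50`).
#' @param n_nodes total number of nodes (`>= 200`).
#' @param refinement `"stretched"` (default) or `"uniform"`.
#' @param h0 fine spacing near `a = 1` for the stretched grid; the default
#'   0.05 keeps the boundary region fully resolved, coarser values (up to
#'   0.5) trade accuracy for speed.
#' @param a_fine right edge of the uniformly fine region.
#' @return an object of class `lipid_grid` with fields `nodes`, `weights`,
#'   `a_max`, `h_min`.
#' @export
make_grid <- function(a_max = 300, n_nodes = 1200,
                      refinement = c("stretched", "uniform"),
                      h0 = 0.05, a_fine = 15) {
  refinement <- match.arg(refinement)
  if (a_max < 50) stop("'a_max' must be >= 50", call. = FALSE)
  if (n_nodes < 200) stop("'n_nodes' must be >= 200", call. = FALSE)
  if (refinement == "uniform") {
    nodes <- seq(1, a_max, length.out = n_nodes)
  } else {
    # the shipped default h0 = 0.05 keeps the boundary region fully
    # resolved; coarser spacings trade accuracy for speed (the advective
    # CFL step scales with h0) and are intended for exploratory runs
    if (h0 > 0.5) stop("'h0' must be <= 0.5", call. = FALSE)
    if (a_fine <= 1 || a_fine >= a_max) stop("need 1 < a_fine < a_max", call. = FALSE)
    n_fine <- ceiling((a_fine - 1) / h0)
    if (n_fine + 2L > n_nodes)
      stop("'n_nodes' too small for the requested fine region", call. = FALSE)
    fine <- seq(1, by = h0, length.out = n_fine + 1L)
    n_geo <- n_nodes - length(fine)        # geometric intervals
    span <- a_max - fine[length(fine)]
    # solve h0 * (r + r^2 + ... + r^n_geo) = span for growth ratio r
    f <- function(r) {
      if (abs(r - 1) < 1e-12) return(h0 * n_geo - span)
      h0 * r * (r^n_geo - 1) / (r - 1) - span
    }
    if (f(1) >= 0) {
      r <- 1  # enough nodes to cover the tail uniformly at h0
      geo <- fine[length(fine)] + h0 * seq_len(n_geo)
    } else {
      r <- stats::uniroot(f, c(1 + 1e-10, 1.5), tol = 1e-14)$root
      geo <- fine[length(fine)] + cumsum(h0 * r^seq_len(n_geo))
    }
    geo[n_geo] <- a_max
    nodes <- c(fine, geo)
  }
  h <- diff(nodes)
  w <- c(h[1] / 2, (h[-length(h)] + h[-1]) / 2, h[length(h)] / 2)
  structure(list(nodes = nodes, weights = w, a_max = a_max,
                 h_min = min(h), refinement = refinement),
            class = "lipid_grid")
}

#' @export
print.lipid_grid <- function(x, ...) {
  cat(sprintf("<lipid_grid> %d nodes on [1, %g], %s, h_min=%.4g h_max=%.4g\n",
              length(x$nodes), x$a_max, x$refinement, x$h_min,
              max(diff(x$nodes))))
  invisible(x)
}

#' Quadrature over the lipid grid
#'
#' Trapezoidal integral of a function sampled on the grid nodes.
#'
#' @param f numeric vector of values on `grid$nodes`.
#' @param grid a [make_grid()] grid.
#' @return the approximate integral over `[1, a_max]`.
#' @export
grid_integrate <- function(f, grid) {
  stopifnot(length(f) == length(grid$nodes))
  sum(f * grid$weights)
}

half_normal_density <- function(a, a_sigma) {
  2 / (a_sigma * sqrt(2 * pi)) * exp(-(a - 1)^2 / (2 * a_sigma^2))
}

#' Initial plaque state
#'
#' Builds the half-normal initial distributions for the live and apoptotic
#' densities. The initial live population `M0` is fixed by requiring that
#' the initial distribution satisfies the recruitment boundary condition at
#' `t = 0`, giving (dimensionless)
#' `M0 = kappa lam sqrt(2 pi) / (a_sigma (a_sigma sqrt(2 pi) - 2 lam))`,
#' which requires `a_sigma > lam sqrt(2/pi)`. Initially the plaque holds
#' fewer dead cells than live (`P0 = 0.5 M0`) and no necrotic lipid
#' (`N = 0`).
#'
#' @param params a [model_parameters()] object.
#' @param grid a [make_grid()] grid.
#' @param a_sigma width of the half-normal initial distributions
#'   (dimensionless lipid; default 1).
#' @return an object of class `plaque_state` with fields `t`, `m`, `p`, `N`
#'   and the reference values `M0`, `P0` stored as attributes.
#' @export
initial_state <- function(params, grid, a_sigma = 1) {
  stopifnot(inherits(params, "model_parameters"), inherits(grid, "lipid_grid"))
  bound <- params$lam * sqrt(2) / sqrt(pi)
  if (a_sigma <= bound)
    stop(sprintf("'a_sigma' must exceed lam*sqrt(2/pi) = %.4g for a positive M0",
                 bound), call. = FALSE)
  M0 <- params$kappa * params$lam * sqrt(2 * pi) /
    (a_sigma * (a_sigma * sqrt(2 * pi) - 2 * params$lam))
  P0 <- 0.5 * M0
  dens <- half_normal_density(grid$nodes, a_sigma)
  st <- plaque_state(t = 0, m = M0 * dens, p = P0 * dens, N = 0, grid = grid)
  attr(st, "M0") <- M0
  attr(st, "P0") <- P0
  st
}

#' Plaque state container
#'
#' Holds the unnormalised dimensionless live density `m(a)` (whose zeroth
#' moment is the live population `M`), the apoptotic density `p(a)`, the
#' necrotic lipid `N` and the time `t`, on a given lipid grid. The
#' probability-density forms are recovered as `m/M` and `p/P`.
#'
#' @param t dimensionless time.
#' @param m,p non-negative numeric densities on `grid$nodes`.
#' @param N non-negative necrotic lipid.
#' @param grid a [make_grid()] grid.
#' @return an object of class `plaque_state`.
#' @export
plaque_state <- function(t, m, p, N, grid) {
  stopifnot(inherits(grid, "lipid_grid"),
            length(m) == length(grid$nodes),
            length(p) == length(grid$nodes))
  if (any(m < 0) || any(p < 0) || N < 0)
    stop("densities and necrotic lipid must be non-negative", call. = FALSE)
  structure(list(t = t, m = m, p = p, N = N, grid = grid),
            class = "plaque_state")
}

#' @export
print.plaque_state <- function(x, ...) {
  mom <- moments(x$m, x$grid)
  momp <- moments(x$p, x$grid)
  cat(sprintf("<plaque_state> t=%g  M=%.4g P=%.4g A_M=%.4g A_P=%.4g N=%.4g\n",
              x$t, mom[1], momp[1], mom[2], momp[2], x$N))
  invisible(x)
}
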