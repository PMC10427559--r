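test_that("efferocytosis convolution matches the closed form and the naive oracle", {
  # shifted exponentials: m = p = e^{-(a-1)} gives q(a) = (a-2) e^{-(a-2)}
  g <- make_grid(60, 1200, refinement = "uniform")
  m <- exp(-(g$nodes - 1))
  q <- efferocytosis_convolution(m, m, g)
  qe <- ifelse(g$nodes > 2, (g$nodes - 2) * exp(-(g$nodes - 2)), 0)
  expect_true(all(q[g$nodes <= 2] == 0))
  expect_lt(max(abs(q - qe)), 1e-3)
  # quadrature consistency: event number and event lipid recovered to
  # second order (exact equality is impossible on a truncated domain)
  w <- g$weights; a <- g$nodes
  p2 <- (a - 1) * exp(-(a - 1) / 2)
  q2 <- efferocytosis_convolution(m, p2, g)
  M <- sum(w * m); P <- sum(w * p2)
  A_M <- sum(w * a * m); A_P <- sum(w * a * p2)
  expect_equal(sum(w * q2), M * P, tolerance = 1e-3)
  expect_equal(sum(w * a * q2), A_M * P + M * A_P, tolerance = 1e-3)
  # naive double-loop oracle agreement to round-off on small grids
  for (grid in list(small_grid(64, 60), make_grid(80, 300, a_fine = 5))) {
    a <- grid$nodes
    m1 <- exp(-(a - 1) / 3) * (1 + 0.3 * sin(a))
    p1 <- exp(-(a - 1) / 5)
    expect_equal(efferocytosis_convolution(m1, p1, grid),
                 naive_convolution(m1, p1, grid), tolerance = 1e-12)
  }
  # symmetry q(m, p) = q(p, m): a continuum identity, discrete to the
  # interpolation error for smooth densities
  grid <- make_grid(120, 2000, refinement = "uniform")
  a <- grid$nodes
  m2 <- exp(-(a - 1) / 4); p3 <- (a - 1) * exp(-(a - 1) / 2)
  expect_equal(efferocytosis_convolution(m2, p3, grid),
               efferocytosis_convolution(p3, m2, grid), tolerance = 1e-4)
})

test_that("proliferation source has the doubling-map moment identities", {
  grid <- make_grid(100, 2000, refinement = "uniform")
  a <- grid$nodes
  m <- exp(-(a - 1) / 2)
  gr <- rate_modulation("proliferation", "saturating", a_half = 9, limit = 0,
                        exponent = 2)
  src <- proliferation_source(m, gr, grid)
  G <- g_functionals(m, gr, grid)
  # zeroth moment: each division event adds two daughters
  expect_equal(grid_integrate(src, grid), 2 * G[["G"]], tolerance = 1e-3)
  # first moment: the daughters carry the parent's lipid plus one unit of
  # new structural lipid per event
  expect_equal(grid_integrate(a * src, grid), G[["G_a"]] + G[["G"]],
               tolerance = 1e-3)
  # support geometry: parents in [1, 2] produce daughters in [1, 1.5]
  m3 <- ifelse(a <= 2, 1, 0)
  src3 <- proliferation_source(m3, rate_modulation("proliferation", "constant"),
                               grid)
  expect_true(all(src3[a > 1.5 + 0.06] == 0))
  expect_true(any(src3[a <= 1.5] > 0))
  # naive oracle agreement
  gs <- small_grid(64, 60)
  ms <- exp(-(gs$nodes - 1) / 3)
  expect_equal(proliferation_source(ms, gr, gs),
               naive_prolif_source(ms, gr, gs), tolerance = 1e-12)
})

test_that("recruitment flux saturates in accumulated lipid", {
  expect_equal(recruitment_flux(0.3, 0.3, 5), 0)
  expect_equal(recruitment_flux(0.3, 0.3 + 5, 5), 0.5)      # half-maximal
  expect_equal(recruitment_flux(0.3, 0.3 + 15, 5), 0.75)
  expect_lt(recruitment_flux(1, 1e9, 5), 1)
  expect_error(recruitment_flux(1, 0.5, 5), "corrupt")
})

test_that("boundary density is recruitment flux over advection speed", {
  params <- model_parameters()
  grid <- make_grid(300, 400, h0 = 0.2)
  st <- initial_state(params, grid)
  mom <- moments(st$m, grid)
  expect_equal(boundary_density(st, params),
               recruitment_flux(mom[[1]], mom[[2]], params$kappa) /
                 (params$lam / mom[[1]] + params$theta * st$N))
  # advection speed arithmetic, a-independent by construction
  st2 <- plaque_state(0, st$m, st$p, N = 4.03, grid)
  M <- moments(st2$m, grid)[[1]]
  expect_equal(advection_speed(st2, params), 0.1 / M + 0.6 * 4.03)
})

test_that("semi-discrete moments obey the closed moment equations", {
  # with all g = 1, integrating dm/dt must reproduce the closed ODE
  # right-hand sides (independently coded here)
  params <- model_parameters(rho = 0.5)
  grid <- make_grid(300, 1200)
  st <- initial_state(params, grid, a_sigma = 1)
  # a mid-transient state exercises every term
  st <- integrate_plaque(st, params, integrator_settings(t_max = 20),
                         mode = "to_time")$state
  r <- plaque_rhs(st, params)
  momm <- moments(st$m, grid); momp <- moments(st$p, grid)
  M <- momm[[1]]; A_M <- momm[[2]]; P <- momp[[1]]; A_P <- momp[[2]]
  Fl <- recruitment_flux(M, A_M, params$kappa)
  dM_pde <- grid_integrate(r$dm, grid)
  dAM_pde <- grid_integrate(grid$nodes * r$dm, grid)
  dP_pde <- grid_integrate(r$dp, grid)
  dAP_pde <- grid_integrate(grid$nodes * r$dp, grid)
  dM_ode <- Fl + params$rho * M - M - params$gamma * M
  dAM_ode <- Fl + params$lam + params$theta * M * st$N +
    params$eta * M * A_P + params$rho * M - A_M - params$gamma * A_M
  dP_ode <- M - (params$nu + params$eta * M) * P
  dAP_ode <- A_M - (params$nu + params$eta * M) * A_P
  expect_lt(abs(dM_pde - dM_ode), 1e-3 * max(1, abs(dM_ode)))
  expect_lt(abs(dAM_pde - dAM_ode), 1e-3 * max(1, abs(dAM_ode)))
  expect_lt(abs(dP_pde - dP_ode), 1e-3 * max(1, abs(dP_ode)))
  expect_lt(abs(dAP_pde - dAP_ode), 1e-3 * max(1, abs(dAP_ode)))
  expect_equal(r$dN, params$nu * A_P - params$theta * M * st$N, tolerance = 1e-10)
})

test_that("PDE moments track the closed ODE oracle over a transient", {
  params <- model_parameters()
  grid <- make_grid(300, 900)
  st <- initial_state(params, grid, a_sigma = 1)
  traj <- integrate_plaque(st, params, integrator_settings(t_max = 40),
                           mode = "to_time")
  init <- c(M = attr(st, "M0"), P = attr(st, "P0"),
            A_M = moments(st$m, grid)[[2]], A_P = moments(st$p, grid)[[2]],
            N = 0)
  ode <- lipid_independent_ode(params, init, t_max = 40, dt = 0.005)
  s <- traj$summary
  for (v in c("M", "P", "A_M", "A_P", "N")) {
    pde_v <- s[[v]][match(ode$t, s$t)]
    keep <- !is.na(pde_v) & ode$t > 1
    expect_lt(max(abs(pde_v[keep] - ode[[v]][keep]) /
                    pmax(abs(ode[[v]][keep]), 0.01)), 0.01)
  }
})

test_that("degenerate and error paths are reported, not NaN", {
  params <- model_parameters()
  grid <- make_grid(300, 400, h0 = 0.2)
  empty <- plaque_state(0, numeric(400), numeric(400), N = 1, grid)
  expect_error(plaque_rhs(empty, params), "collapsed")
  expect_error(advection_speed(empty, params), "collapsed")
})

test_that("integration is deterministic", {
  params <- model_parameters()
  grid <- make_grid(300, 400, h0 = 0.2)
  st <- initial_state(params, grid)
  t1 <- integrate_plaque(st, params, integrator_settings(t_max = 10), "to_time")
  t2 <- integrate_plaque(st, params, integrator_settings(t_max = 10), "to_time")
  expect_identical(t1$summary, t2$summary)
  expect_identical(t1$state$m, t2$state$m)
})
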