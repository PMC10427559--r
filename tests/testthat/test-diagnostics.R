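test_that("moments recover closed-form integrals", {
  grid <- make_grid(100, 2000, refinement = "uniform")
  expect_equal(moments(numeric(2000), grid), c(zeroth = 0, first = 0))
  # e^{-(a-1)}: zeroth 1, first 2
  m <- exp(-(grid$nodes - 1))
  expect_equal(moments(m, grid)[[1]], 1, tolerance = 5e-4)
  expect_equal(moments(m, grid)[[2]], 2, tolerance = 5e-4)
  # half-normal fixture: first moment M0 (1 + 2 a_sigma / sqrt(2 pi))
  a_sigma <- 1.3; M0 <- 0.7
  dens <- M0 * 2 / (a_sigma * sqrt(2 * pi)) *
    exp(-(grid$nodes - 1)^2 / (2 * a_sigma^2))
  expect_equal(moments(dens, grid)[[2]], M0 * (1 + 2 * a_sigma / sqrt(2 * pi)),
               tolerance = 1e-4)
  # naive oracle agreement on a small grid
  gs <- small_grid()
  ms <- exp(-(gs$nodes - 1) / 2)
  expect_equal(unname(moments(ms, gs)), naive_moments(ms, gs),
               tolerance = 1e-12)
})

test_that("g-functionals reduce to moments for constant modulation and are bounded", {
  grid <- make_grid(200, 900)
  m <- exp(-(grid$nodes - 1) / 6)
  mom <- moments(m, grid)
  cst <- rate_modulation("emigration", "constant")
  expect_equal(unname(g_functionals(m, cst, grid)), unname(mom),
               tolerance = 1e-12)
  # bounds G in [gmin M, gmax M] for a bounded modulation
  mod <- rate_modulation("emigration", "saturating", a_half = 18, limit = 0.1,
                         exponent = 1.5)
  G <- g_functionals(m, mod, grid)[["G"]]
  expect_gte(G, 0.1 * mom[[1]] - 1e-12)
  expect_lte(G, 1 * mom[[1]] + 1e-12)
})

test_that("emigration profiles integrate to the g-functionals", {
  grid <- make_grid(200, 900)
  m <- exp(-(grid$nodes - 1) / 6)
  mod <- rate_modulation("emigration", "peaked", floor = 0.1, scale_loc = 9,
                         rise_exp = 1, fall_exp = 2)
  prof <- emigration_profiles(m, mod, grid)
  G <- g_functionals(m, mod, grid)
  expect_equal(prof$G, G[["G"]], tolerance = 1e-12)
  expect_equal(prof$G_a, G[["G_a"]], tolerance = 1e-12)
  expect_equal(prof$mean_lipid_removed, G[["G_a"]] / G[["G"]])
  # constant modulation: profiles proportional to m and a m
  cst <- rate_modulation("emigration", "constant")
  pc <- emigration_profiles(m, cst, grid)
  expect_equal(pc$events, m)
  expect_equal(pc$lipid, grid$nodes * m)
})

test_that("steady residuals flag non-steady states and pass at steady state", {
  params <- model_parameters()
  grid <- make_grid(300, 500)
  st <- initial_state(params, grid)
  # manufactured non-steady state: residuals are O(1)
  fake <- structure(list(summary = data.frame(t = 0), state = st,
                         params = params, status = "converged",
                         dynamics = list(regime = "monotone_settling")),
                    class = "plaque_trajectory")
  res <- steady_residuals(fake)
  expect_gt(max(abs(res[c("dM", "dP", "dN")])), 0.1)
})

test_that("analytic lipid-independent steady state solves the moment equations", {
  for (rho in c(0, 0.5)) {
    params <- model_parameters(rho = rho)
    ss <- lipid_independent_steady(params)
    M <- ss[["M"]]; A_M <- ss[["A_M"]]; P <- ss[["P"]]
    A_P <- ss[["A_P"]]; N <- ss[["N"]]
    Fl <- ss[["F"]]
    expect_equal(Fl + rho * M - M - params$gamma * M, 0, tolerance = 1e-12)
    expect_equal(Fl + params$lam + params$theta * M * N + params$eta * M * A_P +
                   rho * M - A_M - params$gamma * A_M, 0, tolerance = 1e-12)
    expect_equal(M - (params$nu + params$eta * M) * P, 0, tolerance = 1e-12)
    expect_equal(A_M - (params$nu + params$eta * M) * A_P, 0, tolerance = 1e-12)
    expect_equal(params$nu * A_P - params$theta * M * N, 0, tolerance = 1e-12)
    expect_equal(ss[["L"]], A_M + A_P + N)
    expect_gte(ss[["abar_M"]], 1)
  }
  # RK4 oracle relaxes onto the analytic fixed point
  params <- model_parameters()
  ss <- lipid_independent_steady(params)
  ode <- lipid_independent_ode(params,
                               c(M = 0.4, P = 0.2, A_M = 0.8, A_P = 0.4, N = 0),
                               t_max = 400, dt = 0.01)
  last <- ode[nrow(ode), ]
  expect_equal(last$M, ss[["M"]], tolerance = 1e-6)
  expect_equal(last$N, ss[["N"]], tolerance = 1e-5)
})
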