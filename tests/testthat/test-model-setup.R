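test_that("grid quadrature is exact for constants and accurate for decays", {
  g <- make_grid(51, 1001, refinement = "uniform")
  expect_equal(max(abs(diff(g$nodes) - 0.05)), 0, tolerance = 1e-12)
  expect_equal(grid_integrate(rep(1, 1001), g), 50, tolerance = 1e-10)
  # Gamma integral: int (a-1) e^{-(a-1)} da = 1 over a large domain
  g2 <- make_grid(300, 1200)
  f <- (g2$nodes - 1) * exp(-(g2$nodes - 1))
  expect_equal(grid_integrate(f, g2), 1, tolerance = 1e-3)
  # stretched grid: fine spacing near a = 1, strictly increasing nodes
  expect_lte(g2$h_min, 0.05)
  expect_true(all(diff(g2$nodes) > 0))
  expect_equal(g2$nodes[1], 1)
  expect_equal(g2$nodes[length(g2$nodes)], 300)
  expect_equal(grid_integrate(rep(1, 1200), g2), 299, tolerance = 1e-10)
})

test_that("initial state implements the half-normal construction", {
  params <- model_parameters()
  grid <- make_grid(300, 1200)
  st <- initial_state(params, grid, a_sigma = 1)
  M0 <- attr(st, "M0")
  # dimensionless closed form: kappa lam sqrt(2 pi)/(a_sigma(a_sigma sqrt(2 pi) - 2 lam))
  expect_equal(M0, (25 / 6) * 0.1 * sqrt(2 * pi) / (sqrt(2 * pi) - 0.2),
               tolerance = 1e-12)
  expect_equal(M0, 0.45281, tolerance = 1e-4)
  expect_equal(attr(st, "P0") / M0, 0.5)
  expect_equal(st$N, 0)
  momm <- moments(st$m, grid)
  momp <- moments(st$p, grid)
  # densities integrate to M0, P0 and the first moment matches
  # A_M0 = M0 (1 + 2 a_sigma / sqrt(2 pi))
  expect_equal(momm[[1]], M0, tolerance = 1e-6)
  expect_equal(momp[[1]], 0.5 * M0, tolerance = 1e-6)
  expect_equal(momm[[2]], M0 * (1 + 2 / sqrt(2 * pi)), tolerance = 1e-4)
  # the construction satisfies the recruitment boundary condition at t = 0
  expect_equal(boundary_density(st, params), st$m[1], tolerance = 2e-3)
  # width bound: a_sigma must exceed lam sqrt(2/pi)
  expect_error(initial_state(params, grid, a_sigma = 0.05), "a_sigma")
})

test_that("nondimensionalisation reproduces the base-case constants", {
  dimp <- dimensional_parameters()   # beta = nu = 0.05/h, gamma = 0.01/h, ...
  params <- nondimensionalise(dimp)
  expect_equal(params$nu, 1, tolerance = 1e-12)
  expect_equal(params$gamma, 0.2, tolerance = 1e-12)
  expect_equal(params$eta, 2.4e-6 * 1e4 / 0.05^2, tolerance = 1e-12)
  expect_equal(params$eta, 9.6, tolerance = 1e-12)
  expect_equal(params$theta, 0.6, tolerance = 1e-12)
  expect_equal(params$kappa, 25 / 6, tolerance = 1e-12)
  expect_equal(params$lam, 0.1, tolerance = 1e-12)
  # round trip through an arbitrary dimensional set
  d2 <- dimensional_parameters(beta = 0.03, nu_dim = 0.06, gamma_dim = 0.009,
                               alpha = 5e3, eta_dim = 1e-6, theta_dim = 2e-7,
                               a0 = 2, lam_dim = 800, kappa_dim = 5e5)
  p2 <- nondimensionalise(d2, rho_dim = 0.015)
  expect_equal(p2$gamma, 0.3)
  expect_equal(p2$rho, 0.5)
  expect_equal(p2$kappa, 5e5 * 0.03 / (2 * 5e3))
  expect_equal(p2$theta, 2e-7 * 5e3 / 0.03^2)
})

test_that("doubling map is resolvable on the grid", {
  grid <- make_grid(300, 800)
  a <- grid$nodes
  y <- 2 * a - 1
  inside <- y <= grid$a_max
  # linear interpolation of a smooth function at 2a-1 is accurate
  m <- exp(-(a - 1) / 5)
  src <- proliferation_source(m, rate_modulation("proliferation", "constant"), grid)
  expect_equal(src[inside], 4 * exp(-(y[inside] - 1) / 5), tolerance = 1e-3)
  expect_true(all(src[!inside] == 0))
})
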