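test_that("saturating modulation matches its defining values", {
  mod <- rate_modulation("apoptosis", "saturating", a_half = 12, limit = 3,
                         exponent = 2)
  # g(1) = 1 for any parameters
  expect_equal(eval_saturating(1, mod), 1)
  # half-way value (1 + limit)/2 at a = a_half
  expect_equal(eval_saturating(12, mod), 2)
  # direct arithmetic: (11^2 + 3*5.5^2)/(11^2 + 5.5^2) = 1.4
  expect_equal(eval_saturating(6.5, mod), 1.4)
  expect_error(eval_saturating(0.5, mod), "must be >= 1")
})

test_that("saturating modulation is monotone and bounded (property)", {
  set.seed(42)
  a <- c(1, sort(exp(runif(200, 0, log(1e6)))))
  for (i in 1:25) {
    lim <- runif(1, 0, 5)
    mod <- rate_modulation("apoptosis", "saturating",
                           a_half = 1 + exp(runif(1, -1, 4)),
                           limit = lim, exponent = runif(1, 1, 4))
    g <- eval_saturating(a, mod)
    expect_true(all(g >= min(1, lim) - 1e-12 & g <= max(1, lim) + 1e-12))
    d <- diff(g)
    if (lim > 1) expect_true(all(d >= -1e-12)) else expect_true(all(d <= 1e-12))
  }
})

test_that("peaked modulation has the reconstructed floor/peak/limit shape", {
  for (b in c(3, 6, 9)) {
    mod <- rate_modulation("emigration", "peaked", floor = 0.1, scale_loc = b,
                           rise_exp = 1, fall_exp = 2)
    expect_equal(eval_peaked(1, mod), 0.1)             # floor at a = 1
    expect_equal(eval_peaked(1 + b, mod), 1)           # peak value exactly 1
    # numerical argmax on a fine grid agrees with the closed form 1 + b
    a <- seq(1, 60, by = 0.001)
    expect_equal(a[which.max(eval_peaked(a, mod))], 1 + b, tolerance = 2e-3)
    expect_lt(eval_peaked(1e7, mod), 0.1 + 1e-5)       # tends back to floor
  }
  # general exponents: peak at 1 + b (k/(q-k))^(1/q), max exactly 1
  mod <- rate_modulation("emigration", "peaked", floor = 0.3, scale_loc = 5,
                         rise_exp = 2, fall_exp = 3.5)
  astar <- 1 + 5 * (2 / 1.5)^(1 / 3.5)
  expect_equal(eval_peaked(astar, mod), 1, tolerance = 1e-12)
  a <- seq(1, 200, by = 0.005)
  expect_true(all(eval_peaked(a, mod) <= 1 + 1e-12))
  expect_error(rate_modulation("emigration", "peaked", floor = 0.1,
                               scale_loc = 3, rise_exp = 2, fall_exp = 2),
               "fall_exp > rise_exp")
})

test_that("scaling semantics preserve the behaviour-specific limits", {
  # constant ignores scaling
  mod <- rate_modulation("apoptosis", "constant", scaling = 0.72)
  expect_equal(eval_modulation(c(1, 50), mod), c(1, 1))
  # apoptosis: plain multiplication
  mod <- rate_modulation("apoptosis", "saturating", a_half = 12, limit = 3,
                         exponent = 2, scaling = 0.72)
  expect_equal(eval_modulation(12, mod), 0.72 * 2)
  # emigration: limit divided by the scaling, so the a -> Inf limit is kept
  mod <- rate_modulation("emigration", "saturating", a_half = 18, limit = 0.1,
                         exponent = 1.5, scaling = 1.25)
  expect_equal(eval_modulation(1e9, mod), 0.1, tolerance = 1e-6)
  unscaled <- rate_modulation("emigration", "saturating", a_half = 18,
                              limit = 0.1, exponent = 1.5)
  expect_equal(eval_modulation(1e12, mod) - eval_modulation(1e12, unscaled), 0,
               tolerance = 1e-12)
  # peaked: floor fixed at a = 1 and at a -> Inf, only the bump is scaled
  mod <- rate_modulation("emigration", "peaked", floor = 0.1, scale_loc = 9,
                         rise_exp = 1, fall_exp = 2, scaling = 1.9)
  expect_equal(eval_modulation(1, mod), 0.1)
  expect_lt(abs(eval_modulation(1e15, mod) - 0.1), 1e-12)
  expect_equal(eval_modulation(10, mod), 0.1 + 1.9 * 0.9)  # scaled peak
})

test_that("boundedness check evaluates the survival margin", {
  grid <- make_grid(100, 400)
  # all constant: margin 1 + gamma - rho
  p <- model_parameters(gamma = 0.2, rho = 0.5)
  bd <- check_boundedness(p, grid)
  expect_true(bd$ok)
  expect_equal(bd$min_value, 0.7)
  p_bad <- model_parameters(gamma = 0.2, rho = 1.3)
  bd <- check_boundedness(p_bad, grid)
  expect_false(bd$ok)
  expect_equal(bd$min_value, -0.1, tolerance = 1e-12)
  # saturating apoptosis raises the margin everywhere (g_beta >= 1 here)
  p2 <- model_parameters(gamma = 0.2, rho = 0.5,
                         g_beta = rate_modulation("apoptosis", "saturating",
                                                  a_half = 12, limit = 3,
                                                  exponent = 2))
  bd2 <- check_boundedness(p2, grid)
  expect_true(bd2$ok)
  expect_gte(bd2$min_value, 0.7 - 1e-12)
  # integrator refuses an unbounded configuration
  st <- initial_state(p_bad, grid)
  expect_error(integrate_plaque(st, p_bad), "boundedness")
})

test_that("scenario registry modulations carry the published parameters", {
  reg <- list_scenarios()
  expect_true(all(c("base_rho0", "base_rho05") %in% reg$name))
  expect_false(any(reg$behaviour[startsWith(reg$name, "base")] != "none"))
  mod <- scenario_modulation("apoptosis_s_a12_d3", scaled = TRUE)
  expect_equal(mod$scaling, 0.72)
  expect_equal(eval_saturating(12, mod), 2)
  # proliferation rows exist only with proliferation switched on
  expect_true(all(reg$rho[reg$behaviour == "proliferation"] == 0.5))
})
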