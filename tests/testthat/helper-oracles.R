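# Independent brute-force oracles, written in plain R against the same
# quadrature rules (composite trapezoid on the node set, linear
# interpolation off-node) so production code can be checked to round-off.

# convolution q(a_i) = int_1^{a_i - 1} m(a') p(a_i - a') da': composite
# trapezoid over the m nodes with p linearly interpolated off-node, plus
# the partial final interval up to a_i - 1
naive_convolution <- function(m, p, grid) {
  a <- grid$nodes
  n <- length(a)
  p_at <- function(y) stats::approx(a, p, y, rule = 2)$y
  m_at <- function(y) stats::approx(a, m, y, rule = 2)$y
  q <- numeric(n)
  for (i in seq_len(n)) {
    upper <- a[i] - 1
    if (upper <= a[1]) next
    J <- max(which(a <= upper))
    f <- m[1:J] * p_at(a[i] - a[1:J])
    if (J >= 2) {
      h <- diff(a[1:J])
      q[i] <- sum((f[-J] + f[-1]) / 2 * h)
    }
    d <- upper - a[J]
    if (d > 1e-14)
      q[i] <- q[i] + d / 2 * (f[J] + m_at(upper) * p[1])
  }
  q
}

# proliferation source 4 g_rho(2a - 1) m(2a - 1), 0 beyond the domain
naive_prolif_source <- function(m, g_rho_mod, grid) {
  a <- grid$nodes
  out <- numeric(length(a))
  for (i in seq_along(a)) {
    y <- 2 * a[i] - 1
    if (y > grid$a_max) next
    mi <- stats::approx(a, m, y, rule = 2)$y
    out[i] <- 4 * eval_modulation(y, g_rho_mod) * mi
  }
  out
}

naive_moments <- function(density, grid) {
  a <- grid$nodes
  h <- diff(a)
  f0 <- density
  f1 <- a * density
  c(sum((f0[-length(f0)] + f0[-1]) / 2 * h),
    sum((f1[-length(f1)] + f1[-1]) / 2 * h))
}

# small standard fixtures
small_grid <- function(n = 64, a_max = 60)
  make_grid(a_max = a_max, n_nodes = max(n, 200), refinement = "uniform")

base_params <- function(rho = 0) model_parameters(rho = rho)

# settings sized for the test suite: slightly looser steady tolerance than
# the shipped default so runs finish quickly, same window logic
test_settings <- function(t_max = 800, steady_tol = 1e-5, ...)
  integrator_settings(t_max = t_max, steady_tol = steady_tol, ...)
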