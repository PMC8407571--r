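test_that("derived electrotonic constants are consistent with the physical fields", {
  p <- cable_params(r = 2, l = 800, r_a = 150, g_l = 1e-4, c = 0.8,
                    rho = 8)
  um <- 1e-4
  lambda_cm <- sqrt(p$r * um / (2 * p$r_a * p$g_l))
  expect_equal(p$lambda, lambda_cm / um)
  expect_equal(p$L, p$l * um / lambda_cm)
  expect_equal(p$G_inf, pi * (p$r * um)^2 / (lambda_cm * p$r_a))
  expect_equal(p$G_s, 4 * pi * (p$rho * um)^2 * p$g_l)
  expect_equal(p$tau_l, p$c * 1e-6 / p$g_l)
  expect_error(cable_params(r = -1), "r > 0")
})

test_that("synaptic kernel integrates to its charge and rejects equal time constants", {
  k <- std_kernel(theta = 2.5)
  q <- integrate(function(t) syn_current(k, t), 0, Inf,
                 rel.tol = 1e-10)$value
  expect_equal(q, 2.5, tolerance = 1e-8)
  expect_error(syn_kernel(0.01, 0.01), "must differ")
})

test_that("transfer resistance matches limiting forms and is monotone", {
  p <- fig_cable()
  expect_equal(transfer_resistance(p, 0),
               1 / (tanh(p$L) * p$G_inf))
  p_long <- fig_cable(l = 20000) # L = 20, effectively semi-infinite
  expect_equal(transfer_resistance(p_long, 0) * p_long$G_inf, 1,
               tolerance = 1e-10)
  X <- seq(0, p$L, length.out = 50)
  expect_true(all(diff(transfer_resistance(p, X)) < 0))
  expect_error(transfer_resistance(p, p$L * 1.01), "within")
  # a soma is an added leak: resistance drops everywhere
  ps <- fig_cable(rho = 10)
  expect_true(all(transfer_resistance(ps, X) <
                    transfer_resistance(p, X)))
})

test_that("closed forms agree with the compartmental oracle on a parameter grid", {
  for (l in c(250, 500, 1000)) {
    for (frac in c(0, 0.5, 0.9)) {
      for (rho in c(0, 10)) {
        p <- fig_cable(l = l, rho = rho)
        X <- frac * p$L
        analytic <- transfer_resistance(p, X)
        oracle <- compartmental_oracle(p, X, 1, n_comp = 600) / 1e-3
        expect_equal(analytic, oracle, tolerance = 0.01)
      }
    }
  }
})

test_that("compartmental oracle converges under grid refinement and is zero for zero input", {
  p <- fig_cable()
  v1 <- compartmental_oracle(p, p$L / 3, 1, n_comp = 300)
  v2 <- compartmental_oracle(p, p$L / 3, 1, n_comp = 600)
  expect_equal(v1, v2, tolerance = 1e-3)
  expect_equal(compartmental_oracle(p, p$L / 3, 0, n_comp = 300), 0)
  expect_error(compartmental_oracle(p, 0, 1, n_comp = 50), "at least 200")
})

test_that("steady-state moments: exact mean, 1/L scaling, quadrature variance", {
  p <- fig_cable()
  sm <- steady_moments(p, 1)
  expect_equal(sm$mean, 1 / (p$L * p$G_inf))
  expect_equal(sm$mean * p$L * p$G_inf, 1) # exact normalisation identity
  # doubling the length halves the mean exactly
  p2 <- fig_cable(l = 1000)
  expect_equal(steady_moments(p2, 1)$mean, sm$mean / 2)
  # variance equals quadrature of (R_L(X))^2 minus the squared mean
  for (rho in c(0, 10)) {
    pp <- fig_cable(rho = rho)
    smp <- steady_moments(pp, 1.7)
    m_q <- integrate(function(x) transfer_resistance(pp, x), 0, pp$L,
                     rel.tol = 1e-12)$value / pp$L
    m2_q <- integrate(function(x) transfer_resistance(pp, x)^2, 0, pp$L,
                      rel.tol = 1e-12)$value / pp$L
    expect_equal(smp$mean, 1.7 * m_q, tolerance = 1e-8)
    expect_equal(smp$variance, 1.7^2 * (m2_q - m_q^2), tolerance = 1e-6)
  }
  z <- steady_moments(p, 0)
  expect_equal(z$mean, 0)
  expect_equal(z$variance, 0)
})

test_that("impulse response: location average, decay, and truncation self-convergence", {
  p <- fig_cable()
  for (T0 in c(0.05, 0.5, 2)) {
    avg <- integrate(function(x) {
      vapply(x, function(xi) impulse_response(p, xi, T0), numeric(1))
    }, 0, p$L, rel.tol = 1e-9)$value / p$L
    expect_equal(avg, exp(-T0) / (2 * p$L), tolerance = 1e-6)
  }
  expect_lt(impulse_response(p, p$L / 2, 50), 1e-20)
  # tightening the tolerance tenfold changes nothing beyond the tolerance
  v_loose <- impulse_response(p, p$L / 3, 0.1, tol = 1e-6)
  v_tight <- impulse_response(p, p$L / 3, 0.1, tol = 1e-12)
  expect_equal(v_loose, v_tight, tolerance = 1e-5)
  expect_error(impulse_response(p, p$L / 2, -0.1), "non-negative")
})

test_that("mean synaptic voltage: closed form equals the convolution oracle and scales as 1/L", {
  p <- fig_cable()
  k <- std_kernel()
  ts <- c(0.005, 0.02, 0.08)
  conv <- vapply(ts, function(t0) {
    integrate(function(u) {
      syn_current(k, t0 - u) * exp(-u / p$tau_l) / (2 * p$L)
    }, 0, t0, rel.tol = 1e-11)$value
  }, numeric(1))
  expect_equal(mean_synaptic_voltage(p, k, ts), conv, tolerance = 1e-3)
  # exact 1/L ratio at every time
  p2 <- fig_cable(l = 1600)
  ratio <- mean_synaptic_voltage(p, k, ts) /
    mean_synaptic_voltage(p2, k, ts)
  expect_equal(ratio, rep(1600 / 500, 3))
  expect_equal(mean_synaptic_voltage(p, std_kernel(theta = 0), ts),
               rep(0, 3))
  expect_error(
    mean_synaptic_voltage(p, syn_kernel(p$tau_l, 0.05), 0.01),
    "pairwise distinct")
})

test_that("paper-unit responses match the physical compartmental transient", {
  # the normalised response maps to volts via 2 / (G_inf * tau_l); the
  # spatially resolved response convolved with the kernel must match the
  # diagonalised compartmental simulation
  p <- fig_cable()
  k <- std_kernel()
  X <- p$L / 3
  ts <- c(0.01, 0.04)
  oc <- compartmental_oracle(p, X, k, n_comp = 500, t = ts)
  conv <- vapply(ts, function(t0) {
    integrate(function(u) {
      syn_current(k, t0 - u) *
        vapply(u, function(ui) impulse_response(p, X, ui / p$tau_l),
               numeric(1))
    }, 0, t0, rel.tol = 1e-9)$value
  }, numeric(1))
  phys <- 2 / (p$G_inf * p$tau_l) * conv * 1e-3 # mA -> A
  expect_equal(oc$v, phys, tolerance = 5e-3)
})

test_that("voltage variance matches Monte Carlo over synapse location", {
  p <- fig_cable()
  k <- std_kernel()
  t0 <- 0.02
  set.seed(71)
  Xs <- runif(1500, 0, p$L)
  vals <- vapply(Xs, function(x) {
    integrate(function(u) {
      syn_current(k, t0 - u) *
        vapply(u, function(ui) impulse_response(p, x, ui / p$tau_l),
               numeric(1))
    }, 0, t0, rel.tol = 1e-7)$value
  }, numeric(1))
  expect_equal(voltage_variance(p, k, t0), var(vals), tolerance = 0.1)
  expect_equal(voltage_variance(p, k, 0), 0)
  v_loose <- voltage_variance(p, k, t0, tol = 1e-6)
  v_tight <- voltage_variance(p, k, t0, tol = 1e-12)
  expect_equal(v_loose, v_tight, tolerance = 1e-5)
})

test_that("peak voltage matches a dense grid search and is length-invariant in time", {
  p <- fig_cable()
  k <- std_kernel()
  pk <- peak_voltage(p, k)
  grid <- seq(0, 1, by = 1e-5)
  v_grid <- mean_synaptic_voltage(p, k, grid)
  expect_equal(pk$v_max, max(v_grid), tolerance = 1e-6)
  expect_equal(pk$t_star, grid[which.max(v_grid)], tolerance = 1e-3)
  # the peak time does not depend on L, only the amplitude does
  pk2 <- peak_voltage(fig_cable(l = 2000), k)
  expect_equal(pk$t_star, pk2$t_star, tolerance = 1e-10)
  expect_true(all(pk$v_max >= v_grid))
})

test_that("total voltage: exact mean, kernel independence, variance consistency", {
  p <- fig_cable()
  k <- std_kernel(theta = 3)
  tv <- total_voltage(p, k)
  expect_equal(tv$mean, 3 * p$tau_l / (2 * p$L))
  V_quad <- integrate(function(t) mean_synaptic_voltage(p, k, t), 0, 10,
                      rel.tol = 1e-10)$value
  expect_equal(tv$mean, V_quad, tolerance = 1e-6)
  # the mean is independent of the synaptic time constants
  k2 <- syn_kernel(0.01, 0.1, theta_syn = 3)
  expect_equal(total_voltage(p, k2)$mean, tv$mean)
  # reported variance equals the time integral of the instantaneous one
  v_num <- integrate(function(t) voltage_variance(p, k, t), 0, 2,
                     rel.tol = 1e-8, subdivisions = 400)$value
  expect_equal(tv$variance, v_num, tolerance = 1e-4)
  z <- total_voltage(p, std_kernel(theta = 0))
  expect_equal(z$mean, 0)
  expect_equal(z$variance, 0)
})
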