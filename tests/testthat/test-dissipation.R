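test_that("instantaneous dissipation is zero at equilibrium and non-negative always", {
  Geq <- build_generator(circuit_params("no_feedback", u = 0.7, s = 1, r = 1))
  expect_equal(sigma_t(Geq, steady_state(Geq)), 0, tolerance = 1e-12,
               ignore_attr = TRUE)
  set.seed(101)
  draws <- c(random_params("no_feedback", n = 150), random_params("feedback", n = 150))
  for (p in draws) {
    G <- build_generator(p)
    v <- sigma_t(G, propagate(G, sym_dist(runif(1, -1, 1)), rexp(1)))
    expect_gte(as.numeric(v), 0)
  }
})

test_that("sigma_t at the stationary distribution equals sigma_ss", {
  for (p in c(random_params("no_feedback", n = 30, seed = 102),
              random_params("feedback", n = 30, seed = 103))) {
    G <- build_generator(p)
    expect_equal(as.numeric(sigma_t(G, steady_state(G))),
                 as.numeric(sigma_ss(G)), tolerance = 1e-9)
  }
})

test_that("steady-state dissipation matches the no-feedback closed form", {
  G <- build_generator(circuit_params("no_feedback", u = 1, s = 2))
  expect_equal(as.numeric(sigma_ss(G)), 0.2, tolerance = 1e-12)
  expect_equal(as.numeric(sigma_hat_ss(G)), 0.1, tolerance = 1e-12)
  expect_equal(sigma_ss_closed(circuit_params("no_feedback", u = 1, s = 2),
                               rescaled = TRUE), 0.1, tolerance = 1e-12)
  expect_equal(as.numeric(sigma_ss(build_generator(
    circuit_params("no_feedback", u = 1, s = 1)))), 0, tolerance = 1e-12)

  for (p in random_params("no_feedback", n = 1000, seed = 104)) {
    v_num <- as.numeric(sigma_ss(build_generator(p)))
    v_cf <- sigma_ss_closed(p)
    # near s = 1 both forms cancel to ~0, so the comparison is absolute there
    expect_lt(abs(v_num - v_cf), 1e-10 * max(1, abs(v_cf)))
  }
})

test_that("feedback closed form (with the square-root spectral gap) matches numerics", {
  # equilibrium manifold alpha = s*y
  p0 <- circuit_params("feedback", alpha = 0.8, y = 1.6, s = 0.5)
  expect_equal(as.numeric(sigma_ss(build_generator(p0))), 0, tolerance = 1e-12)
  expect_equal(sigma_ss_closed(p0, rescaled = TRUE), 0, tolerance = 1e-12)

  checked <- 0L
  for (p in random_params("feedback", n = 400, seed = 105)) {
    A <- 1 + p$s + p$y + p$alpha
    if (A^2 - 8 * (p$s * p$y + p$alpha) <= 1e-4) next
    v_num <- as.numeric(sigma_hat_ss(build_generator(p)))
    expect_equal(v_num, sigma_ss_closed(p, rescaled = TRUE), tolerance = 1e-8)
    checked <- checked + 1L
  }
  expect_gt(checked, 100L)

  # reduction alpha = y = u collapses the feedback closed form onto the
  # no-feedback one (rho = |1 + s - 2u|)
  for (p in random_params("no_feedback", n = 100, seed = 106)) {
    pf <- circuit_params("feedback", alpha = p$u, y = p$u, s = p$s)
    if ((1 + p$s + 2 * p$u)^2 - 8 * (p$s * p$u + p$u) <= 1e-4) next
    expect_equal(sigma_ss_closed(pf, rescaled = TRUE),
                 sigma_ss_closed(p, rescaled = TRUE), tolerance = 1e-9)
  }
  expect_warning(
    expect_true(is.na(sigma_ss_closed(
      circuit_params("feedback", alpha = 1, y = 2, s = 4), rescaled = TRUE))),
    "complex")
})

test_that("dissipation diverges as the anti-align rate vanishes", {
  vals <- vapply(10^-(2:6), function(s)
    sigma_ss_closed(circuit_params("no_feedback", u = 1, s = s), rescaled = TRUE),
    numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_gt(vals[5], 3)
  v <- sigma_ss_closed(circuit_params("no_feedback", u = 1, s = 0))
  expect_identical(as.numeric(v), Inf)
  expect_true(attr(v, "infinite_dissipation"))
  # one-way transition with positive flux in the generic functional
  G0 <- build_generator(circuit_params("no_feedback", u = 1, s = 0))
  v2 <- sigma_t(G0, sym_dist(0))
  expect_identical(as.numeric(v2), Inf)
  expect_true(attr(v2, "infinite_dissipation"))
})

test_that("sigma(t) relaxes to the steady-state rate", {
  for (p in random_params("no_feedback", n = 25, seed = 107)) {
    G <- build_generator(p)
    t_long <- 40 / relaxation_rate(G)
    expect_equal(as.numeric(sigma_t(G, propagate(G, sym_dist(0.9), t_long))),
                 as.numeric(sigma_ss(G)), tolerance = 1e-6)
  }
})

test_that("average dissipation: stationary start gives exactly sigma_hat_ss", {
  for (p in random_params("no_feedback", n = 20, seed = 108)) {
    G <- build_generator(p)
    expect_equal(sigma_avg(G, mu_steady_state(G), tau_p = 0.8),
                 as.numeric(sigma_hat_ss(G)), tolerance = 1e-9)
  }
})

test_that("average dissipation converges to sigma_hat_ss for long reset times", {
  G <- build_generator(circuit_params("no_feedback", u = 1, s = 2))
  shss <- as.numeric(sigma_hat_ss(G))
  d5 <- abs(sigma_avg(G, 1, 5) - shss)
  d50 <- abs(sigma_avg(G, 1, 50) - shss)
  expect_lt(d50, d5)
  expect_lt(d50, 0.06)
})

test_that("quadrature of the singular initial transient matches trapezoid refinement", {
  G <- build_generator(circuit_params("no_feedback", u = 1, s = 2))
  v <- sigma_avg(G, 1, 0.5)
  expect_equal(v, trapezoid_sigma_avg(G, 1, 0.5), tolerance = 1e-6)
  Gf <- build_generator(circuit_params("feedback", alpha = 1.2, y = 0.7, s = 0.4))
  expect_equal(sigma_avg(Gf, 1, 0.5), trapezoid_sigma_avg(Gf, 1, 0.5),
               tolerance = 1e-6)
})

test_that("dissipation report is internally consistent", {
  G <- build_generator(circuit_params("no_feedback", u = 0.6, s = 1.8))
  rep <- dissipation_report(G, mu0 = 1, tau_p = 0.8, n_trace = 32)
  expect_s3_class(rep, "dissipation_report")
  expect_equal(nrow(rep$trace), 32)
  expect_true(all(rep$trace$sigma_hat >= 0))
  expect_equal(rep$relaxation_cost,
               rep$tau_p * (rep$sigma_avg - rep$sigma_hat_ss), tolerance = 1e-12)
  # infinitely dissipative circuit is flagged, not approximated
  rep0 <- dissipation_report(build_generator(
    circuit_params("no_feedback", u = 1, s = 0)), mu0 = 1, tau_p = 0.5)
  expect_true(rep0$infinite_dissipation)
  expect_identical(rep0$sigma_avg, Inf)
})
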