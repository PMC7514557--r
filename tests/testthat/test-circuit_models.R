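test_that("generators have the documented structure and zero column sums", {
  G <- build_generator(circuit_params("no_feedback", u = 1, s = 1, r = 1))
  W <- unclass(G); diag(W) <- 0
  expect_true(all(W[W != 0] == 1))                  # fully symmetric circuit
  expect_equal(colSums(G), rep(0, 4), ignore_attr = TRUE)
  expect_equal(as.numeric(steady_state(G)), rep(0.25, 4), tolerance = 1e-12)

  draws <- random_params("no_feedback", n = 50, seed = 11)
  for (p in draws) {
    G <- build_generator(p)
    expect_lt(max(abs(colSums(G))), 1e-12 * max(abs(G)))
  }
  expect_error(circuit_params("no_feedback", u = -1, s = 1), "non-negative")
  expect_error(circuit_params("no_feedback", u = 1, s = 1, r = 0), "positive")
})

test_that("feedback generator with alpha = y = u reduces to no-feedback entrywise", {
  for (p in random_params("no_feedback", n = 25, seed = 21)) {
    Gf <- build_generator(circuit_params("feedback", alpha = p$u, y = p$u, s = p$s))
    Gn <- build_generator(p)
    expect_equal(matrix(Gf, 4, 4), matrix(Gn, 4, 4), tolerance = 0)
  }
})

test_that("stationary distribution matches the no-feedback closed form", {
  G <- build_generator(circuit_params("no_feedback", u = 1, s = 3))
  expect_equal(as.numeric(steady_state(G)), c(1, 2, 2, 1) / 6, tolerance = 1e-12)

  for (p in random_params("no_feedback", n = 200, seed = 31)) {
    z <- 2 * p$s + 4 * p$u + 2
    expected <- c(p$u + 1, p$s + p$u, p$s + p$u, p$u + 1) / z
    expect_equal(as.numeric(steady_state(build_generator(p))), expected,
                 tolerance = 1e-12)
  }
})

test_that("feedback stationary distribution agrees with a null-space oracle", {
  G <- build_generator(circuit_params("feedback", alpha = 2, y = 1, s = 0.5))
  expect_equal(as.numeric(steady_state(G)), svd_steady_state(G), tolerance = 1e-10)
  for (p in random_params("feedback", n = 50, seed = 41)) {
    G <- build_generator(p)
    expect_equal(as.numeric(steady_state(G)), svd_steady_state(G), tolerance = 1e-8)
    expect_lt(max(abs(unclass(G) %*% steady_state(G))), 1e-10 * max(abs(G)))
  }
})

test_that("a frozen input makes the generator reducible and warns", {
  G <- build_generator(circuit_params("no_feedback", u = 0, s = 2))
  expect_warning(steady_state(G), "reducible")
})

test_that("relaxation rate follows min(1+s, 2u) without feedback", {
  expect_equal(relaxation_rate(build_generator(
    circuit_params("no_feedback", u = 0.4, s = 0.5))), 0.8, tolerance = 1e-12)
  expect_equal(relaxation_rate(build_generator(
    circuit_params("no_feedback", u = 1, s = 1))), 2, tolerance = 1e-12)
  for (p in random_params("no_feedback", n = 100, seed = 51)) {
    expect_equal(relaxation_rate(build_generator(p)),
                 min(1 + p$s, 2 * p$u), tolerance = 1e-10)
  }
})

test_that("feedback relaxation rate matches (A - rho)/2 when rho is real", {
  checked <- 0L
  for (p in random_params("feedback", n = 100, seed = 61)) {
    A <- 1 + p$s + p$y + p$alpha
    rho2 <- A^2 - 8 * (p$s * p$y + p$alpha)
    if (rho2 <= 1e-6) next
    expect_equal(relaxation_rate(build_generator(p)), (A - sqrt(rho2)) / 2,
                 tolerance = 1e-9)
    checked <- checked + 1L
  }
  expect_gt(checked, 20L)
})

test_that("propagation solves the master equation and preserves the simplex", {
  G <- build_generator(circuit_params("no_feedback", u = 1, s = 2))
  p0 <- sym_dist(1)
  expect_equal(as.numeric(propagate(G, p0, 0)), as.numeric(p0), tolerance = 1e-14)
  expect_equal(as.numeric(propagate(G, p0, 100)), as.numeric(steady_state(G)),
               tolerance = 1e-10)
  expect_error(propagate(G, p0, -0.1), "non-negative")

  # against the adaptive-ODE oracle
  expect_equal(as.numeric(propagate(G, p0, 0.3)), ode_propagate(G, p0, 0.3),
               tolerance = 1e-9)

  set.seed(71)
  draws <- c(random_params("no_feedback", n = 60), random_params("feedback", n = 60))
  for (p in draws) {
    G <- build_generator(p)
    pt <- propagate(G, sym_dist(runif(1, -1, 1)), rexp(1))
    expect_true(all(pt >= -1e-12))
    expect_equal(sum(pt), 1, tolerance = 1e-10)
  }
})

test_that("delayed joint matches the brute-force path sum and stays symmetric", {
  G <- build_generator(circuit_params("no_feedback", u = 1, s = 2))
  J0 <- delayed_joint(G, sym_dist(0.7), 0)
  expect_equal(mu_of(J0), 0.7, tolerance = 1e-12)

  J <- delayed_joint(G, sym_dist(1), 0.5)
  expect_equal(unclass(J), brute_delayed_joint(G, sym_dist(1), 0.5),
               ignore_attr = TRUE, tolerance = 1e-8)

  # decorrelation: joint factorizes at long delays
  Jinf <- delayed_joint(G, sym_dist(1), 60)
  expect_lt(mi_from_joint(Jinf), 1e-12)

  # symmetry closure over random draws, models and times
  set.seed(81)
  draws <- c(random_params("no_feedback", n = 50), random_params("feedback", n = 50))
  for (p in draws) {
    G <- build_generator(p)
    J <- delayed_joint(G, sym_dist(runif(1, -1, 1)), rexp(1))
    expect_lt(abs(J[1, 1] - J[2, 2]), 1e-9)
    expect_lt(abs(J[1, 2] - J[2, 1]), 1e-9)
    expect_equal(sum(J), 1, tolerance = 1e-10)
  }
})

test_that("no-feedback delayed correlation matches the two-mode closed form", {
  set.seed(91)
  for (p in random_params("no_feedback", n = 60)) {
    mu0 <- runif(1, -1, 1); t <- rexp(1)
    mu_num <- mu_of(delayed_joint(build_generator(p), sym_dist(mu0), t))
    expect_equal(mu_num, closed_mu_t(p$u, p$s, mu0, t), tolerance = 1e-6)
  }
})

test_that("mu extraction validates the symmetric class", {
  expect_equal(mu_of(matrix(0.25, 2, 2)), 0, tolerance = 1e-14)
  expect_equal(mu_of(c(0.5, 0, 0, 0.5)), 1)
  expect_equal(mu_of(c(0, 0.5, 0.5, 0)), -1)
  expect_error(mu_of(c(0.5, 0.1, 0.2, 0.2)), "asymmetric")
  expect_error(mu_of(matrix(c(0.4, 0.1, 0.2, 0.3), 2, 2)), "asymmetric")
})
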