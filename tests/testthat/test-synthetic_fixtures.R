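test_that("random parameter draws are reproducible and valid", {
  a <- random_params("feedback", n = 5, seed = 0)
  b <- random_params("feedback", n = 5, seed = 0)
  expect_identical(a, b)
  for (p in c(a, random_params("no_feedback", n = 5, seed = 1))) {
    expect_identical(p$r, 1)
    rates <- unlist(p[setdiff(names(p), "model")])
    expect_true(all(rates > 0 & is.finite(rates)))
  }
})

test_that("simulated trajectories are reproducible and well-formed", {
  G <- build_generator(circuit_params("no_feedback", u = 1, s = 1))
  t1 <- gillespie(G, sym_dist(0), duration = 10, seed = 5)
  t2 <- gillespie(G, sym_dist(0), duration = 10, seed = 5)
  expect_identical(t1, t2)
  expect_true(all(diff(t1$times) > 0))
  expect_true(all(t1$states[-1] != t1$states[-length(t1$states)]))
  # absorbing chain ends early and is flagged: with s = 0 and a frozen input
  # the aligned state of each z-block absorbs the x dynamics
  G0 <- build_generator(circuit_params("no_feedback", u = 0, s = 0))
  t3 <- gillespie(G0, 2L, duration = 50, seed = 6)
  expect_true(t3$absorbed)
  expect_lt(max(t3$times), 50)
})

test_that("ensemble occupancies converge to the stationary distribution", {
  G <- build_generator(circuit_params("no_feedback", u = 1, s = 1))
  trajs <- gillespie_ensemble(G, sym_dist(1), duration = 4, n = 4000, seed = 7)
  states <- vapply(trajs, trajectory_states_at, integer(1), times = 4)
  freq <- tabulate(states, 4) / 4000
  se <- sqrt(0.25 * 0.75 / 4000)
  expect_true(all(abs(freq - 0.25) < 3 * se))
})

test_that("ensemble delayed correlation matches the propagated value", {
  G <- build_generator(circuit_params("no_feedback", u = 1, s = 2))
  n <- 10000
  trajs <- gillespie_ensemble(G, sym_dist(1), duration = 0.4, n = n, seed = 8)
  states <- vapply(trajs, trajectory_states_at, integer(1), times = 0.4)
  p_hat <- tabulate(states, 4) / n
  p_ref <- as.numeric(propagate(G, sym_dist(1), 0.4))
  se <- sqrt(p_ref * (1 - p_ref) / n)
  expect_true(all(abs(p_hat - p_ref) < 3 * se + 1e-12))
})

test_that("path-entropy estimator recovers the stationary dissipation rate", {
  G <- build_generator(circuit_params("no_feedback", u = 1, s = 2))
  trajs <- gillespie_ensemble(G, steady_state(G), duration = 0.5, n = 6000, seed = 9)
  est <- path_entropy_mc(trajs, seq(0, 0.5, by = 0.005), G)
  z <- (attr(est, "pooled") - 0.2) / attr(est, "pooled_se")
  expect_lt(abs(z), 3)
  # equilibrium circuit: estimate consistent with zero
  Geq <- build_generator(circuit_params("no_feedback", u = 1, s = 1))
  teq <- gillespie_ensemble(Geq, steady_state(Geq), duration = 0.5, n = 4000,
                            seed = 10)
  eeq <- path_entropy_mc(teq, seq(0, 0.5, by = 0.005), Geq)
  expect_lt(abs(attr(eeq, "pooled")) , 3 * attr(eeq, "pooled_se") + 1e-9)
})

test_that("estimator standard error shrinks like the square root of the ensemble", {
  G <- build_generator(circuit_params("no_feedback", u = 1, s = 2))
  grid <- seq(0, 0.3, by = 0.0075)
  se_of <- function(n, seed) {
    trajs <- gillespie_ensemble(G, steady_state(G), duration = 0.3, n = n,
                                seed = seed)
    attr(path_entropy_mc(trajs, grid, G), "pooled_se")
  }
  s1 <- se_of(1000, 11); s4 <- se_of(4000, 12)
  expect_lt(s4 / s1, 0.65)    # ideal ratio 0.5
  expect_gt(s4 / s1, 0.35)
})

test_that("a coarse grid triggers the linearization warning", {
  G <- build_generator(circuit_params("no_feedback", u = 1, s = 2))
  trajs <- gillespie_ensemble(G, steady_state(G), duration = 1, n = 10, seed = 13)
  expect_warning(path_entropy_mc(trajs, seq(0, 1, by = 0.5), G), "too coarse")
})
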