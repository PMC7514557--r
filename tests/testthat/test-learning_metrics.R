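test_that("learning rate matches the bipartite flux formula", {
  # oracle: l_x = sum over x-flipping edges of w_ij p_j log2 p(z|x_i)/p(z|x_j),
  # per rescaled time
  flux_lx <- function(p) {
    G <- build_generator(p)
    W <- unclass(G); diag(W) <- 0
    pss <- as.numeric(steady_state(G))
    lam <- relaxation_rate(G)
    zi <- c(1L, 1L, 2L, 2L); xi <- c(1L, 2L, 1L, 2L)
    Q <- matrix(0, 2, 2)
    for (k in 1:4) Q[zi[k], xi[k]] <- Q[zi[k], xi[k]] + pss[k]
    pzgx <- sweep(Q, 2, colSums(Q), "/")
    edges <- rbind(c(2, 1), c(1, 2), c(4, 3), c(3, 4))
    v <- 0
    for (r in 1:4) {
      i <- edges[r, 1]; j <- edges[r, 2]
      if (W[i, j] > 0)
        v <- v + W[i, j] * pss[j] * log2(pzgx[zi[j], xi[i]] / pzgx[zi[j], xi[j]])
    }
    v / lam
  }
  for (p in random_params("no_feedback", n = 50, seed = 201, log_range = c(0.05, 20))) {
    expect_equal(as.numeric(learning_rate(build_generator(p))), flux_lx(p),
                 tolerance = 1e-4)
  }
})

test_that("marginal entropy productions partition the total", {
  draws <- c(random_params("no_feedback", n = 50, seed = 202),
             random_params("feedback", n = 50, seed = 203))
  for (p in draws) {
    G <- build_generator(p)
    sx <- sigma_marginal(G, "x", rescaled = FALSE)
    sz <- sigma_marginal(G, "z", rescaled = FALSE)
    tot <- as.numeric(sigma_ss(G))
    expect_lt(abs(sx + sz - tot), 1e-10 * max(1, abs(tot)))
    if (p$model == "no_feedback") expect_gte(sx, 0)
  }
  # the input flips symmetrically without feedback: all dissipation is x's
  G <- build_generator(circuit_params("no_feedback", u = 1, s = 2))
  expect_equal(sigma_marginal(G, "z", rescaled = FALSE), 0)
})

test_that("learning rate equals the apparent minus the flux-form x dissipation", {
  # with symmetric one-variable marginals the lagged-information derivative
  # decomposes as l_x = sigma_x(apparent) - sigma_x(flux form), the latter
  # being the non-negative partial entropy production of the x-edges
  flux_partial_x <- function(G) {
    W <- unclass(G); diag(W) <- 0
    p <- as.numeric(steady_state(G))
    edges <- rbind(c(2, 1), c(1, 2), c(4, 3), c(3, 4))
    v <- 0
    for (r in 1:4) {
      i <- edges[r, 1]; j <- edges[r, 2]
      v <- v + W[i, j] * p[j] * log2((W[i, j] * p[j]) / (W[j, i] * p[i]))
    }
    v / relaxation_rate(G)
  }
  for (p in random_params("no_feedback", n = 40, seed = 205,
                          log_range = c(0.05, 20))) {
    G <- build_generator(p)
    lx <- as.numeric(learning_rate(G))
    expect_equal(lx, sigma_marginal(G, "x") - flux_partial_x(G),
                 tolerance = 1e-3)
  }
})

test_that("learning efficiency is bounded by one without feedback", {
  for (p in random_params("no_feedback", n = 500, seed = 204,
                          log_range = c(0.05, 20))) {
    if (abs(p$s - 1) < 1e-3) next                  # equilibrium: 0/0
    rep <- learning_report(build_generator(p))
    expect_gte(rep$l_x, -1e-8)
    expect_lte(rep$eta, 1 + 1e-6)
  }
})

test_that("learning vanishes at equilibrium and for a frozen input", {
  Geq <- build_generator(circuit_params("no_feedback", u = 0.8, s = 1))
  expect_lt(abs(learning_rate(Geq)), 1e-6)
  expect_equal(sigma_marginal(Geq, "x"), 0)
  # frozen input: the output sits at conditional equilibrium, so the
  # natural-time learning rate vanishes with u
  Gslow <- build_generator(circuit_params("no_feedback", u = 1e-6, s = 2))
  expect_lt(abs(learning_rate(Gslow, rescaled = FALSE)), 1e-3)
})

test_that("learning rate grows with dissipation along the anti-align family", {
  lx <- vapply(c(1.5, 2, 3, 5, 8), function(s)
    as.numeric(learning_rate(build_generator(
      circuit_params("no_feedback", u = 1, s = s)))), numeric(1))
  expect_true(all(diff(lx) > 0))
})
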