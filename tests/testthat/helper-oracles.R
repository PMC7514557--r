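# Independent oracles used across the suite. They deliberately avoid the
# package's eigendecomposition fast path: propagation goes through an
# adaptive ODE integrator, quadrature through log-space trapezoids with
# Richardson refinement, and information through direct probability sums.

# adaptive-ODE propagation of the master equation (independent of expm)
ode_propagate <- function(G, p0, t) {
  if (t == 0) return(as.numeric(p0))
  Gm <- unclass(G)
  sol <- deSolve::lsoda(y = as.numeric(p0), times = c(0, t),
                        func = function(tt, y, parms) list(as.numeric(Gm %*% y)),
                        rtol = 1e-11, atol = 1e-13)
  as.numeric(sol[2, -1])
}

# brute-force delayed joint (sum over all 16 initial/final state pairs,
# conditional propagators from the ODE oracle)
brute_delayed_joint <- function(G, p0, t) {
  zi <- c(1L, 1L, 2L, 2L); xi <- c(1L, 2L, 1L, 2L)
  Q <- matrix(0, 2, 2)
  for (j in 1:4) {
    e <- numeric(4); e[j] <- 1
    cond <- ode_propagate(G, e, t)
    for (i in 1:4) Q[zi[j], xi[i]] <- Q[zi[j], xi[i]] + cond[i] * p0[j]
  }
  Q
}

# direct mutual-information sum over a 2x2 joint
brute_mi <- function(Q, base = 2) {
  pr <- rowSums(Q); pc <- colSums(Q)
  v <- 0
  for (a in 1:2) for (b in 1:2)
    if (Q[a, b] > 0) v <- v + Q[a, b] * log(Q[a, b] / (pr[a] * pc[b]), base)
  v
}

# hand-derived closed form for the no-feedback delayed-joint parameter:
# mu_t = (mu0 - A) e^{-(1+s)t} + A e^{-2ut},  A = (1-s)/(1+s-2u), r = 1
closed_mu_t <- function(u, s, mu0, t) {
  if (abs(1 + s - 2 * u) < 1e-9) u <- u + 1e-7   # avoid the resonant case
  A <- (1 - s) / (1 + s - 2 * u)
  (mu0 - A) * exp(-(1 + s) * t) + A * exp(-2 * u * t)
}

# time-averaged rescaled dissipation by trapezoid refinement in log time
# with Richardson extrapolation (independent of stats::integrate)
trapezoid_sigma_avg <- function(G, mu0, tau_p, base = 2) {
  lam <- relaxation_rate(G)
  p0 <- sym_dist(mu0)
  f <- function(tau) vapply(tau, function(tv)
    sigma_t(G, propagate(G, p0, tv / lam), base = base) / lam, numeric(1))
  trap <- function(n) {
    x <- seq(log(1e-12), log(tau_p), length.out = n)
    g <- f(exp(x)) * exp(x)
    (x[2] - x[1]) * (sum(g) - (g[1] + g[n]) / 2)
  }
  t1 <- trap(2049); t2 <- trap(4097)
  ((4 * t2 - t1) / 3) / tau_p
}

# stationary distribution via singular value decomposition (null space),
# independent of the package's linear solve
svd_steady_state <- function(G) {
  sv <- svd(unclass(G))
  p <- abs(sv$v[, 4])
  p / sum(p)
}

rand_mu0 <- function(n) runif(n, -1, 1)
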