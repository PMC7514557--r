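# Bipartite learning-rate diagnostics for the circuit models.
#
# The learning rate l_x is the instantaneous rate (at zero lag, in rescaled
# time) at which the output gains information about the current input in
# steady state. For bipartite chains without feedback it is bounded by the
# x-marginal entropy production sigma_x, giving the thermodynamic
# efficiency eta = l_x / sigma_x <= 1.

#' Steady-state learning rate of the output
#'
#' One-sided derivative at zero lag of the stationary delayed information
#' `I[z_0; x_tau]` with respect to the lag, computed with a second-order
#' forward difference, Richardson extrapolation, and a step-halving
#' consistency check (an error is raised when successive extrapolants
#' disagree, which signals a non-smooth or badly scaled model).
#'
#' With `rescaled = TRUE` (default) the lag is measured in rescaled time
#' (units of the relaxation time), matching the rescaled dissipation rates.
#' In the frozen-input limit (`u -> 0`) the natural-time learning rate
#' vanishes -- the output is at conditional equilibrium and there is nothing
#' left to learn -- while the rescaled one need not, because the rescaling
#' divides by a relaxation rate that vanishes at the same speed.
#'
#' @inheritParams steady_state
#' @param h finite-difference step (rescaled or natural lag units).
#' @param base logarithm base (2 for bits per unit lag).
#' @param rescaled measure the lag in rescaled time?
#' @return Scalar learning rate with attributes `"step"` and `"fd_error"`.
#' @export
learning_rate <- function(G, h = 1e-4, base = 2, rescaled = TRUE) {
  G <- .as_generator(G)
  lam <- relaxation_rate(G)
  pss <- steady_state(G)
  cache <- .eig_cache(G)
  scale <- if (rescaled) 1 / lam else 1
  I_of <- function(lag) {
    P <- .propagator_cached(cache, G, lag * scale)
    M <- P %*% diag(as.numeric(pss))
    Q <- matrix(0, 2, 2)
    for (i in 1:4) for (j in 1:4)
      Q[.state_z[j], .state_x[i]] <- Q[.state_z[j], .state_x[i]] + M[i, j]
    mi_from_joint(Q, base = base)
  }
  I0 <- I_of(0)
  d_one <- function(hh) (-3 * I0 + 4 * I_of(hh) - I_of(2 * hh)) / (2 * hh)
  d <- vapply(h / c(1, 2, 4), d_one, numeric(1))
  r1 <- (4 * d[2] - d[1]) / 3
  r2 <- (4 * d[3] - d[2]) / 3
  err <- abs(r2 - r1)
  if (!is.finite(r2) || err > 1e-3 * max(0.01, abs(r2)))
    stop("finite-difference learning rate did not converge (step ", h,
         ", discrepancy ", format(err), ")", call. = FALSE)
  structure(r2, step = h, fd_error = err)
}

#' Marginal entropy production of one variable
#'
#' The stationary entropy-production sum `sum p_j w_ij log(w_ij / w_ji)`
#' restricted to transitions that flip the chosen variable (the chain is
#' bipartite: no transition flips both). The two marginals partition the
#' total exactly, `sigma_x + sigma_z = sigma_ss`.
#'
#' This is the *apparent* (coarse-grained) per-variable contribution: for
#' the no-feedback family the input flips symmetrically so `sigma_z = 0`
#' and `sigma_x = sigma_ss >= 0`, and the learning efficiency
#' `eta = l_x / sigma_x` is bounded by one (numerically,
#' `l_x = sigma_x` minus the non-negative flux-form partial entropy
#' production of the x-edges). For feedback circuits an individual marginal
#' can be negative even though the total is not.
#'
#' @inheritParams steady_state
#' @param which `"x"` (output-flipping edges) or `"z"` (input-flipping).
#' @param rescaled divide by the relaxation rate (default), to match the
#'   rescaled-time learning rate.
#' @param base logarithm base.
#' @return Scalar (non-negative for the no-feedback family).
#' @export
sigma_marginal <- function(G, which = c("x", "z"), rescaled = TRUE, base = 2) {
  which <- match.arg(which)
  G <- .as_generator(G)
  W <- .rates_of(G)
  p <- steady_state(G)
  edges <- if (which == "x") .x_edges else .z_edges
  v <- 0
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    if (W[i, j] <= 0) next
    if (W[j, i] <= 0) { if (p[[j]] > 0) { v <- Inf; break }; next }
    v <- v + p[[j]] * W[i, j] * log(W[i, j] / W[j, i], base)
  }
  if (rescaled && is.finite(v)) v <- v / relaxation_rate(G)
  v
}

#' Learning-rate report: l_x, sigma_x and efficiency
#'
#' @inheritParams learning_rate
#' @return List with `l_x`, `sigma_x` (both per rescaled time), `eta`
#'   (`l_x / sigma_x`, `NaN` at equilibrium where both vanish), and
#'   `finite_difference_step`.
#' @export
learning_report <- function(G, h = 1e-4, base = 2) {
  G <- .as_generator(G)
  lx <- learning_rate(G, h = h, base = base)
  sx <- sigma_marginal(G, "x", rescaled = TRUE, base = base)
  list(l_x = as.numeric(lx), sigma_x = sx,
       eta = as.numeric(lx) / sx,
       finite_difference_step = attr(lx, "step"))
}
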