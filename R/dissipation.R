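# Entropy-production functionals for the four-state circuit models.
#
# All quantities default to base-2 logarithms so that dissipation and
# information share units (bits per unit time / bits per rescaled time).

# TRUE if some directed transition has no reverse (one-way edge):
# any positive flux across it makes the entropy production infinite.
.one_way_edges <- function(W) {
  any(W > 0 & t(W) == 0)
}

# vectorized sigma over the columns of Pmat (4 x n), natural-time rate
.sigma_cols <- function(W, Pmat, base = 2) {
  n <- ncol(Pmat)
  tot <- numeric(n)
  lb <- log(base)
  for (i in 1:4) for (j in 1:4) {
    if (i == j || W[i, j] <= 0) next
    pj <- Pmat[j, ]; pi_ <- Pmat[i, ]
    flux <- W[i, j] * pj
    term <- numeric(n)
    pos <- flux > 0
    rev <- W[j, i] * pi_
    term[pos & rev > 0] <- flux[pos & rev > 0] *
      (log(flux[pos & rev > 0] / rev[pos & rev > 0]) / lb)
    term[pos & rev <= 0] <- Inf
    tot <- tot + term
  }
  tot
}

#' Instantaneous entropy production rate
#'
#' Evaluates `sigma(t) = sum_{i,j} w_ij p_j log( w_ij p_j / (w_ji p_i) )`
#' on an arbitrary distribution `p`, the Kullback-Leibler rate between the
#' forward and time-reversed path ensembles through state `p`. It is
#' non-negative and vanishes iff detailed balance holds at `p`. If some
#' transition with positive flux has no reverse rate the result is infinite
#' and flagged via the attribute `"infinite_dissipation"`.
#'
#' @inheritParams steady_state
#' @param p probability 4-vector.
#' @param base logarithm base (2 for bits per unit time).
#' @return Non-negative rate (possibly `Inf`).
#' @export
sigma_t <- function(G, p, base = 2) {
  G <- .as_generator(G)
  stopifnot(length(p) == 4L, abs(sum(p) - 1) < 1e-8, all(p >= -1e-12))
  p <- pmax(as.numeric(p), 0)
  W <- .rates_of(G)
  v <- .sigma_cols(W, matrix(p, 4, 1), base = base)
  if (!is.finite(v)) attr(v, "infinite_dissipation") <- TRUE
  v
}

#' Steady-state entropy production rate
#'
#' `sigma_ss = sum_{i,j} p^ss_j w_ij log(w_ij / w_ji)`, evaluated at the
#' stationary distribution. Zero iff the Kolmogorov cycle condition holds
#' (detailed balance).
#'
#' @inheritParams sigma_t
#' @return Non-negative rate (possibly `Inf`, flagged as in [sigma_t()]).
#' @export
sigma_ss <- function(G, base = 2) {
  G <- .as_generator(G)
  p <- steady_state(G)
  W <- .rates_of(G)
  v <- 0
  for (i in 1:4) for (j in 1:4) {
    if (i == j || W[i, j] <= 0) next
    if (W[j, i] <= 0) {
      if (p[[j]] > 0) { v <- Inf; break }
      next
    }
    v <- v + p[[j]] * W[i, j] * log(W[i, j] / W[j, i], base)
  }
  v <- max(v, 0)
  if (!is.finite(v)) attr(v, "infinite_dissipation") <- TRUE
  v
}

#' Rescaled steady-state entropy production
#'
#' `sigma_ss` divided by the relaxation rate: dissipation per rescaled time
#' unit, the quantity constrained in the optimization study.
#'
#' @inheritParams sigma_ss
#' @export
sigma_hat_ss <- function(G, base = 2) {
  G <- .as_generator(G)
  v <- sigma_ss(G, base = base)
  out <- v / relaxation_rate(G)
  if (!is.finite(out)) attr(out, "infinite_dissipation") <- TRUE
  out
}

#' Closed-form steady-state dissipation (r = 1)
#'
#' For the no-feedback model,
#' `sigma_ss(u, s) = (s - 1) u log2(s) / (1 + s + 2u)`, and its rescaled
#' version divides by `lambda = min(1 + s, 2u)`. For the feedback model the
#' rescaled closed form is
#' `sigma_hat_ss = 2 (alpha - s y) log2(alpha / (s y)) / (A (A - rho))` with
#' `A = 1 + s + y + alpha` and `rho = sqrt(A^2 - 8 (s y + alpha))`; it applies
#' only where `rho` is real (otherwise `NA` is returned with a warning and
#' the numeric route [sigma_hat_ss()] should be used). `s = 0` gives a
#' flagged `Inf` (the circuit is infinitely dissipative).
#'
#' @param params a [circuit_params()] object with `r = 1`.
#' @param rescaled divide by the relaxation rate? (The feedback closed form
#'   exists only in rescaled form, so `rescaled = FALSE` multiplies it back.)
#' @inheritParams sigma_t
#' @return Scalar dissipation (possibly `Inf` or `NA`).
#' @export
sigma_ss_closed <- function(params, rescaled = FALSE, base = 2) {
  stopifnot(inherits(params, "circuit_params"))
  if (abs(params$r - 1) > 1e-12)
    stop("closed forms assume the rate convention r = 1", call. = FALSE)
  lb <- log(base)
  if (params$model == "no_feedback") {
    u <- params$u; s <- params$s
    if (s == 0) {
      out <- if (u > 0) Inf else 0
      if (!is.finite(out)) attr(out, "infinite_dissipation") <- TRUE
      return(out)
    }
    v <- (s - 1) * u * (log(s) / lb) / (1 + s + 2 * u)
    if (rescaled) v <- v / min(1 + s, 2 * u)
    return(v)
  }
  a <- params$alpha; y <- params$y; s <- params$s
  if (s == 0 || a == 0 || y == 0) {
    out <- Inf
    attr(out, "infinite_dissipation") <- TRUE
    return(out)
  }
  A <- 1 + s + y + a
  rho2 <- A^2 - 8 * (s * y + a)
  if (rho2 < 0) {
    warning("complex relaxation spectrum (rho^2 < 0): closed form inapplicable, ",
            "use sigma_hat_ss() on the generator")
    return(NA_real_)
  }
  rho <- sqrt(rho2)
  v <- 2 * (a - s * y) / (A * (A - rho)) * (log(a / (s * y)) / lb)
  if (!rescaled) v <- v * (A - rho) / 2
  v
}

#' Time-averaged rescaled dissipation up to a reset time
#'
#' `Sigma_avg(tau_p) = (1/tau_p) integral_0^tau_p sigma_hat(tau) d tau`,
#' where `sigma_hat(tau) = sigma(tau/lambda)/lambda` is the rescaled
#' instantaneous entropy production along the relaxation from the initial
#' condition `mu0`. The integrand has an integrable logarithmic singularity
#' at `tau = 0` when `mu0 = +-1`; the quadrature integrates adaptively on
#' `[eps, tau_p]` (`eps = 1e-8`) and adds the analytically bounded remainder
#' of the initial sliver.
#'
#' @inheritParams steady_state
#' @param mu0 initial symmetry parameter, or a probability 4-vector.
#' @param tau_p reset time (rescaled units), `> 0`.
#' @inheritParams sigma_t
#' @param rel_tol relative quadrature tolerance.
#' @return Scalar average dissipation (bits per rescaled time).
#' @export
sigma_avg <- function(G, mu0, tau_p, base = 2, rel_tol = 1e-8) {
  G <- .as_generator(G)
  stopifnot(tau_p > 0)
  W <- .rates_of(G)
  if (.one_way_edges(W)) {
    out <- Inf
    attr(out, "infinite_dissipation") <- TRUE
    return(out)
  }
  p0 <- if (length(mu0) == 1L) sym_dist(mu0) else as.numeric(mu0)
  lam <- relaxation_rate(G)
  cache <- .eig_cache(G)
  f <- function(tau) .sigma_cols(W, .propagate_cached(cache, G, p0, tau / lam),
                                 base = base) / lam
  eps <- 1e-8
  if (tau_p <= 2 * eps) return(f(tau_p / 2))
  # substitute tau = exp(x): the integrable log-singularity at tau = 0
  # (present when mu0 = +-1) becomes a smooth, exponentially damped integrand
  val <- integrate(function(x) f(exp(x)) * exp(x), log(eps), log(tau_p),
                   rel.tol = rel_tol, subdivisions = 500L)$value
  # remainder on [0, eps]: integrand ~ C log(1/tau), bounded by eps * f(eps)
  # up to O(eps); correction keeps the average accurate to ~eps absolute
  val <- val + eps * min(f(eps), f(2 * eps))
  val / tau_p
}

#' Full dissipation report for a relaxing circuit
#'
#' Bundles the sampled rescaled dissipation trace `sigma_hat(tau)` on a
#' geometric grid, the rescaled steady-state value, the time-averaged
#' dissipation up to the reset time, and the relaxation cost
#' `tau_p (Sigma_avg - sigma_hat_ss)` (the extra energy dissipated while
#' relaxing from the initial condition).
#'
#' @inheritParams sigma_avg
#' @param n_trace number of geometric grid points for the trace.
#' @return Object of class `dissipation_report`: a list with elements
#'   `trace` (data.frame `tau`, `sigma_hat`), `sigma_hat_ss`, `sigma_avg`,
#'   `relaxation_cost`, `tau_p`, `base`.
#' @export
dissipation_report <- function(G, mu0, tau_p, n_trace = 64, base = 2) {
  G <- .as_generator(G)
  W <- .rates_of(G)
  shss <- sigma_hat_ss(G, base = base)
  if (!is.finite(shss)) {
    out <- list(trace = data.frame(tau = numeric(), sigma_hat = numeric()),
                sigma_hat_ss = Inf, sigma_avg = Inf, relaxation_cost = Inf,
                tau_p = tau_p, base = base, infinite_dissipation = TRUE)
    return(structure(out, class = "dissipation_report"))
  }
  lam <- relaxation_rate(G)
  cache <- .eig_cache(G)
  p0 <- if (length(mu0) == 1L) sym_dist(mu0) else as.numeric(mu0)
  taus <- exp(seq(log(tau_p * 1e-4), log(tau_p), length.out = n_trace))
  sh <- .sigma_cols(W, .propagate_cached(cache, G, p0, taus / lam), base) / lam
  savg <- sigma_avg(G, mu0, tau_p, base = base)
  out <- list(trace = data.frame(tau = taus, sigma_hat = sh),
              sigma_hat_ss = as.numeric(shss), sigma_avg = savg,
              relaxation_cost = tau_p * (savg - as.numeric(shss)),
              tau_p = tau_p, base = base, infinite_dissipation = FALSE)
  structure(out, class = "dissipation_report")
}

#' @export
print.dissipation_report <- function(x, ...) {
  cat("dissipation report (base", x$base, "logs)\n")
  cat(sprintf("  sigma_hat_ss    = %g\n", x$sigma_hat_ss))
  cat(sprintf("  Sigma_avg(%g)   = %g\n", x$tau_p, x$sigma_avg))
  cat(sprintf("  relaxation cost = %g\n", x$relaxation_cost))
  invisible(x)
}
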