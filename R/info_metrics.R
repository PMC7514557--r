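#' Mutual information of a symmetric binary joint from mu
#'
#' For the symmetric joint `((1+mu)/4, (1-mu)/4, (1-mu)/4, (1+mu)/4)` the
#' mutual information between the two binary variables reduces to
#' `I = ((1+mu) log(1+mu) + (1-mu) log(1-mu)) / 2` (base-2 logs by default,
#' so `I` is in bits; `0 log 0 := 0` by continuity). `I` is symmetric in
#' `mu -> -mu`, increasing on `[0, 1]`, and reaches 1 bit at `mu = 1`.
#'
#' @param mu scalar (or vector) in `[-1, 1]`.
#' @param base logarithm base (2 for bits, `exp(1)` for nats).
#' @return Information in `log(base)` units, same length as `mu`.
#' @examples
#' mi_from_mu(c(0, 0.5, 1))
#' @export
mi_from_mu <- function(mu, base = 2) {
  if (any(!is.finite(mu)) || any(abs(mu) > 1 + 1e-12))
    stop("'mu' must lie in [-1, 1]", call. = FALSE)
  mu <- pmax(-1, pmin(1, mu))
  xlx <- function(x) ifelse(x > 0, x * log(x, base), 0)
  (xlx(1 + mu) + xlx(1 - mu)) / 2
}

#' Mutual information of a general 2x2 joint
#'
#' Direct evaluation of `I = sum p(x,z) log p(x,z)/(p(x) p(z))` over the four
#' cells. For joints in the symmetric class this equals
#' `mi_from_mu(mu_of(pxz))` to machine precision.
#'
#' @param pxz a 2x2 joint probability matrix (e.g. a [delayed_joint()]).
#' @inheritParams mi_from_mu
#' @return Non-negative information value.
#' @export
mi_from_joint <- function(pxz, base = 2) {
  q <- unclass(pxz)
  stopifnot(is.matrix(q), all(dim(q) == c(2L, 2L)), all(q >= -1e-12))
  if (abs(sum(q) - 1) > 1e-8) stop("joint is not normalized", call. = FALSE)
  q[q < 0] <- 0
  pr <- rowSums(q); pc <- colSums(q)
  v <- 0
  for (a in 1:2) for (b in 1:2)
    if (q[a, b] > 0) v <- v + q[a, b] * log(q[a, b] / (pr[a] * pc[b]), base)
  max(v, 0)
}

#' Thermodynamic coupling function of a 2x2 joint
#'
#' The cellwise log-ratio `log2 p(x,z) / (p(x) p(z))`, which measures the
#' local degree of correlation of the two variables; it is identically zero
#' iff the joint factorizes, and its expectation under the joint is the
#' mutual information. Cells with zero joint probability carry `-Inf`
#' (they have zero weight in the information sum).
#'
#' @inheritParams mi_from_joint
#' @return A 2x2 matrix of log-ratios.
#' @export
coupling_function <- function(pxz, base = 2) {
  q <- unclass(pxz)
  stopifnot(is.matrix(q), all(dim(q) == c(2L, 2L)), all(q >= -1e-12))
  q[q < 0] <- 0
  pr <- rowSums(q); pc <- colSums(q)
  if (any(pr <= 0) || any(pc <= 0))
    stop("marginals must be strictly positive", call. = FALSE)
  out <- log(q / outer(pr, pc), base)   # -Inf sentinel where q == 0
  dimnames(out) <- dimnames(q)
  out
}

#' Delayed mutual information of a circuit
#'
#' Convenience wrapper: information (in bits) between the input at time 0 and
#' the output at rescaled readout time `tau`, i.e. at natural time
#' `t = tau / lambda` where `lambda` is the circuit's relaxation rate.
#'
#' @inheritParams steady_state
#' @param mu0 initial symmetry parameter (scalar in `[-1, 1]`); defaults to
#'   the stationary value.
#' @param tau rescaled readout delay (scalar or vector).
#' @inheritParams mi_from_mu
#' @return Information values, one per `tau`.
#' @export
delayed_information <- function(G, tau, mu0 = NULL, base = 2) {
  G <- .as_generator(G)
  lam <- relaxation_rate(G)
  p0 <- if (is.null(mu0)) steady_state(G) else sym_dist(mu0)
  vapply(tau, function(tv) {
    mi_from_joint(delayed_joint(G, p0, tv / lam), base = base)
  }, numeric(1))
}
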