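#' Parameters of a symmetric two-variable circuit
#'
#' Defines the transition rates of the symmetric four-state model of an
#' input-output pair of binary variables. Without feedback the input `z`
#' flips freely at rate `u` in both directions while the output `x` aligns to
#' the input at rate `r` and anti-aligns at rate `s`. With feedback the input
#' flip rates depend on the output: the two variables anti-align at rate
#' `alpha` and align at rate `y` (via `z` flips), while `x` behaves as before.
#' Setting `alpha = y = u` recovers the no-feedback model exactly.
#'
#' All analysis entry points use the convention `r = 1`, which fixes the time
#' unit and breaks the clockwise/counter-clockwise symmetry of the cycle.
#'
#' @param model `"no_feedback"` or `"feedback"`.
#' @param u input flip rate (no-feedback model only), `>= 0`.
#' @param s output anti-align rate, `>= 0`.
#' @param r output align rate, `> 0` (defaults to 1).
#' @param alpha input anti-align rate (feedback model only), `>= 0`.
#' @param y input align rate (feedback model only), `>= 0`.
#' @return An object of class `circuit_params`.
#' @examples
#' circuit_params("no_feedback", u = 1, s = 2)
#' circuit_params("feedback", alpha = 2, y = 1, s = 0.5)
#' @export
circuit_params <- function(model = c("no_feedback", "feedback"),
                           u = NULL, s, r = 1, alpha = NULL, y = NULL) {
  model <- match.arg(model)
  chk <- function(v, nm, strict = FALSE) {
    if (is.null(v) || length(v) != 1L || !is.finite(v) || v < 0 || (strict && v <= 0))
      stop("rate '", nm, "' must be a single finite ",
           if (strict) "positive" else "non-negative", " number", call. = FALSE)
    as.numeric(v)
  }
  s <- chk(s, "s"); r <- chk(r, "r", strict = TRUE)
  if (model == "no_feedback") {
    u <- chk(u, "u")
    if (!is.null(alpha) || !is.null(y))
      stop("'alpha'/'y' are feedback-only parameters", call. = FALSE)
    out <- list(model = model, u = u, s = s, r = r)
  } else {
    alpha <- chk(alpha, "alpha"); y <- chk(y, "y")
    if (!is.null(u)) stop("'u' is a no-feedback-only parameter", call. = FALSE)
    out <- list(model = model, alpha = alpha, y = y, s = s, r = r)
  }
  structure(out, class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  if (x$model == "no_feedback") {
    cat(sprintf("circuit (no feedback): u = %g, s = %g, r = %g\n", x$u, x$s, x$r))
  } else {
    cat(sprintf("circuit (feedback): alpha = %g, y = %g, s = %g, r = %g\n",
                x$alpha, x$y, x$s, x$r))
  }
  invisible(x)
}

#' Build the four-state generator of a circuit
#'
#' Returns the generator `G` of the master equation `dp/dt = G p`, a 4x4
#' matrix whose off-diagonal entry `G[i, j]` is the rate of jumping from
#' state `j` to state `i` and whose columns sum to zero. The state order is
#' `(-,-), (-,+), (+,-), (+,+)` for `(z, x)`. Note that the conventional
#' rate-matrix `L` with positive spectrum (relaxation rates) is `-G`.
#'
#' @param params a [circuit_params()] object.
#' @return A 4x4 matrix of class `generator4` with the parameters attached as
#'   attribute `"params"`.
#' @examples
#' G <- build_generator(circuit_params("no_feedback", u = 1, s = 3))
#' colSums(G)          # zero
#' steady_state(G)     # (1/6, 1/3, 1/3, 1/6)
#' @export
build_generator <- function(params) {
  stopifnot(inherits(params, "circuit_params"))
  W <- matrix(0, 4, 4, dimnames = list(.state_labels, .state_labels))
  # output x: aligned -> anti-aligned at s, anti-aligned -> aligned at r
  W[2, 1] <- params$s; W[1, 2] <- params$r
  W[4, 3] <- params$r; W[3, 4] <- params$s
  if (params$model == "no_feedback") {
    # input z flips at u regardless of x
    W[3, 1] <- W[1, 3] <- W[4, 2] <- W[2, 4] <- params$u
  } else {
    # z flips anti-align the pair at alpha, align it at y
    W[3, 1] <- W[2, 4] <- params$alpha
    W[1, 3] <- W[4, 2] <- params$y
  }
  G <- W - diag(colSums(W))
  structure(G, class = c("generator4", class(G)), params = params)
}

.as_generator <- function(x) {
  if (inherits(x, "circuit_params")) return(build_generator(x))
  if (is.matrix(x) && all(dim(x) == c(4L, 4L))) {
    if (max(abs(colSums(x))) > 1e-8 * max(abs(x), 1))
      stop("matrix is not a generator: columns do not sum to zero", call. = FALSE)
    return(x)
  }
  stop("expected a 'circuit_params' object or a 4x4 generator matrix", call. = FALSE)
}

# off-diagonal rate table w[i, j] = rate j -> i
.rates_of <- function(G) {
  W <- unclass(G)
  diag(W) <- 0
  W
}

# eigendecomposition cache used by all propagation-heavy code paths
.eig_cache <- function(G) {
  e <- eigen(unclass(G))
  V <- e$vectors
  Vinv <- tryCatch(solve(V), error = function(err) NULL)
  ok <- !is.null(Vinv) && max(Mod(V %*% Vinv - diag(4))) < 1e-8
  list(values = e$values, V = V, Vinv = Vinv, ok = ok)
}

# p(t) columns for each t in tvec, from cache (falls back to Matrix::expm
# scaling-and-squaring when the eigenbasis is ill-conditioned)
.propagate_cached <- function(cache, G, p0, tvec) {
  if (cache$ok) {
    C0 <- as.vector(cache$Vinv %*% p0)
    E <- exp(outer(cache$values, tvec))       # 4 x n
    P <- Re(cache$V %*% (E * C0))
  } else {
    P <- vapply(tvec, function(t) {
      as.numeric(as.matrix(Matrix::expm(Matrix::Matrix(unclass(G) * t))) %*% p0)
    }, numeric(4))
    P <- matrix(P, nrow = 4)
  }
  # clip tiny negative round-off and renormalize
  P[P < 0 & P > -1e-12] <- 0
  sweep(P, 2, colSums(P), "/")
}

# full conditional propagator exp(G t) as a 4x4 stochastic matrix
.propagator_cached <- function(cache, G, t) {
  if (cache$ok) {
    P <- Re(cache$V %*% (exp(cache$values * t) * cache$Vinv))
  } else {
    P <- as.matrix(Matrix::expm(Matrix::Matrix(unclass(G) * t)))
  }
  P[P < 0 & P > -1e-12] <- 0
  sweep(P, 2, colSums(P), "/")
}

#' Stationary distribution of a circuit generator
#'
#' Solves `G p = 0` with the normalization constraint. For irreducible
#' generators (all relevant rates positive) the solution is unique; if the
#' generator is reducible (some rate zero creates an absorbing set), a
#' warning is emitted and the absorbing-limit distribution is returned.
#'
#' @param G a `generator4` matrix or a [circuit_params()] object.
#' @return Probability 4-vector with the symmetry parameter as attribute
#'   `"mu"` (when the distribution is in the symmetric class).
#' @export
steady_state <- function(G) {
  G <- .as_generator(G)
  Gm <- unclass(G)
  p <- tryCatch({
    A <- rbind(Gm[1:3, ], rep(1, 4))
    solve(A, c(0, 0, 0, 1))
  }, error = function(e) NULL)
  if (is.null(p) || min(p) < -1e-9) {
    # reducible / degenerate generator: take the null space
    sv <- svd(Gm)
    nz <- sum(sv$d < 1e-10 * max(sv$d, 1))
    if (nz > 1L)
      warning("generator is reducible: stationary distribution is not unique; ",
              "returning one absorbing-limit distribution")
    else
      warning("generator is near-degenerate; returning absorbing-limit distribution")
    p <- abs(sv$v[, 4])
    p <- p / sum(p)
  }
  p[p < 0] <- 0
  p <- p / sum(p)
  names(p) <- .state_labels
  if (abs(p[1] - p[4]) < 1e-9 && abs(p[2] - p[3]) < 1e-9)
    attr(p, "mu") <- 2 * (p[[1]] + p[[4]]) - 1
  p
}

#' Relaxation rate of a circuit
#'
#' The inverse relaxation time `lambda`: the smallest positive real part
#' among the non-zero eigenvalues of the rate matrix `L = -G`. For the
#' no-feedback model with `r = 1` this equals `min(1 + s, 2u)`; for the
#' feedback model it equals `(A - rho)/2` with `A = 1 + s + y + alpha` and
#' `rho = sqrt(A^2 - 8(sy + alpha))` whenever `rho` is real.
#'
#' @inheritParams steady_state
#' @return Positive scalar rate.
#' @export
relaxation_rate <- function(G) {
  G <- .as_generator(G)
  ev <- eigen(-unclass(G), only.values = TRUE)$values
  rad <- max(abs(ev))
  if (rad == 0) stop("degenerate model: all eigenvalues are zero", call. = FALSE)
  re <- Re(ev)[Mod(ev) > 1e-10 * rad]
  re <- re[re > 1e-10 * rad]
  if (length(re) == 0L) stop("degenerate model: no relaxing eigenvalue", call. = FALSE)
  min(re)
}

#' Propagate a distribution under the master equation
#'
#' Matrix-exponential solution `p(t) = exp(G t) p0` of `dp/dt = G p`,
#' computed through the eigendecomposition of `G` (with a
#' scaling-and-squaring fallback when the eigenbasis is ill-conditioned).
#'
#' @inheritParams steady_state
#' @param p0 initial probability 4-vector (e.g. [sym_dist()]).
#' @param t non-negative time (scalar or vector), in natural (unrescaled) units.
#' @return A probability 4-vector, or a 4 x `length(t)` matrix for vector `t`.
#' @export
propagate <- function(G, p0, t) {
  G <- .as_generator(G)
  if (any(t < 0)) stop("time 't' must be non-negative", call. = FALSE)
  stopifnot(length(p0) == 4L, abs(sum(p0) - 1) < 1e-8, all(p0 >= -1e-12))
  P <- .propagate_cached(.eig_cache(G), G, as.numeric(p0), t)
  rownames(P) <- .state_labels
  if (length(t) == 1L) setNames(P[, 1], .state_labels) else P
}

#' Symmetric four-state distribution
#'
#' The one-parameter symmetric family
#' `p = ((1+mu)/4, (1-mu)/4, (1-mu)/4, (1+mu)/4)`: `mu = 1` puts all mass on
#' the aligned states, `mu = 0` is uniform, `mu = -1` is fully anti-aligned.
#'
#' @param mu scalar in `[-1, 1]`.
#' @return Probability 4-vector.
#' @export
sym_dist <- function(mu) {
  if (!is.finite(mu) || abs(mu) > 1 + 1e-12)
    stop("'mu' must lie in [-1, 1]", call. = FALSE)
  mu <- max(-1, min(1, mu))
  setNames(c(1 + mu, 1 - mu, 1 - mu, 1 + mu) / 4, .state_labels)
}

#' Joint distribution of the initial input and the delayed output
#'
#' Computes `p(x_t, z_0)` by propagating a point mass from each initial state,
#' marginalizing over the final input and initial output, and weighting by the
#' initial distribution. For a symmetric `p0` the result stays in the
#' symmetric class and is summarized by a single parameter `mu_t`
#' (see [mu_of()]).
#'
#' @inheritParams propagate
#' @param p0 initial joint distribution of `(z_0, x_0)` (4-vector).
#' @param t readout delay in natural units (scalar).
#' @return A 2x2 matrix of class `delayed_joint` with rows `z0 = -,+` and
#'   columns `xt = -,+`; attributes `t` and `tau` (the delay rescaled by the
#'   relaxation rate).
#' @export
delayed_joint <- function(G, p0, t) {
  G <- .as_generator(G)
  stopifnot(length(t) == 1L, t >= 0)
  P <- .propagator_cached(.eig_cache(G), G, t)          # conditional propagator
  M <- P %*% diag(as.numeric(p0))                       # joint of (state_t, state_0)
  Q <- matrix(0, 2, 2, dimnames = list(z0 = c("-", "+"), xt = c("-", "+")))
  for (i in 1:4) for (j in 1:4)
    Q[.state_z[j], .state_x[i]] <- Q[.state_z[j], .state_x[i]] + M[i, j]
  structure(Q, class = c("delayed_joint", class(Q)),
            t = t, tau = t * relaxation_rate(G))
}

#' Extract the symmetry parameter mu from a joint distribution
#'
#' For a symmetric joint (aligned cells equal, anti-aligned cells equal)
#' returns `mu` = aligned mass minus anti-aligned mass. Accepts either the
#' 2x2 [delayed_joint()] of `(z_0, x_t)` or a symmetric probability 4-vector.
#'
#' @param pxz a `delayed_joint` 2x2 matrix or a probability 4-vector.
#' @param tol symmetry tolerance (default `1e-8`).
#' @return Scalar `mu` in `[-1, 1]`.
#' @export
mu_of <- function(pxz, tol = 1e-8) {
  if (is.matrix(pxz) && all(dim(pxz) == c(2L, 2L))) {
    q <- unclass(pxz)
    if (abs(sum(q) - 1) > 1e-8) stop("joint is not normalized", call. = FALSE)
    if (abs(q[1, 1] - q[2, 2]) > tol)
      stop("asymmetric joint: aligned cells p(-,-) and p(+,+) differ by ",
           format(abs(q[1, 1] - q[2, 2])), call. = FALSE)
    if (abs(q[1, 2] - q[2, 1]) > tol)
      stop("asymmetric joint: anti-aligned cells p(-,+) and p(+,-) differ by ",
           format(abs(q[1, 2] - q[2, 1])), call. = FALSE)
    return(2 * (q[1, 1] + q[2, 2]) - 1)
  }
  if (length(pxz) == 4L) {
    p <- as.numeric(pxz)
    if (abs(sum(p) - 1) > 1e-8) stop("distribution is not normalized", call. = FALSE)
    if (abs(p[1] - p[4]) > tol)
      stop("asymmetric distribution: pure states p1 and p4 differ by ",
           format(abs(p[1] - p[4])), call. = FALSE)
    if (abs(p[2] - p[3]) > tol)
      stop("asymmetric distribution: mixed states p2 and p3 differ by ",
           format(abs(p[2] - p[3])), call. = FALSE)
    return(2 * (p[1] + p[4]) - 1)
  }
  stop("expected a 2x2 joint or a probability 4-vector", call. = FALSE)
}

#' Symmetry parameter of the stationary distribution
#'
#' @inheritParams steady_state
#' @return Scalar `mu` of the stationary distribution.
#' @export
mu_steady_state <- function(G) {
  p <- steady_state(G)
  mu <- attr(p, "mu")
  if (is.null(mu)) stop("stationary distribution is not in the symmetric class",
                        call. = FALSE)
  mu
}
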