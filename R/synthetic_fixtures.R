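# Random parameter draws, exact stochastic simulation, and the
# path-probability Monte Carlo estimator of dissipation. These provide the
# independent trajectory-level oracle for the master-equation functionals.

#' Draw random circuit parameters
#'
#' Rates are log-uniform on `log_range` with `r = 1`; the stream is
#' reproducible from the seed. Used throughout the property-test suites.
#'
#' @param model_kind `"no_feedback"` or `"feedback"`.
#' @param n number of draws.
#' @param seed optional RNG seed.
#' @param log_range two positive numbers: range of the log-uniform rates.
#' @return A list of [circuit_params()] (length `n`).
#' @export
random_params <- function(model_kind = c("no_feedback", "feedback"), n = 1,
                          seed = NULL, log_range = c(1e-2, 1e2)) {
  model_kind <- match.arg(model_kind)
  stopifnot(length(log_range) == 2L, all(log_range > 0), log_range[2] > log_range[1])
  draw <- function() {
    rl <- function() exp(runif(1, log(log_range[1]), log(log_range[2])))
    if (model_kind == "no_feedback")
      circuit_params("no_feedback", u = rl(), s = rl())
    else
      circuit_params("feedback", alpha = rl(), y = rl(), s = rl())
  }
  if (!is.null(seed)) .with_seed(seed, replicate(n, draw(), simplify = FALSE))
  else replicate(n, draw(), simplify = FALSE)
}

#' Exact stochastic simulation of a circuit trajectory
#'
#' Gillespie's direct method on the four-state chain: exponential waiting
#' times with the current state's total exit rate, jump targets drawn
#' proportionally to the outgoing rates. If a state with zero exit rate is
#' reached (absorbing), the trajectory ends early and is flagged.
#'
#' @inheritParams steady_state
#' @param p0 initial distribution (4-vector) or a fixed initial state index.
#' @param duration total simulated time (`> 0`).
#' @param seed optional RNG seed (trajectories are reproducible from it).
#' @return Object of class `trajectory`: list with `times` (jump times,
#'   starting at 0), `states` (state indices, one per jump epoch),
#'   `duration`, `absorbed` flag, and `seed`.
#' @export
gillespie <- function(G, p0, duration, seed = NULL) {
  G <- .as_generator(G)
  stopifnot(duration > 0)
  W <- .rates_of(G)
  exit <- colSums(W)
  sim <- function() {
    s <- if (length(p0) == 1L) as.integer(p0)
         else sample.int(4L, 1L, prob = pmax(p0, 0))
    times <- 0; states <- s; t <- 0
    absorbed <- FALSE
    repeat {
      if (exit[s] <= 0) { absorbed <- TRUE; break }
      t <- t + rexp(1L, exit[s])
      if (t >= duration) break
      s <- sample.int(4L, 1L, prob = W[, s])
      times <- c(times, t); states <- c(states, s)
    }
    structure(list(times = times, states = states, duration = duration,
                   absorbed = absorbed, seed = seed),
              class = "trajectory")
  }
  if (!is.null(seed)) .with_seed(seed, sim()) else sim()
}

#' Simulate an ensemble of trajectories
#'
#' @inheritParams gillespie
#' @param n ensemble size.
#' @return List of `trajectory` objects, reproducible from `seed`.
#' @export
gillespie_ensemble <- function(G, p0, duration, n, seed = NULL) {
  G <- .as_generator(G)
  run <- function() replicate(n, gillespie(G, p0, duration), simplify = FALSE)
  if (!is.null(seed)) .with_seed(seed, run()) else run()
}

#' States of a trajectory at given times
#'
#' @param traj a [gillespie()] trajectory.
#' @param times query times within `[0, duration]`.
#' @return Integer vector of state indices (step-function lookup).
#' @export
trajectory_states_at <- function(traj, times) {
  stopifnot(inherits(traj, "trajectory"), all(times >= 0),
            all(times <= traj$duration))
  traj$states[findInterval(times, traj$times)]
}

#' Path-probability Monte Carlo estimator of dissipation
#'
#' Estimates the instantaneous entropy production rate on a time grid from
#' an ensemble of trajectories, by comparing the probabilities of each
#' observed one-step transition and its reverse. The per-step log-ratio
#' `log[ P(b|a) p_t(a) / (P(a|b) p_t(b)) ]` uses the linearized transition
#' probabilities `P(b|a) = w_ba * dt` (for `b != a`) and the empirical
#' ensemble occupancies `p_t`; averaged over the ensemble and divided by
#' `dt` it converges to `sigma(t)` as `dt -> 0` and the ensemble grows.
#' Transitions whose reverse rate is zero signal infinite dissipation
#' (flagged `Inf`). Grid steps are validated against the linearization
#' criterion `max exit rate * dt <= 0.05`.
#'
#' @param trajectories list of [gillespie()] trajectories from a common
#'   generator and initial condition.
#' @param t_grid increasing time grid; dissipation is estimated on each
#'   interval and reported at its left endpoint.
#' @inheritParams steady_state
#' @param base logarithm base (2 for bits per unit time).
#' @return `data.frame` with columns `t`, `sigma` (estimate, natural-time
#'   rate), `se` (standard error over trajectories), `n`; attributes
#'   `"pooled"` and `"pooled_se"` carry the time-averaged rate with a
#'   trajectory-level standard error (valid for stationary ensembles).
#' @export
path_entropy_mc <- function(trajectories, t_grid, G, base = 2) {
  G <- .as_generator(G)
  W <- .rates_of(G)
  stopifnot(length(t_grid) >= 2L, all(diff(t_grid) > 0))
  dt <- diff(t_grid)
  if (max(colSums(W)) * max(dt) > 0.05 + 1e-12)
    warning("grid step too coarse for the linearized transition probabilities: ",
            "max exit rate * dt = ", format(max(colSums(W)) * max(dt)))
  S <- vapply(trajectories, trajectory_states_at, integer(length(t_grid)),
              times = t_grid)                       # grid-times x n
  S <- matrix(S, nrow = length(t_grid))
  n <- ncol(S)
  lb <- log(base)
  contribs <- matrix(0, length(dt), n)              # per-step rate, per trajectory
  for (k in seq_along(dt)) {
    a <- S[k, ]; b <- S[k + 1L, ]
    p_a <- tabulate(a, 4L) / n
    p_b <- tabulate(b, 4L) / n
    contrib <- numeric(n)
    jump <- a != b
    if (any(jump)) {
      wf <- W[cbind(b[jump], a[jump])]
      wb <- W[cbind(a[jump], b[jump])]
      val <- ifelse(wf > 0 & wb > 0,
                    log(wf * p_a[a[jump]] / (wb * p_b[b[jump]])) / lb,
                    ifelse(wf > 0 & wb == 0, Inf, 0))
      contrib[jump] <- val
    }
    contribs[k, ] <- contrib / dt[k]
  }
  out <- data.frame(t = t_grid[-length(t_grid)],
                    sigma = rowMeans(contribs),
                    se = apply(contribs, 1, stats::sd) / sqrt(n),
                    n = n)
  # time-averaged rate per trajectory: trajectories are independent, so the
  # pooled standard error is valid even though successive steps are not
  traj_mean <- colSums(contribs * dt) / sum(dt)
  attr(out, "pooled") <- mean(traj_mean)
  attr(out, "pooled_se") <- stats::sd(traj_mean) / sqrt(n)
  out
}
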