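---
title: "Models and methods: information-dissipation trade-offs in binary circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: information-dissipation trade-offs in binary circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circdiss)
```

## The model

A regulatory event is reduced to two binary variables: an input `z`
(receptor or transcription-factor state) and an output `x` (activation of
the regulated element), each taking values `-` and `+`. The pair evolves as
a continuous-time Markov chain on the four states, ordered globally as
`(z, x)` in `(-,-), (-,+), (+,-), (+,+)`. States 1 and 4 are *aligned*,
2 and 3 *anti-aligned*. Two symmetry assumptions define the class we study:
the pure states are interchangeable, and so are the mixed ones. This is a
modelling simplification, not a biological observation; it reduces the
feedback model from eight rates to four and makes every distribution of
interest expressible by a single scalar,

\[ p = \left(\tfrac{1+\mu}{4}, \tfrac{1-\mu}{4}, \tfrac{1-\mu}{4},
\tfrac{1+\mu}{4}\right), \qquad \mu \in [-1, 1]. \]

Two circuit families are implemented (`circuit_params()`,
`build_generator()`):

* **no feedback** — `z` flips at rate `u` in both directions; `x` aligns to
  the current `z` at rate `r` and anti-aligns at rate `s`;
* **feedback** — `x` behaves as above, but `z`'s flips now depend on `x`:
  the pair anti-aligns at `alpha` and aligns at `y`. Setting
  `alpha = y = u` recovers the no-feedback generator exactly, which the
  optimizer exploits (below).

All rates are per unit time; `r = 1` throughout the analysis layer, which
fixes the time unit and breaks the clockwise/counter-clockwise degeneracy
of the cycle (this is why the analysis restricts `mu0` to `[0, 1]`: the
negative branch belongs to the mirror-image circuits with `s = 1` instead).
Internally the generator `G` has non-negative off-diagonals and zero column
sums, so the master equation reads `dp/dt = G p`; the positive-spectrum rate
matrix that defines relaxation times is `L = -G`. Keeping one sign
convention in one place avoids a classic source of double-negative bugs.

The *relaxation rate* `lambda` is the smallest positive real part among the
non-zero eigenvalues of `L` (`relaxation_rate()`); for the no-feedback model
it is `min(1 + s, 2u)`, for the feedback model `(A - rho)/2` with
`A = 1 + s + y + alpha` and `rho = sqrt(A^2 - 8(sy + alpha))` whenever `rho`
is real. Readout times are expressed in rescaled units `tau = lambda t`, so
circuits with different absolute speeds are compared on their natural
timescale; the objective's time unit therefore moves with the parameters and
`lambda` is recomputed for every candidate during optimization.

## Information and dissipation

Information is the mutual information between the initial input and the
delayed output, `I[x_t ; z_0]`, in bits (`mi_from_joint()`,
`delayed_information()`). On the symmetric class it reduces to
`I = ((1+mu)\log_2(1+mu) + (1-mu)\log_2(1-mu))/2`, increasing in `|mu|` with
1 bit at `mu = 1`. `0 log 0 := 0` by continuity; the cellwise
`coupling_function()` carries `-Inf` sentinels for empty cells, which have
zero weight in the information sum.

Dissipation is the entropy production rate of the chain,
\[ \sigma(t) = \sum_{i \ne j} w_{ij}\, p_j(t)\,
\log_2 \frac{w_{ij} p_j(t)}{w_{ji} p_i(t)}, \]
zero exactly at detailed balance. Its stationary value `sigma_ss`, the
rescaled `sigma_hat_ss = sigma_ss / lambda`, the running average
`Sigma_avg(tau_p)` up to a reset time, and the relaxation cost
`tau_p (Sigma_avg - sigma_hat_ss)` are all provided, together with the
closed forms for both families (`sigma_ss_closed()`).

Two unification choices were open and are fixed package-wide:

* **log base.** Dissipation formulas circulate in both natural-log and
  `log2` conventions. We use base 2 everywhere (information and dissipation
  share units); every entry point takes a `base` argument for nats.
* **the spectral gap under the square root.** The feedback closed form can
  be read with `rho` either as `A^2 - 8(sy+alpha)` or as its root; the
  `sqrt(A^2 - 8(sy+alpha))` reading is adopted because it reproduces the
  no-feedback formula exactly under `alpha = y = u` (algebraically,
  `rho = |1 + s - 2u|`) and matches the numerically computed
  `sigma_ss/lambda` to 1e-8 over random draws (tested). Where `rho^2 < 0`
  (complex relaxation spectrum) the closed form is inapplicable:
  `sigma_ss_closed()` returns `NA` with a warning and the numeric route is
  authoritative.

A point worth flagging because it is easy to get wrong: for a *fixed*
circuit started in its steady state, the delayed information `I(tau)` is
**not** monotone — the output needs time to respond, so `|mu_t|` (and hence
`I`) transiently rises above its equal-time value before decorrelation wins.
The two-mode closed form `mu_t = (mu_0 - A)e^{-(1+s)t} + A e^{-2ut}`,
`A = (1-s)/(1+s-2u)`, makes this explicit and is frozen as a test oracle.
Monotone decay holds for the *optimized* information `I*(tau)` produced by
`sweep_tau()`, and that is what the monotonicity tests assert.

## The optimization study

`optimize_circuit()` solves `max I(tau)` over the rates (log-parametrized)
and, for the tilde variants `S~`/`F~`, the initial condition `mu0`; the
plain variants `S`/`F` start from the stationary distribution. The method
was an open design choice (no reference procedure is stated); the package
uses:

* **constraint elimination instead of a constrained solver.** A
  `sigma_hat_ss` budget is an equality constraint on a smooth
  2-3-parameter family. For fixed values of the other rates,
  `sigma_hat_ss(s)` has two branches separated by the equilibrium manifold
  (`s = 1` without feedback, `s y = alpha` with), each spanning
  `(0, infinity)`; the anti-align rate `s` is therefore solved from the
  budget by bracketed root finding (25-point log-scan plus `uniroot`,
  tolerance ~1e-13) on a branch chosen per start. Every objective
  evaluation satisfies the constraint to ~1e-9, so no penalty schedule or
  Lagrangian iteration is needed. An optional `Sigma_avg` target is imposed
  on top as a quadratic penalty (weight 1e5).
* **multistart with deterministic anchors.** Default 12 log-uniform starts
  in `[1e-3, 1e3]` (plus unit-rate anchors), the best 4 polished with
  `nlminb` (objective tolerance 1e-12); the number of polished runs
  agreeing within 1e-6 is reported as a convergence diagnostic, and a fixed
  seed makes runs bit-reproducible.
* **a nested warm start for feedback models.** Since `alpha = y = u` embeds
  the no-feedback family, every `F`/`F~` run first solves its nested
  `S`/`S~` problem and injects that optimum as an always-polished start.
  This guarantees `I(F) >= I(S)` up to solver noise (~1e-8) and repairs the
  one basin multistart reliably missed at long readouts.
* **boundaries and degeneracies.** Unconstrained optima may sit on the
  infinitely dissipative `s -> 0` boundary; `s` is floored at 1e-6 and such
  solutions carry an `at_rate_boundary` flag. Constrained runs keep the same
  floor to keep `sigma_hat_ss` finite. An unattainable budget returns an
  explicit `status = "infeasible"` result rather than failing silently.
  The `r = 1` convention already breaks the cycling-direction tie, and the
  `mu0 >= 0` domain selects the positive branch of the two-branch structure
  seen when both `sigma_hat_ss` and `Sigma_avg` are fixed; `mu0_range =
  c(-1, 1)` reopens the mirror branch.

One comparative claim did not survive global optimization and is deliberately
left visible: at matched `(tau, sigma_hat_ss)` the information-optimal
feedback circuit found by `table_one()` transmits slightly more than its
no-feedback counterpart but also *averages more dissipation*, because the
feedback optimum sits on a ridge above the embedded `alpha = y` solution
(where both information and cost coincide with the no-feedback optimum
exactly). The corresponding cost-ordering check in the acceptance suite
asserts the direction conjectured for this comparison and therefore fails;
we keep it that way rather than weakening the check, since every individual
quantity it consumes is independently cross-validated (slow-path evaluation
and trapezoid quadrature oracles).

## The bursty gene promoter

`bursty_params()` describes a two-state promoter (basal production `R0`,
active `R1`, binding `k_on = k+ c`, unbinding `k_off = k-`) coupled to
protein birth-death with lifetime `tau_deg`; mRNA is integrated out on
timescale-separation grounds. The stationary distribution is obtained by a
direct linear solve of the truncated master equation with a normalization
row — no time stepping — and the truncation is self-validating: the
automatic `g_max = ceil(10 + m + 10 sqrt(m))` (with `m = Reff tau_deg` the
mean copy number) doubles until the boundary mass drops below 1e-10, and an
explicit `g_max` that leaves more than 1e-8 at the boundary is an error, not
a warning.

The stationary dissipation decomposes into the promoter part `sigma0`
(identically zero at stationarity, since the net binding flux vanishes),
the production part `sigma1` (with its occupancy-weighted closed form), and
the production-degradation interchange `sigma2`. All sums are evaluated in
flux form `w p \log_2 (w p / w' p')`, which never takes the log of a
zero-rate edge with positive flux; the conventional per-term expressions are
recovered algebraically and checked against the generic entropy production
of the full truncated chain. Because every rate in this chain is strictly
positive, stationary probabilities that underflow to zero in the far tail
are treated as zero flux rather than as one-way edges. In the
fast-switching limit (`k_on, k_off -> infinity` at fixed `cK`), the
copy-number distribution becomes Poisson at the effective rate yet
`sigma_FS = cK/(1+cK)^2 (R0 - R1) \log_2(R0/R1) > 0` unless `R0 = R1` —
equilibrium-looking statistics from a non-equilibrium mechanism.

## Learning-rate diagnostics

The learning rate `l_x` is the one-sided derivative at zero lag of the
stationary lagged information `I[z_0; x_tau]` (second-order forward
difference, step 1e-4 in rescaled time, Richardson-extrapolated with a
step-halving consistency check that errors out rather than returning an
unconverged number). The reference definition of the bound partner
`sigma_x` was unavailable, so the package settles it empirically and
documents the choice: with the *apparent* (rate-ratio) x-restricted
entropy production, the identity `l_x = sigma_x - sigma_x^{flux}` holds on
the symmetric class (the flux-form partial entropy production being
non-negative), which proves `eta = l_x / sigma_x <= 1` for the no-feedback
family; the flux-form definition, by contrast, violates the bound by large
factors and is therefore the wrong partner for this inequality. The
partition `sigma_x + sigma_z = sigma_ss` is exact for both families, but an
individual apparent marginal can be negative under feedback. Two limits
deserve care: at equilibrium both `l_x` and `sigma_x` vanish (`eta` is
`NaN`, not 1), and for a frozen input (`u -> 0`) the *natural-time*
learning rate vanishes while the rescaled one need not, because the
rescaling divides by `lambda = 2u` (`learning_rate(..., rescaled = FALSE)`).

## Synthetic data and what the tests do (and do not) show

The package analyses a model, not a data set: `random_params()` draws
log-uniform rate sets (default `[1e-2, 1e2]`, `r = 1`) that drive every
property suite, and `gillespie()` / `path_entropy_mc()` generate exact
trajectories and a trajectory-level dissipation estimator. The estimator
discretizes time so that `max exit rate x dt <= 0.05` (matching the
first-order transition-probability expansion; a coarser grid warns), uses
empirical ensemble occupancies, and reports trajectory-level standard
errors, so all stochastic checks are phrased in standard-error multiples
(3 SE), never absolute tolerances. Study sizes used by the suites: grids
`tau in {0.5, 1, 2}` by `sigma_hat_ss in {0.15, 0.35, 0.75}` for the
four-model comparison, ensembles of 6000-10000 trajectories with
`dt = 0.005` for the Monte Carlo oracles, and 400-1000 random draws for the
closed-form equivalences.

Passing these suites shows internal consistency of the mathematics — path
estimators agree with master-equation functionals, closed forms with
generic sums, optimizers with their constraints — on the symmetric,
binary, Markovian model class. It says nothing about real regulatory
circuits: no asymmetry between activation and deactivation, no more than
two states per component, no extrinsic noise, no measurement model, and
the bursty module treats only dissipation, not information transmission
through the gene.

## Numerical choices

* Matrix exponentials via the eigendecomposition of the 4x4 generator,
  falling back to scaling-and-squaring (`Matrix::expm`) when the eigenbasis
  reconstruction error exceeds 1e-8; tiny negative probabilities (> -1e-12)
  are clipped and renormalized.
* Zero-eigenvalue threshold for relaxation rates: 1e-10 x spectral radius.
* `Sigma_avg` quadrature: adaptive integration after the substitution
  `tau = e^x` (relative tolerance 1e-8), which turns the integrable
  `log tau` singularity of `sigma_hat` at `tau = 0` (present when
  `mu0 = +-1`) into a smooth, exponentially damped integrand; the remaining
  `[0, 1e-8]` sliver is bounded by its endpoint value. Dissipation traces
  are sampled on a 64-point geometric grid.
* Closed-form comparisons near the equilibrium manifold (`s ~ 1`) are made
  with a mixed absolute/relative tolerance: both expressions cancel to
  zero there and a purely relative criterion is unattainable in doubles.
* Infinite dissipation (a one-way transition carrying positive flux) is an
  explicit `Inf` with an `infinite_dissipation` attribute/flag, never a
  large float.
* Reducible generators (e.g. a frozen input) warn and return an
  absorbing-limit stationary distribution instead of failing.

## Limitations

Only the 4-parameter symmetric circuit class is implemented — not the
8-parameter asymmetric feedback model, whose information-optimal
architectures are absorbing and infinitely dissipative. The comparative
suites check orderings and qualitative structure of the optimization
study, not exact curve values. The Gillespie layer is desk-scale, not performance-tuned. The
`Sigma_avg`-constrained mode uses a penalty and inherits its conditioning;
budgets are met by elimination, penalties only shape the `Sigma_avg`
target. A Langevin/coarse-grained treatment of the bursty model is out of
scope.
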