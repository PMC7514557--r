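# circdiss

Information–dissipation trade-offs in small binary regulatory circuits.

Cells transmit environmental signals through small molecular circuits — a
receptor activating a kinase, a transcription factor switching a promoter.
`circdiss` is an R package for analysing the simplest such circuit: an input
`z` and an output `x`, each binary, coupled into a four-state
continuous-time Markov chain. It quantifies two competing currencies:

* **information** — the delayed mutual information `I[x_t ; z_0]` (bits)
  between the initial input and the output read out after a delay, and
* **dissipation** — the entropy production rate
  `sigma(t) = sum_{ij} w_ij p_j log2( w_ij p_j / (w_ji p_i) )`
  (bits per unit time), the KL rate between forward and time-reversed
  trajectory ensembles, which measures how far the circuit operates from
  equilibrium.

The package is aimed at researchers in stochastic thermodynamics and
quantitative biology who want reproducible, tested implementations of:

* symmetric four-state circuit generators with and without feedback
  (no feedback: input flips at `u`, output aligns at `r = 1` / anti-aligns
  at `s`; feedback: the pair anti-aligns at `alpha` and aligns at `y`),
  their stationary states, relaxation rates and matrix-exponential
  propagators;
* the symmetric one-parameter family
  `p = ((1+mu)/4, (1-mu)/4, (1-mu)/4, (1+mu)/4)` and the closed-form
  information `I = ((1+mu) log2(1+mu) + (1-mu) log2(1-mu)) / 2`;
* instantaneous, steady-state (`sigma_ss`), rescaled (`sigma_hat_ss =
  sigma_ss / lambda`) and time-averaged (`Sigma_avg(tau_p)`) entropy
  production, with the closed forms
  `sigma_ss(u, s) = (s-1) u log2(s) / (1 + s + 2u)` and
  `sigma_hat_ss(alpha, s, y) = 2 (alpha - s y) log2(alpha/(s y)) / (A (A - rho))`,
  `A = 1 + s + y + alpha`, `rho = sqrt(A^2 - 8 (s y + alpha))`;
* constrained multistart optimization `max I(tau)` subject to a fixed
  `sigma_hat_ss` budget (and optionally a fixed `Sigma_avg`), over rates and
  the initial condition `mu0`, for all four model variants `S`, `S~`, `F`,
  `F~`;
* the two-state bursty gene promoter (binding `k+c`, unbinding `k-`,
  production `R0`/`R1`, protein lifetime `tau_deg`): truncated stationary
  master-equation solve, the dissipation decomposition
  `sigma_ss = sigma0 + sigma1 + sigma2`, detailed-balance diagnostics, and
  the fast-switching limit
  `sigma_FS = cK/(1+cK)^2 (R0 - R1) log2(R0/R1)`, which stays positive even
  when the copy-number statistics look Poissonian;
* bipartite learning-rate diagnostics (`l_x`, `sigma_x`,
  `eta = l_x / sigma_x`);
* Gillespie simulation and a path-probability Monte Carlo estimator of
  `sigma(t)` that serves as a trajectory-level oracle for the
  master-equation functionals.

## Worked example

```r
library(circdiss)

G <- build_generator(circuit_params("no_feedback", u = 1, s = 2))
round(steady_state(G), 4)
#> (-,-) (-,+) (+,-) (+,+)
#>   0.2   0.3   0.3   0.2
relaxation_rate(G)        # lambda = min(1 + s, 2u) = 2
sigma_hat_ss(G)           # 0.1 bits per rescaled time

dissipation_report(G, mu0 = 1, tau_p = 0.5)
#> dissipation report (base 2 logs)
#>   sigma_hat_ss    = 0.1
#>   Sigma_avg(0.5)   = 2.58378
#>   relaxation cost = 1.24189
```

Starting from the fully aligned state (`mu0 = 1`, i.e. `p0 =
(0.5, 0, 0, 0.5)`) the circuit dissipates on average 2.58 bits per rescaled
time until the reset at `tau_p = 0.5` — far above its steady-state rate of
0.1 — and the relaxation cost `tau_p (Sigma_avg - sigma_hat_ss) = 1.24` bits
is the price of exploiting that initial condition.

Maximizing the transmitted information at readout `tau = 0.5` under a
steady-state dissipation budget of 0.35:

```r
fit <- optimize_circuit(opt_problem("S_tilde", tau = 0.5,
                                    sigma_hat_ss = 0.35, seed = 1))
fit
#> opt_result [S_tilde] tau = 0.5: I* = 0.531981 bits
#> circuit (no feedback): u = 0.609762, s = 0.219524, r = 1
#>   mu0 = 1.000000, sigma_hat_ss = 0.35 (residual 1.2e-09), Sigma_avg = 1.38142
#>   restarts agreeing: 3
```

The optimizer picks the fully aligned initial condition (`mu0 = 1`) and
slow anti-alignment (`s < 1`), transmitting 0.53 bits — compare 0.12 bits
for the same circuit forced to start in steady state
(`optimize_circuit(opt_problem("S", ...))`).

The bursty promoter in the fast-switching regime stays dissipative even
though its copy-number distribution is Poisson:

```r
bp <- bursty_params(k_on = 1e4, k_off = 1e4, R0 = 1, R1 = 2)
dissipation_decomposition(bp)
#> bursty dissipation (base 2): sigma0 = -0, sigma1 = 1, sigma2 = -0.750012
#>   total = 0.249988 (flux form 0.249988), fast-switching limit 0.25
```

`table_one()` reproduces the four-model comparison (information and total
cost orderings) on a grid of readout times and dissipation budgets, and
`run_pipeline()` drives any of the analyses from a serializable YAML/list
configuration, writing seed- and fingerprint-stamped CSV/JSON outputs.

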