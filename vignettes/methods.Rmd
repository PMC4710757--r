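---
title: "Methods: analytic voltage-clamp simulation and hybrid parameter estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analytic voltage-clamp simulation and hybrid parameter estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4.5)
library(clampfitr)
```

## The scientific problem

Mathematical models of cardiac myocytes describe each transmembrane ionic
current with a Hodgkin–Huxley formulation: a maximum conductance, one or
more gating variables relaxing toward voltage-dependent steady states with
voltage-dependent time constants, and the driving force $V - E_K$. To
personalize such a model — to a patient, a disease condition, or a new
experimental data set — the formulation's parameters must be estimated from
voltage-clamp recordings. The resulting least-squares problem is deceptively
hard: parameters enter the rate equations nonlinearly, several of them
compensate each other almost exactly, and the cost surface combines long
curved valleys with many local minima.

`clampfitr` implements this estimation pipeline for three potassium currents
of the Courtemanche–Ramirez–Nattel human atrial myocyte model: the rapid
delayed rectifier $I_{Kr}$, the ultrarapid delayed rectifier $I_{Kur}$, and
the slow delayed rectifier $I_{Ks}$. It provides an exact analytic simulator
for step protocols, synthetic data generation with controlled measurement
noise, and four estimation algorithms — a local trust-region-reflective
least-squares solver (TRR), constriction-type particle swarm optimization
(PSO), their sequential combination, and a per-iteration hybrid that embeds
capped trust-region refinement inside every swarm iteration.

## Current formulations

All three currents share the structure

$$ I = g(V)\, \prod_j x_j^{n_j}\, (V - E_K), $$

with current density in pA/pF, conductance in nS/pF, and each gating
variable $x_j \in (0,1)$ obeying

$$ \frac{dx}{dt} = \frac{x_\infty(V) - x}{\tau_x(V)}. $$

For $I_{Kr}$,

$$ I_{Kr} = g_{Kr}\, x_r\, \frac{V - E_K}{1 + \exp\!\big(\tfrac{V + 15}{22.4}\big)}, $$

with activation kinetics assembled from the rates

$$ \alpha_{x_r} = \frac{0.0003\,(V + 14.1)}{1 - \exp\!\big(-\tfrac{V + 14.1}{5}\big)}, \qquad
   \beta_{x_r} = \frac{7.3898\times10^{-5}\,(V - 3.3328)}{\exp\!\big(\tfrac{V - 3.3328}{5.1237}\big) - 1}, $$

$\tau_{x_r} = (\alpha_{x_r} + \beta_{x_r})^{-1}$ and
$x_{r,\infty} = \big(1 + \exp(-\tfrac{V + 14.1}{6.5})\big)^{-1}$. $I_{Kur}$
uses a voltage-dependent conductance
$g_{Kur}(V) = 0.005 + 0.05 / \big(1 + \exp(-\tfrac{V-15}{13})\big)$, an
activation gate $u_a$ (cubed) and an inactivation gate $u_i$, whose time
constants carry a fixed temperature factor $K_{Q10} = 3$. $I_{Ks}$ uses a
squared activation gate $x_s$ with $\tau_{x_s} = 0.5/(\alpha_{x_s} +
\beta_{x_s})$. The potassium Nernst voltage is a fixed physical constant,

```{r nernst}
nernst_EK()
```

computed from $[K^+]_o = 5.4$ mM, $[K^+]_i = 139$ mM at 310 K, and is never
estimated.

### Parameter enumeration

The adjustable parameters are every numeric constant of the formulations
except the fixed physical/structural ones ($E_K$, $K_{Q10}$, the gate
exponents). This yields **12** parameters for $I_{Kr}$, **25** for
$I_{Kur}$, and **11** for $I_{Ks}$:

```{r params}
vapply(c("IKr", "IKur", "IKs"), function(id) current_model(id)$n_params,
       integer(1))
head(current_model("IKr")$params, 12)
```

Two conventions deserve explanation, because the printed equations alone do
not determine the count:

* In $\alpha_{x_r}$ the voltage shift appears twice — in the numerator and
  inside the exponential. These are counted as **two independent
  parameters** (`alpha_xr_shift_num`, `alpha_xr_shift_exp`), both with base
  value 14.1 mV. In $\beta_{x_r}$ the analogous shift (3.3328 mV) is counted
  **once** and used in both places, which keeps that rate's singularity
  removable for every admissible vector. The same convention is applied to
  the $I_{Ks}$ rates. With it, the adjustable counts come out at exactly
  12 and 11.
* For $I_{Kur}$, the rates $\alpha_{u_i}$ and $\beta_{u_i}$ are written with
  explicit unit prefactors (`alpha_ui_scale`, `beta_ui_scale`, base value
  1), and the $u_a$ exponent (base 3) is adjustable; this yields the count
  of 25.

When the two $\alpha_{x_r}$ shifts drift apart during a fit, the rate
acquires a true pole inside the protocol's voltage range for some vectors.
Such vectors are *kinetically invalid*: the simulator refuses them, the cost
is $+\infty$, and the optimizers treat them exactly like any other bad
candidate.

### Additive and multiplicative parameters, search spaces

Each parameter is classified by how it enters its equation: **additive**
parameters are voltage shifts (summands, in mV); everything else —
conductances, rate scales, slope factors, offsets, exponents — is
**multiplicative** (a factor). The classification drives the box
constraints: additive parameters vary within $b \pm 60$ mV (narrow space) or
$b \pm 120$ mV (wide space) around their base value $b$; multiplicative
parameters vary between $0.1\times$ and $10\times$ (narrow) or $0.01\times$
and $100\times$ (wide) of it.

```{r bounds}
make_bounds(current_model("IKr"), "narrow")
```

## Analytic simulation

The voltage-clamp command is piecewise constant, so within each segment
every gate relaxes exponentially and the gating ODE has the exact solution

$$ x(t_0 + \Delta t) = x_\infty + \big(x(t_0) - x_\infty\big)\,
   e^{-\Delta t/\tau}, $$

the update familiar from Rush–Larsen integration — except that here it is
*exact*, not an approximation, because $V$ really is constant within a
segment. `simulate_current()` therefore involves no numerical ODE solver at
all: gates start at the steady state of the first segment's holding
potential, are propagated analytically across segment boundaries (where the
command voltage steps but the gate value is continuous), and the current is
evaluated at every sample instant. A sample falling exactly on a boundary is
attributed to the segment that starts there. The test suite validates the
analytic trace against an independent `deSolve::lsoda` integration of the
gating ODEs; they agree to better than $10^{-10}$ pA/pF, far below the
tolerance of $10^{-6}$ the suite enforces.

The standard protocol holds 13 sweeps: 20 ms at $-80$ mV, 400 ms at a test
potential from $-70$ to $+50$ mV in 10 mV steps, and 400 ms at $-110$ mV,
sampled every 2 ms — 411 samples per sweep, 5343 residuals, 10.66 s of
recording:

```{r protocol}
standard_protocol()
```

The hot path (the residual and cost evaluations that optimizers call tens of
thousands of times) is implemented in C++ via Rcpp. Because samples within a
segment are uniformly spaced, the per-sample exponential decay is advanced by
a single precomputed ratio $e^{-\Delta t/\tau}$ per gate rather than a fresh
`exp` call per sample, and the voltage-dependent prefactors of each current
are hoisted out of the sample loop; one $I_{Kr}$ cost evaluation takes about
0.2 ms. A pure-R reference implementation with identical semantics backs the
compiled path in the test suite (agreement to better than $10^{-13}$ pA/pF).

## Synthetic data and noise

`generate_ground_truth()` simulates a model at its base parameter values and
records those values in the trace metadata (the optimizers never read them).
`add_noise()` corrupts a trace with i.i.d. zero-mean Gaussian noise whose
variance is set from a signal-to-noise ratio in dB,

$$ \sigma^2 = P_{\text{signal}} \big/ 10^{\mathrm{SNR}/10}, \qquad
   P_{\text{signal}} = \overline{I^2}, $$

with the mean squared current pooled over all samples of all sweeps — one
SNR figure per data set. The energy of the injected noise is then the floor
below which no fit against the noisy input can go; at 10 dB on the standard
$I_{Kr}$ data set it is about $2.8 \times 10^1$ (pA/pF)².

```{r noise}
clean <- generate_ground_truth(current_model("IKr"))
noisy <- add_noise(clean, noise_spec(snr_db = 10, seed = 1))
ground_truth_sse(noisy, clean)
```

## The objective

All estimators minimize the sum of squared sample-wise differences between
the simulated and the observed trace, in (pA/pF)², with every sample of
every sweep weighted equally:

```{r objective}
obj <- build_objective(current_model("IKr"), standard_protocol(), clean)
sse_cost(obj, current_model("IKr")$base)
```

## Optimizers

### Trust-region-reflective least squares (TRR)

`trr_minimize()` is a bounded Gauss–Newton trust-region solver written for
this package: forward-difference Jacobians, the Coleman–Li scaling implied
by the distance of the iterate to its active bounds, an exact (SVD-based)
solution of the trust-region subproblem, and a reflected candidate step when
the trust-region step hits a bound. Steps are accepted only when they reduce
the cost, so iterates descend monotonically and never leave the box.

Termination reports exactly one of `pTol` (accepted step norm below
$10^{-11}$, or a collapsed trust region), `fTol` (cost decrease below
$10^{-11}$ (pA/pF)²), `maxIter` ($10^5$), `maxFunEval` ($5\times10^5$), or
`iteration_cap` (the embedded-use cap). Both tolerances are **absolute**, in
the units stated. One consequence is worth spelling out: on a smoothly
converging run the cost decrease per step scales like the squared step norm,
so the cost-change test fires while steps are still orders of magnitude
above $10^{-11}$ — converged runs typically report `fTol`, and `pTol` is
reported where the trust region collapses (tight local minima, active
bounds). Solvers whose tolerances are relative to the current cost and
parameter norm (e.g. commercial implementations) report the step criterion
as decisive on the same problems; the termination *statistics* are sensitive
to this semantic choice even though the final costs are not.

### Constriction particle swarm optimization (PSO)

`pso_run()` implements the constriction-type swarm: velocities update as

$$ v \leftarrow \chi\big(v + U(0,\varphi_1)\otimes(b_i - p)
   + U(0,\varphi_2)\otimes(b_g - p)\big), \qquad
   \chi = \frac{2}{\varphi - 2 + \sqrt{\varphi^2 - 4\varphi}}, $$

with $\varphi = \varphi_1 + \varphi_2 = 4.1$, giving $\chi \approx 0.73$;
$b_i$ and $b_g$ are the personal and global best positions, and $U$ draws
component-wise uniforms. Particles start uniformly in the box with zero
velocity. A component that leaves the box is re-drawn uniformly within the
25% of the parameter range adjacent to the crossed bound. Personal and
global bests update synchronously at the end of each iteration, making the
global-best trace monotone.

### Sequential two-stage and per-iteration hybrid

`two_stage_run()` runs a full swarm and then refines the best $M$ distinct
personal bests to convergence with TRR. The per-iteration hybrid
(`hybrid_run()`) couples the two algorithms much more tightly: in every
iteration, each particle's boundary-enforced candidate position undergoes up
to $K$ trust-region iterations, the velocity is redefined as the
displacement to the refined position, and the particle moves there. After
$L$ iterations the best $M$ personal bests are refined to convergence. With
$K = 0$ the trajectory is identical, draw for draw, to `pso_run()` under the
same seed — a property the test suite checks exactly.

Budget tiers:

```{r setups}
str(hybrid_setup("medium"), give.attr = FALSE)
str(hybrid_setup("desk"), give.attr = FALSE)
```

`low`, `medium` and `high` are the published tiers. `desk` (K = 5, L = 60,
N = 48, M = 8) is this package's own scaled-down preset, sized so that a
wide-space $I_{Kr}$ estimation finishes in about a minute on one CPU; it is
the tier the acceptance tests run at. At desk scale the hybrid still
recovers all 12 $I_{Kr}$ parameters from the wide space to within far less
than 0.1%, and reaches final costs below $10^{-9}$ (pA/pF)² — but budget-
dependent statements (e.g. how often the *pre-refinement* swarm has already
converged) should be read against the tier that produced them.

## Numerical choices worth knowing about

* **Removable singularities.** The rates $x/(1-e^{-x/s})$ and
  $x/(e^{x/s}-1)$ are evaluated by their series limits $s \pm x/2$ for
  $|x| < 10^{-7}$, so traces are smooth across the singular voltages.
* **Kinetic validity.** Vectors producing non-positive or non-finite time
  constants at any protocol voltage are rejected: `residuals_at()` raises an
  error, `sse_cost()` returns $+\infty$, swarm candidates score $+\infty$.
* **RNG discipline.** Every stochastic component (noise, swarm, random
  starts) is driven by one explicitly seeded stream; `with_seed()` restores
  the caller's RNG state. A single master seed reproduces an entire
  experiment bit for bit.
* **Jacobian steps.** Forward differences with relative step $10^{-8}$,
  floored at 1% of the box width per parameter, with a sign flip at bounds.
* **Slow valleys.** A minority of narrow-space starts creep along active
  bounds in long curved valleys, decreasing the cost by $\sim 10^{-4}$
  (pA/pF)² per iteration for thousands of iterations without changing the
  qualitative outcome. Experiment drivers may cap `max_iter` (the acceptance
  suite uses 5000) purely to bound wall time; affected runs sit far above
  the run median.

## Experiments

`experiment_plan()` / `run_experiment()` run repeated seeded estimations of
one cell (current × algorithm × space × data) and summarize the final-cost
distribution by order statistics; `noise_study()` reports the dual error
metric (cost against the noisy input vs squared error against the clean
truth) per SNR; `sweep_particles()` doubles the particle count and fits the
log-median regression; `report_experiments()` writes tables, box plots, and
parameter-deviation plots. The installed script `inst/cli/clampfitr` exposes
the pipeline as subcommands (`simulate`, `make-fixtures`, `fit-trr`,
`fit-pso`, `fit-two-stage`, `fit-hybrid`).

```{r experiment, eval = FALSE}
plan <- experiment_plan("IKr", "trr", "narrow", n_runs = 25, seed = 1,
                        config = list(control = trr_control(max_iter = 5000)))
res <- run_experiment(plan)
res$summary
```

## Scaled-down budgets and limitations

The published full-budget experiments (particle counts up to 12,288, the
`high` hybrid tier, 25 repetitions of everything) need many CPU-hours. This
package's test and acceptance suites deliberately run reduced versions —
the `desk` hybrid tier, 25 repetitions only where a run takes seconds,
handfuls of seeds elsewhere — chosen so that each scientific claim is still
exercised at a budget where it can hold. Stochastic medians are compared
within a factor of 3 of the published values.

Known limitations:

* Only step protocols (piecewise-constant voltage) are supported; ramps
  would require a numerical gate integrator.
* The noise model is additive white Gaussian with one pooled signal power;
  real recordings have colored noise, capacitive transients, and drift.
* Measured-data workflows are limited to reading traces from CSV; no
  leak/artifact correction is included.
* The TRR termination-reason statistics depend on the absolute tolerance
  semantics described above and will differ from solvers with relative
  tolerances, even where the costs agree.
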