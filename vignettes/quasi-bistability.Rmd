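---
title: "Bistable and quasi-bistable ERK activation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bistable and quasi-bistable ERK activation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapkqb)
```

## The scientific problem

PC-12 cells decide between proliferation and differentiation according to
the *duration* of ERK activation: epidermal growth factor (EGF) elicits a
transient ppERK response, nerve growth factor (NGF) a sustained one.  The
textbook explanation for a sustained response to a transient signal is
bistability created by positive feedback.  `mapkqb` implements a
Bayesian analysis of a minimal Raf/MEK/ERK cascade model that makes a more
nuanced point: a *monostable* system can hold an elevated ERK state for
hours after the upper steady state has disappeared, because the vector
field near the "ghost" of that state is extremely small.  We call this
behavior quasi-bistable, and the package quantifies how much of a
posterior parameter population is genuinely bistable versus quasi-bistable.

## The model

The cascade is reduced to four rescaled states — `x1` (pRaf), `x2`
(ppMEK), `x3` (pERK), `x4` (ppERK), each a fraction of the corresponding
total protein — using conservation of total Raf, MEK and ERK.  MEK double
phosphorylation is processive (one step), ERK activation distributive (two
steps).  With silencing factors `s1..s3` (remaining total protein after
RNA interference) the mass-action equations are

```
dx1/dt = [k1p u(t) + fp kFp h(x4)] (s1 - x1) - [k1m + fn kFn x4] x1
dx2/dt = k2p x1 (s2 - x2) - k2m x2
dx3/dt = k3p x2 (s3 - x3 - x4) - k3m x3 - k4p x2 x3 + k4m x4
dx4/dt = k4p x2 x3 - k4m x4
```

with `h(y) = y^g / (1 + y^g)` the sigmoidal positive feedback and
`u(t) = ku (1 - t^3/(t^3 + K^3))` the transient input that jumps to `ku`
at stimulation and decays with half-time `K` (active Ras returns to its
GDP state within minutes).  The Boolean flags select the effective
topology: `fn` (negative feedback ppERK -> pRaf dephosphorylation) for
EGF, `fp` (positive feedback ppERK -> Raf phosphorylation) for NGF.  The
origin is an exact steady state at `u = 0`; basal activities are
neglected because the calibration data carry no information about them.

Two modeling choices deserve emphasis.  The half-saturation of the
positive feedback is fixed at 1 on the rescaled concentration scale: the
parameter vector carries only a strength `kFp` and a Hill exponent `g`,
and any threshold shift can be traded against `kFp` and the rates, so a
separate threshold parameter would be unidentifiable.  Second, `h(0) = 0`
is required so that the positive feedback does not destroy the trivial
steady state.  The negative feedback is the simplest mass-action form,
`kFn x4 x1`, enhancing pRaf dephosphorylation.

The twelve inferred constants are, in canonical order,
`k1p, k2p, k3p, k4p` (phosphorylation), `k1m..k4m`
(dephosphorylation), `kFn`, `kFp`, `g >= 1`, and `K` (min).  Simulation
uses a stiff-capable solver (`deSolve::lsoda` on a compiled
right-hand side; `atol = 1e-10`, `rtol = 1e-8`) — near saddle-node
bifurcations the system is genuinely stiff.  Dose is modeled by `ku`
multiplying the input, equivalent to scaling `k1p`.

```{r}
theta <- mapk_fixture("quasi_bistable")
traj <- simulate_cascade(theta, cond_ngf(), c(0, 2, 5, 10, 15, 30, 45, 60))
round(normalize_trajectory(traj, t_ref = 5), 3)
```

Observables are pRaf, ppMEK and ppERK (`x1`, `x2`, `x4`).  Because blot
and cytometry signals carry arbitrary units, both data and model are
normalized to the activity at `t_ref = 5` min (configurable; 5 min is the
response peak and the conventional anchor).

## Calibration data and the synthetic-data generator

The original calibration data — growth-factor time courses and a table of
3x3 global response coefficients (GRCs) from four silencing replicates —
were digitized from published figures and are not recoverable in usable
form.  `generate_dataset()` therefore produces synthetic data with the
same statistical structure from a known ground truth:

* time-course block: normalized model predictions at
  `{2, 5, 10, 15, 30, 45, 60}` min for both growth factors, multiplied by
  log-normal noise with log-sd `sigma_log = 0.2` (the error model of the
  real data).  `t = 0` is excluded by design: the model's resting state
  is exactly zero, which lies outside the log-normal support, and the
  original analysis likewise had no usable `t = 0` point;
* GRC block: per replicate, log-normal noise is injected at the
  concentration level into silenced and control activities, the response
  coefficient `R = 2 (v_s - v_c)/(v_s + v_c)` is computed from the noisy
  pair, and four replicates are summarized to mean and sd — mirroring how
  the real replicate tables arose.  Silencing factors are 0.72 / 0.70 /
  0.65 for Raf / MEK / ERK, applied one at a time; evaluation times are
  5 min (EGF) and 5, 15 min (NGF), treated as near-steady-state.

The default ground truth is the quasi-bistable fixture, which produces a
transient EGF and a sustained NGF response.  What the generator does *not*
emulate: receptor-level dynamics (dose units are arbitrary), basal
activities, cell-to-cell variability in total protein (the rescaled model
cannot carry it), and correlated blot errors.  Passing tests therefore
demonstrate the pipeline's internal correctness and its behavior on data
with the assumed error structure, not robustness to real-data pathologies.

## Prior, likelihood, posterior

The detailed error-propagation scheme of the original analysis is not
recoverable, so the package states its own defaults plainly:

* prior: independent log-uniform on `[1e-4, 1e4]` for the ten rate and
  feedback constants (scale-free over eight decades), uniform on `[1, 8]`
  for `g`, log-uniform on `[0.5, 100]` min for `K`;
* time-course likelihood: Gaussian on log values with sd 0.2 (log-normal
  error model), applied to normalized observables — invariant under joint
  rescaling of data and prediction;
* GRC likelihood: Gaussian in coefficient space around the simulated
  GRCs, with the empirical per-cell sd floored at 0.05 so that
  accidentally tiny replicate spreads cannot dominate the posterior.  A
  delta-method alternative on log fold changes
  (`log rho`, `rho = (2+R)/(2-R)`, log-sd `sqrt(2) * 0.2`) is available
  via `grc_model = "lognormal_delta"`.

Failed ODE solves during sampling map to `-Inf`, never to exceptions.
`mcmc_sample()` is an adaptive Metropolis sampler on log-parameters
(Haario-style: proposal covariance `2.38^2/d` times the running chain
covariance with a small nugget, global scale tuned toward 30%
acceptance).  Chains are reproducible from their seed; burn-in (default
half) is discarded and the remainder thinned.  For production use the
default is `2e5` steps; the worked analyses and the test suite use
`2e4`-step chains with 500 retained draws, which this 12-parameter
problem mixes well enough for interval summaries (acceptance rates
~0.37, coverage checks in the test suite).

On synthetic data the dephosphorylation rates `k1m`, `k2m` and the input
half-time `K` are sharply identified while most other marginals stay
wide — the expected identifiability pattern for normalized cascade data —
so parameter-recovery checks assert credible-interval coverage only for
those three.

## Steady states by circuit breaking

All feedback passes through ppERK, so clamping the cutset `x4 = kappa`
leaves a loop-free chain whose steady state is available in closed form
(`cascade_steady_state()`).  Substituting the chain into the ppERK
balance gives the one-dimensional circuit characteristic

```
c(kappa) = k4p x2(kappa) x3(kappa) - k4m kappa ,
```

whose zeros on `[0, s3]` are exactly the steady-state ppERK coordinates
of the full system.  `find_steady_states()` scans an 800-point grid,
refines each sign change by bisection to `1e-10`, reconstructs the full
state, and classifies stability by the eigenvalues of the full 4x4
Jacobian (central finite differences, step `1e-7`; stable means all real
parts below `-1e-9`).  The Jacobian verdict is authoritative — the 1-D
slope criterion agrees for simple zeros but is not trusted near
tangencies.  Zeros closer than the grid spacing, or an even zero count at
rest (the origin plus saddle-node pairs must make it odd), set an
`unresolved` flag rather than being merged silently.

The independent check is `newton_steady_states()`: damped Newton from 200
random admissible starts on the full 4-D system.  It iterates to *step*
convergence rather than stopping at a small residual — in quasi-bistable
regimes the vector-field norm dips below any absolute residual tolerance
without a root being present, and residual-based stopping would
hallucinate steady states on the slow manifold.

## Trajectory classification and the two delay mechanisms

With ppERK at 5 min as reference, `r60` and `r600` denote ppERK at 60 and
600 min relative to the reference.  The classes are: class 1 (bistable)
`r60 > 0.2` and `r600 >= 0.1`; class 2 (quasi-bistable) `r60 > 0.2` and
`r600 < 0.1`; class 3 (monostable) `r60 <= 0.2`, with exactly these
boundary conventions.  The switching time is the first `t > 5` min at
which normalized ppERK settles below 0.1 — the same threshold as the
600-min class boundary, a deliberate consistency choice since no analytic
definition of switching exists; non-monotone tails return the last
downward crossing with a warning.

Quasi-bistability combines two delays, which the package separates:

1. while `u(t) > u_SNB` the system *is* bistable and the state sits in
   the upper basin; `bifurcation_sweep()` locates `u_SNB` by bisection on
   the stable-state count and `time_of_monostability()` inverts the input
   analytically, `t_mono = K ((1-q)/q)^{1/3}` with `q = u_SNB/ku`;
2. after `t_mono` the upper state is gone, but the trajectory creeps
   through the region where it used to be; `vector_field_norm()` and
   `plateau_ratio()` quantify this (plateau below 1% of the first peak
   for genuine quasi-bistability).

For every class-2 system with a resolvable saddle-node, `t_mono <
t_switch`; the gap between them is the slow-manifold delay.

## Fixtures

Three reference parameter vectors ship with the package
(`mapk_fixture()`), discovered by a seeded randomized search and frozen
with their validation results (`mapk_fixture_metadata()`).  The search
draws from the physiologically scaled core of the prior support — rates
within two decades of 1/min, `g >= 2`, `K` between 2 and 50 min — because
draws from the full eight-decade prior are almost always so ill-scaled
(time-scale ratios of 1e6 and more) that the required properties never
co-occur; the narrower search region is a package design choice, not a
statement about the prior.  Near-misses that are bistable at rest are
refined by damping `kFp` until the rest state is monostable, and `kFn`
(which acts only in the EGF topology) is raised if needed to obtain a
transient EGF response without altering the NGF dynamics.  The
quasi-bistable fixture must in addition hold its plateau through the last
measured time point (`t_switch > 120` min, `r60 >= 0.5`) and lose its
sustained response when the feedback is removed, so that its
quasi-bistability is feedback-borne rather than a bare slow time scale.

## Scenario analyses

The validation scenarios are pure functions of a posterior sample and a
configuration: dose response (`ku` sweeps; bimodality of the population
response flagged by a Gaussian-mixture BIC comparison on log ppERK with a
fixed margin of 10 — a mixture criterion rather than a dip statistic, as
only a qualitative unimodal/bimodal call is needed), MEK inhibition
(`k2p = 0`), feedback removal (`kFp = kFn = 0`), and abrupt signal
termination (`t_off`).  Scenario PPDs are reported on raw observables
because interventions like MEK inhibition drive reference activities to
zero, where per-trajectory normalization is undefined.

## Numerical choices and problem sizes

* solver: `lsoda`, `atol 1e-10 / rtol 1e-8`; integration restarts at
  input discontinuities (`t_off`);
* characteristic grid 800 points, bisection to `1e-10` in `kappa` and
  `1e-8` in `u`; Jacobian step `1e-7`;
* classification grid: 1-min resolution to 600 min;
* analyses in the test suite and acceptance script: 500-draw posteriors
  from `2e4`-step chains (three seeds for recovery), 100-draw oracle
  comparisons at `u` in `{0, 0.2, 1}`, 25-dataset noise calibration —
  sizes chosen so the whole suite re-runs comfortably on one CPU.

## Known limitations

No receptor model (doses are arbitrary units, comparisons qualitative);
no direct ERK->MEK feedback (one simulated GRC sign is expected to
deviate, as in the original analysis); no subpopulation/mixture modeling
of single-cell heterogeneity; switching times beyond the simulated
horizon are reported as absent rather than extrapolated; the
normalization to 5 min precludes statements about absolute activity
levels.
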