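# mapkqb

Bayesian analysis of bistable and quasi-bistable ERK activation in the
Raf/MEK/ERK (MAPK) signaling cascade.

## The problem

In PC-12 cells the duration of ERK activation decides cell fate: EGF
produces a transient ppERK response (proliferation), NGF a sustained one
(differentiation).  Sustained responses to transient signals are usually
attributed to bistability from positive feedback.  This package
implements a pipeline showing that a second mechanism — *quasi-bistability*
— can carry the sustained response: a monostable system whose trajectory
lingers for hours near the ghost of a steady state that has already
vanished through a saddle-node bifurcation, because the vector field
there is virtually zero.

Who it is for: modelers of signaling cascades who want to (i) calibrate a
feedback-switchable cascade ODE model to normalized time-course and
gene-silencing data with MCMC, and (ii) dissect a posterior population
into bistable / quasi-bistable / monostable responders with steady-state
and trajectory-based methods that cross-validate each other.

## Model and methods in brief

Four rescaled states (fractions of total protein) with mass-action
kinetics, conservation laws, and growth-factor-dependent feedback:

    dx1/dt = [k1p u(t) + fp kFp h(x4)] (s1 - x1) - [k1m + fn kFn x4] x1
    dx2/dt = k2p x1 (s2 - x2) - k2m x2
    dx3/dt = k3p x2 (s3 - x3 - x4) - k3m x3 - k4p x2 x3 + k4m x4
    dx4/dt = k4p x2 x3 - k4m x4

where x1 = pRaf, x2 = ppMEK, x3 = pERK, x4 = ppERK,
h(y) = y^g/(1+y^g), and the input u(t) = ku (1 - t^3/(t^3+K^3)) decays
sigmoidally after stimulation.  `fp` (NGF) switches on the positive
feedback, `fn` (EGF) the negative one; s1..s3 are silencing factors.

Main components:

* **Inference** — log-normal error model (log-sd 0.2) on observables
  normalized to t = 5 min, Gaussian likelihood on 3x3 global response
  coefficients R = 2(v_s - v_c)/(v_s + v_c) from silencing experiments,
  log-uniform/uniform priors, adaptive Metropolis MCMC, posterior
  predictive distributions.
* **Circuit-breaking algorithm** — clamp the cutset x4 = kappa, solve the
  remaining chain in closed form, and read all steady states off the
  zeros of the circuit characteristic
  c(kappa) = k4p x2(kappa) x3(kappa) - k4m kappa; stability from the full
  Jacobian.  Cross-checked against multi-start damped Newton.
* **Trajectory classification** — with r60 and r600 the ppERK levels at
  60/600 min relative to 5 min: class 1 (bistable) r60 > 0.2 and
  r600 >= 0.1; class 2 (quasi-bistable) r60 > 0.2 and r600 < 0.1;
  class 3 (monostable) r60 <= 0.2.  Plus switching times, saddle-node
  sweeps in u, vector-field-norm diagnostics, and sensitivity analyses.
* **Synthetic data** — a generator reproducing the statistical structure
  of the calibration experiments (transient EGF / sustained NGF time
  courses, GRC replicate tables, log-normal noise), so the whole pipeline
  is testable end to end from a known ground truth.

## Worked example

The shipped quasi-bistable fixture illustrates the mechanism:

```r
library(mapkqb)
theta <- mapk_fixture("quasi_bistable")

find_steady_states(theta, u = 0)
#> Steady states at u = 0 -> monostable
#>   x1 x2 x3 x4 stability
#> 1  0  0  0  0    stable

bif <- bifurcation_sweep(theta)
bif
#> Bifurcation sweep over 42 input levels; saddle-node(s) at u = 0.00571775, 0.114602

grid <- sort(unique(c(0, 2, 5, seq(0, 600, by = 1))))
traj <- simulate_cascade(theta, cond_ngf(), grid)
classify_trajectory(traj)
#> $label    "class2_quasi_bistable"
#> $r60      1.43
#> $r600     7.52e-07
#> $t_switch 203

time_of_monostability(theta, cond_ngf(), u_snb = min(bif$u_snb))
#> [1] 69.6
plateau_ratio(traj)
#> [1] 0.00125
```

Read: at rest the system has a single stable state (the origin), so it is
*not* bistable.  Yet after NGF stimulation ppERK stays above its 5-min
reference for a full hour (r60 = 1.43) and only collapses at t ≈ 203 min.
The input falls below the saddle-node level u_SNB ≈ 0.0057 at t ≈ 70 min
— from then on the upper state no longer exists, and the remaining
130 min of apparent memory are pure slow-manifold dynamics: along the
plateau the vector-field norm is 0.1% of its initial peak.

A full calibration (synthetic data → MCMC → classification) runs with
`run_pipeline()`; on a 500-draw posterior fitted to the default synthetic
dataset the population splits into roughly 5–12% class 1 and 88–95%
class 2, with class 3 empty and the class-1 set coinciding with the
CBA-bistable set.

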