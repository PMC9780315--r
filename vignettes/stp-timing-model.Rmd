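---
title: "A cerebellar circuit model in which synaptic short-term plasticity tells time"
author: "stptiming package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cerebellar circuit model in which synaptic short-term plasticity tells time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stptiming)
```

## The model

`stptiming` implements a rate-based model of the cerebellar cortical
microcircuit whose *only* source of temporal dynamics is short-term
plasticity (STP) of the mossy-fiber (MF) to granule-cell (GC) synapse. The
circuit is a two-layer perceptron: 100 MF rate units project onto 3000 GCs
(four synapses each), the GCs excite a single Purkinje cell (PC), and a
single molecular-layer interneuron (MLI) relays the GC population mean as
feed-forward inhibition, so each GC's net effect on the PC is set by the
difference between its excitatory weight `J_E` and the common inhibitory
weight `J_I`. There is no recurrence, no delay lines, no intrinsic
adaptation: if the PC can learn to time its output, the temporal information
must come from the synapses.

### The two-pool synapse

Each MF-GC synapse has two readily releasable vesicle pools in parallel: a
small, slowly refilling pool (`tau_ref_slow` = 2 s) with high fusion
probability and a large, fast pool (`tau_ref_fast` = 20 ms) with lower
fusion probability. Pool occupancies `x` deplete at the release rate and
recover with their refill constants; a phenomenological immediate-refill
probability `p_ref` = 0.6 on the slow pool mimics activity-dependent
recovery and slows the approach to steady state. Release probabilities `u`
facilitate toward 1 with time constant `tau_F` (12 ms; 30 ms for the one
facilitation-dominated type) and a single desensitization variable `q`
scales the quantal size (recovery `tau_D` = 100 ms, depression factor
`Delta_D` = 0.1). The synaptic weight is
`W = q (N_slow u_slow x_slow + N_fast u_fast x_fast)` and the transmitted
current per unit time is `W * m`.

Five experimentally constrained synapse types (relative occurrences 6, 16,
38, 24, 16%) span strong, fast-depressing "driver"-like synapses to weak,
slowly depressing "supporter"-like synapses; one type lacks the slow pool
entirely. The facilitation constant is 12 ms for types 1--4 and 30 ms for
type 5 — type 5 is the one facilitation-dominated synapse class
(paired-pulse ratio above one), the reason it alone carries the longer
constant. A two-type reduced registry
(driver/supporter, no facilitation, no desensitization, fractional
`N_slow` = 3.5 allowed -- the model is mean-field) supports the analytic
work.

### Step-response analytics

For the reduced model, an instantaneous rate switch `m_pre -> m` produces,
per pool, a mono-exponential current
`I(t) = A_s + A_t exp(-t/tau_syn)` with

* `tau_syn = tau_ref / (1 + alpha p_v m)`, `alpha = tau_ref (1 - p_ref)`
  for the slow pool and `tau_ref` for the fast pool,
* `A_s = N p_v m / (1 + alpha p_v m)`,
* `A_t = A_s * alpha p_v (m - m_pre) / (1 + alpha p_v m_pre)`.

`tau_syn` is inversely related to both the rate and the release
probability, and is capped by the refill constant (2 s): slow components of
the GC temporal basis come from low-`p_v` synapses driven at low rates.
`A_t` is signed with `m - m_pre` and vanishes when `m = 0` (no
transmission). These closed forms are verified in the test suite against
Euler integration of the pool equations to 0.1% relative accuracy, and
`joint_At_tau_density()` reproduces the sampling scheme used to map the
joint distribution of `A_t` and `tau_syn` over a rate ensemble (10^5 draws,
zero post-switch rates excluded, kernel densities for display only).

### MF rate ensembles

MF rates are drawn per synapse type from "thresholded" Gaussians: negative
values are set to zero, and the *underlying* Gaussian parameters are solved
(damped Newton on the two moment equations, residuals < 1e-8) so that the
rectified distribution has the stated target moments -- for the full model,
mean 200 Hz (types 1--2) or 20 Hz (types 3--5) with sd 20 Hz. Rectification
produces exact zero rates; for the reduced reference ensemble
(supporters at 25 +/- 15 Hz) the implied zero fraction is about 6%, which
matters because a fiber silent before the stimulus maximizes the transient
amplitude of its synapse. Uniform ensembles split into contiguous equal
groups (`split_uniform_spec()`) have per-group sd `width/(n sqrt(12))` --
38.2 Hz for two groups of `uniform(5, 270)`, 15.3 Hz for five. A Gaussian
copula (`sample_correlated_pv_rate()`) imposes a chosen rank correlation
between release probability and rate while preserving both uniform
marginals exactly by reordering.

### Calibration of the granule layer

Changing rate ensembles changes GC excitability, which would confound any
comparison of learning performance. The package therefore calibrates each
GC on 1000 random patterns using the closed-form steady states of the
synapse equations: the threshold is set at the 80th percentile of that GC's
steady-state input distribution (lifetime sparsity 0.2; the percentile rule
is this package's procedure for hitting that target) and the gain scales
its mean steady rate to 5 Hz. Out of sample the
population mean lands within about +/-1.5% of 5 Hz at these problem sizes
(the spread is dominated by the 1000 evaluation patterns, not by
calibration noise).

### Simulation

`simulate_circuit()` integrates everything with explicit Euler at 0.5 ms
(`dt` is exposed; a warning fires if a step overshoots the state bounds).
Synapse states are initialized at the analytic steady state of the first
schedule segment -- the pre-stimulus epoch is assumed stationary. Because
all synapses sharing a presynaptic fiber follow identical trajectories, the
synaptic state dimension is the number of fibers, not of connections, and
the GC drive is a sparse matrix product; this is what makes the full model
cheap enough to run in plain R. GC traces are recorded as 5 ms block
averages (the quadrature the learning rule uses); PC and MLI at every step.
`stp_off = TRUE` freezes all synapse states at the pre-switch steady state,
removing the temporal basis while leaving the static readout intact: after
a pattern switch only the 10 ms membrane relaxation remains. Note that
freezing does not shrink the *size* of switch responses -- live depression
compresses steady-state differences between patterns, so frozen synapses
actually jump further -- it removes their slow time course, which is the
property learning depends on.

## Supervised learning of PC pauses

The loss is a weighted least-squares deviation of the PC drive from a
target that equals the 40 Hz baseline everywhere except one 5 ms bin at the
desired pause time, where it is zero. The loss weight is 3.5 in the target
bin and 1 elsewhere, normalized to unit integral over the window
(`T_pre` = 0.1 s before onset, `T_CS` = 1.4 s after). The error drives a
climbing-fiber rate `cf = max(cf_spont + beta * eps, 0)`
(`cf_spont` = 1 Hz, `beta` = 0.5) and the weight update is

```
dJ_i = eta * integral w_err_tilde(t)^2 (cf_spont - cf(t)) gc_i(t) dt
```

with `eta` = 0.0025, evaluated as a Riemann sum on the 5 ms grid, and
weights clipped at zero. Two numerical decisions deserve notice:

* **Size-invariant step.** The gradient of the loss with respect to `J_i`
  carries a factor `1/N` from the population-averaged readout. The package
  deliberately does *not* include that factor in the update: with it, the
  per-trial movement of the PC rate shrinks as `1/N` and a fixed trial
  budget would mean less learning in a larger network, which is
  inconsistent with using one budget (4000 eyelid trials, 12000 interval
  trials) across model sizes. On unrectified trials the update therefore
  equals `-eta*beta*N` times the loss gradient -- the proportionality the
  gradient-fidelity test asserts.
* **Restart tolerance.** Acceleration uses Nesterov momentum with
  coefficient `(k-1)/(k+2)` and function-value adaptive restart. The
  rectified climbing fiber makes the loss chatter at the 1e-6 relative
  level near its attractor; an exact restart criterion fires on that
  chatter, destroys the momentum, and learning freezes far from the
  optimum. The package restarts only when the trial loss exceeds the best
  loss since the last restart by more than `restart_tol` = 1e-4
  (relative). With this scheme the learned weights approach the
  nonnegativity-constrained least-squares solution (verified against a
  projected-gradient oracle in development).

The rule has the expected biology: simultaneous GC activity and
above-baseline climbing-fiber activity depresses the synapse; GC activity
with a silent climbing fiber potentiates it. Because the rectification caps
how much below-baseline error the climbing fiber can report, deep pauses
are carved quickly by momentum-accelerated depression and then eroded only
slowly -- learned pauses are a long-lived transient of the rule, not its
fixed point.

## The three experiments

**Pattern switches** (`run_pattern_switch()`): MF patterns are re-drawn
every second, optionally with correlation `c` between successive underlying
Gaussian patterns (mixing before rectification,
`raw_new = c raw_old + sqrt(1-c^2) raw_fresh` -- the construction of
correlated patterns is not specified by the source and this is the
package's choice; the realized rate correlation is reported by the
sampler). The per-switch transient amplitude is the peak deviation of the
PC rate from the segment's settled tail; the normalized standard deviation
of these amplitudes falls monotonically as `c` rises to 1.

**Delay eyelid conditioning** (`run_eyelid()`): the conditioned stimulus is
an instantaneous persistent switch to a fresh MF pattern; the target pause
sits at the stimulus-to-reinforcement delay. Across delays from 25 to
400 ms the learned pause amplitude decreases and its width increases; with
`stp_off` no pause forms (amplitude under 10% of baseline). At the
scaled-down size used in the tests (300 GCs, 1000 trials) the pause minimum
tracks the target within one bin at the shortest delay but sits early for
50--150 ms delays: the rectified rule cannot reach the well-timed optimum
there, although the optimum exists (the constrained least-squares solution
is correctly timed at every delay). At the full size (3000 GCs) timing is
accurate from about 200 ms upward. Pause metrics follow a fixed error
measure: `(1 - amplitude/baseline) + fwhm/s + 5*|t_min - t_target|/s` with
`s` = 1 s; a trace with no dip gets amplitude 0, a window-length width
penalty, and a zero timing term (both are undefined); flat clipped minima
take the plateau midpoint as `t_min`.

**Bayesian interval estimation** (`run_bayes()`): per trial the pause
target is drawn uniformly from a prior interval (25--150 up to 300--500 ms;
the two longest priors use a raised climbing-fiber baseline of 5 Hz). The
package trains on the drawn sample interval directly -- the network's own
temporal basis plays the role of measurement noise; explicitly sampling a
noisy measurement per trial is a documented alternative. A
dentate-nucleus unit integrates `I_ext - pc` with `I_ext` the mean PC rate
over a configurable window (`i_ext_mode`), each DN curve is affinely mapped
so its extrema hit the prior bounds, and a single Weber fraction is fitted
jointly across priors by 1-D least squares against the Bayesian
least-squares (posterior mean) estimator under scalar noise
`t_m | t_s ~ N(t_s, (w t_s)^2)`. The estimator itself is computed by
quadrature on a grid of at most 0.1 ms. Parameter recovery on noiseless
synthetic curves is exact to +/-0.005.

**Golgi feedback** (`golgi_self_consistent()`): adding one Golgi cell that
inhibits every GC in proportion to the population mean turns the threshold
activity-dependent. With homogenized gains and thresholds (reduced by 10%),
the two mean-field conditions -- Gaussian-input rectified mean equal to
5 Hz and active fraction 0.2 -- are solved for the feedback weight and the
common gain by damped Newton iteration (residuals below 1e-8; the reduced
threshold is used consistently in both the mean and the active-fraction
condition). The per-pattern
steady state of the recurrent loop is computed by bracketed root finding on
the population mean (plain fixed-point iteration diverges here: the loop
gain is about -7). Direct evaluation at 3000 GCs reproduces both targets.

## Problem sizes and runtimes

The shipped tests and the acceptance script use: full model 100 MFs x
3000 GCs with 1000 calibration and 1000 evaluation patterns; transient
decay analysis on 1000 recorded GCs over 8 s, 10 seeds; eyelid learning at
300 GCs x 1000 trials across five delays; Weber-fraction recovery on
synthetic curves. These sizes were chosen so the entire suite runs on a
single CPU in a few minutes; the full protocols (4000 trials, 20
realizations, 12000 interval trials) are supported by the same functions
and simply take proportionally longer.

## Known limitations

* Vesicle release is deterministic (mean-field); no release stochasticity,
  no serial pool refilling, no receptor kinetics beyond the scalar quantal
  variable.
* The synthetic rate ensembles emulate stationary, piecewise-constant MF
  rates with instantaneous switches; real MF input carries burst structure
  and temporal correlations the generator does not model, so green tests
  here certify the circuit mechanism, not behavior on physiological spike
  trains.
* Learned pause timing at desk scale is biased early for delays of
  50--150 ms (see above); conclusions about short-delay timing should use
  the full network size.
* The Golgi extension treats a single homogeneous feedback unit in steady
  state; simulating its fast dynamics adds no time constant of its own.
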