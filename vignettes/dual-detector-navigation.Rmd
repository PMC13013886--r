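---
title: "Modelling dual-detector pheromone navigation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dual-detector pheromone navigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antagonav)
```

# The scientific problem

A *C. elegans* male searching for a mate must climb the gradient of a
volatile sex pheromone. The gradient is shallow, fast-evolving, and — for
an animal about a millimetre long — essentially unreadable as an
instantaneous head-versus-tail concentration difference. The package
models the alternative strategy: two detectors with *different response
properties* (a gradient-sensing head channel and a threshold-sensing tail
channel) are integrated antagonistically, and their difference drives
speed, tumbling and directed turns.

`antagonav` implements four layers of that study: the pheromone transport
field in the assay arena, the agent-based navigation model, the
trajectory and calcium-trace analytics used to characterise behaviour and
neural responses, and the optimal-turn design analysis. A fifth module
generates seeded synthetic data with known ground truth for all of them.

# The arena field

The assay plate is a circular dish, half agar, with the stimulus droplet
on the lid: a two-layer transport problem (4 mm of air at
`D_air = 1.6` mm²/s over 9 mm of agar at `D_agar = 1e-3` mm²/s, no-flux
walls, concentration continuity at the interface). `solve_bilayer_diffusion()`
uses an explicit conservative finite-difference scheme on a uniform
Cartesian grid (default 1–2 mm lateral, 1 mm vertical; stable step chosen
automatically). Cells outside the circular wall are masked and every
masked face carries zero conductance, so total mass is conserved to
rounding error — the property the test suite checks at `1e-3` relative
tolerance.

Two numerical choices deserve emphasis:

* **Face diffusivities** across the air–agar interface are harmonic
  means, the standard conservative treatment of a diffusivity jump.
* **Ghost values at the rim.** When a lateral plane is extracted with
  `slice_field()`, cells outside the wall are filled with the nearest
  in-plate values before interpolation. A zero-filled exterior would fake
  steep gradients at the rim — where the no-flux condition actually
  forces the normal gradient to vanish — and those artifacts would
  dominate the upper tail of the head–tail contrast statistic.

The navigation plane is the cross-section at `z = -0.5` mm inside the
agar, where the worms crawl. `head_tail_contrast()` samples
`|C(head) - C(tail)| / C(body)` for a 1-mm body over all in-plate
positions, stored frames and a uniform grid of orientations; samples with
near-zero midpoint concentration are flagged rather than dropped (near
the plate edge the ratio is numerically noisy). The acceptance script
recomputes the 99th percentile of this distribution on the 8-cm arena;
the droplet footprint, mesh and body length are not fixed by the source
material, so this quantity is treated as reproducible only to tens of
percent, and the grid sensitivity (1 mm vs 2 mm lateral spacing moves the
percentile by a few percent) is part of that budget.

# The navigation model

Each worm carries two confidence variables, `Q_H` (head) and `Q_T`
(tail), relaxing with a single memory timescale `1/k1 = 60` s:

```
dQ/dt = -k1 Q + k2 f(C, dC/dt)
```

with sensory inputs

```
f_H = (Cdot / Cdot0) * (1 + tanh(log(C / C0))) / 2
f_T = exp(-log(C/C0)^2)          if C <= C0
f_T = max(1 - log(C/C0)^2, -1)   if C  > C0
```

The floor at -1 and the clamping of `Q` to `[-1, 1]` reconcile the
first-order dynamics (whose unclamped steady states are `60 f` with the
published `k1 = 1/60`, `k2 = 1`) with the stated limiting behaviour
`Q_T -> 0, 1, -1` as `C -> 0, C0, Inf`. The difference `Q_H - Q_T` sets
the motor state,

```
gamma = gamma0 * exp(-lambda_K * (Q_H - Q_T))      # klinokinesis
U     = max(0, U0 + U1 * (Q_H - Q_T + eta))        # orthokinesis
```

with baseline tumble rate `gamma0 = 0.067`/s, speed
`U0 = 0.064` mm/s, modulation `U1 = 0.03` mm/s, rotational diffusivity
`D_R = 0.02` rad²/s, and `eta` a unit-s.d. Gaussian speed noise redrawn
each step (a constant-offset reading is available via `eta_mode`).
Tumble increments are drawn from a mixture of a uniform circle component
(weight `alpha = 0.3`) and a reversal-biased wrapped Gaussian centred at
pi (width `sigma = 0.6` rad) — neither constant is fixed by the source
material; both are exposed in `model_params()`. The klinokinesis strength
`lambda_K = 2` is likewise a package default, and the null-condition
acceptance quantity is constructed to be independent of it (`Q == 0`
throughout).

Integration is Euler–Maruyama at `dt = 0.1` s with tumbles as a thinned
per-step Poisson process; the wall is reflective; runs are bit-for-bit
reproducible given a seed.

## Referencing the sensory scales to the arena

`C0` is functionally the tail detector's *preferred* concentration: `Q_T`
peaks there and is suppressed above it. On the `z = -0.5` mm navigation
plane the absolute concentrations are about four orders of magnitude
below the droplet surface value, so using the droplet's `c0` for `C0`
would silence both detectors entirely. `arena_params()` therefore places
`C0` one decade below the peak concentration at the source position on
the plane (`reference_concentration()`), the smallest decade factor for
which the arena exhibits all three described tail regimes at once: a
quiescent far field, an "anchoring" band at moderate concentration where
the worm slows and tumbles, and a suppressed tail (`Q_T -> -1`) near the
source producing the sprint. The reference rate is `Cdot0 = C0 / 60`
(one `C0` per memory time) and the taxis threshold is `0.1 * C0`.

## Directed (taxis) turns

A head-enabled worm that senses a concentration above the taxis threshold
while experiencing a *decrease* along its path is armed for a directed
turn, which is perfectly accurate toward the source. By default the turn
executes at the next reorientation event drawn at the tumble rate
(`taxis_mode = "tumble-gated"`): a worm heading down-gradient loses head
confidence, its tumble rate rises, and the resulting reorientation is the
corrective taxis turn. This couples klinotaxis to the klinokinesis
machinery and rate-limits directed turns; the alternative
(`"continuous"`), which overrides the heading on every armed step,
produces implausibly fast, quasi-deterministic homing at `dt = 0.1` s.
Head-disabled conditions never perform taxis turns.

## Detector-silencing conditions and what they reproduce

`run_cohort()` simulates the four conditions (`both`, `head_only`,
`tail_only`, `none`), initialising worms uniformly in a 5-mm disc 15 mm
to the +x side of the source with random headings, freezing captured
worms (within 3 mm of the source) in place. The acceptance suite checks,
on the simulated 8-cm arena:

* the null condition finds the source in roughly one run in ten;
* head input saturates success near 100% (taxis dominates);
* tail input alone substantially enhances success and biases the search
  phase toward the source (`mean_x < 0`) while enlarging the maximum
  excursions `d_max`;
* confidence-readout noise in the 0.01–0.1 range moves success by at
  most a few percentage points.

`mean_x` averages each worm's position over its *pre-capture* search
phase (captured worms sit frozen at the source and would otherwise
dominate the average mechanically); the all-time average is reported
alongside as `mean_x_all`.

Two known limitations. First, the tail-only enhancement in this
implementation is stronger than the published "almost doubling" (the
enhancement factor depends on where `C0` sits relative to the late-time,
nearly uniform field, which the source material does not pin down).
Second, the published claim that the searching population's mean position
turns *positive* whenever tail input is absent is reproduced for the null
condition but not for `head_only`, where taxis turns pull the search
paths toward the source under every averaging we examined; the test suite
asserts the orderings and the tail-present signs only.

# Trajectory and calcium analytics

`speed_series()` and `power_spectrum()` (single-taper periodogram, linear
detrend) quantify stimulation-locked locomotion; the `peak_strength`
summary — peak power over the local background median — operationalises
"amplitude and sharpness" of the protocol peak. `classify_motifs()`
labels contiguous 2-s windows of signed velocity by their sign changes
(none: forward/backward; one: the two reversal transitions; more than
two: high-frequency; a sustained self-proximity flag: self-exploratory in
the six-motif scheme). Windows with exactly two changes are labelled by
the first transition observed — the source material calls more than two
changes unassignable, implying two or fewer are assignable, but does not
state the rule. `chemotaxis_index()` implements both endpoint-assay
scores; `cohort_summary()` the success curve, `mean_x` and `d_max`
summaries.

`ratio_trace()` computes the two-channel ratio with order-1, length-13
Savitzky–Golay smoothing per channel (mirror padding at the edges; an
order-1 filter passes affine signals through unchanged, which the tests
assert at machine precision in the interior). The baseline `R0` is the
mean ratio over the quiescent pre-stimulus epoch. `auc_response()`
integrates baseline-subtracted activity over a 2-min post-stimulus window
restricted to sub-baseline (suppression) or supra-baseline (excitation)
intervals, by the trapezoidal rule; for titration series the baseline of
the most dilute condition can be supplied explicitly.
`fit_linear_combination()` is ordinary least squares with intercept; the
synthetic-circuit generator composes a command-neuron trace from two
upstream traces so recovery of the generative weights can be tested both
noiselessly (exact) and under noise (Monte-Carlo calibrated tolerance).

# The optimal-turn analysis

An idealised crawler estimates the local gradient from two directional
derivatives measured along successive legs of its path. The two
derivatives are built from three concentration readings — start, turn
point, end — so with iid reading noise their errors are *anticorrelated*
(the turn-point reading is shared). The least-squares gradient estimate
and its direction uncertainty follow in closed form; at finite noise the
package evaluates the root-mean-square angular error of the nonlinear
estimator exactly by Gauss–Hermite quadrature.

For a *fixed* initial orientation relative to the gradient, sweeping the
turn angle yields a per-orientation optimum; at the default reading noise
(0.3 of the per-leg concentration increment) every orientation's optimum
exceeds 90 degrees. A worm that does not know its orientation cannot use
those per-orientation optima; the default `"uniform"` rule therefore
minimises the worst case over orientations of the direction variance.
Under the shared-reading noise model this criterion has a sharp,
closed-form optimum at the turn angle that makes the three sampled points
an equilateral triangle — 120 degrees — where the gradient information
matrix becomes isotropic. Three design decisions are worth recording:

* with *independent* derivative noise (no shared reading) the same
  machinery yields 90 degrees, and the test suite asserts this pair as a
  regression check distinguishing the two noise placements;
* the orientation-*mean* criterion (rather than worst-case) gives an
  optimum near 105 degrees and is exposed via `orientation_rule`;
* the default noise level 0.3 was chosen once as moderate sensory noise;
  below about 0.2 the finite-noise per-orientation optima can dip under
  90 degrees for oblique starts.

Angles are degrees at the interface and radians internally; grid ties
resolve to the smallest angle.

# Synthetic data

`gen_calcium_traces()` draws fast responders (probability 0.625, onset at
the stimulus, sustained slowly decaying plateau) and slow responders
(onset delayed 150 s, peak scaled by 0.6) with multiplicative channel
noise; the kinetic shape (10-s rise, 600-s decay) is a package choice,
while the class fractions, delay and amplitude factor are fixed by the
study. `gen_periodic_speed()` adds a stimulation-locked elevation to the
baseline speed; `gen_circuit_traces()` composes linear circuit triplets;
`gen_endpoint_counts()` draws multinomial endpoint assays (20 worms per
trial, 10 trials by default); `gen_toy_field()` provides uniform, linear
and Gaussian-hill slices with exact samplers, which serve as oracles for
the navigator and contrast code. All generators embed their parameters
and are bit-reproducible under a fixed seed.

What the generators deliberately do not emulate: tracker segmentation
artifacts, posture and body-curvature dynamics, photobleaching, or the
real inter-animal variability structure. Passing tests on synthetic data
therefore validate the *computations*, not the biology of any particular
recording.

# Problem sizes and runtimes

The test suite solves the standard arena once on the 2-mm grid and runs
cohorts of 600–4000 worms; the acceptance script uses the 1-mm grid and
10,000 worms for the null-condition fraction, matching the study's cohort
size. These sizes were chosen so the full pipeline — field, slice,
contrast, four conditions, analytics — runs comfortably on a single CPU.

# Reproducing the headline numbers

`scripts/acceptance.R` recomputes, from a fresh field solve and fresh
simulations: the two stimulation-locked spectral peaks, the
uniform-orientation optimal turn angle and the minimum per-orientation
optimum, the 99th percentile of the head–tail contrast on the 8-cm
arena, and the null-condition success percentage at n = 10,000. See the
README for invocation.
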