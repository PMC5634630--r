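---
title: "Methods: pseudolinear force-encoding models of muscle spindle firing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudolinear force-encoding models of muscle spindle firing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindlefit)
```

## The scientific question

Muscle spindle Ia afferents fire during passive stretch in ways that classic
length-and-velocity descriptions do not capture: an initial burst at stretch
onset after an isometric rest, an elevated dynamic response, and rate
relaxation — a decay of tonic firing while the muscle is held at constant
length. All three are *history-dependent*: they depend on what the muscle was
doing before the stretch. Whole-muscle force shows matching history
dependence (short-range stiffness at onset, force relaxation during holds,
first-stretch force enhancement in repeated ramp-release stretches), which
suggests that the spindle's receptor encodes force-related rather than
length-related variables.

`spindlefit` implements the analysis that adjudicates this: a set of
pseudolinear candidate models of the instantaneous firing rate (IFR), fitted
per afferent under a swept neuromechanical lag and compared by
cross-validated AICc.

## The encoding model

Every candidate predicts the IFR as a rectified linear combination of
mechanical channels $x_i$ evaluated a lag $\lambda$ before the spike:

$$\widehat{IFR}(t) \;=\; \sum_i k_i \,\big\lfloor x_i(t-\lambda) + b_i \big\rfloor_+ ,$$

floored at zero (a firing rate cannot be negative). $\lfloor\cdot\rfloor_+$
is half-wave rectification, $k_i \ge 0$ a gain in imp/s per predictor unit,
$b_i$ an offset in predictor units, and $\lambda$ an integer number of
milliseconds between 0 and 15 shared by all predictors of a model.

Two readings of the rectification are defensible: rectify-then-offset
(`model$rectify_order = "as_printed"`) or treat $-b_i$ as a threshold below
which a channel contributes nothing (`"threshold"`, the default — it matches
the verbal description "only positive changes above a threshold are
retained", and makes $b$ interpretable as a recruitment threshold). Both are
implemented and test-pinned; for the synthetic ground truths used here they
coincide wherever the operating range keeps the argument positive.

The six candidates are: **force** (whole-muscle force and dF/dt), **length**
(musculotendon length, velocity, acceleration), **length-power** (velocity
raised to a fractional exponent $a \in [0.1, 1]$, fitted by a nested grid in
steps of 0.05 with the velocity rectified before exponentiation),
**fascicle-low/high** (length-related variables after subtracting the
elongation of an exponential series tendon with constant 2 or 6 per mm), and
**all** (a free regression on all 11 predictors). For the force model a
*competing-influence* variant is available in which, wherever the force and
dF/dt components are simultaneously positive, the smaller-magnitude
component is zeroed; zeroing the smaller component cannot change which one
is larger, so one pass over the time points is the fixed point of that rule
(ties keep the force component, the tonic pathway). The variant is retained
for an afferent only if it strictly improves the mean R².

## Signal processing

Length and force are sampled at 2 kHz. Channels are low-pass filtered at
the recording convention — velocity 40 Hz, acceleration 40 Hz, force 50 Hz,
dF/dt 100 Hz — with a 4th-order Butterworth applied forward and backward so
that filtering is zero-phase: any latency between a predictor and the rate
is then carried solely by the fitted $\lambda$. The filter is run from
steady-state initial conditions on odd-reflected extensions, so a constant
series passes through unchanged to machine precision (`signal::filtfilt`
does not maintain this, which is why the application loop is ours while the
design comes from `signal::butter`). Derivatives use second-order central
differences, computed after filtering the parent channel and then filtered
at their own cutoff. The IFR is the reciprocal inter-spike interval assigned
at the *later* spike of each pair, so that predictors at $t-\lambda$ always
precede the rate sample they explain. Fits use the IFR samples at spike
times only; the evenly-binned traces sometimes used for display are never
fitted.

Fascicle length is musculotendon length minus the tendon elongation
$\Delta\ell(F) = \ln(F/F_{ref})/c$, the unique form whose stiffness grows
linearly with force ($dF/d\Delta\ell = cF$); $F_{ref}$ defaults to the
0.1 N resting tension and elongation is clamped at zero below it (slack).
Pinnation is ignored — a constant pinnation angle only rescales the
channels, which the gains absorb.

## Fitting and model comparison

Per trial, the fit minimizes $J = SSE/SSM$ (so $R^2 = 1 - J$ identically) by
bounded nonlinear least squares: an analytic objective and subgradient in
compiled code under L-BFGS-B, with a deterministic multi-start (zeros, bound
midpoints, exploratory values). The lag is swept over all 16 values;
per-trial best lags are averaged (half-up rounding) into one frozen lag per
afferent and model. Search limits come from exploratory per-trial fits on a
deterministic subset of trials: gains bounded by three times the largest
exploratory estimate, offsets by the largest predictor magnitude. For the
free regression the limits are widened to admit every sub-model's box, and
each cross-validation fit is additionally warm-started from the fitted
sub-models embedded in the 11-predictor coordinates — the free regression
nests the candidates, and these starts let the optimizer realize the
nesting in practice.

Model comparison uses 100 randomized 75/25 train/test splits at the trial
level (rounding toward train, stratified by stretch type so test sets
contain unseen waveform types). Held-out fit quality is summarized by AICc
with the likelihood proxied by $1/J_{test}$ — a proxy, not a true
likelihood; it is used comparatively, never absolutely — and $n$ equal to
the number of test *trials*. We use the standard small-sample correction

$$AICc = 2\left(k - \ln\hat L + \frac{k(k+1)}{n-k-1}\right).$$

A sign-flipped variant of the correction term is selectable
(`selection$aicc_form = "as_printed"`). It is not the default because under
that sign the correction *rewards* parameters near the small-sample limit —
with 30 test trials the 22-parameter free regression would receive a bonus
of about 145 AICc units and win every comparison, inverting the entire
model ranking; the standard form is the one under which a parsimonious
generating model can beat a free regression that nests it, which is also
the qualitative outcome this analysis is designed to detect. Akaike weights
$w_j = e^{-\Delta_j/2}/\sum_r e^{-\Delta_r/2}$ are computed from the mean
AICc across iterations, at the afferent level and again at the population
level from per-afferent means; selection frequency counts per-iteration
AICc winners (ties toward fewer parameters, then fixed candidate order).
The parameter count $k$ is the number of fitted gains and offsets (+1 for
the velocity exponent); the frozen lag is determined before
cross-validation and not counted. When a model is too rich for a split
($n \le k+1$) its AICc is recorded as missing, it cannot win, and it is
excluded from the weights with a warning — at the default 120 trials per
afferent (30 test trials) every candidate is admissible.

## The synthetic cohort

Because the analysis is validated without recordings, the package generates
its own ground-truth data at the study's conditions: ramp-hold-release and
sawtooth stretches spanning 1–4 mm, 4–50 mm/s and 200–3500 mm/s² built as
acceleration-limited trapezoidal-velocity profiles with at least 5 s of
isometric rest before each stretch; 120 trials per afferent (about the
per-afferent trial count of a well-sampled experiment, and enough for 30
test trials per split).

Whole-muscle force is phenomenological:
$F = F_{rest} + k_{passive}(L - L_0) + F_{xb}$ with a Maxwell-slip
cross-bridge element

$$\dot F_{xb} = k_{xb}\,(1 + \eta R)\,v \;-\; |v|\,F_{xb}/s_0 \;-\; F_{xb}/\tau,
\qquad \dot R = (1-R)/\tau_{rec} - |v|\,R/s_r,$$

integrated at the sampling rate. The fast slip element ($s_0 = 0.2$ mm,
$\tau = 0.5$ s) produces short-range stiffness — a dF/dt transient at
stretch onset after rest — and force relaxation during holds. The slow
rested-state fraction $R$ ($\eta = 1$, $s_r = 2$ mm, $\tau_{rec} = 5$ s) is
thixotropy: stiffness that rebuilds during quiescence and is destroyed by
movement. It is needed because the slip element alone forgets its history
within a fraction of one sawtooth cycle, leaving first-stretch force
enhancement at the numerical-noise level; with it, the first stretch of a
sawtooth develops a robustly (~5%) greater peak force, as observed in
rested muscle. Measured force is floored at zero (the musculotendon goes
slack rather than pushing during rapid release). Default parameters
($k_{passive} = 0.5$ N/mm, $k_{xb} = 3$ N/mm) give forces of order 2 N for
a 3 mm stretch — order-of-magnitude plausible for a cat triceps surae
preparation, not calibrated to any particular muscle.

Ground-truth firing rates apply a candidate model's parameters to the same
processed channels the fitting sees, floored at a 5 imp/s resting
discharge (the floor does not bind at the default truths, so the encoder is
exactly recoverable). Spikes come in two modes. The *deterministic* mode
emits the train whose IFR samples the rate exactly: each spike time solves
$(t_i - t_{i-1})\,r(t_i) = 1$. This, rather than integrating the rate to
successive integer crossings, is what makes noiseless parameter recovery
exact — integer-crossing would make each $1/ISI$ an average of the rate
over the preceding interval, which lags the instantaneous rate during
transients, biases the fitted lag upward, and leaks a few percent of error
into the gains. The *poisson* mode replaces the unit threshold with
independent gamma unit-mean thresholds $G_i$: at `shape = 1` and constant
rate this is exactly a Poisson process; the synthetic afferents default to
`shape = 50` (ISI CV ≈ 0.14), the near-regular discharge characteristic of
Ia afferents — a genuinely Poisson-irregular train is not a realistic Ia
model, and the heavy right tail of $1/ISI$ under exponential intervals
would dominate a least-squares fit.

What the generator does *not* emulate: fusimotor drive, intrafusal fiber
mechanics (bag1/bag2/chain), receptor-potential dynamics, electrode noise
or spike-sorting errors, and any nonlinearity of the true muscle beyond the
slip/thixotropy phenomenology. Passing recovery and selection checks on
this cohort therefore demonstrates that the *pipeline* is correct and
well-posed — that the fitting recovers known parameters and the selection
identifies known generating models under realistic signal structure — not
that real spindles encode force; that evidence must come from recordings.

## Spindle metrics

The dynamic index is the classical measure: peak IFR in a window ending at
the ramp end minus the IFR 0.5 s into the hold (taken from the last spike
at or before that instant; no interpolation). Trials are grouped in five
10 mm/s velocity bins, dropping bins with fewer than 4 trials. The
initial-burst window runs from stretch onset (velocity crossing 0.5 mm/s)
to the first zero-crossing of acceleration — the minimal kinematically
anchored choice, which by construction excludes the second acceleration
peak at release; burst amplitude is the peak IFR in that window, paired
with the window's peak dF/dt and peak acceleration, and regressed by
ordinary least squares (12 trials minimum, slope t-test).

## Numerical choices and degenerate inputs

- Lags shift by whole samples only (1 ms = 2 samples at 2 kHz); the
  leading gap holds the first value.
- Trials whose IFR is constant (zero variance) cannot enter the
  $SSM$-normalized cost and are rejected with an explicit error.
- $J_{test}$ is clamped at $10^{-15}$ before inversion into the likelihood
  proxy so that a numerically perfect noiseless fit does not produce an
  infinite AICc.
- Optimizer ties across starts resolve to the lowest cost; exact AICc ties
  resolve toward fewer parameters, then candidate order — both
  deterministic, so identical seeds reproduce identical outputs
  byte-for-byte.
- Trial-level QC: at least 50 spikes per trial (an explicit exclusion flag
  stands in for visual signal-quality screening of real recordings);
  afferent-level QC: at least 40 passing trials.

## Problem sizes used in the checks

The test suite and the acceptance script run the full procedure at the
study's scale where the property demands it: selection correctness and the
nesting property use 120-trial afferents with the complete 100-iteration
cross-validation; parameter recovery uses 20 trials per spike mode;
formula-level checks are exact and instantaneous. The reproducibility
check runs the whole simulate–fit–select–report chain twice at a reduced
size (two 40-trial afferents, 5 iterations) and compares every written
byte.

## Known limitations

- The likelihood proxy $1/J$ has no distributional justification; AICc
  differences are meaningful only within this fixed candidate set.
- The competing-influence rule's "significant contribution" threshold is
  configurable but defaults to zero; the original rule's threshold is not
  specified anywhere we could pin it.
- The exponent grid for the velocity-power model trades resolution (0.05)
  for determinism; a continuous fit of $a$ would be marginally tighter.
- Synthetic force magnitudes are plausible, not calibrated; quantitative
  DI values from the cohort should not be compared against recorded cats,
  only their ordering and velocity trends.
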