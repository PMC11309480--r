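---
title: "Tensor cardiography: model, estimation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tensor cardiography: model, estimation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tensorcardio)
```

## The probabilistic beat model

The package treats the ECG of one beat as the difference between the
electrical activity of two myocardial populations: an anodic group
(endocardial side of the ventricular wall, contributing positive
potential to a lead along the main electrical axis) and a cathodic
group (epicardial side, negative). Each cell's action-potential (AP)
onset and offset are transition events; modelling their times as
normally distributed, the depolarized fraction of a group follows a
Gaussian CDF in time and returns along the complementary curve
`k (1 - Phi)` during repolarization. The lead voltage is the
anodic-minus-cathodic difference plus a baseline level.

Assumptions worth keeping in mind:

* transition times are Gaussian — adequate for large synchronized
  populations, wrong for conduction blocks or ectopy, where the
  point-process is no longer unimodal;
* the dipole superposition is additive and stationary within a beat;
* a positive-dominant QRS; net-negative leads are fitted after sign
  inversion (flagged), and genuinely complex morphologies (delta waves,
  deep S, J waves) need the extended mode's extra CDF pairs.

Two fitting conventions coexist. **RT-separate** fits the QRS window
and the T window independently (7 free parameters each: two means, two
spreads, two weights, one level), which is faithful to each wave's
shape but leaves the four CDFs unconnected. **RT-bulk** fits one
trapezoid equation over `[QRS onset, T end]`, joining each rise to its
fall at the depolarized plateau; the repolarization weights are tied to
the depolarization weights either exactly (`plateau = "hard"`, the
default: stable, the natural choice when ST information matters) or
through a quadratic penalty (`plateau = "penalty"`,
`lambda = 10 * mean(y^2)` by default), which tolerates slightly open
trapezoids at the cost of a mild pull on the weights. Population tables
fitted in bulk mode show slightly unequal weight pairs, which is why
the soft option exists at all.

## Parameters and units

Everything is millivolts and milliseconds. Per component
(`Rp, Rn, Tn, Tp`): mean `mu` (ms, relative to a per-beat origin at QRS
onset — only differences are physiologically meaningful, the absolute
reference is arbitrary and tables therefore publish intervals), spread
`sigma` (ms, > 0), weight `k` (mV, >= 0). Levels: `betaR`/`betaT`
(separate) or one `beta` (bulk). Derived intervals:
`muRTp = muTp - muRp` (collective anodic AP duration, close to
textbook APD), `muRTn` (cathodic duration, systematically shorter),
`muRpn` and `muTpn` (transmural delays). The identity
`muRpn + muRTn + muTpn = muRTp` is algebraic and is enforced to
machine precision by construction.

Healthy lead-II population means ship in
`healthy_reference_params()`; two clinical per-beat series
(`pci_case_series()`, `ers_case_series()`) provide realistic abnormal
parameter trajectories. The falling curve is parameterized as
`k (1 - Phi)` with positive `sigma` rather than a reversed-argument
CDF, so direction is explicit and bounds stay one-sided.

## Estimation

Per-segment bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`). Defaults, all overridable via `fit_config()`:

* bounds: `sigma` in [1, 200] ms, `k` in [0, 20] mV, means inside the
  fit window ± 50 ms, `beta` in [−2, 2] mV;
* initialization from fiducials: R means straddle the R peak at ±
  quarter QRS width with `sigma_R` = QRS width / 4; T means straddle
  the T peak at ± an eighth of the T-window width with
  `sigma_Tn` = width / 4 and `sigma_Tp` = width / 8 (preserving the
  physiologic hierarchy `sigma_Rn < sigma_Rp << sigma_Tp < sigma_Tn`).
  Wider T initializations (half-width spreads) were tried and let the
  level parameter absorb the T wave in a wrong local minimum on clean
  beats, so the tighter start is the default;
* 3 restarts (the plain start plus two jittered by ~5 ms on means,
  ~10% on scales), lowest cost kept; deterministic given
  `fit_config(seed=)`;
* tolerances `ftol = 1e-12`, `ptol = 1e-10`, 200 iterations;
* no pre-filtering: the model itself acts as the denoiser. An optional
  PQ-median baseline correction exists but is off by default.

Fit quality is `r2 = 1 - SS_res / SS_tot` per window plus the residual
SD. Non-converged fits, fits with `r2 < 0.5`, bound-stuck parameters,
ordering violations (`muRp <= muRn <= muTn <= muTp` must hold for
physiologic beats — violations are flagged, never reordered) and
late-repolarization crossings all surface as warnings on the
`tcg_fit`; non-converged beats are masked in the tensor, never dropped
or interpolated, so beat indexing and downstream Mahalanobis scoring
stay honest.

Extended mode adds one or two anodic/cathodic CDF pairs inside the QRS
window, seeded from the plain fit with near-zero weights so its optimum
can never be worse (nested models). A small ridge (weight `1e-3`) on
the extra weights resolves an identifiability gap: a cancelling pair
with arbitrarily large equal weights is observationally equivalent to
no pair at all.

## Segmentation

A transparent rule-based delineator, since fiducials only set fit
windows and initializations: R peaks from a smoothed slope-energy
detector (20 ms boxcar — which also nulls 50 Hz mains — squared
derivative averaged over 60 ms, 30% peak threshold, amplitude veto,
200 ms refractory); QRS onset / J point as the first/last crossing of
10% of the peak absolute derivative within ± 80 ms of R; T end by the
tangent method (steepest post-peak slope extended to the PQ baseline);
T onset at J + 40 ms. Standard-interval clamps (QRS ≤ 200 ms,
QT ≤ 600 ms) mark beats unusable rather than guessing. ST level is
measured at J + 60–80 ms against the PQ baseline (the measurement point
is a convention; the clinical threshold figures it feeds are level
thresholds, not definitions). Note the tangent T end is systematically
earlier than the generator's 3-sigma envelope truth (below); the two
are different definitions of the same loose concept, so pipelines
compare QT trends, not absolute offsets.

## The synthetic generator

`synthesize_record()` is the package's ground truth: beats evaluated
from the forward model at drawn RR intervals, plus white noise (default
SD 0.01 mV, a clean clinical recording), optional sinusoidal baseline
wander, and per-beat parameter draws. Model-implied fiducial truth uses
3-sigma envelopes (`QRS onset = muRp - 3 sigmaRp`,
`T end = muTp + 3 sigmaTp`, `J = muRn + 3 sigmaRn`,
`T onset = max(J, muTn - 3 sigmaTn)`). Scenarios:

* `"normal"` — stationary healthy-population parameters
  (RR 1000 ± 25 ms by default, a resting adult);
* `"ischemia"` — the cathodic repolarization spread `sigmaTn` ramps
  60 → 104 ms (the span seen across a staged coronary occlusion) over
  50 beats, and only later does an ST-level shift appear (realized
  through the cathodic plateau weights, −0.1 mV by default, 15 beats
  after the spread onset). This encodes the ordering the method is
  designed to exploit: repolarization variance moves before the
  conventional indices do;
* `"ers"` — per-beat parameters cycle through the printed
  early-repolarization case series, including its beat-to-beat
  `sigmaTn` alternans before ventricular fibrillation.

What the generator does **not** emulate: P waves, respiratory
modulation, electrode artefacts, ectopic beats, multi-lead projection
geometry. Passing tests therefore demonstrate correctness of the
estimation machinery and internal consistency on model-generated data;
they say nothing about fit quality on arbitrary clinical recordings,
where the model is at best an approximation.

For RT-separate synthesis the beat is piecewise (R-segment equation up
to the J point, T-segment beyond), matching how the two windows are
fitted independently; the bulk model covers the whole beat in one
expression and is the default everywhere a full record is needed.

## Abnormality scoring

Fixed-threshold flagging uses the case-derived working thresholds
`sigmaTp >= 45 / <= 35` ms and `sigmaTn >= 80 / <= 70` ms
(`default_threshold_rules()`); they are derived from a single
intervention case, not population-calibrated, and are deliberately
easy to replace.

The Mahalanobis distance of a parameter pair (typically
`(sigmaTn, sigmaTp)`, `(muRTp, muRTn)` or the conventional
`(ST, QT)`) is computed against the mean and sample covariance of an
explicit reference beat window — in intervention data, the waiting
period before each intervention segment, chosen by the analyst; no
change-point automation is attempted. The distance (not its square) is
reported, on raw parameter scale (no standardization: immaterial with
an exact covariance, and with regularization the raw scale keeps the
ridge interpretable in parameter units). Repolarization spreads are
strongly correlated, so a ridge `eps * trace/dim` (`eps = 1e-6`) is
added when the covariance condition number exceeds 1e8; an all-constant
window degenerates gracefully (distance 0 at the constant).
`md_crossing()` declares onset at the first run of at least 3
consecutive beats above the 99th reference percentile — single-beat
excursions above a high quantile are expected by chance and are not an
onset.

## Numerical and degenerate-input conventions

* Crossing detection (`find_repolarization_crossing`) scans a 1 ms grid
  over `[muTn - 3 sigmaTn, muTp + 4 sigmaTp]`, takes the **latest**
  anodic-above to cathodic-above sign change (multiple crossings occur
  with strongly unequal spreads) and refines it by bisection; amplitude
  differences below `1e-9 * max(k)` count as zero, so identical curves
  report "no crossing" rather than numerical noise.
* Flat/constant windows: `r2` is undefined and returned as `NA` with a
  `"constant"` flag instead of a misleading 1 or 0.
* Windows shorter than 8 samples are refused (under-determined).
* WFDB output is the format-16 subset (int16 little-endian, gain in
  ADC units/mV, honored on read); values are always converted to mV,
  and unknown unit suffixes are an error, never a guess.
* Every stochastic call takes an explicit seed and restores the
  caller's RNG state; identical input + config + seed reproduces
  results bit for bit, including through the command line.

## Problem sizes

The shipped tests run the noiseless round trips on single 1000 Hz
beats, noise studies on 40–200 replicate beats, record-level pipelines
on 10–200 beats at 500–1000 Hz, and Mahalanobis calibration on 500
simulated beats — sizes chosen so the full suite exercises every path
in well under half an hour on one core while keeping Monte-Carlo checks
(chi-square mean of squared distances, CI coverage) statistically
meaningful.

## Known limitations

* Identifiability: with hard plateau constraints, data generated from
  unequal weight pairs is mis-specified by construction; recovered
  spreads absorb part of the discrepancy (sub-percent at the printed
  parameter values, but real). The penalty mode trades this against a
  pull toward equal weights.
* The tangent T end and the 3-sigma model envelope are different
  definitions; absolute QT values from the delineator sit tens of ms
  below the envelope truth, consistently.
* Thresholds and the reference-window MD are descriptive tools; no
  alarm calibration or ROC analysis is attempted (no labelled data).
* The model covers R and T waves only; P waves, conduction
  disturbances and paced rhythms are out of scope.
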