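# tensorcardio

Decomposition of ECG heartbeats into differences of Gaussian cumulative
distribution functions (CDFs), estimating the timing statistics of
collective myocardial action-potential (AP) transitions from a
body-surface signal — "tensor cardiography".

## Who this is for

Biomedical-signal researchers and electrophysiologists who want a
model-based, per-beat quantification of depolarization and
repolarization variance (rather than landmark amplitudes/intervals
alone), and a reproducible synthetic test bed for such pipelines. The
package is self-contained: it generates its own ground-truth ECG from
the same forward model it fits, so every claim is testable without
clinical recordings.

## The model

Myocardial cells fire and repolarize as a population. Modelling each
transition time as normally distributed, the fraction of depolarized
tissue in a group rises as a Gaussian CDF Φ and falls back as 1 − Φ. A
given lead sees two groups of opposite polarity: anodic (endocardial
side, subscript *p*) and cathodic (epicardial side, subscript *n*).
With weights *k* (mV), means μ and spreads σ (ms), and a baseline
level β:

* **R wave** (RT-separate): `y(t) = kRp Φ((t−μRp)/σRp) − kRn Φ((t−μRn)/σRn) + βR`
* **T wave** (RT-separate): `y(t) = kTp [1−Φ((t−μTp)/σTp)] − kTn [1−Φ((t−μTn)/σTn)] + βT`
* **RT-bulk**: one equation over the whole beat, each anodic/cathodic
  rise joined to its fall at the plateau
  (`A(t) = kRp ΦRp − kTp ΦTp`, `C(t) = kRn ΦRn − kTn ΦTn`,
  `y = A − C + β`), with the repolarization weights constrained to the
  depolarization weights (hard or penalized).

Each beat is fitted by bounded Levenberg–Marquardt least squares
(`minpack.lm`). The fitted parameters give interval metrics

* `muRTp = μTp − μRp` — collective anodic AP duration (≈ APD),
* `muRTn = μTn − μRn` — cathodic AP duration,
* `muRpn`, `muTpn` — transmural delays of depolarization/repolarization,

which satisfy `muRpn + muRTn + muTpn = muRTp` identically. Per-beat,
per-lead parameters form a 4th-order tensor
`[beat × lead × component(Rp,Rn,Tp,Tn) × metric(μ,σ,k)]` with β,
interval metrics and conventional indices (ST level, QT, RRI)
alongside. Abnormality over time is scored by fixed thresholds on the
repolarization spreads (σTp ≥ 45 / ≤ 35 ms, σTn ≥ 80 / ≤ 70 ms) and by
the Mahalanobis distance of parameter pairs from a reference beat
window.

## Worked example

Synthesize one noisy lead-II-like beat from the healthy-population mean
parameters, then fit it back:

```r
library(tensorcardio)
params <- healthy_reference_params("separate")
model  <- reference_beat_model(params, mode = "separate", mu_Rp = 100)
beat   <- synthesize_beat(model, fs = 1000, noise_sd = 0.03, seed = 42)
fit    <- fit_rt_separate(beat$signal, beat$fs, beat$truth$fiducials)
print(fit)
```

```
<tcg_fit> mode = separate (converged)
<beat_model> mode = separate
          Rp      Rn      Tn      Tp
mu    99.891 122.110 345.746 407.325
sigma  6.471   5.627  50.092  21.214
k      1.944   1.964   0.692   0.699
beta: R=0.014 T=-0.005
r2: QRS=0.9984 T=0.9677 overall=0.9944
```

The fitted means sit within a few ms of the generating values
(μRp = 100, μRn = 122.18, μTn = 253.88 + 100, μTp = 307.35 + 100), the
spreads reproduce the physiologic hierarchy σRn < σRp ≪ σTp < σTn, and

```r
fit$metrics$muRTp
#> 307.4   # anodic collective AP duration, ms (generating value 307.35)
```

Record-level use: `synthesize_record()` (scenarios `"normal"`,
`"ischemia"`, `"ers"`) → `fit_record()` → `extract_series()` /
`flag_thresholds()` / `md_crossing()`. A command-line front end wraps
the same calls:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","tcg.R",package="tensorcardio"))') \
  simulate --scenario ischemia --beats 200 --seed 5 --out rec --format csv
```

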