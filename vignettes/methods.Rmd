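---
title: "Decoding naturalistic behavioral states from high-gamma dynamics: models and methods"
author: "gammastate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding naturalistic behavioral states from high-gamma dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Intracranial recordings collected over days in a hospital room have no
trial structure: behavior is annotated only as coarse 5-minute blocks
("dialogue", "electronics", "television", "rest"). The question this
package addresses is which statistical features of the 70–110 Hz amplitude
envelope — long-term mean, variance, inter-channel covariance, slow versus
fast fluctuations, or coherent spatiotemporal factors — discriminate such
states, and how to evaluate that discriminability honestly on temporally
correlated data.

This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic tests do and do not establish.

# Signal conditioning

The conditioning chain runs in a fixed order: channel rejection →
referencing → (downsampling for depth-electrode recordings) → notch
filtering → band-pass + Hilbert envelope + binning → despiking.

* **Channel rejection.** A channel is rejected when its mean squared value
  exceeds the across-channel mean by `k` across-channel standard
  deviations, with `k = 3` for ECoG grids and `k = 1.5` for sEEG, and when
  any sample is exactly zero (a hallmark of amplifier clipping or dead
  contacts). Whether the rule should see raw or referenced signals is
  genuinely open; the default applies it to referenced signals (the signal
  actually analyzed), with `rejectOnReferenced = FALSE` to switch.
* **Referencing.** Common average for grids; bipolar differences of
  adjacent contacts along each shank for depth electrodes (labels
  `"A1-A2"` style).
* **Filters.** Filter realizations are not dictated by the analysis design,
  so standard, stable, phase-free choices are used: 2nd-order Butterworth
  band-stops of 1 Hz width at 60/120/180/240 Hz, a 4th-order Butterworth
  band-pass for 70–110 Hz, and an 8th-order low-pass at 0.8× the target
  Nyquist before decimation — all applied forward–backward (zero phase).
  Centers at or above Nyquist are dropped with a warning.
* **Envelope.** The magnitude of the analytic signal (computed by the
  standard frequency-domain construction) is averaged over non-overlapping
  250 ms bins (128 samples at 512 Hz; 125 at 500 Hz); the average amplitude
  estimates the square root of band power. A trailing partial bin is
  dropped; bin edges anchor at each contiguous segment's first sample.
* **Despiking** operates on the *binned* envelope, per channel and per
  contiguous segment: bins above 7× the segment median are replaced by
  linear interpolation between the nearest clean neighbors (edges take the
  nearest clean value). A segment whose bins are all flagged is an error.
* **Z-scoring** (for the features that require it) subtracts the mean and
  divides by the sample standard deviation (denominator n−1; the choice is
  immaterial at n = 1200 bins but is fixed for reproducibility) within each
  labeled 5-minute block. A zero-variance window is set to zero with a
  warning rather than producing NaNs.

# Features and decoding

Thirty-second epochs (120 bins) are tiled inside each labeled block;
epochs that would straddle a recording gap are discarded. The five feature
families and their required normalization:

| family     | z-scoring | feature                                   | decoder |
|------------|-----------|-------------------------------------------|---------|
| mean       | none      | per-channel epoch mean                     | linear SVM |
| variance   | none      | per-channel epoch sample variance          | linear SVM |
| covariance | 5-min     | q×q epoch covariance                       | MDM |
| slow       | 5-min     | analytic magnitude of < 0.333 Hz component | linear SVM |
| fast       | 5-min     | analytic magnitude of > 0.333 Hz component | linear SVM |

`runExperiment()` enforces the normalization column: requesting a
z-scored family with z-scoring disabled is a configuration error.

**Cross-validation.** Folds are contiguous in time (never shuffled), and a
1-fold buffer on each side of the test fold is excluded from training;
with folds spanning at least five minutes this guarantees test and
training data at least five minutes apart. The buffer, not a wall-clock
rule, is the mechanism; an optional `minGapS` argument additionally
enforces an explicit gap for unusually small plans. Training and test sets
are class-balanced by uniform subsampling without replacement (seeded;
balancing happens after fold assignment, per train/test set). The SVM is
linear with one-vs-one vote aggregation and `C = 1` (exposed); features
are standardized per fold using training-set statistics (a flag disables
this). The MDM classifier uses the arithmetic class mean and Frobenius
distance; ties break deterministically to the first class in canonical
order, with a message.

**Chance.** With finitely many balanced trials, guessing can exceed
`100/classes`%. The chance level is `100·k*/n` where `k*` is the smallest
integer with `BinomCDF(k*; n, 1/classes) ≥ 1 − alpha`, `alpha = 0.05`.
`n` is the total balanced epoch count across folds; at the reference
class-duration table (minimum class 40 and 75 minutes) this yields 29%
(4 classes, n = 320) and 37% (3 classes, n = 450).

**Welch spectra.** The analysis design fixes a Hann window, a 256-point
FFT, 30-second segments, and 75% overlap, but is ambiguous about whether
the overlap applies within or across segments. Since a 30-s epoch holds
120 bins < 256 points, the implementation reads it as: 120-sample Hann
windows sliding with 75% overlap across each state's concatenated epochs,
zero-padded to 256. The standard error is computed across periodograms
before averaging. A Parseval check (total power ≈ variance within 10%) is
part of the test suite.

# Gaussian process factor analysis

The observation model is `y_t | x_t ~ N(C x_t + d, R)` with diagonal `R`;
each latent factor is an independent, unit-variance Gaussian process over
the epoch with squared-exponential kernel
`(1 − σ_n²)·exp(−Δt²/(2τ_i²)) + σ_n²·1[Δt = 0]`. The noise floor is fixed
at `σ_n² = 10⁻³`, the convention of the reference formulation of this
model; it keeps kernels well-conditioned without visibly coloring the
latents.

**EM.** The E-step computes the exact joint posterior over an epoch's
`p·T` latents: with time-major ordering the prior precision is
block-sparse per factor and the likelihood adds `C'R⁻¹C` per time bin, so
one Cholesky factorization of a `pT × pT` matrix per iteration serves all
epochs. The expected complete-data log-likelihood separates exactly into
an observation part (closed-form joint update of `C` and `d`, then
diagonal `R`) and one 1-D term per timescale, so maximizing each `τ_i` by
Brent search in log-τ (bounds `[binMs/2, 100·T·binMs]`, search tolerance
10⁻³) constitutes a full M-step and EM monotonicity holds exactly; the
per-iteration data log-likelihood is recorded and its monotonicity is a
validity condition of the fitted object. Convergence is a relative
log-likelihood gain below 10⁻⁶ with a 500-iteration cap. Slow timescales
(τ ≫ epoch length / 4) are the slowest parameters to converge; parameter-
recovery runs use the full 500-iteration budget. `C`, `d`, `R` initialize
from a factor-analysis EM fit on pooled bins; timescales from a cycling
ladder 500, 1000, 2000, … ms. `R` entries are floored at 10⁻⁸× the channel
variance; a singular class covariance in the downstream classifier gets a
ridge of 10⁻⁶·trace/p, logged.

**Orthonormalization.** `C = U D V'` and `x~ = D V' x`, so `U x~ = C x`
exactly; factors are ordered by singular value (covariance explained) with
the sign convention that each column of `U` has its largest-magnitude
entry positive. Zero singular directions of a rank-deficient loading are
dropped with a warning.

**Prediction error.** For each held-out channel, latents are inferred from
the remaining channels and the held-out channel is predicted as
`C_j E[x|y_−j] + d_j`. RMSE is computed per behavioral class and the class
RMSEs are summed ("class-balanced RMSE"), so a majority class cannot
dominate. The FA baseline uses the same leave-one-channel-out scheme with
time-independent conditioning; the smoothed-FA control (`preSmoothMs`)
fits FA after Gaussian-kernel smoothing, probing whether a single
universal autocorrelation could explain the data. Reduced GPFA evaluates
the top-m orthonormalized factors of a larger fit; on synthetic data it
tracks full GPFA within fold noise at matched dimensionality (a truncated
projection of a larger model need not strictly beat a directly fitted
smaller one), which is how the corresponding test asserts it.

**Latent-state classification.** Vectorized `p × T` epochs get a Gaussian
class model with the mean tiled statically in time and the class
covariance — estimated from all class bins pooled — repeated along the
block diagonal (time points treated as independent; this deliberate
model/classifier mismatch is what makes the covariance estimable from few
epochs). The per-class score is then just a sum of per-bin Gaussian
log-densities, verified in the tests against the explicit `pT`-dimensional
density. A pooled-covariance variant is the LDA control: if classes
differed only in latent mean it would perform as well as QDA, so QDA ≫ LDA
localizes the information in latent (co)variance. Because each fold refits
GPFA, factors are aligned across folds by timescale rank when averaging
single-factor accuracies.

# The synthetic-data module

The generator plants, per state: channel means, channel standard
deviations, a loading matrix onto latent GP factors with per-factor
timescales, and unit-variance Gaussian channel noise — so per-state
envelope covariance is `diag(sd)·(C·diag(scale²)·C' + I)·diag(sd)`.
Latents are drawn independently per 5-minute block (states change at block
boundaries, so continuity across blocks is not meaningful). Raw
recordings are synthesized as band-limited (70–110 Hz) unit-variance noise
carriers, independent per channel, amplitude-modulated by the envelope
(zero-order hold per bin — the exact inverse of binning), plus 1/f
background noise, 60 Hz line noise with harmonics, and sparse one-bin
amplitude spikes at 10× the channel median (Poisson arrivals, default one
per five minutes) that exercise the 7× despiking rule.

Default study conditions: three states over 12 channels at baseline
amplitude 3 (arbitrary units), mean shifts ±0.8, standard-deviation ratio
1.4, one latent factor per state with loadings `±1/√q`, factor scales
1.8/1.8/0.8·√q, and timescales 8000/1000/300 ms — so the states differ
simultaneously in mean, variance, covariance sign, and timescale, and the
schedule cycles the states over 21 five-minute blocks (210 epochs). The
modulation depths were chosen once, against the physics of the synthesis:
the envelope of a 40 Hz-wide noise carrier averaged over 250 ms bins
fluctuates with CV ≈ 0.17 of the instantaneous amplitude, so planted
standard deviations must be comparable to `0.17 × baseline` for the
conditioning chain to recover envelopes with high fidelity. Round-trip
evaluations generate the driving envelope with `clip = TRUE` (a physical
amplitude is nonnegative; without clipping, negative Gaussian excursions
are rectified by the synthesis and the comparison is distorted), while
oracle tests of planted moments keep the unclipped, exactly-Gaussian
default.

What the generator does **not** emulate: volume conduction or any
cross-channel noise correlation, electrode geometry, non-stationarity
within a block, seizure or pathological activity, behavioral label noise,
and recording dropouts (segments exist in the data model but the generator
emits one contiguous segment). Passing tests therefore demonstrate
correctness of the algorithms under the stated generative model — not that
real recordings satisfy that model.

# Problem sizes used by the tests

The test suite and acceptance script run at desk scale, chosen as the
smallest sizes at which each property is stable across seeds: parameter
recovery at q = 12, p = 3, 60 epochs of 120 bins, τ ∈ {300, 1500, 8000} ms
(three seeds); RMSE curves at q = 10, two smooth factors, 70 epochs of 60
bins, dimensionalities 1–3 with the reduced evaluation from a 4-factor
fit; feature-family decoding at the default 210-epoch synthetic study;
latent decoding contrasts at q = 8, two states, 140 epochs. Oracle
equivalences (posterior inference, constrained QDA) are exact to 10⁻⁸ at
`p·T ≤ 60`.

# Known limitations

* The EM τ update is a conditional 1-D search per factor; factors with
  nearly equal timescales can swap identities between runs (the subspace,
  not the factor labels, is identifiable — hence subspace angles and
  τ-rank alignment in all comparisons).
* Long timescales are weakly identified from 30-second epochs
  (τ = 8 s ≈ a quarter epoch) and converge slowly; expect broad
  uncertainty above a few seconds.
* The constrained classifier ignores temporal correlation by design;
  its scores are not calibrated probabilities.
* Bipolar referencing assumes contacts are listed in order along shanks;
  no geometry is read.
* EDF and HDF5 containers are not read or written; all I/O is plain
  TSV/JSON with the same content.
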