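---
title: "Expanding low-density EEG with a stacked bidirectional LSTM: models and design choices"
author: "eegdense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expanding low-density EEG with a stacked bidirectional LSTM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Wearable and clinical EEG systems record from few electrodes (9-18), while
many analyses -- source imaging, topographic mapping, spatial-filter
classifiers -- benefit from dense coverage (here, a 60-channel 10-10
montage). Because nearby scalp electrodes record strongly correlated
mixtures of the same cortical generators, and because EEG is a structured
time series, the signal at an unrecorded electrode is partly predictable
from the recorded ones. `eegdense` reconstructs ("super-densifies") the
missing channels with a recurrent network, and ships the classical spatial
interpolators and a downstream motor-imagery classification pipeline used
to judge whether the reconstruction actually helps.

## The interpolation network

The core model is a two-layer stacked bidirectional LSTM. Each LSTM cell
maintains a cell state $C_t$ and hidden state $h_t$ updated through three
sigmoid gates and a tanh candidate, all computed from the concatenation
$[h_{t-1}, x_t]$:

$$
f_t = \sigma(W_f [h_{t-1}, x_t] + b_f), \quad
i_t = \sigma(W_i [h_{t-1}, x_t] + b_i), \quad
o_t = \sigma(W_o [h_{t-1}, x_t] + b_o)
$$
$$
\tilde C_t = \tanh(W_c [h_{t-1}, x_t] + b_c), \quad
C_t = f_t \odot C_{t-1} + i_t \odot \tilde C_t, \quad
h_t = o_t \odot \tanh(C_t).
$$

At each time step the input $x_t$ is the vector of all observed (z-scored)
channels, so spatial information enters as the feature dimension and
temporal structure is carried by the recurrence. Each layer runs once
forward and once backward over the window from zero initial state and
concatenates the two hidden sequences; the first layer has 120 hidden
units per direction, the second 128, so the second layer consumes
240-dimensional inputs and emits 256-dimensional features. A per-timestep
linear readout maps these features to *all* target channels jointly, and
predictions are de-standardized back to microvolts with the target
channels' training statistics.

Design choices that the architecture description leaves open, and how this
package resolves them:

* **Output head.** One joint linear readout over all target channels,
  rather than one network per electrode. Joint prediction subsumes the
  single-electrode case, shares the recurrent features across targets, and
  is what an 18-to-60-channel expansion actually requires.
* **Loss and optimizer.** Mean squared error (the evaluation metric is
  RMSE), Adam with initial step size `1e-2`, per-epoch exponential decay
  (`lr_decay`, default 0.95), global gradient-norm clipping at 1, and
  early stopping on held-out validation MSE.
* **Readout refit.** After gradient training, the linear readout is
  re-solved in closed form (ridge least squares on the recurrent features
  of the training windows) and kept only if it lowers the validation
  loss. Given fixed features the readout optimum is exactly computable, so
  discarding it would waste information; the refit typically buys the last
  factor of two in MSE at negligible cost.
* **Standardization.** Per-channel z-scores estimated on training data
  only; the same statistics standardize validation, test and prediction
  inputs, and de-standardize outputs.
* **Windows.** Training windows default to `seq_len = 150` samples (0.6 s
  at 250 Hz) with batch size 100, both inside the designed ranges of
  120-180 and 80-120; values outside those ranges require an explicit
  override. Windows overlapping artifact-masked samples are dropped rather
  than repaired.
* **Initialization.** Uniform weights scaled by fan-in, forget-gate bias
  1 (so early training does not erase memory), seeded and bit-reproducible.

The forward pass and full backpropagation through time are implemented in
C++ (RcppArmadillo) and are verified in the test suite against an
independent scalar-loop evaluation of the gate equations and against
central finite differences of the loss.

## Confidence intervals

The calibration is deliberately simple and stated explicitly, since the
interval construction is otherwise easy to leave implicit: per target
channel, residuals on a held-out calibration recording are assumed
Gaussian, and the interval half-width is $z_{(1+\alpha)/2}\,\hat\sigma$
with $\hat\sigma$ the calibration residual standard deviation. Empirical
coverage is then reported on test data. This will under-cover if test
residuals are heavier-tailed than calibration residuals (e.g. artifact
segments unseen in calibration); it makes no claim of conditional
coverage.

## Classical baselines

Two baselines operate instant by instant on the azimuthal-equidistant
planar projection of the montage:

* **Inverse-distance weighting**: the prediction is the convex combination
  of observed channels with weights proportional to $d^{-1}$ or $d^{-2}$,
  normalized to sum to one (un-normalized weights would not preserve
  microvolt units). A coincident electrode ($d = 0$) is passed through
  exactly; any smooth alternative is numerically unstable as $d \to 0$.
* **Natural cubic spline along an electrode line**: the observed
  electrodes in the same anterior-posterior (or lateral) band as the
  target are ordered along the line, abscissae are cumulative planar
  distances, and a natural cubic spline (zero second derivative at both
  ends -- the parameter-free boundary choice) is fitted per instant and
  evaluated at the target's abscissa. Extrapolation beyond the knot span
  is refused. Because the natural-spline fit is linear in the knot values,
  the per-instant fits collapse to a fixed linear functional, which is how
  the series path is computed; tests verify equality with per-instant
  dense solves.

## Montage geometry

Electrode positions are generated, not digitized: the head is a unit
sphere, 10% of the nasion-inion arc is 18 degrees, the midline and central
coronal arcs carry their electrodes directly, the outer ring (polar angle
72 degrees) holds twenty 18-degree slots, and interior rows are placed at
proportional fractions along the planar segment from the row's midline
electrode to its ring terminus. This yields exact midline and left-right
mirror symmetry, which the tests assert for every homolog pair. The planar
projection is azimuthal-equidistant about the vertex: planar radius equals
arc distance from Cz, angles are preserved. The canonical 60-channel index
order (1 = Nz, 21 = FCz, 31 = Cz, 60 = O2) is fixed; note this montage has
no P1/P8 (P2 is present without its homolog), so symmetric subsets use the
P3/P4 and P5/P6 pairs.

The four built-in low-density subsets (9, 12, 15, 18 electrodes) are
package defaults, not a claim about any particular published figure: they
are left-right symmetric, cover frontal, central/temporal, parietal and
occipital regions, and grow by nesting; the 18-channel set contains C3,
Cz, C4. Arbitrary user subsets are accepted as label lists.

## The synthetic-data generator

All tests and the acceptance script run on synthetic recordings, so the
generator defines the study conditions:

* **Spatial structure.** Band-limited Gaussian sources at scalp locations
  are mixed onto channels with a Gaussian kernel
  $g(d) = \exp(-d^2 / 2s^2)$ of scale $s = 0.5$ planar radians
  (neighbouring 10-10 electrodes are ~0.31 apart), plus white sensor
  noise. A monotone distance-decaying kernel is the minimal structure that
  makes spatial interpolation learnable; no volume-conduction physics is
  claimed.
* **Sources.** Twelve broadband (1-45 Hz) background sources by default,
  realized by band-pass filtering white noise with the package's own
  zero-phase filter, unit variance, amplitude 10 uV at distance zero.
* **Motor-imagery epochs.** Trials are 2 s rest + 4 s imagery at 250 Hz
  (cue at sample 501 of 1500). Every electrode named in the ERD map hosts
  a local mu-band (8-13 Hz) source; during the imagery period of a trial
  the sources of that trial's class are scaled by $\sqrt{1 - d}$ with ERD
  depth $d = 0.5$, i.e. a 50% band-power reduction. The default map
  places the focal sources *between* the sparse-montage electrodes, at
  their physiological sites: hand-knob areas medial/anterior to C3/C4
  (C1/FC3 and C2/FC4), the midline supplementary-motor strip for foot
  (FCz/CPz), ventral sensorimotor cortex for tongue (C5/C6). With
  discriminative detail at observed electrodes the montage-density
  contrast the package exists to study would disappear by construction.
* **Noise level.** `noise_sd = 16` uV against 10 uV sources. This was
  chosen so that four-class classification from the sparse 18-channel
  montage lands in the low-60s percent range -- the regime reported for
  real four-class competition recordings -- rather than saturating near
  ceiling, where density comparisons are uninformative.
* **Round structure.** Round ids cycle 1..10 over trials; the 5-fold
  round split (fold $k$ tests rounds $2k-1, 2k$) then matches the 8/2
  train/test convention.
* **Linear-mixture fixture.** For parameter-recovery benchmarks, target
  channels are fixed random convex combinations of the observed channels
  plus Gaussian noise of known standard deviation; the returned true
  weights give an oracle predictor whose RMSE is the generative noise
  floor.

What the generator does **not** emulate: ocular/muscle artifacts,
non-stationary noise, inter-subject variability, realistic volume
conduction, 1/f spectra. Passing tests on these conditions demonstrate
that the pipeline recovers structure it is designed to recover; they do
not certify performance on real recordings.

## Downstream evaluation

The quality check mirrors standard motor-imagery practice: band-pass 8-30
Hz (mu + beta), feature window 0.5-3.5 s after the cue, per class a
common-spatial-patterns filter set (class versus rest, 3 filter pairs)
from trace-normalized average covariances, log-variance-share features,
and a one-versus-rest regularized linear discriminant, with the argmax
over class scores and ties broken toward the lowest class index. The same
pipeline is applied to the sparse channels, the network-reconstructed
60 channels and the true 60 channels over the five round-folds.

One numerical choice deserves emphasis: the CSP covariance shrinkage
default in the classification path is `0.05` (times mean channel
variance), not a token `1e-6`. Reconstructed channels are close to linear
combinations of the observed ones, so the 60-channel class covariances are
near rank-deficient; whitening then amplifies near-null directions into
spurious filters unless the covariances are meaningfully shrunk. Shrinkage
of this order is standard practice for CSP with many channels and few
trials, and the same value is applied identically to all inputs being
compared. The bare `csp_fit()` primitive keeps a minimal `1e-6` default
for well-conditioned use.

## Problem sizes used by the tests and the acceptance script

These are the package's chosen benchmark scales (chosen to make the
properties sharp at desk scale): the parameter-recovery fixture uses 18
observed channels, 4 targets, 66 s at 250 Hz (50 s train / 10 s
validation / 6 s test), noise 0.1 uV, and the full 120+128-unit network
for 70 epochs; the channel-count trend uses 24 s recordings and a reduced
24+24-unit network at two montage densities over three seeds; the
classification comparison uses 50 trials per class, a 32+32-unit network
trained on rounds 1-8, and the full five-fold CSP/OVR pipeline. The
reduced hidden sizes in the latter two keep the properties intact (they
are comparisons, not absolute benchmarks) at a fraction of the cost.

## Degenerate inputs, tie-breaks, tolerances

Zero-variance channels make z-scoring undefined and are a hard error.
Zero-distance IDW passes through the first coincident electrode in
montage order. Spline lines need at least three observed knots; targets
outside the knot span are an error, not an extrapolation. OVR score ties
go to the lowest class index. Gate activations are mathematically confined
to (0,1) and hidden components to (-1,1); oracle-equivalence tests run at
1e-10, spline exactness at 1e-9 to 1e-12, CSP eigen-recovery at 1e-8.

## Known limitations

The network is trained per recording/session; no transfer across subjects
is attempted. The confidence intervals are marginal and Gaussian. The
spline baseline depends on how many observed electrodes share a line with
the target, so it is only defined for some targets under sparse montages.
EDF input is not implemented (CSV and the package's own formats are); an
independent-component artifact-removal hook is documented but deliberately
out of scope -- only threshold marking plus band filtering are provided.
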