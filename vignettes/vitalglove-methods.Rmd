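---
title: "Methods: smoothing, alerting and false-alarm evaluation for smart-glove sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smoothing, alerting and false-alarm evaluation for smart-glove sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitalglove)
```

## The problem

A wearable smart glove streams heart rate (BPM), blood oxygen saturation
(SpO2, %), body and ambient temperature (deg C) and inertial data while an
athlete rests, walks and runs. Two computations sit on top of the stream:
a kinematic conversion of gyroscope angular velocity into linear speed, and
a threshold alert that warns the athlete when the heart rate exceeds a safe
ceiling. Raw optical heart-rate and IMU signals carry motion artifacts —
single-sample spikes from sensor displacement — so the alert engine fires
false alarms unless the stream is smoothed first. This package implements
the full chain (session I/O, kinematics, smoothing, alerting, evaluation,
synthetic data, pipeline) and quantifies how much smoothing reduces false
alarms.

## Data model

A session is a tibble of per-sample rows (`index`, `time_s`, `hr_bpm`,
`spo2_pct`, `ambient_c`, `body_c`, `speed_cm_s`, `alert`) with the activity
phase and the sampling period attached as attributes. Eight packaged
reference tables (30 samples each) cover the three phases raw, the three
moving-average-filtered versions, and the Gaussian-filtered resting and
walking versions; the published Gaussian running table duplicates the
walking one verbatim and is excluded as an erratum. The tables print no
timestamps; we attach a 1 Hz period, consistent with the per-second
narration of the source experiment, and make it overridable everywhere. A
flat Firebase-style key-path record (`sensor/BPM`, `sensor/gyro/x`, ...,
`timestamp`) is provided as a JSON interchange schema; it adds `sensor/SpO2`,
`sensor/ambient` and `sensor/speed` to the core paths so one sample
round-trips losslessly.

## Kinematics

With the elbow as rotation origin and the sensor at position vector
$\mathbf r$ (default $(0.25, 0, 0)$ m, a typical forearm length), a
gyroscope reading $\boldsymbol\omega$ (converted deg/s $\to$ rad/s) gives
the linear velocity $\mathbf v = \boldsymbol\omega \times \mathbf r$ and
speed $\|\mathbf v\|$, reported in cm/s. The cm/s unit is deliberate: at
rest, gyroscope drift of around 1 deg/s yields a visible ~0.5 cm/s speed
floor that m/s units would hide. Radius variation over a stride is
neglected; $\mathbf r$ is a per-session configuration parameter. Because
the gyroscope traces behind the published speed columns are not printed,
kinematics is validated by properties (orthogonality $\mathbf v \cdot
\boldsymbol\omega = \mathbf v \cdot \mathbf r = 0$, linearity,
antisymmetry, agreement with a determinant-expansion oracle to 1e-12), not
by table regression.

## Smoothing

Two filters, applied independently per channel (never to the alert flag,
which is recomputed downstream):

* **Moving average**, window 5: each output is the unweighted mean of the
  window. Output lies within the window's min/max.
* **Gaussian**, sigma 2 samples: convolution with a normalised kernel
  $w_k \propto e^{-k^2/2\sigma^2}$, truncated at 4 sigmas (half-width
  $\lceil 4\sigma \rceil$ samples). Normalisation makes smoothing of a
  constant exact.

Edge handling is a documented choice, since filtered streams can be
reported either aligned-and-shortened or length-preserving:
`"complete_only"` emits only full-window values (n − window + 1 outputs),
`"reflect"` pads by edge-inclusive reflection and preserves length. The
packaged moving-average tables are block means over a longer underlying
recording: a brute-force offset search (re-run in the test suite per
channel) shows printed filtered row $i$ equals the mean of printed raw rows
$i{+}1 \ldots i{+}5$ for every channel and phase, to the print precision of
0.005 — 375 cells in total. Rows 26–30 of the filtered tables depend on
unprinted samples and are not regressed. The Gaussian tables cannot be
reproduced from the printed raw tables because the original kernel
truncation, boundary mode and row alignment are unstated; the Gaussian
filter is therefore verified against a direct convolution oracle and by its
kernel properties, and the Gaussian tables serve as fixtures only.

## Alerts

A sample is flagged when heart rate exceeds the threshold (default
150 BPM); an optional compound mode additionally requires speed above
100 cm/s, but every flagged row in the running reference table satisfies
the heart-rate rule alone, so `hr_only` is the default. With an athlete's
age the threshold follows the age-predicted maximum heart rate, 220 − age.
Each alert takes 2 s to reset: flagged runs separated by a gap shorter than
the refractory period merge into one episode. Per-sample flags remain
instantaneous (the reference table prints consecutive flagged rows), and
the engine is signal-agnostic — callers flag raw or smoothed sessions
alike. One subtlety the test suite documents: the number of *flagged
samples* is monotone non-increasing in the threshold (flag sets are
nested), but the number of *episodes* is not, because removing interior
flags can split a refractory-merged run in two; on the running reference
table, moving the threshold from 140 to 150 BPM splits one episode into
two.

## Evaluation

Alert quality is scored by cross-matching episodes: a raw episode is
confirmed if a reference-variant episode overlaps it within a matching
window (default: the 2 s refractory time), each reference episode
confirming at most one candidate, greedily in start order. The reference
variant is the last filter supplied — by default the Gaussian filter, the
better-performing smoother — and is an explicit convention, not clinical
ground truth. `confirmed + false_positive` always equals the raw count, and
the true-positive percentage of a session that raised no alarms is defined
as 100 (no alarms, hence no false alarms). The source experiment's
full-session counts (seven raw alerts, three surviving the moving average,
one surviving the Gaussian) come from data that was never printed, so the
package checks the mechanism two ways: the bookkeeping on a
seven-candidate/three-confirmed configuration (4 false alarms), and a
distributional property — over 100 seeded spike-heavy synthetic sessions,
median episode counts are ordered raw ≥ moving average ≥ Gaussian.

## Synthetic sessions

The generator emulates level-and-noise structure per phase, not
physiology: Gaussian noise around a base (plus a linear ramp for running
heart rate), near-integer SpO2 plateaus with rare ±1 steps, linear
temperature drifts, and speed derived by drawing a gyroscope trace whose
magnitude corresponds to the target speed through the arm model — so the
resting drift floor emerges from gyroscope noise exactly as in the real
device. Defaults mirror the reference tables: resting HR 77 ± 2.5 BPM and
~0.5 cm/s drift speed (1 deg/s gyro noise); walking HR around 80 BPM with
speeds up to ~60 cm/s; running HR ramping from 85 toward ~160 BPM over
300 s (crossing the 150 BPM threshold, so alert paths are exercised) with
speeds spanning roughly 50–290 cm/s. Body temperature is slightly lower
while walking than at rest because the tables show it; no physiological
mechanism is asserted. Artifact spikes are Poisson-placed single-sample
multiplicative events on the heart-rate channel — the narrowest artifact,
hence maximally attenuated by both filters, which is exactly the false-alarm
mechanism under study. The resting tables are stable, so resting defaults to
no spikes. All randomness flows from one caller-supplied seed and the
global RNG state is restored afterwards.

What passing tests on synthetic data do *not* show: real optical
heart-rate artifacts are not purely single-sample or multiplicative, real
speed is not a stationary Gaussian magnitude, and a single athlete's
physiology (the source data's provenance) does not represent population
variability.

## Numerical and design choices

* Fixture values are stored exactly as printed (two decimals); comparisons
  use absolute tolerance 0.005 to absorb print rounding.
* The moving-average/Gaussian cores run through `stats::filter`
  convolution; the test oracle is an explicit double loop, keeping the two
  routes independent.
* Degenerate inputs: empty sessions, series shorter than a full window
  (`complete_only`), non-positive sigma, ages outside (0, 120], unknown
  fixture ids and schema-incomplete node records all raise informative
  errors; invariant violations name the offending row.
* The complete-window moving average of a fixture starts one row before
  the printed filtered table (output row 2 aligns with printed row 1); the
  offset is re-derived by search in the tests rather than hard-coded blind.
* Problem sizes: property tests use 50–100 seeded replicates of 300-sample
  sessions and 100-point random input sweeps — large enough for stable
  medians and 3-standard-error parameter recovery, small enough to keep the
  suite in tens of seconds.
* Reports are written as JSON (machine) and text (human); runs log a
  configuration hash, input and package version to standard error.

## Known limitations

Single-subject provenance of the reference tables; no accelerometer
fusion, GPS or adaptive filtering; no SpO2 or temperature alert rules (the
device defines none); Gaussian reference tables are fixtures, not a
regression surface; the published whole-session true-positive rates (≈65%
raw, 100% Gaussian-filtered) are not reproducible from printed data and
are deliberately not asserted anywhere.
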