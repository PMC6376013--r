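---
title: "Methods: envelope-correlation imaging of deep sources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: envelope-correlation imaging of deep sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
model behind each stage, the parameters that matter, what the synthetic data
do and do not emulate, and the numerical and design choices made where the
procedure itself leaves them open.

## The question and the estimator

Whether scalp EEG carries usable information about subcortical generators is
contested: deep sources are far from the sensors, their potentials are
heavily attenuated, and instantaneous inverse maps are dominated by cortex.
The estimator implemented here does not ask the inverse solution to place
amplitude correctly at depth. Instead it uses an *independently recorded*
intracranial signal as a temporal fingerprint: if the alpha-band amplitude
envelope reconstructed at a solution point co-fluctuates, at lag zero and on
the scale of seconds, with the envelope recorded by a DBS-lead contact, then
that point's reconstruction contains the deep signal — even if its absolute
amplitude is biased. Localization quality is then summarized by the distance
between the recording contact and the correlation maximum of the nearest
significant cluster.

The chain is: individual alpha band selection → zero-phase narrow-band
filtering → Hilbert analytic signal per sensor → linear inversion of real and
imaginary parts → per-point complex magnitude per Cartesian component,
combined by the norm → per-frame spatial thresholding → Pearson correlation
with the intracranial envelope (negatives zeroed) → max-statistic lag-shift
permutation inference → cluster-based localization report.

Key assumptions: the deep oscillation is narrowband around an individual
alpha peak shared between scalp and depth; its envelope dynamics live on the
scale of seconds, far below the carrier (Bedrosian's condition, so the
envelope commutes with narrow-band filtering); volume conduction is linear
and instantaneous, so a zero-lag correlation peak distinguishes conduction of
the same source from slower, lagged neuronal coupling; and the forward model
is linear in the dipole moments.

## Forward model

The realistic, MRI-derived head geometry of clinical practice is deliberately
replaced by a concentric 3-shell spherical model (brain/skull/scalp, default
radii 80/85/92 mm, conductivities 0.33 / 0.0132 / 0.33 S/m — a 1:25 skull
ratio, configurable). Individual anatomy is unobtainable at desk scale, the
pipeline's logic is geometry-agnostic, and `build_laura_operator()` accepts
any externally supplied gain matrix should a realistic lead field be
available later.

Potentials are the exact series solution of the piecewise-homogeneous
boundary-value problem: per Legendre degree the two interface-continuity
conditions and the insulating outer boundary are propagated outside-in (all
intermediates scale with interface radius ratios, keeping the solve
well-conditioned to degree 200), and the per-degree surface coefficients are
cached in the head model. The series is truncated adaptively when the term
bound falls below 1e-10 of the accumulated total, capped at 200 terms; tests
assert that ten further terms change no potential by more than 1e-8
relative, and that the equal-conductivity limit matches the
generating-function closed form of the homogeneous sphere to better than
1e-6. Unit convention: positions in mm (head-centred RAS, origin at the
sphere centre), moments in nAm, potentials in µV.

The source space is a regular grid clipped to strictly inside the brain
shell, with spacing derived from the target count (about 5000 points at full
scale; reduced counts for tests) and refined until the realized count is
within 20% of the target. Grid indices are kept for neighbourhood and
cluster connectivity.

## Inverse operator

The distributed inverse is the weighted-minimum-norm family with a local
autoregressive spatial prior:

G = M⁻¹Lᵀ(LM⁻¹Lᵀ + λC)⁻¹,  M = AᵀA,  C = I.

The published description of the LAURA solution fixes the family but not the
exact weights, so this package declares its own convention and exposes it as
configuration: neighbours within `1.05·spacing·√3` (the full
26-neighbourhood), weights ∝ distance⁻², diagonal `(26/|Vᵢ|)·Σw` (so
boundary points are strictly diagonally dominant and A is nonsingular),
applied identically per Cartesian component; orientations are free, coupled
only through the spatial prior. With an empty neighbourhood (radius 0) A is
the identity and G reduces — verified to 1e-10 — to the classical Tikhonov
minimum-norm operator; in the square well-conditioned limit with λ → 0 it
recovers the exact inverse. No noise-covariance whitening is used (C = I).

λ defaults to generalized cross-validation on the data to be inverted,
computed from the eigendecomposition of LM⁻¹Lᵀ on a deterministic subsample
of time points, so `"auto"` is reproducible for identical input; a fixed λ
override exists for tests and exact reproducibility across configurations.

## Envelope imaging

The Hilbert transform is applied on sensors first and the operator after, as
a linear operator commutes with the sample-wise analytic construction (a
commutation test asserts the equivalence). Envelope fields are evaluated on
a 25 Hz time grid by default. Because the inverse is linear and
time-pointwise and the magnitude is a pointwise function, this decimation is
implemented as exact subsampling of the analytic sensor signal — the
decimated field equals the full-rate field at those instants bit for bit
(asserted in tests), not an approximation. Alpha envelopes with seconds-scale
dynamics are band-limited far below 12.5 Hz, so nothing of interest is lost;
`decimate_to = NULL` restores the full rate.

Per-frame spatial thresholding zeroes entries strictly below the frame's
spatial mean; ties at the mean are kept (the procedure's description does not
fix the tie, and keeping ≥ makes the constant frame a no-op). Thresholding
is applied at the envelope grid rate, before any further temporal reduction,
and is deliberately not idempotent — a second application is an error rather
than a silent re-threshold.

Filter realization: Hamming-windowed linear-phase FIR, applied by FFT
convolution with exact group-delay compensation (zero-phase overall). The
transition width is half the lower band edge, giving < 0.1 dB passband ripple
and > 50 dB attenuation one octave outside the band — comfortably inside the
≥ 40 dB contract asserted by the tests. The first and last
`2/bandwidth + half-kernel` seconds of every envelope are flagged as edge
frames and excluded from all correlation statistics.

Degenerate inputs are handled explicitly: constant (e.g. fully thresholded)
point series have undefined Pearson correlation and are stored as zero with a
logged count; an intracranial channel without a detectable spectral peak
excludes its hemisphere from correlation analysis rather than aborting the
run, mirroring how a subject without an intracranial alpha peak is excluded
from analysis.

## Permutation inference

The null hypothesis is "no zero-lag temporal alignment beyond what arbitrary
alignments produce". The reference envelope is circularly shifted (wrap-
around preserves the sample count per permutation), the per-point
correlations are recomputed with the same negative-zeroing as the observed
map, and the map-wide maximum is recorded; the observed map is thresholded at
the empirical (1−α) quantile of these maxima, controlling family-wise error
over the whole solution space. Lags within 2 s of zero alignment are
inadmissible because seconds-scale envelopes remain autocorrelated there
(configurable via `min_lag_s`); for records concatenated from segments, lags
that would align a wrap point within the same span of a seam are excluded as
well. Lags are drawn uniformly with replacement from the admissible set; an
`exhaustive` mode enumerates the set once, which the tests compare against a
brute-force oracle on a tiny instance. The quantile is the upper empirical
order statistic `sorted[⌈(1−α)n⌉]`, fixed for bit-reproducibility; a point is
significant iff its correlation strictly exceeds it. Defaults are 10⁴
permutations and α = 0.01.

Clusters of significant points use 26-connectivity on the source grid — the
procedure's "cluster" is otherwise undefined. The localization report picks
the cluster whose nearest member is closest to the contact, reports the
Euclidean distance from the contact to that cluster's correlation maximum,
and the min–max contact distance over the cluster ("range"). Pearson (not
rank) correlation is used throughout, matching the convention of reporting
r values; distance profiles default to 4-mm bins and to all points (a
significant-only mode exists).

## The synthetic sessions

`simulate_session()` emulates what the analysis assumes about eyes-closed
rest with externalized DBS leads:

- **Deep envelopes.** Rectified Ornstein–Uhlenbeck processes: unit-variance
  latent AR(1) with time constant `envelope_timescale` (default 2 s), shifted
  by 2 SD and clipped at zero. Left/right latents share a common innovation
  stream whose mixing weight is calibrated by Gauss–Hermite quadrature and
  root finding so the *rectified* envelopes hit the target
  `interhemi_rho` (default 0.5) despite the distortion from clipping.
- **Cortical context.** `n_cortical_sources` (default 4) alpha sources on a
  shell at 85% of the brain radius, alternating hemispheres, carriers drawn
  within ±0.5 Hz of the deep peak, envelopes coupled to their hemisphere's
  deep latent at `cortico_deep_rho` (default 0.3) — "loosely coupled", so the
  correlation analysis has realistic competition from cortex.
- **Volume conduction.** Each source is a fixed random-orientation dipole;
  scalp data are the average-referenced forward projections plus white
  sensor noise (default 1 µV SD). The electrode cap is a deterministic
  Fibonacci covering of ~2.6π sr (a geodesic-net-like extent) — no
  manufacturer coordinates are reproduced.
- **Intracranial leads.** Four collinear contacts per hemisphere along a
  dorsolateral trajectory starting 0.5 mm from the deep source
  (centre-to-centre spacing 2 mm by default, matching the 1.5 mm
  contact + 0.5 mm gap lead geometry; 3 mm reproduces the wider-spaced lead).
  Contact potentials are constructed so each adjacent bipolar derivation
  equals the deep source current scaled by `lfp_gain/(1 + d)` with `d` the
  distance from source to pair midpoint — the local field falls off with
  distance and scales with the same source strength as the scalp projection,
  so a silenced source (zero moment) leaves no intracranial alpha. A common
  far-field term (rejected exactly by the bipolar derivation) and independent
  contact noise complete the model. Bipolar sign convention: deeper minus
  shallower contact.

Defaults represent rest conditions: 5 min at 1 kHz with 256 sensors, reduced
in tests to keep runtimes reasonable. What the generator does **not**
emulate: cortical folding and realistic anatomy, eye/muscle/stimulation
artifacts, 1/f background brain noise (sensor noise is white), nonstationary
alpha blocking, or a physiological LFP forward model (none is established for
this geometry; the 1/(1+d) falloff is this package's declared convention).
Passing tests therefore demonstrate internal consistency and recoverability
under the stated statistical structure, not performance on real recordings
with realistic geometry — the single spherical head is the largest such gap.

### The deep-source SNR knob

Nothing in the analysis fixes how strong a deep source is at the scalp, and
no such number is established; `deep_moment` is therefore an explicit free
parameter. The default (25 nAm against 60 nAm cortical sources) makes the
deep pair's scalp contribution realistically small — well below the cortical
alpha and near the sensor noise. The *adequate-SNR* condition used by the
pipeline-level checks sets `deep_moment = 240`, at which the deep pair's
scalp contribution is comparable to the cortical alpha; this is declared as
the study condition for parameter-recovery checks, chosen on the physical
ground that detectability requires the target signal to be a non-negligible
fraction of the scalp variance in its band, and kept fixed across all such
checks.

## Problem sizes in the test suite

Parameter-recovery checks run at 128 sensors, ~1500 solution points, 250 Hz
and 300 s with 10³ permutations over 20 seeds; calibration checks (family-
wise error under an independent reference) at 64 sensors, ~500 points, 120 s
and 500 permutations over 100 sessions; unit tests use 32-sensor, ~150-point
fixtures. These sizes are the package's chosen desk-scale regime: large
enough that the spatial statistics behave like the full-scale problem, small
enough to iterate on.

## Other conventions and limitations

- Sessions are persisted as plain TSV matrices + `.sfp` montage text + JSON
  sidecars (`write_session()`/`read_session()`); units are µV, with declared
  mV converted on read. No binary container format is required at this
  scale.
- The Welch estimator defaults to 2-s Hamming windows with 50% overlap; the
  alpha peak is picked from the posterior channel average for scalp data
  (per-channel override available) and per channel for intracranial data,
  each signal filtered around its own peak.
- The peak criterion (local maximum ≥ 3 dB above a log–log linear 1/f fit)
  is a declared convention; the prerequisite-peak principle names no
  threshold.
- Matrix results (recordings, lead fields, envelope fields) are matrix-based
  S3 objects; tabular results (PSDs, maps, reports, profiles) are tibbles
  with `tidy()`/`glance()`/`autoplot()` methods. This hybrid keeps the
  linear algebra idiomatic while making every reportable result
  pipe-friendly.
- Beamformers, dipole fits, orientation-constrained cortical surfaces,
  coherence/phase metrics, cross-frequency coupling and automated artifact
  rejection are out of scope.
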