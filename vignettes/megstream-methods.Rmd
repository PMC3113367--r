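---
title: "megstream: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{megstream: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package is

`megstream` is a self-contained simulation and re-implementation of a
real-time MEG streaming and neurofeedback chain: acquisition hardware is
replaced by a synthetic 306-channel Elekta-like array driven by simulated
cortical alpha sources; the transport layer is a FieldTrip-style real-time
buffer with its TCP wire protocol; and the analysis is the classic
precomputed-linear-inverse trick that makes source-level feedback feasible
at a 500-ms cadence. Everything runs from one seed, with no external data.

The package exists to make three things reproducible and testable:

1. **The streaming contract** — a buffer holding one header, a growing
   channels-by-samples matrix and an event list, written in DSP-like chunks
   (28 samples minimum) and read by any number of clients, with delays
   bounded by chunk arithmetic rather than hardware happenstance.
2. **The real-time source-imaging pipeline** — SSP denoising, an
   overlapping-sphere forward model, and a depth-weighted cortically
   constrained minimum-norm (WMNE) imaging kernel, precomputed once from a
   baseline run and applied to FFT coefficients every 500 ms.
3. **The evaluation methodology** — a discrete-event loopback delay
   measurement, and an online-versus-offline comparison with simulated
   head-displacement sweeps.

# The model chain

## Forward model

Head conduction is modeled by the overlapping-sphere analytic approach: one
conducting sphere per sensor site, least-squares fitted to the scalp points
with Gaussian weights (length scale 0.05 m) concentrated under that site.
The weighting scheme is an open choice in the overlapping-sphere literature;
Gaussian weights centered on the site position are this package's choice,
and a uniform weighting provably collapses to the single best-fit sphere.
The fit itself is the standard algebraic linearization (solve for center
and $r^2 - \|c\|^2$), which is exact for points sampled on a true sphere.

Within each sphere, the magnetic field of a current dipole has the Sarvas
closed form, which is independent of the radial conductivity profile and in
which radially oriented dipoles are exactly silent. Magnetometers read the
field component along the site normal at a single point (no coil-area
quadrature — a simulator-grade simplification); planar gradiometers are two
point evaluations 16.8 mm apart along the tangential measurement direction,
differenced and divided by the baseline, which matches the vendor's planar
geometry closely enough for a simulator and is documented as an
approximation. Units are SI throughout (m, T, T/m, A m); vendor-style
calibration coefficients exist only in the acquisition layer.

The test suite validates the closed form against an independent oracle
built from potential theory alone: outside the conductor
$B = -\mu_0 \nabla U$ with
$U(r) = \frac{1}{\mu_0}\int_0^\infty B_{rad}(r + s\,\hat r)\,ds$, where the
radial field component along the ray is given exactly by the
primary-current Biot–Savart term (volume currents in a spherically
symmetric conductor contribute no radial field).

## Inverse model

The imaging kernel is the standard depth-weighted minimum-norm estimate
with fixed ("cortically constrained") orientations:

- whiten channels by the per-channel noise SD and apply the SSP projector
  to the gain: $G' = \Sigma^{-1/2} P G$;
- diagonal source weights $w_j = \|g'_j\|^{-2\gamma}$, rescaled so
  $\mathrm{trace}(G' R G'^T)/n_{ch} = 1$;
- $\lambda^2 = 1/\mathrm{snr}^2$ and
  $K = R G'^T (G' R G'^T + \lambda^2 I)^{-1}$;
- rows restricted to the target ROIs and $\Sigma^{-1/2} P$ folded into the
  stored matrix, so $K$ applies to raw sensor vectors.

Defaults $\gamma = 0.5$ and $\mathrm{snr} = 3$ are the community-standard
values, stated openly as choices: the emulated study delegated the
estimator to an analysis toolbox whose exact 2011-era settings are not
recorded, so numerical agreement with that toolbox is not a goal. The noise
covariance is diagonal because the baseline run is only 10 s — far too
short to stabilize a full 306 × 306 covariance. A useful exact property of
this construction (and the form the usual "whitening consistency" check
takes here): rescaling the noise covariance by any factor leaves the folded
kernel, and hence every source estimate, unchanged.

SSP estimates the interference subspace as the top-k left singular vectors
of a channel-mean-removed interference-dominated segment; the projector
$P = I - UU^T$ is symmetric and idempotent by construction, and k = 2
matches the rank of the simulated interference.

## The real-time loop

Every 500 ms the newest 500-sample segment is pulled from the buffer,
rectangular-windowed and zero-padded to a 1000-point FFT (1-Hz bins), and
the kernel is applied to the Fourier coefficients. ROI alpha power is the
sum of the **magnitudes** (degree-1, not squared) of the source-level
coefficients over the 8–13 Hz bins (inclusive: 6 bins at 1-Hz spacing) and
all ROI sources. By FFT linearity this equals projecting to source time
series first and FFT-ing those — the order-of-operations identity is a
standing test — but the kernel-times-coefficients order makes the per-update
cost one small matrix product. In practice the package multiplies only the
in-band coefficient columns, which is algebraically the same restriction.

Zero-padding 500 samples to 1000 bins reconciles the 500-ms update with
1-Hz bin bookkeeping; whether the original system padded or used a 1-s
window is unknowable from the record, and padding is the choice adopted
here. Rectangular windowing, one-sided spectra and inclusive band edges are
likewise this package's documented choices.

Each run's first 20 s (40 segments, eyes open) freezes the Z-score
baseline; the remainder of the run is standardized against it. The
feedback gauge is indexed to inverse alpha power, `baselineMean / power`:
1 at baseline, rising as alpha falls, with the target at gauge ≥ 2 — i.e.
half-baseline power. The alternative reading (target at twice the baseline
display radius) cannot be excluded; the inverse-power definition itself is
unambiguous and is what the code computes.

# The synthetic paradigm and what it does (not) emulate

The schedule is a 10-s eyes-open baseline run followed by three 130-s
feedback runs tiled by alternating 20-s eyes-open/eyes-closed segments,
starting with the 20-s eyes-open reference window. 130 s is not a multiple
of 20 s, so the final segment of each run is truncated to 10 s; segment
tiling is otherwise exact.

Alpha generation: each ROI carries 5 latent processes of white noise
brick-wall band-passed to 8–13 Hz (zero-phase, FFT domain), and each dipole
mixes its ROI's latents with fixed non-negative unit-norm weights — alpha
is spatially coherent, so per-dipole independence would be unrealistic and
would also cancel excessively at the sensors. The parieto-occipital
envelope follows the paradigm state (eyes-closed amplitude divided by 3
when open, with a 200-ms raised-cosine transition, since alpha does not
switch instantaneously); prefrontal alpha is weak and state-independent,
which is what makes the PO/PFC dissociation a falsifiable prediction of
the pipeline rather than a built-in certainty.

Magnitudes are calibrated to the field's typical scales and then left
alone: per-dipole eyes-closed moments of 1.5 nA m (the ~500-dipole
semi-coherent patch then produces posterior sensor alpha of a few hundred
fT, the textbook scale of the eyes-closed rhythm), magnetometer noise of
~70 fT and gradiometer noise of ~5.6 pT/m per sample at 1 kHz (white
densities ~3 fT/√Hz and ~2.5 fT/cm/√Hz), and rank-2 environmental
interference of a few pT driven by < 2 Hz random drifts. The rank-2
interference model is deliberately idealized so that SSP with k = 2 has a
well-defined target; real interference is not exactly low-rank.

Not emulated: eye blinks and other biological artifacts, head movement
*within* a run, HPI coils, the vendor's SSS denoising (the offline arm
uses SSP too, so the online/offline denoising asymmetry of a real
installation is only partially represented), int16 DSP quantization
(streams are float32 end-to-end; calibration coefficients are carried as
metadata), and coil-area integration. Passing tests therefore demonstrate
the correctness and internal consistency of the chain under these
idealizations, not performance on real recordings.

# Numerical and engineering choices

- **Indexing**: 0-based global sample indices and half-open `[begin, end)`
  ranges uniformly across buffer, pipeline and recordings. The TCP wire
  format keeps FieldTrip's inclusive index pairs for interoperability and
  maps at the boundary.
- **Retention**: the buffer keeps the most recent 600 000 samples
  (10 min at 1 kHz) at block granularity — a block is evicted only when it
  lies entirely outside the window, so slightly more than the nominal
  capacity may be retained. Reads into evicted history raise an error
  distinct from reads past the write pointer.
- **Reset semantics**: installing a header discards samples and events and
  zeroes both counters; clients mid-read simply see the new emptiness.
  What happens to clients across a reset is unspecified upstream; this is
  the package's contract.
- **float32 quantization**: streams are rounded to float32-representable
  values once at synthesis, so float32 recordings are lossless mirrors of
  the buffer contents and replaying a recording is bit-identical to the
  live accelerated run.
- **Delay harness**: runs as a discrete-event simulation at sample
  resolution (sample *i* acquired during millisecond *i*; a chunk commits
  when its last sample arrives, plus a configurable transit and responder
  poll residual), so the distribution is exactly reproducible. With
  29-sample chunks at 1 kHz and 500-ms pulses the onset phase steps by
  500 mod 29 = 7 per pulse, which is coprime to 29, so all 29 residues are
  visited and delays take every value in [1, 29] ms — width 29 ms. The
  responder's sleep interval in the original hardware measurement is
  unrecorded; it is a free parameter here (default 0). A wall-clock
  pacing mode exists for demonstration; assertions use the
  discrete-event mode only.
- **RMS% definition**: `100 · ‖online − offline‖₂ / ‖offline‖₂` on the
  Z-scored series. The upstream definition of the denominator (and whether
  raw or Z-scored power was compared) is unrecorded; both are parameters,
  with these defaults.
- **Head movement** is simulated by rigidly transforming sources and scalp
  relative to a fixed sensor array; the sweep displaces along a
  posterior-superior axis over 0–12.5 mm, the range matching the maximum
  displacement observed in the emulated session.
- **Degenerate inputs**: coplanar scalp points, zero-variance channels,
  zero-SD baselines, zero segment power (gauge capped, with a warning),
  k ≥ n channels, chunks < 28 samples and ratio < 1 are all rejected with
  classed conditions (`megstreamProtocolError`, `megstreamConfigError`,
  `megstreamDomainError`, `megstreamNotAvailableError`,
  `megstreamEvictedError`).

# Problem sizes

The full demonstration (`runDemo()`) runs the complete study conditions:
306 + 3 channels at 1 kHz, 750 dipoles, a 10-s baseline run and three
130-s feedback runs (260 segments per ROI per run), 29-sample streaming
chunks, and a six-point displacement sweep; it completes in a few minutes
on one CPU in accelerated mode. Unit tests use shorter schedules and toy
kernels; spectral-estimation tests use one- to two-minute single-run
schedules, which keeps band-power estimates within their stated
tolerances.

# Known limitations

- The acquisition chain is a simulator; no FIF/vendor file I/O exists.
- The TCP server is sequential (one client at a time); concurrent
  multi-client service would need multiple R processes sharing recordings
  or an external FieldTrip buffer daemon.
- The hardware headline numbers of the original deployment (44 ± 17 ms
  access delay; ~100 ms kernel application in an interpreted environment)
  bundle hardware transit and sleep times and are intentionally not
  reproduction targets; the deterministic chunk-arithmetic quantities are.
- Single-subject effect sizes (RMS error percentages of the original
  session) depend on that subject's head movements and are likewise not
  targets; only their qualitative structure (collapse at 0 mm, growth with
  displacement) is asserted.

```{r example}
library(megstream)
demo <- runDemo(runConfig(seed = 1), outDir = "demo-out")
demo$kernel          # 750 x 306 imaging kernel
demo$delay           # measured vs theoretical vs reference delays
demo$sweep           # RMS% vs head displacement
```
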