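---
title: "Streaming calcium-imaging analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Streaming calcium-imaging analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`calstream` is a headless engine for analysing two-photon calcium-imaging
movies while they are being acquired: it follows a raw-binary or TIF frame
stream, registers each frame, extracts per-cell fluorescence, converts it to
ΔF/F₀, and layers multi-timescale downstream analyses (functional networks,
spiking synchrony, auditory tuning) plus Gerchberg–Saxton hologram
computation for photostimulation targeting. This vignette explains the
models, the tunable parameters, the synthetic-data generator used to
validate everything, and the design decisions that were genuinely open.

## Frame streams

Frames arrive as headerless little-endian 16-bit raw binaries (unsigned, or
signed with conversion to the unsigned range), or as grayscale TIF stacks.
Geometry (height, width) and frame rate come from the configuration, never
from vendor metadata, which keeps the reader independent of acquisition
software. In live mode the reader polls the growing file and yields a frame
only once all of its bytes exist — frame completeness is simply
`file size >= (index + 1) * height * width * 2`, which matches sequential
appends; a truncated final frame ends the stream cleanly before it.

Signed samples are clamped at zero by default (`convert_signed`): negative
values are photomultiplier offsets below the dark level and carry no
signal. A fixed-offset mode (+32768) is available in the stream
configuration for rigs where the offset matters; the map is monotone either
way, and ΔF/F₀ is unaffected by any common gain.

## Registration

Each frame is registered against a fixed template — the pixelwise mean of
the initial batch (default 30 frames), i.e. the same average image a user
identifies cells on. Drift is estimated by discrete-Fourier-transform
cross-correlation with single-step upsampled refinement: the integer peak
comes from the full-frame cross-correlation, then the correlation surface
is re-evaluated on a `1/upsample`-pixel grid around that peak with a small
matrix-multiply DFT. The default `upsample = 10` gives 0.1 px precision at
negligible cost. Estimates beyond `max_shift` (default 20 px) are clamped
and flagged rather than applied, so one bad frame cannot corrupt the
traces. Correction translates by the negated estimate via a Fourier phase
shift; border pixels that would wrap are filled with the frame median,
which is neutral for the sliding ΔF/F₀ baseline. The template is never
refreshed during a session: a drifting template would silently redefine
every ROI, and sessions long enough to outgrow one template deserve an
explicit re-identification step instead.

## ROIs and fluorescence

Somata are ring-shaped ROIs: pixels whose centre lies between `r_inner`
(default 2 px) and `r_outer` (default 6 px) of the clicked cell centre,
Euclidean distance, bounds inclusive. At the default field scale of
370/512 ≈ 0.72 µm/px this ring sits over the soma shell where the
cytoplasmic indicator lives. Pixels claimed by two or more rings are
excluded from all of them (closely juxtaposed neurons); a cell whose ring
empties is flagged inactive. The neuropil mask is the annulus from one
pixel beyond the soma ring to 15 µm, minus every somatic pixel of every
cell — including pixels that the overlap rule removed from the rings,
because those are still somatic and must not masquerade as neuropil.

Per frame, `F_soma` and `F_NP` are plain means over the two masks, and the
corrected fluorescence is `F = F_soma − α·F_NP` with `α = 0.7` by default
(adjustable). The baseline `F₀` is computed over the trailing 10 s window
of `F` (including the current sample) as the mean of samples strictly below
the window's 50th percentile; a constant window falls back to the window
median, which also makes the very first sample's baseline equal itself so
the stream can start without a warm-up. The percentile is the
linear-interpolation median; the baseline runs on the corrected series `F`
rather than `F_soma` so that numerator and denominator of
`ΔF/F₀ = (F − F₀)/F₀` describe the same signal. Missing samples (empty
masks, failed extraction) are excluded from baseline windows, and a
non-positive `F₀` records ΔF/F₀ as missing rather than fabricating a value.

## Functional networks and ranking

Pairwise Pearson correlations of ΔF/F₀ are computed over a cumulative
window by default (a sliding window is available for long sessions where
the network itself evolves), withheld entirely when fewer than
`min_samples = 30` frames exist. Two prunings are offered. The minimum
spanning tree uses edge weight `1 − |ρ|`, so its N−1 edges link the most
correlated neurons while keeping every neuron in one component; Kruskal's
algorithm with edges pre-sorted by (weight, smaller id, larger id) makes
ties deterministic. Undefined correlations (flat traces) enter at weight 1
and therefore connect last; in thresholded networks (`|ρ| ≥ θ`) they never
form edges. Degree in the pruned network ranks the neurons — ties break
toward the lower id — and the top five are the automatic display and
stimulation candidates. Ranking stability across successive updates is
reported as top-10 set turnover (percent of the top-10 set replaced between
adjacent updates, averaged), with a positional variant logged alongside
since "percent change of the top ranks" admits both readings.

## Synchrony

Every 30 s the ΔF/F₀ matrix is deconvolved and tested for enhanced or
suppressed coincident spiking of orders k = 2–4. Deconvolution is a
deliberately small AR(1)-innovation method: calcium decays approximately as
`c_t = γ·c_{t−1}` between events (γ set by a 1.5 s indicator time constant
at the stream frame rate), so innovations `c_t − γ·c_{t−1}` concentrate at
spike times, and spikes are innovations above 3 robust (MAD-based) noise
standard deviations. The synchrony statistic counts bins where at least k
cells spike and compares it against a null built from independent circular
shifts of each cell's spike train (200 surrogates by default, seeded),
which preserves every cell's rate and autostructure while destroying
alignment; counts above the upper `1 − α/2` surrogate quantile read
"enhanced", below the lower `α/2` quantile "suppressed" (α = 0.05). This
surrogate test is a documented stand-in with the same report semantics as
the Markov point-process synchrony framework it replaces — that framework
is not reproduced here — and it is isolated behind `synchrony_test()` so a
different statistic can be dropped in.

## Auditory tuning

A stimulus schedule (onset, duration, frequency, level) is folded into the
trace stream as trials complete. A trial's response is the mean ΔF/F₀ over
the presentation window — deliberately without pre-stimulus subtraction,
matching the plain definition of the receptive field as the mean response
per (frequency, level) over repeats; a config option adds baseline
subtraction for users who want it. Events shorter than one frame keep the
frame covering their onset. Best frequency is the frequency of the maximal
receptive-field entry at any sound level, ties broken toward the lower
frequency. The canonical grid is the eight-step half-octave ladder from
4 kHz (4 … 45.3 kHz) at 50/60/70 dB with 10 repeats: 24 cells of the
receptive field, each with 10 trials after a full session.

## Holography

The virtual SLM is a phase-only plane related to the focal plane by a
unitary discrete Fourier transform (the single-lens far-field relation that
relay optics reduce to for mask computation), with the focal DC at the grid
centre. Targets are disk beamlets (uniform amplitude, radius in pixels) or
optical vortices: a thin ring of radius `r0·√|L|` carrying spiral phase
`exp(iLθ)`. The mode-to-size relation is a documented heuristic — a vortex
ring's area grows with |L|, and the exact optics are not published — with
`r0 = 3` px by default. The vortex template also claims its dark interior
as part of the constraint region, so the central null is enforced by the
algorithm, not left to chance. Gerchberg–Saxton iterations (default 30,
seeded random initial phase) alternate between unit amplitude at the SLM
plane and the target complex amplitude on its support at the focal plane,
leaving off-support pixels free; the focal residual is non-increasing and
is recorded per iteration. FOV→SLM coordinates go through an affine
calibration (identity by default, or fitted from a ≥3-point correspondence
file). Sequential stimulation precomputes one mask per target with
deterministic per-target seeds and a dwell of `1/rate`. Laser-power values
are metadata echoed in stimulation records and never used in computation.

## The real-time loop

"Real time" is modelled as stream time (frame index / frame rate), not
wall clock, so a replayed movie and a live session produce byte-identical
event logs and every session is reproducible. The loop runs traces every
frame, indicator records at 2 Hz, network/ranking updates at 1 Hz,
synchrony every 30 s, and receptive-field updates on trial completion; a
failed downstream stage becomes a warning record and never interrupts
trace extraction. The watch-group trigger fires when the mean current
ΔF/F₀ of a named cell group crosses a threshold, with a 3 s refractory
period, and records a (virtual) stimulation event.

## The synthetic-data generator

The generator is first-class, tested code: it is the package's ground
truth. The canonical demo session is a 256 × 256 px, 30 Hz, 120 s movie
with 60 non-overlapping ring somata (baseline 1000 counts over a
100-count offset), a smooth neuropil field (300 counts) carrying 30% of
the population-mean transient, Gaussian noise at 2% of soma baseline,
GCaMP-like difference-of-exponentials kernels (0.05 s rise, 1.5 s decay),
and a slow linear drift that begins after the template batch.

Spiking has three components. (1) Background: independent Poisson at
0.15 Hz per cell. (2) Population events at 1.5 Hz with graded coupling:
the five designated "group" cells join each event with probability 0.8,
every other cell with a per-cell probability drawn uniformly from
[0, 0.3]. The gradient matters: cortical populations show exactly this
graded coupling to population events, and it is what makes degree in a
minimum spanning tree a meaningful hub statistic — if only five cells
carried the latent drive and the rest were silent bystanders, background
cells would attach to arbitrary partners and no ranking method could
systematically surface the driven cells. (3) Tone responses: per trial a
reliability gate (0.9 at 70 dB, scaled with level) times a Poisson spike
count with mean `3 · exp(−log2(f/BF)²/(2·0.4²))` — amplitude-tuned
responses with sub-octave Gaussian tuning in log-frequency, the standard
receptive-field model for primary auditory cortex. Best frequencies cycle
deterministically through the tone ladder so every frequency is
represented.

Because tone-evoked responses superimpose a second correlation structure
(cells with similar best frequencies co-respond), the network-recovery
validation uses a spontaneous session (`response_amp_spikes = 0`) and the
tuning validation uses tone sessions — the same separation an experimenter
makes between a passive block used to characterise correlations and a
stimulus block used for tuning.

What the generator does **not** emulate: photon shot noise (noise is
Gaussian, not Poisson-scaled), optical point-spread blur and scattering,
z-drift, bleaching, and somatic signals that overlap in depth. Passing
tests therefore demonstrate the correctness of the analysis chain under a
faithful geometric and statistical model, not robustness to every optical
artefact of a real microscope.

## Problem sizes in the validation suite

The test suite validates at desk scale, chosen so the full suite runs on a
single CPU in well under half an hour: the demo movie is 256 × 256 px ×
120 s (one full render and pipeline pass), the cadence and live-mode
contracts run on a 64 × 64 px, 10-cell, 120 s session, MST minimality is
enumerated exhaustively for up to 7 nodes (all n^(n−2) Prüfer trees, 200
seeds), synchrony calibration uses 100 null simulations × 200 surrogates,
best-frequency recovery uses 50 trace-level tone sessions with the full
240-trial schedule, and holography runs at the 512 × 512 virtual-SLM
default (the full 1536 × 1536 SLM is supported by configuration).

## Known limitations

- The AR(1)-innovation deconvolution is a lightweight stand-in for a full
  sparse-deconvolution solver; it is accurate for isolated transients and
  conservative for dense firing.
- The synchrony verdict is a surrogate-quantile test, not the Markov
  point-process framework it emulates; its semantics (per-order
  enhanced/suppressed at 30 s cadence) are identical but its statistic is
  not.
- Trace export is CSV (wide, incremental); no HDF5 container is written.
- Registration is rigid x–y only; non-rigid motion and z-drift are out of
  scope.
- The holography module computes and simulates masks against a virtual
  SLM; no hardware I/O of any kind is performed.
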