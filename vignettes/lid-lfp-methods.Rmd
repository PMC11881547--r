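---
title: "Methods: spectral, phase-coupling and behavioral analysis of dyskinesia recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral, phase-coupling and behavioral analysis of dyskinesia recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`lidlfp` analyzes multichannel local field potential (LFP) recordings and
pose-tracked behavior from the unilateral 6-OHDA hemiparkinsonian rat model
under levodopa, where levodopa-induced dyskinesia (LID) is accompanied by
narrowband gamma oscillations (NBG, ~65-110 Hz) in sensorimotor structures of
the lesioned hemisphere. The package implements five analysis stages and a
synthetic-data generator that emulates the statistical structure each stage
assumes, with full ground truth, so every stage can be validated end to end
without access to in-vivo recordings.

The stages are:

1. **Normalized spectra** (`lfp_spectra()`): within-structure bipolar LFPs,
   single-taper Hanning spectrograms (8-s windows, 50% overlap, 0-300 Hz,
   0.5-Hz output grid), and separation of oscillatory from aperiodic power
   by irregular resampling (IRASA).
2. **NBG detection** (`track_nbg()`): a five-parameter peak model
   $y(f) = A\,e^{-((f-B)/C)^2} + Df + E$ fitted per window to the
   structure-averaged normalized spectrum, with the printed detection
   thresholds ($R^2 > 0.2$, $2 < A < 100$ dB, $1 < C < 20$ Hz, $-1 < D < 1$,
   $-10 < E < 10$, and $B$ inside a band class).
3. **Phase coupling** (`kappa_matrix()`): instantaneous Hilbert phases of
   monopolar wires bandpassed ±5 Hz around the session median NBG
   frequency; the functional-connectivity readout for a structure pair is
   the median von Mises concentration $\kappa$ of wire-pair phase
   differences ($\sigma^2 \approx 1/\kappa$).
4. **Behavior** (`detect_rotations()`, `global_aims()`): complete rotations
   from the heading angle passing monotonically through eight 45°
   sectors, binned per 10 min; global AIMs (ALO) scores as
   severity × amplitude summed over the axial/limb/orolingual subtypes.
5. **Brain states** (`state_spectrum()`, `treatment_similarity()`):
   per-electrode 4-s-window fractal-normalized spectra over 1-200 Hz,
   averaged per structure and period, compared across treatments by Pearson
   correlation.

# Numerical choices

**Spectral estimation.** Spectrograms use a single Hanning taper per 8-s
window (0.125-Hz native resolution). The stated 0.5-Hz resolution is met by
averaging four adjacent native bins in linear power, which keeps the 8-s
windows while reporting on the 0.5-Hz grid. PSDs are one-sided and
taper-corrected so that total windowed power matches the time-domain
variance (Parseval), which the tests assert to 1%.

**IRASA.** For resampling factors $h \in \{1.10, 1.15, \dots, 1.90\}$ (the
method's published set, configurable) each window is band-limited-resampled
(Fourier truncation/zero-padding, lengths rounded up to 5-smooth integers
for fast transforms) by $h$ and $1/h$; the aperiodic (fractal) spectrum is
the median across $h$ of $\sqrt{P_h \cdot P_{1/h}}$. Per-factor PSDs are
averaged across windows *before* the geometric mean and median: medians of
raw periodograms are biased low by spectral noise, and this ordering removes
that bias. The normalized spectrum is reported as
$\mathrm{dB}_{fractal} = 10\log_{10} P_{total} - 10\log_{10} P_{fractal}$,
which is exactly invariant to a constant gain. For full sessions the
fractal spectrum of each electrode pair is estimated from 12 evenly spaced
windows (the aperiodic background is treated as stationary at the session
scale; the per-window total spectra are normalized against this session
fractal). Brain-state analysis instead normalizes every 4-s window by its
own single-window IRASA estimate, since those windows are the unit of
comparison; the extra per-window noise averages out over windows and sites.

**Peak fitting.** The model is linear in $(A, D, E)$ given $(B, C)$, so the
fit uses variable projection: bounded L-BFGS-B over $(B, C)$ with the
linear part solved exactly at each step. Gaussian-peak objectives are
multimodal, so fits run from five starts (the spectral argmax plus a grid
across the band) and stop early only when a start already explains 98% of
the variance. Optimizer failure yields an undetectable fit with a
diagnostic rather than an error. Detection thresholds are strict
inequalities, exactly as printed, and the 65-110 Hz NBG band is kept as a
class of its own alongside the printed gamma (30-70 Hz) and HFO
(115-170 Hz) classes — the two band definitions genuinely differ in the
source method and are not reconciled here.

**Detection rate.** The model is fitted once per 8-s analysis window on the
structure-averaged normalized spectrum, and the detection rate is the
fraction of windows with a positive detection. A per-window definition is
the only one under which a rate exists; the session median of the fitted
$B$ over detected windows defines the peak frequency used for the 20-Hz
band-power band and the phase-analysis center.

**Phase analysis.** The ±5 Hz bandpass is an order-64 FIR (65 taps,
Hamming-windowed least-squares design) applied forwards and backwards, so
group delay is zero and no phase-difference bias is introduced (tested to
0.01 rad). Phase analysis uses monopolar wires, unlike the bipolar spectral
chain: bipolar differencing of two tightly coupled wires would cancel the
very oscillation whose phase is being measured. Phase samples are decimated
to 10-ms spacing before fitting; concentration estimates on densely
autocorrelated samples would otherwise be inflated. $\kappa$ is estimated
from the mean resultant length $\bar R$ by the classical piecewise
approximation and capped at 1000 for degenerate samples so medians and
difference maps stay finite. Fewer than 10 usable samples yields an
undefined fit. The pipeline centers the band on the session-level median NBG
frequency (the median of the fitted peak frequency over all detected windows
of the recording), so every wire is filtered once; `kappa_matrix()` also
accepts per-structure centers, in which case a pair whose structures
disagree is filtered at the mean of the two centers (rounded to 0.5 Hz so
filtered phases can be cached per wire).

The 65-tap filter is deliberately short and therefore spectrally broad:
its measured response is only −6 dB at ±20 Hz, reaching 20 dB rejection
around ±40 Hz. Two consequences matter for interpretation. First, some
aperiodic background inevitably passes the filter, so instantaneous phases
are noise-perturbed wherever the oscillation's analytic amplitude dips —
and since a band-limited Gaussian oscillation fades like a Rayleigh
process, these dips dominate the decoherence of concentration estimates:
$\hat\kappa$ is attenuated below the generating concentration even at high
average SNR. `structure_pair_kappa()` therefore supports an optional
amplitude gate (`amp_gate`) that drops phase samples below a joint
analytic-amplitude quantile; the default keeps all samples in the analysis
window, and the generator-recovery tests enable a 0.25 gate so they
measure the estimator rather than the fading floor. Second, treatment
contrasts (kappa difference maps) are robust to the attenuation because it
applies to both conditions.

**Rotation detection.** Sector 0 is centered on angle 0, and a 5°
hysteresis at sector boundaries suppresses jitter-induced transitions;
both choices are free parameters of the method (the source procedure does
not state a jitter policy) and are configurable. A reversal resets the
accumulation, so incomplete arcs are never counted; multi-sector jumps in
one frame are treated as sequential steps. Counter-clockwise rotations (in
image coordinates with y up) map to "contralateral" for a right-hemisphere
lesion; the lesion side must be given explicitly. Coordinates are smoothed
by a zero-phase 4th-order Butterworth low-pass at 5 Hz with odd-reflection
padding against startup transients; frames below 0.6 tracking likelihood
are interpolated before smoothing.

**Reporting windows.** Peak-dose (40-80 min) and late (120-160 min)
windows after levodopa injection are the canonical reporting periods; for
sessions shorter than 180 min the pipeline scales both windows
proportionally, so desk-scale sessions exercise the same code paths.

# The synthetic-data generator

`generate_session()` emulates what the analysis assumes about real
recordings:

* **Aperiodic background**: per wire, independent $1/f^\chi$ noise from
  spectral shaping of white noise (amplitude $\propto f^{-\chi/2}$, random
  phases), exact in expectation; $\chi = 2$ by default. Backgrounds are
  normalized to unit variance in the $\geq 1$ Hz analysis band — a
  total-variance normalization would let the sub-1-Hz drift dominate for
  steep exponents, making "oscillation amplitude relative to background"
  mean very different in-band signal-to-noise ratios at different session
  lengths.
* **Narrowband oscillations**: band-limited Gaussian noise (a complex
  baseband with a Gaussian band profile whose full width at half maximum
  is the nominal bandwidth, times a carrier), not pure sinusoids, so peak
  width is a meaningful recovery target. Schedules are gated with 100-ms
  raised-cosine ramps; the carrier frequency may drift linearly. The
  default session carries a drug-gated 80-Hz NBG (6-Hz bandwidth,
  amplitude 0.8 background SDs) in M1/dStr/thal, an always-on 85-Hz limbic
  oscillation in dHipp/vHipp/OFC, and an always-on 7-Hz theta — mirroring
  the empirical pattern that sensorimotor NBG is drug-locked while similar
  limbic-band oscillations are not.
* **Phase coupling**: wires sharing an oscillation receive smooth
  (2-Hz-bandlimited) Gaussian phase jitter $\psi_w(t)$. For Gaussian
  $\psi$, $|E\,e^{i\psi}| = e^{-\sigma^2/2}$ exactly, so the wire-pair
  difference has mean resultant length $e^{-\sigma_w^2}$; setting
  $\sigma_w^2 = -\log(I_1(\kappa)/I_0(\kappa))$ makes the
  resultant-length-based $\kappa$ estimator recover the target
  concentration by construction (the marginal is wrapped-normal rather
  than von Mises, which matters to neither the estimator nor the
  downstream contrasts). Each wire also gets a log-normal coupling gain
  (SD 0.3 on the log scale): without wire-to-wire gain differences, tight
  phase coupling would make bipolar differencing cancel the oscillation
  almost completely, which real electrode pairs do not do.
* **Drug response**: a piecewise-linear envelope (onset 20-40 min, plateau
  40-80 min, decay to 120 min for the canonical 180-min course, scaled
  proportionally for shorter sessions) gates or amplitude-modulates
  oscillations and drives the AIMs schedule, so NBG epochs and AIMs are
  correlated as in the modeled condition.
* **Behavior**: heading-angle paths with exactly the requested number of
  complete rotations, optional 7/8-turn arcs with reversals that a correct
  detector must discard (their sweep direction is fixed so that arc plus
  reversal can never concatenate into a monotone 8-sector passage), and
  AIMs schedules on the 0/1/2/2.5 × 1-4 scales with mild seeded rater
  jitter. The video frame rate defaults to 30 Hz.

The default test-scale session is 11 structures × 4 wires × 30 min at
2000 Hz (with `long = TRUE` for the 180-min course). What the generator
does *not* emulate: spikes and unit activity, volume conduction across
structures, line noise and movement artifacts, non-stationary aperiodic
exponents, and rater disagreement beyond the simple jitter. Passing tests
therefore demonstrate correctness of the analysis chain under its own
assumptions, not robustness to every artifact of in-vivo data.

Where a realistic value was not dictated by the modeled study, it was
chosen once on field-typical grounds: oscillation amplitudes of 0.4-1.2
band-referenced background SDs give normalized peaks of roughly 8-20 dB
(comfortably detectable but far from the 100-dB ceiling); the 2-Hz
phase-jitter bandwidth sits well inside the ±5 Hz analysis band so the
generated concentration survives filtering; the NBG source has no
published SNR, so amplitude stays a free parameter — coupling-recovery
tests use strong oscillations (2.5 background SDs) so the concentration
readout is not confounded by background phase noise.

# Problem sizes and determinism

Simulation-based tests run at desk scale by choice: coupled-structure
sessions of 1-8 min with 2 wires per structure, brain-state sessions of
40 s, and one full default session for the end-to-end determinism check.
All randomness flows through explicit integer seeds (`local` RNG scope, so
library calls never perturb the caller's RNG state), and identical seed
plus configuration reproduces recordings, reports and report hashes
bit-identically. The report hash is an MD5 over the serialized stage
outputs.

# Known limitations

* The aperiodic exponent is constant per structure and session; drifting
  backgrounds would require per-window fractal fits (supported for the
  brain-state chain only).
* One peak per band per window: overlapping oscillations inside one band
  are fitted as a single Gaussian, as the model implies.
* Phase-sample gating by detected NBG episodes is optional and off by
  default (all samples in the analysis window are used); with very sparse
  oscillation epochs the kappa estimate mixes in phase noise from
  oscillation-free stretches.
* The rank-based annotations accompanying kappa difference maps and
  treatment similarity are reporting plumbing, not a full inferential
  framework (mixed-effects modeling of behavior is out of scope).
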