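---
title: "Models and methods: simulating and analysing fNIRS neurofeedback training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating and analysing fNIRS neurofeedback training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfnirs)
```

# The problem

Neurofeedback training for music performance anxiety alternates short
anxiety-induction segments with longer self-regulation segments while a
prefrontal fNIRS signal is displayed back to the participant. The
scientific readout is a per-epoch *signal energy ratio*: after
preprocessing, the hemodynamic series is cut into 15-s epochs at event
onsets, each epoch's energy $E=\sum_n |x(n)|^2$ is divided by the mean
epoch energy of its session, and the across-session trajectory of the
control-condition mean ratio is read as a learning curve. This package
implements that full chain, plus a forward simulator with known ground
truth, so every stage is verifiable without access to human recordings.

# Protocol model

A session is laid out on a common clock: baseline (180 s),
contextualisation (60 s), then `n_blocks` = 5 blocks of 180 s. Each block
starts with a 30-s induction segment (one induction prompt at the block
start) followed by 150 s of regulation with prompts every 30 s. We place
the first regulation prompt at the end of the induction segment and
subsequent prompts every 30 s up to, but excluding, the block end. This
reading yields 5 induction + 25 regulation prompts per session, so the
printed pools — 40 induction and 200 control phrases — are exhausted
*exactly* by the 8-session programme, which we take as strong evidence for
the cadence. Stimulus assignment is sampling without replacement from
each pool with a seeded generator, stratified per session: "controlled
randomization" is thus made concrete as *no phrase ever repeats within a
programme*, which removes habituation by construction and makes the
schedule a pure function of the seed.

Two open points were resolved as follows. One induction prompt marks each
30-s induction segment (the prompts are short verbal phrases; one per
segment matches the pool arithmetic, which would break under repetition).
Contextualisation scenarios are mapped to sessions by linear
interpolation over the ranked 19-item exposure hierarchy (lowest rank at
session 1, highest at the final session), so anxiety rank is monotone
across the programme and a compact 4-session variant spreads evenly; ties
in the hierarchy are broken by input order (stable sort).

# Forward model

**Hemodynamics.** The neural drive is a piecewise-constant design:
induction segments at gain 1, regulation segments at gain 0.6, rest at 0.
It is convolved with a canonical double-gamma HRF (peak 6 s, undershoot
16 s, undershoot ratio 1/6). Two numerical choices matter. The gammas are
mode-parameterised (shape $=1+\text{delay}/\text{dispersion}$) so the
kernel's argmax falls on the stated peak delay rather than one dispersion
earlier. The convolution is normalised to unit DC gain, so a sustained
unit drive produces a plateau of exactly the `amplitude` parameter —
amplitudes are then in concentration units (default 2 µM, a plausible
prefrontal task-evoked HbO response; deoxyhemoglobin is coupled as
$\Delta\mathrm{HbR} = -\tfrac13\,\Delta\mathrm{HbO}$).

**Learning profile.** Session-wise multipliers scale the
*regulation-condition component of the drive only*. This is deliberate: a
whole-channel multiplier would be annihilated by RMS normalisation and by
the within-session ratio normalisation, leaving no recoverable trend.
Defaults embed the design target the analysis must recover: multipliers
(1, 1.5, 2.0, 2.05) for S3-D2, S3-D5 and S5-D4 (rise to session 3, then a
+2.5% step — below the 5% plateau tolerance) and (1, 1.4, 1.8, 2.3) for
S5-D5 (rising throughout).

**Optics and noise.** Concentrations map to optical density through the
modified Beer–Lambert law,
$\Delta OD(\lambda)=\big(\varepsilon_{HbO}(\lambda)\Delta HbO+
\varepsilon_{HbR}(\lambda)\Delta HbR\big)\,L\,\mathrm{DPF}(\lambda)$,
with per-channel separations (30–35 mm) and DPF 7.25/6.38. Intensity is
$I(t)=I_0\,10^{-(OD_{clean}+OD_{noise})}$, strictly positive by
construction. $OD_{noise}$ holds sinusoids at 1.1 Hz (cardiac), 0.25 Hz
(respiratory) and 0.1 Hz (Mayer) with amplitudes 0.004/0.006/0.008 OD and
phases shared across wavelengths (physiology is common to both), a linear
drift of 2×10⁻⁵ OD/s, white noise (σ = 0.002 OD) independent per
wavelength, and Poisson-timed motion spikes (0.5/min, 0.05 OD,
2-s exponential decay) exercising the wavelet stage. All sub-seeds derive
deterministically from one top-level seed, so partial reruns agree with
full runs.

What the generator does *not* emulate: photon-transport anatomy,
scalp/systemic compartments, short-separation channels, serially
correlated (1/f) physiological noise, or inter-subject variability.
Passing the recovery suite therefore shows the chain is correct and
sensitive under these conditions — not that real adolescent recordings
would yield the same curves.

# Preprocessing chain

Stages run in a fixed order: crop → FIR bandpass → wavelet denoise →
optical density → Beer–Lambert inversion → demean + RMS normalise.

* **FIR bandpass.** Windowed-sinc design, order 1000 read as 1001
  symmetric taps (standard convention), Blackman window, 0.01–0.1 Hz.
  Zero phase is realised as forward–backward application with odd
  reflection padding; attenuation is effectively squared. Stopband
  rejection at 1 Hz exceeds 40 dB by a wide margin.
* **Wavelet denoising.** A Symlet-4 *maximal-overlap* DWT (MODWT) with
  circular boundary, 10 levels; details D1–D5 are zeroed before inverse
  transform. The MODWT was chosen over a decimated DWT with symmetric
  padding because it is shift-invariant, preserves length exactly for any
  $N$, and reconstructs untouched coefficients to machine precision at
  arbitrary lengths. At 10.2 Hz, D1–D5 span ≈0.16–5.1 Hz, so their
  removal complements the bandpass. One property is knowingly different
  from an orthogonal DWT: band-zeroing in a redundant transform is not a
  projection, so denoising is not idempotent on arbitrary signals
  (exactly low-pass content, e.g. a constant, is preserved to 1e-10). If
  a series is too short for 10 levels, the level count is reduced with a
  warning, never silently.
* **Optical density after filtering.** The stated order filters
  *intensity* before OD conversion, which removes the DC reference the
  log ratio needs. We therefore store each channel's pre-filter mean and
  reintroduce it inside the log:
  $\Delta OD = -\log_{10}\!\big((x_{filt}+\bar I)/\bar I\big)$. This
  keeps the log defined, makes the chain exactly invariant to
  multiplicative intensity rescaling, and reduces to the usual definition
  for unfiltered input. Samples driving the argument non-positive are
  clipped at $10^{-6}\bar I$ and counted in QC.
* **Beer–Lambert inversion.** A per-sample 2×2 solve. The printed HbO
  extinction pair (645.5, 1669.0) has no stated unit system; HbR defaults
  (1548.5, 691.3) come from the standard compiled absorption tables and
  are configurable. The condition number of the matrix is stored with the
  parameters. Unit ambiguity is immaterial downstream: RMS normalisation
  makes the energy ratio invariant to any consistent rescaling — for the
  same reason, absolute concentrations are not reported.
* **Normalisation.** Per channel: subtract the mean, divide by RMS;
  output contracts $|\bar x|\le 10^{-9}$, $|\mathrm{RMS}-1|\le 10^{-9}$.
  Constant channels raise a degenerate-channel error and are flagged.

A consequence worth stating: the 0.01 Hz high-pass edge sits *above* the
block-design fundamental (1/180 s ≈ 0.0056 Hz), so even noise-free
recovery of the raw ground truth is imperfect (r ≈ 0.93); against the
band-limited ground truth the chain is exact (r > 0.999). All spectral
tests are therefore relative, never absolute unity.

# Energy-ratio analysis

Epochs are 15 s (153 samples at 10.2 Hz) from event onsets; stressor
epochs at induction prompts, control epochs at each regulation prompt
(5 per block). Epochs running past the recording end are discarded and
counted. The ratio denominator is the mean epoch energy over *all*
epochs of the same channel × chromophore × session (both conditions
pooled) — the wording "epoch to mean energy ratio" does not name the
pool, and pooling yields the exact invariant that every group's mean
ratio is 1, making the ratio a within-session relative measure. Per-
condition denominators remain available via an argument. HbO is the
default analysis chromophore; HbR is computed and reported in parallel.

Trend classification labels each session-over-session increment up /
flat / down against a plateau tolerance δ = 5% of the previous mean:
all-up is `rising_throughout`, all-flat is `flat`, ups followed only by
flats (no downs) is `rising_then_plateau`, anything else `other`. The
rule is an explicit, testable stand-in for a verbal description; δ is an
argument.

# Closed-loop feedback

The online path is causal by necessity: a second-order Butterworth
bandpass at 0.01–0.3 Hz (the online band of commercial neurofeedback
software; the band is a *pass* band — we read the curious phrase
"stopband of 0.01 to 0.3 Hz" as the hemodynamic passband it plainly
isolates) with explicit filter state, so streaming chunks reproduce
one-shot filtering bit-for-bit. The thermometer maps the
baseline-referenced ROI value linearly in z-units over ±2σ onto integer
levels (baseline mean → middle level, clipped at the ends). A responder
maps displayed level to the next interval's regulation gain; a
constant-gain responder makes the loop collapse exactly to an open-loop
run, and a positive-learning responder accumulates gain across sessions.

# Problem sizes and reproducibility

The test and acceptance runs use sessions at full length (1140 s ×
10.2 Hz = 11628 samples) but restrict montages to the 2–4 channels under
study, and use 20-seed ensembles of 4-session programmes for the
parameter-recovery checks; these sizes give stable majorities while
keeping a full run in minutes on one CPU. Every stochastic quantity
derives from a single integer seed through a documented integer map, and
`run_all()` manifests are hash-identical across reruns of the same
configuration.

# Known limitations

* No SNIRF interchange: the supported on-disk dialect is wide CSV plus a
  JSON sidecar (and BIDS-style events.tsv).
* The responder model is a two-parameter caricature of learning; it is
  meant to exercise the loop, not to model behaviour.
* Montage geometry is nominal (labels and separations only); region
  labels are opaque annotations and no anatomical claims attach to them.
* The recovery suite's majorities are properties of the generator's
  declared noise conditions; they are not estimates of human effect
  sizes.
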