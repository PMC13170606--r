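# nfnirs

Simulation and energy-ratio analysis of fNIRS neurofeedback training
programmes for music performance anxiety (MPA) self-regulation.

Block-design neurofeedback protocols for MPA train adolescents to
down-regulate performance anxiety while prefrontal hemodynamics are
monitored with functional near-infrared spectroscopy (fNIRS) and fed back
as a visual thermometer. Because raw recordings from such studies are
rarely deposited, every stage here is testable against a forward simulator
with known ground truth. The package provides, end to end:

* **Protocol scheduling** — sessions of 3 min baseline + 1 min
  contextualisation + 15 min active training (five 3-min blocks of 30 s
  anxiety induction + 2.5 min regulation, prompts every 30 s), eight
  sessions in four stages, with seeded non-repeating assignment of a
  240-phrase stimulus pool (40 induction + 200 control) and a 19-item
  graded-exposure hierarchy.
* **Forward simulation** — two-wavelength (760/850 nm) raw intensity over
  an 8×8 prefrontal montage at 10.2 Hz: canonical double-gamma
  hemodynamic responses, HbO/HbR anticorrelation, cardiac / respiratory /
  Mayer-wave oscillations, drift, white noise, motion spikes, and a
  session-wise learning profile that raises the regulation-condition
  response across sessions in selected channels.
* **Preprocessing** — crop, zero-phase FIR bandpass (order 1000, Blackman
  window, 0.01–0.1 Hz), Symlet-4 wavelet denoising (10 levels, details
  D1–D5 removed), optical-density conversion, modified Beer–Lambert
  inversion (DPF 7.25 @760 nm, 6.38 @850 nm), demeaning and RMS
  normalisation.
* **Energy-ratio analysis** — 15-s epochs at stressor/control event
  onsets; per-epoch signal energy

  $$E = \sum_n |x(n)|^2$$

  divided by the mean epoch energy of its channel × chromophore × session
  group (the *epoch-to-mean energy ratio*, group mean exactly 1),
  averaged per event type, summarised as per-session boxplot statistics,
  and classified into across-session trends
  (rising-then-plateau / rising-throughout / flat / other).
* **Closed-loop feedback simulation** — causal 0.01–0.3 Hz online filter,
  baseline-referenced thermometer quantisation, and a responder model
  coupling displayed levels back into the regulation drive.

## Worked example

```r
library(nfnirs)

# four-session compact programme on the four channels of interest
recs <- simulate_programme(n_sessions = 4, seed = 1,
                           montage = default_montage(
                             c("S3-D2", "S3-D5", "S5-D4", "S5-D5")))
ana <- analyze_programme(recs)
print(ana)
#> Energy-ratio analysis: 4 sessions, 4 channels, 480 epochs (0 discarded)
#> Control-condition HBO trends (plateau tolerance 5%):
#>   S3-D2    rising_then_plateau
#>   S3-D5    rising_then_plateau
#>   S5-D4    rising_then_plateau
#>   S5-D5    rising_throughout

plot(ana)               # per-channel boxplots of energy ratio by session
head(summary(ana))      # five-number summaries per channel/session/condition
```

The printed trends recover the learning profile the simulator embedded:
the control-condition energy ratio rises over sessions 1–3 and plateaus at
session 4 in S3-D2 / S3-D5 / S5-D4, and keeps rising through session 4 in
S5-D5. Each boxplot shows the distribution of the 25 control-epoch ratios
of one session; a ratio of 1 means an epoch carries exactly the session's
average energy.

A full reproducible run (schedule → simulate → preprocess → analyze),
writing events.tsv, intensity CSVs, sidecars, tidy ratio tables and a
hash manifest:

```r
res <- run_all(run_config(seed = 7, n_sessions = 2,
                          channels = c("S3-D2", "S5-D5")))
res$manifest
```

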