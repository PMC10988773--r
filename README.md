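# fpvstag

Frequency-tagged EEG analysis for fast periodic visual stimulation (FPVS)
oddball designs.

In an FPVS oddball experiment, base-category stimuli (e.g. nonwords or
pseudowords) flash at a fixed rapid rate — 10 Hz here — and a contrasting
deviant category (words) is embedded every 5th item, i.e. periodically at
10/5 = 2 Hz. Any neural process that discriminates the deviant category
from the base produces a response that is periodic at 2 Hz, so in the EEG
amplitude spectrum it concentrates at exactly 2 Hz and its harmonics
(4, 6, 8 Hz, …), while general visual processing projects to 10 Hz and
its harmonics. The response can therefore be quantified objectively at
frequencies known in advance, with very high signal-to-noise ratio, and
without any explicit task — participants just monitor colour changes on a
fixation cross (focused attention) or on two flanking vertical bars
(deployed attention, go/no-go).

`fpvstag` implements the full pipeline for designing, simulating and
analysing such experiments:

* **Sequence design** — constraint-aware oddball scheduling
  (`plan_sequence()`, `plan_session()`): a deviant every 5th presentation,
  no immediate repetition of any item, set-size versus item-repetition
  control of relative item frequency, blocked task order, and uniformly
  placed 200-ms task events (`plan_task_events()`); matching of
  psycholinguistic attributes between stimulus sets is checked with
  t-tests (`validate_matching()`).
* **Synthetic EEG** — a 68-channel generator (`synthesize_recording()`)
  that injects known periodic responses (2 Hz oddball over left
  occipito-temporal channels, 10 Hz base response over medial-occipital
  channels) into 1/f background noise (`make_pink_noise()`), so every
  downstream stage is testable against ground truth.
* **Preprocessing** — the standard chain (`preprocess()`): zero-phase FFT
  band-pass (0.1–100 Hz), segmentation (−2 to 62 s), resampling to
  512 Hz, bad-channel interpolation, common-average reference, and
  cropping to an integer number of 500-ms oddball cycles (120 cycles,
  59.998 s) so all stimulation frequencies land exactly on FFT bins.
* **Frequency-domain statistics** — amplitude spectra with
  ~0.017 Hz resolution (`amplitude_spectrum()`) and the neighbouring-bin
  noise model (`bin_stats()`): for a target bin with amplitude *x* and
  flanking noise bins,

  - SNR = *x* / mean of the 20 surrounding bins (10 per side),
  - baseline-subtracted amplitude = *x* − mean(noise), in µV,
  - *Z* = (*x* − mean(noise)) / SD(noise), using 12 bins per side minus
    the immediately adjacent bins and the global min and max (20 bins),

  plus harmonic bookkeeping: candidates at multiples of 2 Hz excluding
  base-rate multiples (`candidate_harmonics()`), group-level selection at
  *z* > 3.1 (one-tailed p < .001, `select_significant_harmonics()`), and
  per-participant summation of baseline-subtracted amplitudes
  (`sum_harmonics()`).
* **Reporting** — ROI averaging (left/right occipito-temporal and
  medial-occipital sets, `roi_average()`), grand averages, individual
  significance at *z* > 1.64 (`individual_significance()`), Spearman
  correlations and go/no-go behavioural scoring (`score_behavior()`).
* **Pipeline** — `fpvs_simulate()` / `fpvs_analyze()` run config-driven
  disk-to-disk simulations and analyses with full seed determinism; a
  thin CLI lives at `inst/scripts/fpvs`.

## Worked example

Plan one 60-s sequence, simulate three repetitions with the default
responses and 1/f noise, preprocess, and quantify the word-selective
response in the left ROI:

```r
library(fpvstag)

words    <- stimulus_set(sprintf("w%02d", 1:30), "word", "words")
nonwords <- stimulus_set(sprintf("n%02d", 1:30), "nonword", "NW1")
plan <- plan_sequence(words, nonwords, control_type = "set_size",
                      task = "bars", seed = 1)
plan
#> <fpvs_plan> 60s @ 10 Hz, deviant every 5 (2.0 Hz), set_size control, bars task
#>   600 presentations (120 deviants), 8 task events, seed 1

montage <- fpvs_montage()
epochs <- lapply(1:3, function(r) {
  rec <- synthesize_recording(plan, montage = montage, fs_hz = 512, seed = r)
  preprocess(rec, target_fs = 512)
})
spec <- amplitude_spectrum(average_epochs(epochs))
spec
#> <fpvs_spectrum> 68 channels x 15361 bins, df = 0.016667 Hz (0-256 Hz)

lroi <- roi_average(spec, default_rois()$LROI)
bin_stats(lroi, 2)
#>   f_hz bin   amp noise_mean noise_sd  snr corrected_amp    z
#> 1    2 121 0.127      0.094   0.0213 1.34        0.0329 1.55

sum_harmonics(lroi, candidate_harmonics(2, 10, 8))
#> <fpvs_harmonic_summary> 2/4/6/8 Hz: summed corrected amplitude 0.2072 uV

z <- summed_amplitude_z(lroi, c(2, 4, 6, 8))
round(z$z, 2)
#> [1] 7.36
```

The 2 Hz bin alone is weak (SNR 1.34, z = 1.55) because 1/f noise is
largest at low frequencies, but summing the baseline-subtracted
amplitudes over the four harmonics recovers the response clearly
(0.21 µV, individual z = 7.36 > 1.64): the usual motivation for harmonic
summation in oddball frequency tagging.

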