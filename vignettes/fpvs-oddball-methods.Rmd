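---
title: "Methods: oddball frequency tagging with fpvstag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oddball frequency tagging with fpvstag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fpvstag)
```

## The measurement model

An FPVS oddball sequence presents base-category stimuli at a fixed rate
$f_\mathrm{base}$ (10 Hz by default) and replaces every $k$-th
presentation (default $k = 5$) with a deviant-category stimulus, so the
deviant category recurs at $f_\mathrm{odd} = f_\mathrm{base}/k = 2$ Hz.
Neural processes common to base and deviant stimuli are periodic at
$f_\mathrm{base}$; any process that *discriminates* the categories is
periodic at $f_\mathrm{odd}$ and appears in the amplitude spectrum at
$f_\mathrm{odd}$ and its harmonics. Because a periodic response need not
be sinusoidal, its energy spreads over harmonics ($2, 4, 6, 8$ Hz, ...),
and the harmonic set — excluding every multiple of the base rate, whose
response reflects general visual processing — is the quantity of
interest.

Three indices are computed per target frequency from the flanking
("noise") bins:

* $\mathrm{SNR}(x) = x / \overline{\mathrm{noise}}$, baseline 1 under
  pure noise;
* baseline-subtracted amplitude $x - \overline{\mathrm{noise}}$, in
  microvolts, an additive estimate of the periodic signal;
* $Z(x) = (x - \overline{\mathrm{noise}})\, /\,
  \mathrm{SD}(\mathrm{noise})$.

Group-level harmonic selection uses $z > 3.1$ (one-tailed $p < .001$) on
the grand-averaged, ROI-averaged spectrum of each condition; the selected
set is then applied to all participants, whose baseline-subtracted
amplitudes are summed over it. Individual-level significance uses
$z > 1.64$ ($p < .05$) on non-corrected summed amplitudes.

## Noise windows

Two window conventions coexist in the oddball frequency-tagging
literature and are both implemented (`noise_window_spec()`):

* **SNR window**: the 10 bins on each side of the target (20 bins).
* **Z / baseline window**: 12 bins per side, minus the bin immediately
  adjacent to the target on each side (22), minus the single global
  minimum and maximum bin (20). Dropping the adjacent bins guards
  against spectral leakage from the target; dropping the extremes makes
  the noise estimate robust to a stray neighbouring response or artifact
  line.

Ties when removing the extremes are broken at the lowest bin index, and
an all-equal window still loses exactly two bins. The sample SD
($n - 1$) is used in $Z$. Both windows leave exactly 20 bins at their
defaults; `bin_stats()` takes either or both.

### Calibration of the empirical-window Z

The $z > 1.64$ and $z > 3.1$ cut-offs are normal-theory quantiles, but
the statistic is *not* standard normal under the null, for three
compounding reasons: (i) amplitude-spectrum noise bins are
Rayleigh-distributed (right-skewed), not Gaussian; (ii) the noise mean
and SD are estimated from only 20 bins, making the statistic
Student-like rather than normal; and (iii) removing the global min and
max biases the SD estimate downward. The acceptance suite measures the
resulting null tail rates by Monte-Carlo (20,000+ bins of simulated
white-noise spectra): the empirical $P(z > 1.64)$ is roughly twice the
nominal 5% and $P(z > 3.1)$ roughly 2%, rather than 0.1%. Even under
ideal Gaussian bins with no trimming, a 20-bin empirical window yields
about 6.4% at the 1.64 cut-off. The package implements the conventional
statistic exactly as used in the field and reports these measured rates
rather than hiding them; users who need strictly nominal error rates
should treat the fixed cut-offs as conventional labels, raise them, or
enlarge the noise window.

## Sequence scheduling

Counts are exact by construction: with a 60-s sequence at 10 Hz and
$k = 5$, 600 presentations comprise 480 base and 120 deviant slots.
Under *set-size* control the base and deviant sets both have 30 items
(16 and 4 repetitions each); under *item-repetition* control the base
set has 120 items and every item — base or deviant — appears exactly 4
times. The scheduler fills base slots sequentially, drawing items with
probability proportional to their remaining counts while excluding the
previous label and the flanking deviants, and forces any item that holds
at least half the remaining slots (a dead-end guard); infeasible draws
are retried up to 10,000 times before a scheduling error. Deviant slots
are never adjacent to each other, so deviants are plainly shuffled. The
no-immediate-repetition constraint is enforced across the whole stream.

Task events (default 8 per 60 s, 200 ms each) are placed uniformly at
random subject to a 1.0-s minimum gap, via the spacings method, and only
within the stimulation window — never in the fades. In the bars task an
event affects both bars (go) with probability 0.5, otherwise one bar
(no-go), sides equiprobable; the expected 4 go per 8 events treats the
observed split in published data as one realization, not a constraint.
Fades (2 s in/out) reuse the scheduled stream under a raised-cosine
amplitude ramp; repetition counts refer to the 60-s stimulation window
only.

## The synthetic-data generator

`synthesize_recording()` emulates a 68-channel acquisition at 1024 Hz:
64 standard 10-10 channels plus PO9/I1/I2/PO10, on a *schematic*
spherical montage generated from the electrode-name grid (18° per 10%
step, exactly mirror-symmetric). Injected responses are phase-locked to
stimulation onset and land exactly on FFT bins of the cycle-cropped
window, mirroring the cycle-locked design. Defaults:

* oddball response at 2/4/6/8 Hz with peak amplitudes 0.15, 0.15, 0.20,
  0.10 µV (largest at 6 Hz, as commonly observed), Gaussian topography
  peaking at PO7 with a 0.3-weight right-hemisphere counterpart at PO8 —
  after common-average referencing and left-ROI averaging this yields
  summed corrected amplitudes of a few tenths of a microvolt, the order
  of magnitude reported for word-selective responses;
* base response at 10/20/30/40 Hz (2.0, 0.8, 0.4, 0.2 µV) peaking at Oz;
* 1/f noise via spectral shaping of white Gaussian noise, one-sided PSD
  $s^2/f$ with $s = 1.4\ \mu V/\sqrt{Hz}$ at 1 Hz — chosen once so that
  single-sequence noise bins near 5 Hz average ~0.1 µV at 0.017 Hz
  resolution, typical of occipito-temporal amplitude spectra at this
  resolution — plus 0.05 µV/sample white sensor noise; a narrow-band
  alpha bump is available but off by default.

The generator does **not** emulate eye blinks, muscle or electrode
artifacts, heartbeat, non-stationarity, channel-correlated noise, or any
biophysical volume conduction: channels are independent noise sources
plus deterministic topographies. Passing tests therefore demonstrates
the correctness of the analysis arithmetic and its statistical
behaviour under a realistic 1/f noise floor — not robustness to real
recording artifacts.

Behavioural key presses are simulated per event (hit probability,
Gaussian RT, no-go press probability, stray-press rate) with defaults
set to published group means (hit rates ~95/97%, RTs ~463/501 ms, false
alarms ~3/5%), so the scoring path is exercised end-to-end.

## Preprocessing: numerical choices

The chain is fixed in this order: FFT band-pass → segmentation →
resampling → bad-channel interpolation → common-average reference →
cycle cropping.

* **Band-pass** (0.1–100 Hz): hard spectral mask, zero-phase, matching
  the FFT filters of frequency-tagging toolboxes; an optional
  raised-cosine transition width is available for ringing-sensitive
  uses.
* **Segmentation**: −2 to 62 s around stimulation onset, taken as the
  *end of the fade-in*, since the sequence item-count arithmetic covers
  exactly the 60-s stimulation window; the marker is a configuration
  switch for data segmented relative to fade-in instead.
* **Resampling** (1024 → 512 Hz): FFT-domain truncation, the natural
  companion of the spectral-mask filter; it is exact for bin-locked
  components and preserves in-band amplitudes well within 0.5%.
  Upsampling is out of scope.
* **Interpolation**: the paper-style "linear interpolation" is
  implemented as inverse-distance-weighted means of the $k = 4$ nearest
  good channels on the montage sphere.
* **Cycle cropping**: from $t = 0$ through the largest whole number of
  500-ms cycles, capped at the stimulation duration; at 512 Hz this
  keeps 30,720 samples whose last timestamp is 59.998 s, and puts both
  2 Hz and 10 Hz (and all harmonics below Nyquist) exactly on bin
  centres. Sample indexing is 0-based in time ($t =$ index$/f_s$).
* **Amplitude normalization**: one-sided spectrum scaled so a sinusoid
  of peak amplitude $A$ at an exact bin reads $A$ (factor $2/N$; DC and
  Nyquist $1/N$). No window function and no zero-padding, since the
  design is bin-locked and tapering would bias amplitudes.

A common-average reference subtracts the mean topography weight from
every channel, so recovered amplitudes equal the injected amplitude
times the *re-referenced* weight $w - \bar w$; the recovery tests use
exactly this ground truth.

## Open design points and their resolutions

* The published description of "each sequence repeated twice … 4
  conditions × 3 repetitions" is internally inconsistent; the package
  follows the 2 × 4 × 3 = 24 arithmetic and exposes `n_reps`.
* How the individual-level z on *summed* amplitudes aggregates noise is
  not fully specified in the literature; the default sums target-bin
  amplitudes and forms the null by summing flanking bins offset-by-offset
  across the same harmonics (extremes of the summed values dropped), a
  `mean_z` variant is available behind a flag
  (`summed_amplitude_z(method =)`).
* The exact left-ROI electrode set ("5 electrodes around PO7") is not
  printed in the source literature; the default is
  PO7, P7, P9, PO9, O1 (mirror: PO8, P8, P10, PO10, O2), configurable,
  and every report echoes the configured set.
* The behavioural response window (0.15–1.0 s after a go onset) and the
  cross-task false-alarm denominator (count per event, since the cross
  task has no no-go trials) are package choices, documented in
  `score_behavior()`.

## Problem sizes

Unit tests run on scaled-down designs (3–10-s sequences, 64–256 Hz)
wherever the arithmetic generalizes, and at full scale (68 channels,
1024 Hz, 60-s sequences) for the noiseless recovery checks, which
complete in seconds. The acceptance script uses 20,000+ Monte-Carlo
noise bins for the null-calibration estimates, 100 seeded three-sequence
runs for lateralization recovery, and 1,250 simulated sequences per task
for behavioural scoring — sizes chosen to make the Monte-Carlo standard
errors small relative to the quantities being estimated.

## Known limitations

* EDF/BDF ingestion is not implemented; recordings enter either from
  the generator or from the documented fixture container (float32
  matrix + JSON sidecar). The preprocessing chain is agnostic to the
  source.
* Group inferential statistics (repeated-measures ANOVA, Bayes factors)
  are deliberately out of scope; the tidy TSV outputs are designed to be
  handed to any statistics package.
* The montage is schematic; interpolation and ROI geometry are sensible
  but positions are not digitized head coordinates.
* The fixed z cut-offs are conventional and anticonservative under the
  empirical noise window (measured above); cross-condition comparisons
  of summed amplitudes are unaffected.
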