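---
title: "Methods: proteinoid spike-train analysis and optical character recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteinoid spike-train analysis and optical character recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protospike)
```

## The system and the analysis

Proteinoid (thermal protein) microspheres in solution exhibit spontaneous
electrical spiking, and their spiking statistics change when a light pattern
— here, a projected alphabet character — is shone on the sample.
`protospike` implements the analysis chain for such recordings:

1. **Spike statistics.** A recording (potential in mV, or temperature in
   °C, sampled uniformly in seconds) is detrended, spikes are detected as
   prominent local maxima, and the detected peak heights ("amplitudes") and
   the differences of successive peak times ("periods") are summarized by
   quartiles, mean, extremes and standard deviation. One such seven-number
   summary pair per character is a row of the packaged per-character
   profile table.
2. **Recognition.** A character is *assigned* when its mean amplitude
   $A_i$ and mean period $P_i$ strictly exceed thresholds $A_{th}$ and
   $P_{th}$, and *rejected* otherwise; assignments are tallied in a
   $26 \times 26$ confusion matrix (rows true, columns predicted) with the
   rejects kept in a separate per-class tally, from which accuracy
   $\sum_i C_{ii} / N$, precision $C_{ii} / \sum_j C_{ji}$ and recall
   $C_{ii} / (\sum_j C_{ij} + \mathrm{rej}_i)$ follow. A nearest-profile
   classifier (Euclidean distance in the z-scored $(A_i, P_i)$ plane)
   makes the chain exercisable end to end on synthetic recordings.
3. **Boolean gates.** The 26 mean amplitudes and periods are min-max
   normalized and thresholded: AND ($A > T_A \wedge P > T_P$), OR, NOT
   (small amplitude *or* brief period), NAND $= \neg$AND, NOR $= \neg$OR,
   all strict.
4. **Morphology.** Microsphere diameters are summarized by a
   Gaussian-kernel density estimate
   $f(x) = \frac{1}{nw}\sum_i \varphi\!\left(\frac{x - X_i}{w}\right)$ at
   the Scott's-rule bandwidth $w = \hat\sigma\, n^{-1/5}$, and by box
   statistics with Tukey fences $Q_1 - 1.5\,\mathrm{IQR}$,
   $Q_3 + 1.5\,\mathrm{IQR}$.
5. **Spectra.** Zero-phase Butterworth low/high-pass filtering and a
   periodogram reported as $10 \log_{10}$ power at positive frequencies.

A seeded synthetic-recording generator stands in for laboratory data, so
every stage is testable offline.

## The synthetic generator: what it emulates, and what it does not

The generator draws inter-event intervals and event amplitudes i.i.d. from
log-normal distributions moment-matched to a target mean $m$ and standard
deviation $s$ via $\mu = \ln(m^2/\sqrt{v + m^2})$,
$\sigma^2 = \ln(1 + v/m^2)$ with $v = s^2$. The log-normal was chosen
because the measured period tables are strongly right-skewed (means far
above medians — e.g. the letter-A period mean 2034.88 s against a median of
847.00 s) and both quantities are positive. Zero dispersion degenerates to
a point mass, which the tests use for exact constructions. Events are
rendered as unit-peak Gaussian bumps (default scale 20 s — no single-spike
shape is published, and the only property downstream stages rely on is
"peak height equals amplitude") on a configurable baseline (offset, linear
drift, sinusoid) plus white Gaussian noise; temperature co-traces use the
same machinery with small amplitudes (a few tenths of a °C) and a slow
drift.

The published tables' min/max columns are treated as descriptive, not as
truncation bounds: clipping the generator at them would bias the recovered
means, which the parameter-recovery tests check.

What the generator does **not** emulate: per-character waveform shape
differences (all characters share the bump shape and differ only in their
amplitude/period statistics), bursting or serial correlation of intervals,
electrode drift nonstationarity beyond the configured baseline, and any
biophysics of photoexcitation. Passing recognition tests therefore show
that the pipeline recovers and separates the *statistical* signatures it
assumes; they say nothing about whether real proteinoid recordings are this
well behaved.

## Numerical and design choices

**Spike detection.** A sample $i$ is a candidate peak when
$v_i > v_{i-1}$ and $v_i \ge v_{i+1}$ (the leftmost sample of a flat
plateau, a deterministic and order-stable tie-break). Prominence is the
standard topographic one: the height minus the higher of the two minima
separating the peak from higher terrain or the record edge. Among peaks
closer than `min_separation` (default 10 s) the taller wins, ties to the
earlier. Amplitude is the detrended *height* at the peak, not the
prominence: the published workflow detrends and normalizes before peak
picking, so height above the removed baseline is the natural reading; the
printed tables cannot distinguish the two conventions, and the choice is
confined to one line of `detect_spikes()`.

The default prominence floor is length-adaptive:
$\max\!\big(5,\; 2\sqrt{2\ln n}\big)\,\hat\sigma$, with $\hat\sigma$ the
noise floor estimated as $\mathrm{MAD}(\Delta v)/\sqrt{2}$. A fixed
multiple of the noise sd looks natural but fails on long records: the
topographic prominence that pure white noise reaches grows with record
length (its extremes scale like $\sigma\sqrt{2\ln n}$, and a prominence
spans a noise maximum *and* a noise minimum, hence the factor 2). On a
$2\times 10^7$-sample recording a plain $5\hat\sigma$ floor admits tens of
thousands of noise peaks; the adaptive floor keeps the $5\hat\sigma$
behaviour on short records and suppresses noise prominences at any length.
Two residual biases remain and are documented rather than corrected: the
reported height includes the noise value at the selected sample, which is a
local maximum over the few samples spanning the bump top (an upward bias of
order one noise sd, about +1.5% at the default 0.05 mV noise on
letter-A-scale spikes), and events closer together than the separation
window merge (a per-mille effect at the published period scales).

**Baseline removal.** Three estimators: pre-stimulus mean, least-squares
line, and running median (default window 500 s). The running-median window
must be much wider than a spike's support (about $10\sigma_w$) and shorter
than the baseline's variation scale; peaks within half a window of the
record edge sit in the shrinking edge windows of the running median and are
estimated low, so rendered recordings pad the duration past the last event.

**Summaries.** Quartiles use linear interpolation of order statistics
(`stats::quantile` type 7), configurable because the source software for
the published tables is unknown; the seven-number summaries validate
$\min \le Q_1 \le Q_2 \le Q_3 \le \max$, $\min \le \text{mean} \le \max$,
$sd \ge 0$. One published row (letter H, period $Q_2 = 10983.50$ s against
$Q_3 = 10923.00$ s) violates the ordering — almost certainly a transcription
slip in the source — so the packaged table is transcribed verbatim and the
loader warns on that row by default instead of refusing it
(`check = "error"` is available for user tables).

**Recognition.** The published classification rule has no else-branch; a
REJECT outcome was introduced and kept outside the $26\times 26$ matrix to
preserve its shape. Recall counts a class's rejects in its denominator
(they are true instances); a zero denominator yields `NA`, never a silent
0. $A_{th}$ and $P_{th}$ are required arguments with no default — the
publication states the rule but no values.

**Gates.** The source lists two single-feature NOT gates but reports a
single NOT row satisfied by all 26 characters; the package combines them as
a disjunction ("small magnitude *or* brief duration"), which reproduces the
published counts at the default thresholds, whereas a conjunction would
exclude the letters whose normalized amplitude or period is exactly 1. The
rule is switchable (`not_rule = "and"`). Default thresholds are
$T_A = T_P = 1$ with strict inequalities — the minimal choice consistent
with all five published counts; the thresholds actually used for the
published table are not stated.

**Morphology.** The Scott's-rule constant is exposed
(`scott_bandwidth(..., constant = )`): the published bandwidth
$w = 135.05798$ nm is reported without $n$ or $\hat\sigma$, so the exact
constant used there cannot be reverse-engineered, and that value is not a
package target. Fences are reported unclamped because the published
whisker endpoints equal $Q_1 - 1.5\,\mathrm{IQR}$ and
$Q_3 + 1.5\,\mathrm{IQR}$ exactly (to 0.02 nm rounding), not data extremes.

**Filtering.** Filter family, order and cutoff are not published; the
package uses Butterworth (maximally flat passband), default order 4,
cutoff a required argument, applied forward-backward for zero phase so
spike timing is undistorted (the −3 dB single-pass cutoff attenuation
becomes −6 dB). `signal::filtfilt` leaves large edge transients on a
constant input, so the zero-phase application is implemented in-package
with odd-extension padding and a steady-state initial filter state
(direct-form II transposed); a constant signal passes the low-pass
unchanged to below $10^{-6}$. The published time-domain statistics of the
filtered spontaneous-spiking signal report identical means for the low-
and high-pass outputs, which cannot hold for a DC-blocking high-pass;
those statistics are noted as internally inconsistent and not chased.

**Degenerate inputs.** Constant vectors error in `min_max_normalize` and
`scott_bandwidth`; empty samples error in `summarize_stats`, `kde` and
`box_stats`; recordings shorter than 3 samples error in `detect_spikes`;
fewer than 2 detected peaks error in `profile_character` (no period is
defined); a constant reference column is dropped by the nearest-profile
z-scoring, and an all-tied distance resolves alphabetically.

## Problem sizes and reproducibility

All randomness flows through explicit integer seeds (R's default
Mersenne-Twister stream); identical configuration and seed give
byte-identical outputs, and every pipeline CSV carries a hash of the
scientific configuration in its header. The bundled analysis scripts and
the test suite run at desk scale, chosen as the package's own working
sizes: 26 characters at 60 events each on a 5 s grid for recognition
(about $1.8\times 10^6$ samples per replicate), 10 replicate seeds for the
above-chance recognition check, a 10,000-event letter-A recording on a 1 s
grid (about $2\times 10^7$ samples) for the amplitude-recovery closure
check, and 200 random instances of length up to 1,000 for the exhaustive
peak-detection oracle comparison. At 60 events per character the sampling
error of a period mean is large (the letter-A period sd exceeds its mean),
which is why a handful of the ten clustered mid-table characters swap
under nearest-profile recognition; accuracy remains an order of magnitude
above the 1/26 chance level, and collapsing all characters onto one
generator configuration drives it back to chance.

## Known limitations

- The event count behind each published table row is unknown, so the
  generator cannot reproduce the real sampling error of those rows; the
  per-character event count is a user choice.
- Recognition operates on (mean amplitude, mean period) only — the same
  two features the published rule uses; waveform-shape features are out of
  scope.
- The KDE is univariate; no image analysis is provided to obtain diameters.
- Persistent (max-hold) spectra and wavelet scalograms are not
  implemented; the spectral module stops at the plain dB periodogram.
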