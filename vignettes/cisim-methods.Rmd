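---
title: "Simulating cochlear-implant sound: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cochlear-implant sound: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisim)
```

## What cisim models

A cochlear implant (CI) digitizes sound, splits it into a small number of
frequency bands, and stimulates the auditory nerve with the band envelopes.
Users with single-sided deafness can compare that electric percept directly
with acoustic hearing in the other ear, and what they report hearing through
the implant is *not* well described by a single textbook vocoder: depending
on the listener it resembles band-limited, comb-filtered, pitch-shifted, or
vocoded speech, or combinations of these. cisim implements that whole family
of transformations as composable stages, so that any mono 44.1 kHz recording
can be turned into the CI-sound approximations a listener might endorse:

* low-, high-, and band-pass **Butterworth filters** on a clinical grid
  (order 1–10, cutoffs 0–8 kHz in 0.1 kHz steps);
* a **feedback comb filter** (peak spacing `f0`, quality factor `q = f0 / bandwidth`);
* duration-preserving **pitch shifting** in semitones (±15);
* **single-sideband frequency shifting** in Hz (−30…+800 in 5 Hz steps),
  which destroys harmonic ratios;
* **overmodulation/clipping** (gain 1.0–20.0 in 0.1 steps, cut at the input
  peak);
* a 22-channel **FFT vocoder** in the style of the ACE ("n-of-m") coding
  strategy, and a 22-channel **band-pass-filter-bank vocoder**, both with
  sine or seeded-noise carriers and a spread-of-excitation (SOE) control.

Stages are combined into `parameter_set()` chains. The package ships two
catalogs — ten screening chains and fifteen participant-optimized chains
with similarity ratings — plus a builder for the 10 × 10 screening stimulus
battery and a synthetic sentence generator for license-free testing.

## The processing stages

### Pass filters

The grid (order 1–10, cutoffs on a 0.1 kHz lattice up to 8 kHz) matches the
range in which speech carries essentially all of its energy and the analysis
range of the implant's filter bank. The family is Butterworth (maximally
flat): it is the natural realization of an "order + cutoff" parameterization,
and its −3 dB point sits exactly at the cutoff for every order and kind.
Filtering is causal (single pass, phase-distorting), mirroring a real-time
processing chain rather than an offline zero-phase one.

Numerically, filters are designed and applied as cascaded second-order
sections (biquads): the analog prototype poles are frequency-transformed and
bilinear-mapped pole by pole. Expanding a 10th-order band-pass into one
transfer-function polynomial (order 20) is unstable in double precision at
grid extremes such as a 0.1 kHz lower edge — the SOS cascade is exact and
stable there. `stage_response()` exposes the realized magnitude response;
tests compare it against an independent filter-design implementation at
moderate orders.

Two degenerate grid points need a convention, chosen once: a *high-pass at
0 kHz* is a passthrough, and a *band-pass with a 0 kHz lower edge* is the
corresponding low-pass (a true 0 Hz cutoff is undefined). A low-pass cutoff
of 0 kHz is rejected.

### Comb filter

The comb has unity-gain peaks every `f0` Hz (including DC) and is realized
as the classic feedback comb

$$H(z) = \frac{1-c}{2}\,\frac{1 + z^{-N}}{1 - c\,z^{-N}}, \qquad N = f_s / f_0,$$

which requires the sampling rate to be an integer multiple of `f0` — hence
the admissible spacings are exactly the divisors of 44 100 between 1 and
14.7 kHz (`admissible_comb_spacings()`); 14.7 kHz is the largest divisor
below the 22.05 kHz Nyquist limit. Solving $|H|^2 = 1/2$ gives the feedback
coefficient in closed form, $c = \frac{1-\tan(\pi/2q)}{1+\tan(\pi/2q)}$, so
the −3 dB bandwidth of *every* peak equals `f0/q` exactly, matching the
definition of the quality factor. A cascade of per-peak resonator sections
was considered and rejected: sections centered at different frequencies
multiply, so each would attenuate all other peaks — a cascade cannot realize
a comb of unity-gain peaks.

### Pitch and frequency shift

Pitch shifting multiplies every component frequency by $2^{s/12}$ while
preserving duration. It is implemented as a phase-vocoder time stretch
(2048-sample Hann frames, analysis hop 512) followed by band-limited
resampling. The synthesis hop is `round(512 * 2^(s/12))`, which makes the
realized ratio rational — exact at ±12 semitones and within 0.1 % elsewhere,
comfortably inside the 1 % contract the tests enforce. At `s = 0` the
synthesis phases equal the analysis phases and the stage is transparent.

Frequency shifting adds a *constant* offset to every component: the analytic
signal (FFT Hilbert weights) is multiplied by $e^{2\pi i\,\Delta f t}$ and
the real part is taken. Components that would land below 0 Hz (downshift) or
above Nyquist (upshift) are removed in the analytic spectrum rather than
mirrored. Unlike a pitch shift this destroys harmonicity: partials at 200,
400, 600 Hz shifted by +800 Hz land at 1000, 1200, 1400 Hz — ratios
1 : 1.2 : 1.4, no longer integers.

### Overmodulation/clipping

The signal is multiplied by the factor and cut at the *input's own peak*
amplitude, not at digital full scale. That bound is forced by the grid
semantics: factor 1.0 must be "no clipping" — an exact identity — for inputs
at any level. For a full-scale sine at factor 20 the clipped fraction has
the closed form $1 - \tfrac{2}{\pi}\arcsin(1/20) \approx 0.968$, which the
tests verify on a 440 Hz fixture (a frequency with a non-integer sample
period, so the sampled phases cover the cycle densely; an integer-period
sine such as 441 Hz at 44.1 kHz samples only 100 fixed phases and biases
the fraction).

### The vocoders

Both vocoders run at the implant processor's rate: input is resampled
44.1 kHz → 16 kHz (polyphase FIR), processed, resampled back, and RMS-matched
to the input. The analysis table is the standard 22-channel allocation of
125 Hz FFT bins (128-point FFT, Hann window, 2 ms hop): one bin per channel
at the low end widening to eight bins at the top, spanning 187.5–7937.5 Hz.
It ships as a versioned CSV (`extdata/ace-band-table.csv`) so it is
auditable and swappable without code changes; a checksum test guards
accidental edits.

The FFT vocoder computes per-frame band envelopes as the sum of FFT-bin
magnitudes per channel, keeps the `n` largest envelopes per frame and zeroes
the rest (n-of-m; ties broken toward the lower band), then modulates
carriers: zero-phase sines at the band centers, or Gaussian noise band-passed
per channel and scaled to sine RMS. A mandatory seed makes noise carriers
reproducible — the same chain, input, and seed yield bit-identical stimuli.

The SOE setting maps narrow/moderate/flat to noise-band Butterworth orders
4/2/1. Since all orders share the band edges (which are the −3 dB points of
a Butterworth band-pass by construction), the orders do not differ in −3 dB
bandwidth; they differ in slope, i.e. in how much carrier energy spreads
beyond the band. The tests therefore compare equivalent noise bandwidth and
realized out-of-band energy, where narrow < flat holds strictly.

The band-pass vocoder replaces the FFT analysis with contiguous 4th-order
Butterworth band-passes (the 22 table bands merged into `n` near-equal
groups, so `n = 22` coincides with the FFT bank's bands and `n = 1` spans the
full range). Envelopes are full-wave rectification followed by a 4th-order
400 Hz low-pass — standard envelope-vocoder practice, kept as configuration.
There is no maxima selection in this path.

### Chains, catalogs, battery

`apply_chain()` applies stages in listed order and ends by matching the
output RMS to the input, standardizing level across chains (the study set
presentation loudness per listener, which a library cannot reproduce). An
empty chain — two of the fifteen participants needed no modification — is an
exact identity. A failing stage aborts with its index; nothing partial is
produced.

The two catalogs are YAML data files, not code. The published per-cell
values were not machine-readable in the source available to this package, so
the shipped files are **reconstructions**, explicitly labelled as such
(`*-reconstructed.yaml`), constrained to reproduce every aggregate the
accompanying text states: 15 records #201–#215, two unmodified, a maximum of
3 stages (#203), a mean of 1.4 modifications, low-pass and comb filters each
used by four participants and every other kind by fewer, no use of the BP
vocoder, frequency shift, or overmodulation, sentence-score means of
9.7 / 8.4 / 8.9 with sentence-1 median 10.0 and ten records (67 %) at the
scale maximum, and no transfer sentence scored above sentence 1. Cells
beyond those constraints are documented choices. One aggregate cannot be
reconciled: given the other constraints, the stage-count multiset is forced
and its sample SD is 0.8, not the reported 0.7; `catalog_summary()` reports
what the packaged data actually yield.

`build_battery()` applies the ten screening chains to ten sentences —
10 blocks of 10 stimuli, 100 in total — with the presentation order of each
block drawn as a seeded permutation. One master seed derives a per-block
sub-seed (`(seed mod 10^6) * 1000 + block`, kept far below 2^31), so block
shuffles are independent but the whole session is reproducible. Block order
itself is fixed, sentence 1 to 10; only within-block order is randomized.
Stimuli whose RMS-matched waveform would exceed digital full scale are
scaled to a 0.99 peak before writing, trading a level offset for freedom
from saturation distortion.

## The synthetic sentence generator

The study's speech material is licensed and cannot ship. The generator
stands in for it with the gross acoustics that matter to the stages under
test: a male-typical falling f0 contour (130 → 100 Hz by default), a
sawtooth glottal-like source shaped by three formant resonators whose
frequencies are drawn per voiced segment from male-typical ranges (F1
300–800, F2 1000–2000, F3 2300–3000 Hz), two high-passed noise bursts as
fricative stand-ins, short pauses suggesting a three-word utterance, a
6th-order 7 kHz low-pass guaranteeing ≥ 99 % of energy below 8 kHz, and a
0.5 peak at 44.1 kHz. It is a pure function of its spec and seed.

What it does **not** emulate: phonemes, intelligibility, coarticulation,
sentence prosody beyond the f0 ramp, or speaker identity. Tests passing on
these signals demonstrate that the DSP contracts hold on speech-like
spectra — band envelopes, harmonicity, formant structure — not that the
processed output sounds like any particular talker; perceptual claims are
outside what this package can verify.

## Numerical choices and degenerate inputs

* Framing defaults (FFT 128/hop 32 at 16 kHz; phase vocoder 2048/512) are
  configuration with tested defaults.
* n-of-m ties are broken toward the lower band index; bands already at zero
  are never counted as "selected".
* RMS matching of a silent input returns it unchanged (no gain can change a
  zero signal); a silent *reference* is an error.
* 16-bit WAV samples are scaled by 32768 on write (clamped at 32767) and
  read back as x/32768; +1.0 therefore saturates by one LSB. Out-of-range
  samples are clipped at write time with a warning.
* Multichannel WAVs are averaged to mono deterministically.
* Resampling trims or zero-pads the polyphase output to
  `round(n * target/rate)` samples so length bookkeeping is exact.

## Problem sizes

The test suite and the battery builder run on synthetic sentences of 0.4–1.2
s and a full 100-stimulus battery at 0.8 s per sentence; the complete suite
executes in well under a minute on one CPU. These sizes exercise every code
path (all ten screening chains, including the three vocoder presets, and all
fifteen participant chains) while keeping iteration fast; nothing in the
implementation depends on signal length.

## Known limitations

* Echo and reverberation stages are out of scope (no participant required
  them, and their reference implementation details are unpublished).
* The catalogs are reconstructions, as above; if the authoritative table
  cells become available they can be dropped into the YAML files (updating
  the recorded checksums) without touching code.
* SOE is modeled purely as carrier-filter slope; there is no electrode-level
  stimulation, loudness growth, or current-spread modeling.
* The optimization dialogue itself (adjective-guided adjustment with a
  listener in the loop) is not reproduced; the package replays its outcomes.
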