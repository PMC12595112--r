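# Screening parameter sets, v1 — RECONSTRUCTED DATA.
# The published table of the ten screening chains is not machine-readable in
# the source available to this package, so the cell values below are a
# reconstruction consistent with the described set kinds: three mild pass
# filters (sets 1-3), pitch/frequency shift combined with overmodulation
# (sets 4-5), two comb variants (sets 6 and 10), the BP vocoder (set 7) and
# the FFT vocoders with sine and noise carriers (sets 8-9). Edit here, not
# in code, if the authoritative values become available.
sets:
- id: "1"
  stages:
  - stage: pass_filter
    kind: band
    order: 3
    cutoff_low: 0.2
    cutoff_high: 7.0
- id: "2"
  stages:
  - stage: pass_filter
    kind: low
    order: 4
    cutoff_high: 1.5
- id: "3"
  stages:
  - stage: pass_filter
    kind: high
    order: 3
    cutoff_low: 0.5
- id: "4"
  stages:
  - stage: pitch_shift
    semitones: 8
  - stage: clip
    factor: 10.0
- id: "5"
  stages:
  - stage: frequency_shift
    delta_f: 400
  - stage: clip
    factor: 5.0
- id: "6"
  stages:
  - stage: comb_filter
    f0: 2205
    q: 150
- id: "7"
  stages:
  - stage: bp_vocoder
    n_bands: 12
    carrier: sine
    soe: moderate
- id: "8"
  stages:
  - stage: fft_vocoder
    n_selected: 8
    carrier: sine
    soe: moderate
- id: "9"
  stages:
  - stage: fft_vocoder
    n_selected: 8
    carrier: noise
    soe: moderate
    noise_seed: 9
- id: "10"
  stages:
  - stage: comb_filter
    f0: 1470
    q: 300
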