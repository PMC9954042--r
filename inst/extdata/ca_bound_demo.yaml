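# Demo pipeline: simulate the calcium-bound photocycle, run the sequential
# three-component global analysis, fit the stimulated-emission band trace,
# then simulate the excited-state FSRS series and fit the 1641 1/cm
# photoproduct marker-band rise. Steady-state stage fits a two-state
# titration and reports the Stokes shift landmarks.
seed: 11
output_dir: "."
stages:
  - stage: simulate_ta
    preset: ca_bound
    noise_sigma: 0.3
    output: ta.tsv
  - stage: globalfit
    input: ta.tsv
    n_components: 3
    irf_fwhm_fs: 140
    init_lifetimes: [4.5, 100.0, 1600.0]
  - stage: tracefit
    input: ta.tsv
    window: [583, 620]
    n: 3
  - stage: simulate_fsrs
    preset: ca_bound
    noise_sigma: 0.004
    output: fsrs.tsv
  - stage: fsrs
    input: fsrs.tsv
    peak_window: [1610, 1675]
    baseline_anchors:
      - [900, 950]
      - [1080, 1130]
      - [1430, 1470]
      - [1740, 1800]
    n: 2
  - stage: steady
    pka: 6.5
    ph: [3.5, 5.0, 6.5, 8.0, 11.0]
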