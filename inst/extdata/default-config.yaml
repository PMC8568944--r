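# default end-to-end run: simulate every input, analyze, report
seed: 20260926
stages:
  parenchyma:
    width_px: 256
    height_px: 256
    pixel_size_um: 1
    n_airspaces: 12
    tissue_saturation: 0.8
    air_saturation: 0.05
    saturation_threshold: auto
    min_diameter_um: 5
  pv:
    A: 1.2
    B: 1.0
    K: 0.12
    p_max: 30
    n_down: 30
    noise_sd: 0.01
    eval_pressure_cmh2o: 5
  cohort:
    n_patients: 2000
    abrasion_threshold_pct: 70
    exclude_smokers: true
    alpha: 0.1
  genotyping:
    n_samples: 12
    length_nt: 250
  calcium:
    baseline_f: 100
    peak_delta_f: 80
    ionomycin_f: 500
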