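# Desk-scale demo configuration: a small two-cohort synthetic study that
# exercises every pipeline stage in a few seconds.
seed: 1
cohorts:
  train:
    cohort_id: CDDP
    n_patients_per_class: {RecPro: 6, NED: 5}
    spectra_per_patient: 60
    n_features: 120
    n_signal_features: 12
    slide_count: 4
    seed: 1
  transfer:
    cohort_id: MMC
    n_patients_per_class: {RecPro: 5, NED: 5}
    spectra_per_patient: 60
    n_features: 120
    n_signal_features: 12
    slide_count: 4
    seed: 1001
shared_signal: false
preprocessing:
  structure_width: 201
  tolerance: 0.2
  min_prominence: 0
  smooth: false
screening:
  auc_lo: 0.3
  auc_hi: 0.7
  alpha: 0.001
  method: BH
  n_draws: 1
models:
  all_mz:
    lambda: 0.02
  restricted:
    lambda: 0.05
cv:
  n_folds: 5
annotation:
  tolerance_da: 0.2
  min_peptides: 2
  min_correlation: 0.4
  n_proteins: 4
  peptides_per_protein: 2
  mass_jitter_sd: 0.05
  n_singletons: 2
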