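# Demo configuration for `run_pipeline()` / `phenoscore.R run`.
# A small cohort that completes in well under a minute on one CPU.
n_samples: 2000
n_variants: 2000
n_causal: 40
h2_liability: 0.5
prevalence: 0.10
maf_low: 0.05
maf_high: 0.5
missing_rate: 0.02
seed: 1
channels:
  billing: {sensitivity: 0.95, specificity: 0.90}
  problem_list: {sensitivity: 0.60, specificity: 0.995}
  algorithm: {sensitivity: 0.80, specificity: 0.995}
billing_count_params: [2.0, 0.3]
qc:
  maf_min: 0.01
  callrate_min: 0.90
  hwe_alpha: 1.0e-6
  window: 50
  step: 5
  vif_max: 10
  passes: 3
pcs: 0
grid: {p_min: 5.0e-5, p_max: 0.1, n: 12}
folds: 5
billing_thresholds: [1, 2, 3]
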