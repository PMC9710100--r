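# Default simulation-driven pipeline configuration.
# Emulates the two-strain brainstem array design: 4 samples per group,
# planted fold changes >= 4 (log2FC 2) in both directions, all six lncRNA
# positional categories planted, and 115 lincRNA-neighbor pairs with a
# planted direction concordance of 0.685.
simulate:
  n_coding: 400
  n_lncrna: 2000
  n_samples_per_group: 4
  planted_de_fraction: 0.05
  planted_log2fc: 2
  noise_sd: 0.25
  baseline_log2_mean: 8
  n_linc_pairs: 115
  concordant_fraction: 0.685
thresholds:
  fc_min: 2.0
  p_max: 0.05
  fdr_max: 0.05
  bidirectional_window: 1000
  neighbor_window: 300000
de_regime: primary
qpcr:
  n_replicates: 4
  noise_sd: 0.1
enrich:
  n_sets: 20
seed: 1
output_dir: results/pipeline
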