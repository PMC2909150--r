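# Declarative configuration for the packaged default analysis:
# a synthetic cohort matching the defaults of default_simulation_spec()
# (4,000 unrelated individuals, 43 independent SNPs, a focal trait at
# 3.2% SNP-set variance, companion traits graded by rho), followed by
# genotype QC, SNP-set scoring, covariate adjustment, association and
# the power annex.  Consume with:
#   Rscript inst/cli/snpsetassoc.R run --config inst/examples/teds_like.yaml
simulation:
  n_individuals: 4000
  n_snps: 43
  target_r: 0.179
  plex_dropout_rate: 0.02
  snp_miss_rate: 0.01
  pheno_miss_rate: 0.05
qc:
  min_individual_plex_call_rate: 0.70
  min_snp_call_rate: 0.95
  hwe_alpha: 0.01
focal_measure: math10
controls:
  g_and_reading: [g10, reading10]
  g_only: [g10]
out_dir: teds_like_run
seed: 1
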