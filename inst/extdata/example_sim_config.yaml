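# Example simulation configuration for read_sim_config(): a two-gene panel,
# two patients, 10% of variants planted as missing from WES and 5% as
# zygosity flips. The seed fully determines every generated file.
seed: 7
n_patients: 2
p_missing: 0.10
p_zygosity_flip: 0.05
variants_per_patient:
  coding: 6
  intronic_near: 3
  intronic_deep: 3
genes:
- {gene: GENEA, n_exons: 4, exon_len: 300, intron_len: 400, gc_target: 0.40, mean_depth: 48, low_cov_fraction: 0.0}
- {gene: GENEB, n_exons: 4, exon_len: 300, intron_len: 400, gc_target: 0.56, mean_depth: 30, low_cov_fraction: 0.35}
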