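# Small single-chromosome configuration for a fast end-to-end run.
seed: 1
out_dir: rrbsdml_smoke
genome:
  n_chroms: 1
  chrom_length_bp: 1000000
  cpg_density: 0.005
dmr:
  n_dmr: 40
  dmr_length_bp: 1000
enrich:
  n_perm: 100
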