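# Demo configuration for `run_pipeline()` / the retroburst CLI.
# A small self-contained run: simulate a 200 kb genome with two families
# (one Gypsy/Chromoviridae, one Copia) of known-age insertions, detect,
# classify, date, census, and run a planted GO enrichment.
seed: 1
out_dir: retroburst_out
stages:
  simulate: true
  detect: true
  classify: true
  date: true
  census: true
  phylo: false
  enrich: true
simulate:
  genome_length: 200000
  gc_fraction: 0.5
  n_families: 2
  n_insertions: 4
  ages: [2500000.0, 5000000.0]
  ltr_len: 350
  truncation_fraction: 0.0
  solo_ltr_fraction: 0.0
  rate_r: 1.05e-9
  transition_fraction: 0.5
date:
  rate_r: 1.05e-9
  bin_width: 5000000.0
  max_age: 50000000.0
  domain_confirmed_only: false
enrich:
  n_genes: 2000
  n_secreted: 100
  alpha: 0.05
  min_genome_count: 1
  planted:
    - term: "GO:0030600"
      count_in_secretome: 6
      count_in_genome: 9
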