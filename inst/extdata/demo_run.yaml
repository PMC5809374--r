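# Demo pipeline configuration: a desk-scale synthetic study with one
# 2 Mb chromosome, 400 genes, a 200 kb pericentromeric heterochromatin
# block and 2e5 reads per sample (four samples: H3.1-like, H3.3-like,
# mixed, uniform control).
synthetic:
  genome_length: 2000000
  n_chroms: 1
  n_genes: 400
  het_fraction: 0.1
  n_reads: 200000
  enrichment_fold: 8
  three_prime_bias: 0.6
caller:
  window_size: 200
  gap: 200
  fragment_size: 200
  eligibility_p: 0.2
  p0: 1.0e-3
metagene:
  flank: 2000
  n_bins: 20
  pseudocount: 1
seed: 1
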