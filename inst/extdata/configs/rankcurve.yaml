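# rank-abundance dataset: 200 target genes with Zipf-like planted weights;
# rank 1 takes 12% of targeting weight and ranks 1-88 accumulate 70%
seed: 11
genome:
  length: 620000
  gc_content: 0.45
  chrom: chr1
gene_array:
  n_genes: 200
  id_prefix: g
  n_exons: 3
  exon_len: [400, 400]
  intron_len: [200, 200]
  utr5_len: 100
  utr3_len: 300
  strand: "+"
pgf_array:
  exon_range: [2, 3]
  five_prime_truncation: 0
  divergence: 0.0
  tsd_length: 10
  orientation: antisense
  cluster_length: 300
  cluster_strand: "+"
  weights:
    type: zipf_mix
    top1: 0.12
    top_k: 88
    top_coverage: 0.70
    alpha: 0.5
pirna_sampling:
  total_reads: 200000
  u1_probability: 0.75
  background_fraction: 0.2
  pgf_fraction: 0.85
  pingpong_fraction: 0.0
expression:
  effect_size_top: 1.0
  effect_size_lower: 0.25
  sd: 0.5
  n_non_targets: 300
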