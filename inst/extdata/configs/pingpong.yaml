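# ping-pong dataset: 30% of reads are opposite-strand responders with
# 10-nt 5' overlaps; set pingpong_fraction to 0 for the primary-only null
seed: 5
genome:
  length: 25000
  gc_content: 0.45
  chrom: chr1
genes:
  - gene_id: g1
    n_exons: 3
    exon_len: [250, 300]
    intron_len: [200, 300]
    utr5_len: 100
    utr3_len: 250
    strand: "+"
clusters:
  - cluster_id: c1
    length: 1500
    strand: "+"
pgfs:
  - pgf_id: pgf_g1
    source_gene: g1
    host_cluster: c1
    exon_range: [2, 3]
    five_prime_truncation: 0
    divergence: 0.0
    tsd_length: 10
    orientation: antisense
pirna_sampling:
  total_reads: 20000
  u1_probability: 0.75
  background_fraction: 0.3
  cluster_weights:
    c1: 1.0
  pgf_fraction: 0.7
  pingpong_fraction: 0.3
expression:
  effect_size_top: 1.0
  effect_size_lower: 0.25
  sd: 0.5
  n_non_targets: 200
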