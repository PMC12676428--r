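# partly processed fragment: exons 3-10 of the source gene with the intron
# before the last exon retained, 5'-truncated, mildly diverged
seed: 7
genome:
  length: 70000
  gc_content: 0.44
  chrom: chr1
genes:
  - gene_id: ago2
    n_exons: 10
    exon_len: [200, 240]
    intron_len: [200, 300]
    utr5_len: 120
    utr3_len: 400
    strand: "+"
  - gene_id: dec1
    n_exons: 3
    exon_len: [250, 300]
    intron_len: [200, 300]
    utr5_len: 100
    utr3_len: 250
    strand: "+"
clusters:
  - cluster_id: c1
    length: 5000
    strand: "+"
pgfs:
  - pgf_id: pgf_ago2
    source_gene: ago2
    host_cluster: c1
    exon_range: [3, 10]
    five_prime_truncation: 80
    divergence: 0.03
    tsd_length: 15
    orientation: antisense
    include_intron: true
pirna_sampling:
  total_reads: 50000
  u1_probability: 0.8
  background_fraction: 0.2
  cluster_weights:
    c1: 1.0
  pgf_fraction: 0.8
  pingpong_fraction: 0.0
expression:
  effect_size_top: 1.0
  effect_size_lower: 0.25
  sd: 0.5
  n_non_targets: 300
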