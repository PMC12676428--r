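# one dominant and one minor source cluster for a single target gene:
# the dominant cluster carries a 5'-truncated, 5%-diverged processed
# fragment of exons 3-5 flanked by a 14-bp target-site duplication, and
# receives 81% of the target-engaging emission (81:19 against the minor
# cluster, which carries a fragment of exons 6-8)
seed: 42
genome:
  length: 60000
  gc_content: 0.42
  chrom: chr1
genes:
  - gene_id: spin1
    n_exons: 8
    exon_len: [230, 270]
    intron_len: [250, 350]
    utr5_len: 150
    utr3_len: 500
    strand: "+"
  - gene_id: dec1
    n_exons: 3
    exon_len: [250, 300]
    intron_len: [200, 300]
    utr5_len: 100
    utr3_len: 250
    strand: "+"
  - gene_id: dec2
    n_exons: 4
    exon_len: [200, 260]
    intron_len: [200, 300]
    utr5_len: 120
    utr3_len: 300
    strand: "-"
  - gene_id: dec3
    n_exons: 3
    exon_len: [250, 300]
    intron_len: [200, 300]
    utr5_len: 100
    utr3_len: 250
    strand: "+"
clusters:
  - cluster_id: c1
    length: 4000
    strand: "+"
  - cluster_id: c2
    length: 2500
    strand: "+"
  - cluster_id: c3
    length: 2000
    strand: "-"
pgfs:
  - pgf_id: pgf_spin1_a
    source_gene: spin1
    host_cluster: c1
    exon_range: [3, 5]
    five_prime_truncation: 100
    divergence: 0.05
    tsd_length: 14
    orientation: antisense
  - pgf_id: pgf_spin1_b
    source_gene: spin1
    host_cluster: c2
    exon_range: [6, 8]
    five_prime_truncation: 0
    divergence: 0.05
    tsd_length: 12
    orientation: antisense
pirna_sampling:
  total_reads: 200000
  u1_probability: 0.8
  background_fraction: 0.15
  cluster_weights:
    c1: 0.648
    c2: 0.152
    c3: 0.200
  pgf_fraction: 0.8
  pingpong_fraction: 0.0
expression:
  effect_size_top: 1.0
  effect_size_lower: 0.25
  sd: 0.5
  n_non_targets: 300
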