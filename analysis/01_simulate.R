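#!/usr/bin/env Rscript
# Generate the synthetic study datasets with full ground truth.
#
# Each dataset emulates one figure-level analysis condition:
#   spin1like - one target gene with a dominant (81%) and a minor (19%)
#               source cluster, each carrying an antisense pseudogene
#               fragment (5% diverged; TSDs of 14 and 12 bp)
#   rankcurve     - 200 target genes with Zipf-like planted weights (rank 1
#               = 12%, ranks 1-88 = 70% of targeting piRNAs)
#   ago2like  - a partly processed fragment retaining one intron
#   pingpong  - 30% opposite-strand responder reads (10-nt 5' overlap)
# Truth bundles (FASTA/GTF/BED/TSV) are exported under scratch/datasets/.

source("analysis/00_common.R")

summary_rows <- list()
for (name in c("spin1like", "rankcurve", "ago2like", "pingpong")) {
  bundle <- get_bundle(name)
  out <- file.path(DATA_DIR, name)
  write_truth_bundle(bundle, out)
  summary_rows[[name]] <- data.frame(
    dataset = name,
    genome_nt = nchar(bundle$genome[[1]]),
    n_genes = length(bundle$models),
    n_clusters = nrow(bundle$clusters),
    n_pgfs = length(bundle$pgf_truth),
    n_reads = length(bundle$reads))
  print(bundle)
}
save_table(do.call(rbind, summary_rows), "datasets_summary.tsv")
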