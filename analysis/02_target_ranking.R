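#!/usr/bin/env Rscript
# Target-centered matching and ranking on the rankcurve dataset: which mRNAs do
# swarms of piRNAs converge on, and how much of the targeting pool do the
# top-ranked targets capture?

source("analysis/00_common.R")

bundle <- get_bundle("rankcurve")
pool <- get_pool(bundle, "rankcurve")
index <- build_seed_index(bundle$transcripts)
sites <- match_pool(pool, index)
rank_tab <- aggregate_by_gene(sites)
save_table(rank_tab, "rankcurve_rank_table.tsv")

tf <- targeting_fraction(pool, sites)
tops <- top_target_set(rank_tab, coverage = 0.70)
cat(sprintf("piRNA pool: %d reads, %d unique sequences\n",
            pool$total_reads, nrow(pool$records)))
cat(sprintf("fraction of pool targeting mRNAs: %.3f\n", tf))
cat(sprintf("rank-1 gene %s holds %.1f%% of targeting weight\n",
            rank_tab$gene_id[1], 100 * rank_tab$fraction[1]))
cat(sprintf("top %d targets capture %.1f%% of targeting weight\n",
            length(tops), 100 * sum(rank_tab$fraction[rank_tab$rank <= length(tops)])))
cat(sprintf("at 1e7 piRNA molecules per cell, a 1.6%% targeting fraction is ~%s molecules\n",
            format(molecules_per_cell(0.016, 1e7), big.mark = ",")))

# metagene profile of piRNA 5'-end positions over the top-target set
mg <- metagene_profile(sites, bundle$transcripts, genes = tops)
mg_tab <- data.frame(feature = rep(rownames(mg), each = ncol(mg)),
                     bin = rep(seq_len(ncol(mg)), 3),
                     mean_fraction = as.vector(t(mg)))
save_table(mg_tab, "rankcurve_metagene.tsv")
by_feat <- rowSums(mg)
cat(sprintf("metagene mass by feature: 5'UTR %.3f, CDS %.3f, 3'UTR %.3f\n",
            by_feat["5UTR"], by_feat["CDS"], by_feat["3UTR"]))
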