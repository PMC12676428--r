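#!/usr/bin/env Rscript
# Trace targeting piRNAs of the spin1like dataset to their genomic source
# loci: perfect genome mapping, cluster attribution, per-gene decomposition
# and cis/trans classification.

source("analysis/00_common.R")

bundle <- get_bundle("spin1like")
pool <- get_pool(bundle, "spin1like")
sites <- match_pool(pool, build_seed_index(bundle$transcripts))
rank_tab <- aggregate_by_gene(sites)
target <- rank_tab$gene_id[1]
cat(sprintf("top-ranked target: %s (%.1f%% of targeting weight, span %d nt)\n",
            target, 100 * rank_tab$fraction[1], rank_tab$span_nt[1]))

hits <- map_perfect(pool, bundle$genome)
cat(sprintf("%d of %d unique sequences lack a perfect genomic match\n",
            length(attr(hits, "unmapped")), nrow(pool$records)))
sources <- attribute_sources(hits, bundle$clusters)
dec <- decompose_gene(target, sites, sources)
print(dec)
save_table(cbind(gene_id = target, dec$entries), "spin1like_decomposition.tsv")
save_table(data.frame(component = names(dec$summary),
                      fraction = unname(dec$summary)),
           "spin1like_decomposition_summary.tsv")

labels <- classify_cis_trans(sites, hits, bundle$models)
cat(sprintf("trans-acting fraction of targeting piRNA weight: %.3f\n",
            attr(labels, "trans_fraction")))
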