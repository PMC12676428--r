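#!/usr/bin/env Rscript
# Sequence signatures of the simulated pools: 1U/10A position frequencies
# and the ping-pong 5'-overlap profile with its z10 score.

source("analysis/00_common.R")

bundle <- get_bundle("spin1like")
pool <- get_pool(bundle, "spin1like")
pfm <- position_frequencies(pool)
cat(sprintf("spin1like pool: 1U = %.3f (configured %.2f), 10A = %.3f\n",
            u1_fraction(pfm), bundle$config$pirna_sampling$u1_probability,
            a10_fraction(pfm)))
pfm_tab <- data.frame(position = as.integer(rownames(pfm)), unclass(pfm))
save_table(pfm_tab, "spin1like_pfm.tsv")

z_for <- function(bundle) {
  pool <- collapse_reads(bundle$reads)
  ping_pong_overlap(map_perfect(pool, bundle$genome), pool)
}
pp <- z_for(get_bundle("pingpong"))
cfg0 <- sim_config("pingpong")
cfg0$pirna_sampling$pingpong_fraction <- 0
null <- z_for(simulate_dataset(cfg0))
cat(sprintf("ping-pong dataset z10 = %.1f; primary-only z10 = %.2f\n",
            pp$z10, null$z10))
save_table(data.frame(offset = pp$offsets, pingpong_weight = pp$weight,
                      primary_only_weight = null$weight),
           "pingpong_profile.tsv")
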