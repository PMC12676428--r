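# piswarm — target-centered analysis of pachytene piRNA swarms

Pachytene piRNAs are ~26–32-nt small RNAs, produced in meiotic
spermatocytes from genomic piRNA clusters and loaded onto PIWI-clade
Argonaute proteins. Individually they show little complementarity to
cellular mRNAs, which has long obscured their targets. `piswarm`
implements the target-centered view: it asks which mRNAs accumulate
*swarms* of near-perfect antisense piRNA matches, traces those piRNAs back
to their source clusters, and dissects the pseudogene fragments inside
those clusters that supply the antisense sequence information.

The package is aimed at small-RNA / germline genomics analysts. It covers:

* **Matching rule.** A piRNA targets an mRNA when the reverse complement of
  its guide window (nt 2–21, 1-based from the 5′ end) occurs in the mRNA
  with Hamming distance ≤ 1 (nt 1 and any 3′ tail are never evaluated;
  G:U counts as a mismatch). A pigeonhole seed index accelerates the search
  and is tested to be exactly equivalent to the brute-force matcher.
* **Convergence.** Per-gene aggregation of targeting read weight, target
  ranking, top-target sets by cumulative coverage (e.g. the smallest prefix
  holding 70% of targeting weight), metagene profiles of piRNA 5′ ends over
  5′UTR/CDS/3′UTR (20 bins per feature), and molecules-per-cell scaling
  (fraction × 10⁷).
* **Source attribution.** Exact full-length genomic mapping (1/k weight per
  multi-mapped locus), attribution to annotated clusters by strand-aware 5′
  end, per-gene decomposition (top / second / third / minor <5% / non-cluster),
  and cis/trans classification.
* **Pseudogene-fragment anatomy.** Smith–Waterman discovery of fragments in
  cluster sequence, exon composition, 5′ truncation, processed vs partly
  processed state (retained introns), exact flanking target-site
  duplications (TSDs), and pairwise locus identity.
* **Signatures & expression.** 1U/10A position frequencies, ping-pong
  5′-overlap profiles with a z-score at offset 10, and two-sample
  Kolmogorov–Smirnov comparison of log2 fold-change distributions between
  target groups.
* **Synthetic data.** A generator that plants genes, clusters, fragment
  insertions (with TSDs, truncation, divergence, retained introns), piRNA
  pools (length distribution, tunable 1U bias, background, optional
  ping-pong mates) and expression tables — with complete ground truth, so
  the whole pipeline is testable without any external download.

## Worked example

Simulate the shipped `spin1like` study condition (one target gene; a
dominant and a minor source cluster carrying 5%-diverged antisense
fragments at 81:19 emission; 200,000 reads) and run the full pipeline:

```r
library(piswarm)

bundle <- simulate_dataset(sim_config("spin1like"))
pool   <- collapse_reads(bundle$reads)
pool
#> piRNA pool: 55609 unique sequences, 200000 reads (dropped: 0 with N, 0 by length)

sites <- match_pool(pool, build_seed_index(bundle$transcripts))
head(aggregate_by_gene(sites), 1)
#>   gene_id weight fraction rank span_nt n_unique_pirnas
#> 1   spin1 108594        1    1    1283            4930

hits <- map_perfect(pool, bundle$genome)
decompose_gene("spin1", sites, attribute_sources(hits, bundle$clusters))
#> Decomposition of targeting weight for spin1 (split policy)
#>       top    second     third minor_lt5   non_pic
#>      0.81      0.19      0.00      0.00      0.00

tr <- bundle$pgf_truth$pgf_spin1_a
detect_tsd(bundle$genome[[1]], tr$start, tr$end)$repeat_length
#> [1] 14

u1_fraction(position_frequencies(pool))
#> [1] 0.7998
```

Reading the output: the planted target collects all mRNA-targeting weight
(fraction 1, rank 1) across a 1,283-nt target space; 81% of that weight
maps back to the dominant cluster, matching the planted 81:19 emission; the
fragment insertion is flanked by the planted 14-bp target-site duplication;
and the pool shows the configured 80% 1U bias.

The numbered scripts under `analysis/` run the same steps as a narrative
workflow (simulation → ranking/metagene → attribution → fragment anatomy →
signatures → expression groups), printing what each stage found and writing
its tables under `results/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

## Layout

```
R/                  package code (matching, ranking, attribution, fragments,
                    signatures, expression, synthetic data, IO)
src/                Smith–Waterman and Hamming kernels (Rcpp)
inst/extdata/configs/  shipped study configurations (YAML)
analysis/           numbered workflow drivers over the package
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette (model, parameters, design choices)
scripts/acceptance.R  headline-quantity reproduction script
```
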