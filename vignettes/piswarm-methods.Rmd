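---
title: "Methods: target-centered analysis of pachytene piRNA swarms"
author: "piswarm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: target-centered analysis of pachytene piRNA swarms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piswarm)
```

## The problem and the model

Pachytene piRNAs are ~26-32 nt single-stranded RNAs produced in meiotic
spermatocytes from long precursors transcribed off discrete genomic piRNA
clusters, and loaded onto PIWI-clade Argonaute proteins whose slicer activity
cleaves RNA opposite guide nucleotides 10-11. Individually these piRNAs show
little obvious complementarity to cellular mRNAs; the question this package
addresses is what happens when mRNAs are examined against the *collective*
pool. The analysis is target-centered: instead of asking where one piRNA
matches, it asks which mRNAs accumulate many near-perfect antisense piRNA
matches, where those piRNAs were transcribed, and what sequence element
inside the source locus supplies the antisense information.

The mechanistic picture the pipeline is built to quantify is:

1. **Matching.** A piRNA engages an mRNA in antisense with at most one
   mismatch across guide positions 2-21 (position 1 is held by the PIWI
   protein's MID pocket and is not evaluated; nothing 3' of position 21 is
   evaluated either). Wobble G:U pairs count as mismatches; the comparison is
   ungapped, as the rule is a mismatch count over a fixed coordinate range.
2. **Convergence.** Targeting weight (read counts of all site-bearing
   piRNAs) is aggregated per gene; targets are ranked by their fraction of
   the mRNA-targeting pool, and a top-target set is defined as the smallest
   rank prefix accumulating a chosen coverage (default 70%).
3. **Source attribution.** Each piRNA is mapped back to the genome by exact
   full-length matching (its biogenesis is by precursor fragmentation, so
   the mature sequence is a genomic substring); weight is attributed to the
   annotated cluster containing the strand-aware 5' end, and each target
   gene's swarm is decomposed by source locus.
4. **Fragment anatomy.** Inside the dominant source cluster, local alignment
   against the target mRNA identifies a pseudogene fragment (PGF): a
   retrotransposed mRNA copy, typically 5'-truncated, point-diverged,
   inserted antisense, and flanked by an exact target-site duplication (TSD)
   left by staggered-nick integration.
5. **Signatures and consequences.** Position-1 uridine bias (primary
   biogenesis), absence of position-10 adenosine enrichment and of 10-nt
   5'-overlap pairs (no ping-pong amplification), and upward expression
   shifts of strongly targeted genes when the pathway is removed,
   quantified by two-sample Kolmogorov-Smirnov comparisons of log2
   fold-change distributions.

## Coordinate conventions

All genomic and transcript intervals are 1-based and closed in memory, the
native convention of the IRanges/Biostrings stack this package builds on.
BED stays 0-based half-open on disk and is converted at the file boundary;
GTF is 1-based closed on disk and in memory. piRNA positions are 1-based
from the 5' end, so the evaluated window "nt 2-21" is written exactly as the
field writes it. For a site starting at transcript position $s$ with window
end $w_e$, piRNA nt $k$ pairs with transcript position $s + w_e - k$; the
reported slice position is the transcript base paired to piRNA nt 10, and
metagene profiles use the transcript base paired to the piRNA 5' end (the
last base of the site interval).

## The matcher and its correctness argument

`find_sites_bruteforce()` is the reference implementation: it slides the
reverse complement of piRNA window positions over the transcript and counts
Hamming mismatches ('N' never matches). The production matcher
(`build_seed_index()` + `match_pool()`) splits the 20-nt window into
`max_mismatches + 1` near-equal seeds (the last seed absorbs the remainder
when the window is not divisible). By the pigeonhole principle, any window
placement with at most `max_mismatches` mismatches contains at least one
exact seed, so exact k-mer lookup of every seed slot followed by full-window
verification recovers the brute-force site set exactly. This equivalence is
asserted on planted and random instances in the test suite rather than
assumed. Reads shorter than the window end cannot fill the evaluated
positions and are excluded (and counted); this is a stated interpretation
choice, as is counting G:U as a mismatch.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `window_start`, `window_end` | 2, 21 | piRNA nt | evaluated guide window |
| `max_mismatches` | 1 | count | Hamming budget inside the window |
| multi-target policy | `split` | - | equal split of a piRNA's weight across its target genes (keeps fractions interpretable as pool proportions); `full` credits each gene fully and renormalises |
| top-set coverage | 0.70 | proportion | cumulative fraction defining top targets |
| `total_per_cell` | 1e7 | molecules | scaling for molecules-per-cell estimates |
| `n_bins` | 20 | bins/feature | metagene resolution per 5'UTR/CDS/3'UTR |
| `min_len` (PGF) | 100 | aligned nt | minimum fragment alignment length |
| `min_identity` (PGF) | 80 | % | minimum fragment identity |
| `trunc_threshold` | 50 | nt | missing mRNA 5' end before a fragment is called truncated |
| `min_exon_cov` | 10 | nt | aligned nt needed before an exon is listed as covered |
| TSD `search_window` / `min_len` / `boundary_slack` | 30 / 8 / 5 | nt | flank searched, shortest reported repeat, allowed distance from the insertion boundary |
| SW scoring | +2 / -3 / 5 / 2 | score | match, mismatch, gap open, gap extension (a gap of length $k$ costs $5 + 2k$) |

The PGF thresholds are package choices, not field constants: they are set so
that fragments with up to ~20% divergence are found while random local
alignments are not, and they are exposed as arguments. The truncation
threshold is likewise a parameter, since "5' truncated" has no canonical
cutoff.

## Numerical and algorithmic choices

* **Ranking ties** break lexicographically by gene id after descending
  fraction, so all outputs are deterministic.
* **Position frequencies** use ragged normalisation: a position's
  denominator only includes records long enough to reach it, which keeps
  logos of mixed-length pools well defined.
* **Ping-pong z10** scores offset 10 against the mean and standard deviation
  of the other 19 offsets; the profile accumulates products of read-weighted
  hit weights for opposite-strand 5' ends at each overlap.
* **KS test**: D is computed exactly by evaluating both ECDFs at the pooled
  unique sample values; the p-value uses the asymptotic Kolmogorov
  distribution at effective size $n_1 n_2/(n_1+n_2)$, evaluated through the
  two Jacobi theta series (the small-statistic branch for
  $\sqrt{n}D < 1$, the alternating series otherwise) to machine precision.
  Only asymptotic p-values are offered; the intended group sizes are in the
  hundreds to thousands, and a warning is issued below 8 observations.
  At $n_1 = n_2 = 100$ the asymptotic test is mildly conservative (true
  size ~0.036 at nominal 0.05), which the type-I test accounts for by using
  enough simulations to estimate the rate within the tolerance band.
* **Local alignment** is an affine-gap Smith-Waterman in C++ with
  deterministic tie-breaking; suboptimal hits are obtained by splitting the
  query at each reported alignment and recursing, which guarantees
  query-disjoint segments without score-matrix masking. Fragment chains
  allow a 10-nt subject tolerance at junctions; since alignment ends can
  absorb a few chance-matching bases across a splice junction, the exon
  ordinal at a junction is read a few bases inside each segment and both
  candidate introns are tested.
* **TSD maximality**: the detector enumerates anchored left/right copy
  placements, extends each maximally, discards left-extendable candidates
  (their extension is enumerated separately), and reports the longest repeat
  satisfying the boundary-slack constraints, preferring the copy pair
  closest to the insertion boundaries on ties.

## What the synthetic data emulate

The generator builds a genome compositionally: gene pieces (random sequence
with configured exon/intron/UTR layout), cluster pieces (random sequence
with pseudogene fragments inserted), and random intergenic spacers, shuffled
and concatenated. This matches the data model the pipeline assumes:
single-stranded cluster transcription, fragments inserted with exact TSDs,
point divergence, optional retained introns, optional 5' truncation. Reads
are always genome substrings (strand-aware), so exact genomic mapping is
lossless by construction.

Three generator design choices deserve explanation:

* **1U bias by start-site choice.** With probability `u1_probability` a read
  start is drawn from T-starting positions of the emitting strand, otherwise
  from non-T-starting positions. Bases are never edited, so mapping remains
  perfect, and the configured probability equals the expected 1U fraction
  exactly.
* **Targeting validity at emission.** Cluster emission weights are defined
  over target-engaging reads: positions inside a fragment are eligible when
  the read's antisense window lies within an exonic block and spans at most
  the mismatch budget of divergence mutations. Without this, the realised
  attribution split between two diverged fragments would drift with the
  accidental placement of their divergence mutations (about ±1.5 percentage
  points at the shipped fragment lengths), and the planted attribution
  truth would not be identifiable at desk scale.
* **Distinguishability from the parent gene.** For diverged fragments, reads
  must cover at least one mutated position or one spliced exon-exon
  junction; otherwise they would also match the parent gene's exons
  perfectly and split their mapping weight with a non-cluster locus. With
  zero divergence (as in the rank-abundance config, where attribution is not
  the measured quantity) no such filter is applied.

The TSD insertion point is resampled until the planted duplication cannot be
extended by flank coincidence, so the planted repeat length is exactly the
maximal repeat. Background reads are drawn from intergenic spacers only:
antisense exonic background would plant target sites absent from the truth
tables. Ping-pong responders are emitted as opposite-strand mates whose 5'
ends overlap a partner read by exactly 10 nt; their position-10 base is then
automatically the complement of the partner's 1U, so the 10A signature
emerges from geometry rather than from editing.

Features of real data the generator does **not** emulate: sequencing errors
(a rate knob exists in scope but defaults off, so the unmapped pathway is
exercised only in unit tests), non-uniform precursor processing along a
cluster, RNA secondary structure, isoform diversity (one collapsed exon
model per gene, which is also the analysis-side convention), base
composition beyond a single GC parameter, and multi-chromosome genomes.
Passing the planted-recovery tests therefore demonstrates that the
implementation measures what it claims on data obeying the stated model,
not that the biological values of any particular dataset are reproduced.

## Study conditions and problem sizes

The shipped configurations are data files under `inst/extdata/configs/`.
`spin1like` (seed 42) plants one target gene whose fragments sit in a
dominant and a minor cluster at 81:19 target-engaging emission, divergence
0.05, a 14-bp TSD on the dominant fragment, exons 3-5, 100-nt truncation,
and 200,000 reads with 1U probability 0.8 — mirroring a dominant-cluster
attribution of 81%, fragment identity near 95%, and an exactly recoverable
TSD. `rankcurve` (seed 11) plants 200 target genes with a monotone Zipf-like
weight vector constructed so rank 1 carries 12% and ranks 1-88 carry 70% of
targeting weight, with 200,000 reads. The mid- and tail-rank exponents are
flattened (alpha = 0.5) because a steeper tail over only ~100 lower-ranked
genes would break monotonicity — with few genes outside the top set, each
would carry more weight than mid-ranked genes, and the planted prefix would
not be real. `ago2like` retains the intron before the last fragment exon
(partly processed); `pingpong` emits 30% responder mates. These sizes keep
the full test suite and the acceptance script within a few minutes on one
CPU while leaving sampling error well inside the stated tolerances (the
multinomial error of an 81% share at ~10^5 targeting reads is ~0.1
percentage points).

## Known limitations

* Genomic mapping is exact-match only; a piRNA carrying a sequencing error
  is reported `UNMAPPED` and excluded from decomposition fractions by
  default rather than rescued by mismatched alignment.
* Cluster annotations must be non-overlapping; bidirectional clusters are a
  single annotation with strand `.`, not two overlapping stranded ones.
* The KS p-value is asymptotic; for very small groups use a dedicated exact
  test instead.
* `scan_pgf` reports chains of collinear local alignments; fragments
  rearranged internally (inversions within an insertion) would be reported
  as separate hits rather than one fragment.
* The expression table is consumed, never estimated: differential-expression
  results must come from a dedicated tool, and the synthetic `padj` column
  is a placeholder with the right shape, not a calibrated quantity.
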