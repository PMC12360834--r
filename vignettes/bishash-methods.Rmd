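---
title: "Multi-metric MinHash bisulfite alignment: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-metric MinHash bisulfite alignment: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bishash)
```

## The problem

Bisulfite treatment converts unmethylated cytosines to uracil, read as
thymine after PCR. A directional library therefore yields reads that differ
from the reference by systematic, position-dependent C→T substitutions
(original top strand) or — once the bottom-strand read is
reverse-complemented onto the forward reference — G→A substitutions.
An aligner that demands exact seed matches loses seeds wherever conversion
happened; an aligner that collapses the alphabet (all C treated as T)
keeps the seeds but discards the very C/T distinction that carries the
methylation signal and inflates multi-mapping. The approach implemented
here keeps **both** views simultaneously: similarity between a read and a
reference window is assessed under a family of k-mer equivalence metrics —
exact identity *and* a letter-collapse — and a window is a candidate if
*either* metric finds it similar.

## The multi-metric MinHash sketch

A sequence is represented by its set of distinct k-mers (windows containing
non-ACGT letters are dropped; there is no strand canonicalisation, because
bisulfite conversion is strand-asymmetric and strand handling belongs to
the aligner). The k-mer universe is partitioned into $z = 3^\kappa$ cells
by the first $\kappa$ letters of each k-mer read in a 3-letter collapsed
alphabet, so that conversion cannot move a k-mer across cells. A sketch is
a $z \times \Delta \times R$ grid: for cell $i$, metric $j$ and repetition
$r$, the entry is

$$h'_{i,j,r}(A) = \min_{x \in A \cap \zeta_i} h_{j,r}(x),$$

where $h_{j,r}$ hashes the *collapsed image* of $x$ under metric $j$ with
the seed of slot $(j, r)$. Hashing the collapsed image enforces the
defining constraint that equivalent k-mers receive equal values. Cells
that received no k-mer are *undefined*; since membership depends only on
the prefix, undefined status is constant across metrics and repetitions of
a cell.

Two sketches are compared with the match statistic $\Xi_s$: for each
(cell, repetition), the indicator is 1 when some metric's values are
defined and equal, or when the cell is empty on both sides; a cell empty on
one side only never matches. $\Xi_s$ is the mean indicator. For a single
cell and the identity metric this is the classic MinHash estimator, whose
match probability equals the Jaccard similarity; for the metric family it
estimates a multi-metric Jaccard similarity in which each cell is scored by
its most favourable metric:

$$\mathrm{JSIM}(A,B) = \max_{\pi} \sum_{i=1}^{z}
  \frac{\lvert (A \cap \zeta_i) \cap_{d_{\pi_i}} (B \cap \zeta_i)\rvert}
       {\lvert A \cup B \rvert}.$$

Because the per-cell terms are independent, the maximum over all
$\Delta^z$ metric assignments decomposes cell by cell;
`multi_metric_jaccard()` exploits this, and the test suite checks it
against an exhaustive $\Delta^z$ oracle. The metric-mediated intersection
$\cap_d$ is not fully determined by the defining formula when a collapse
merges several members; this package counts the members of $A$ in the cell
whose collapsed image also occurs among the collapsed images of $B$'s
members — a convention isolated in one operation and exercised directly by
the oracle tests. That convention is mildly asymmetric in $A$ and $B$;
the sketch statistic $\Xi_s$ itself is exactly symmetric.

One derivation step deserves caution: replacing "the expectation of the
best metric per cell" by $1 - \prod_j (1 - E[\Xi_{i,j}])$ is exact only
when the per-metric match events are independent, which holds here because
every slot $(j, r)$ draws an independent seed. The relationship is
therefore *verified empirically* in the acceptance suite (mean $\Xi_s$
against the closed form $\tfrac1z \sum_i [1 - \prod_j (1 - J(c_j(A_i),
c_j(B_i)))]$) rather than asserted as an identity of JSIM.

### Numerical choices

* Hash values are the splitmix64 finalizer applied to the 2-bit-packed
  collapsed k-mer XORed with a mixed per-slot seed, truncated to 53 bits so
  every value is exactly representable in an R double; `NA` marks undefined
  slots. Any avalanche-quality mixer would do; this one is dependency-free
  and identical across platforms.
* Slot seeds derive from the master seed by fixed integer mixing of
  $(j, r)$, so sketches are bit-reproducible and, importantly, the seed of
  slot $(j, r)$ does not depend on the metric list — adding a metric can
  then only add matches, which makes the nested-metric monotonicity
  property hold pointwise, not just in expectation.
* Partition digits are the alphabetical rank of the collapsed letter
  (CT alphabet A, G, T → 0, 1, 2; GA alphabet A, C, T → 0, 1, 2). The
  ordering is an arbitrary fixed convention, documented so that indexes
  are portable.

## Indexing and candidate selection

The reference is cut into segments of length $T$ stepping by $T - \tau$,
with the final segment anchored at the contig end; $\tau$ must be at least
the maximum read length, which guarantees every read window lies entirely
inside at least one segment (a property test checks 200 random geometries).
Defaults are $T = 500$, $\tau = 300$: $\tau$ equals the longest read the
aligner accepts and $T$ keeps segments comparable to read scale, which
keeps the read-to-segment Jaccard similarity — and hence vote counts —
well above the background of unrelated segments.

Each segment is sketched twice: once for the CT index (metrics identity +
C/T collapse, partition under C/T collapse) and once for the GA index
(identity + G/A, partition under G/A). Every defined sketch entry is stored
in an ordered table keyed by (cell, metric, repetition, value) mapping to
the segments carrying it — the R realisation, via a keyed `data.table`, of
a tree-map with a counting pass. Querying a read sketch increments one
vote per agreeing coordinate; segments with votes below
$\max(\text{min\_votes}, \lceil \text{fraction} \times \text{best}\rceil)$
are discarded (defaults 2 and 0.8, capped at 10 candidates). The threshold
is a selectivity/recall trade-off: a read lying near a segment boundary is
fully contained in one segment but shares most of its k-mers with the
neighbouring, partially-overlapping segment, and sampling noise in the
votes occasionally promotes the partial container over the full one. The
downstream effect is a small rate of alignments soft-clipped at a segment
boundary and shifted by a few bases — visible in the evaluation as a
percent-scale incorrect fraction — which we accept as the cost of bounding
extension work; raising `max_candidates` or lowering `fraction` trades
runtime for placement accuracy.

## Bisulfite-asymmetric local alignment

Candidates are resolved by a Smith–Waterman-style local alignment over the
full read × segment matrix with affine gaps (defaults +2 / −3 / −5 first
gap base / −2 per further base). The substitution function is asymmetric:
in CT mode a genomic C against a read T scores as a **full match** while a
genomic T against a read C remains a mismatch; GA mode mirrors this. We
interpret the "no penalty for converted positions" rule as the full match
reward rather than a literal zero, because a zero would systematically
penalise heavily converted (unmethylated) reads relative to unconverted
ones and bias mapping toward methylated regions — the very artefact
wildcard aligners are criticised for. With this choice a fully converted,
error-free copy of a segment window attains exactly the perfect score
(an acceptance property), and disabling the asymmetry makes the DP agree
exactly with a brute-force textbook local aligner (a second acceptance
property).

Traceback prefers diagonal, then deletion, then insertion, making CIGARs
deterministic. The read is mapped by the best alignment across the two
attempts (read vs CT index; reverse complement vs GA index — the
directional-library convention; PBAT/non-directional libraries are out of
scope), with ties broken by contig order then position. A read is
unmapped when no candidate passes the vote rule or the best score falls
below 0.66 of the perfect score. The mapping-quality surrogate
$\min(60, 4(\text{best} - \text{second}))$, zero on positional ties, is
package plumbing, not a calibrated error probability.

## The simulator

The simulator emulates the factors of the desk-scale study design:
directional reads from both strands, a methylation landscape, and uniform
substitution error.

* `generate_reference()` draws i.i.d. bases at a target GC content
  (default 0.42, vertebrate-like) and optionally embeds CpG-island blocks
  (default 1% of the genome in 600 bp islands with elevated GC and planted
  CG dinucleotides). It is a synthetic stand-in: it has no repeats,
  segmental duplications or compositional domains, so mapping accuracy on
  it is an upper bound on real-genome behaviour — which is exactly what a
  correctness test wants, and what a benchmark against real genomes would
  not get from it.
* `assign_methylation()` produces one probability per C site (forward) and
  per G site (the bottom-strand C proxy). "normal" mirrors vertebrate
  biology qualitatively — CpG cytosines 0.8, island CpGs 0.2, non-CpG
  0.02; these are stated assumptions, not reproductions of measured
  values. "random" draws every site from uniform(0,1), the disordered
  landscape of the cancer-like scenario.
* `simulate_reads()` samples uniform (contig, offset, strand) windows,
  converts each cytosine with probability $1 - m$ (per-molecule Bernoulli,
  so coverage of a site varies read to read), then applies uniform
  substitution errors (default 1%; the error model has no indels or
  quality structure by default, matching an aligner that ignores
  qualities). Truth records keep the 0-based origin, strand, and
  conversion/error counts.

## Evaluation

A mapped read is correct when its contig matches and its reported leftmost
position is within 1 bp of the simulated origin (SAM is 1-based, truth is
0-based; the conversion is internal and fixture-tested in both directions).
The false discovery rate is incorrect/mapped, 0 when nothing maps. Strand
agreement is optional (`require_strand`), since positional distance alone
defines correctness; both percent-of-all-reads and percent-of-mapped
denominators are reported.

## Problem sizes and the statistical character of the checks

The end-to-end study runs a 200 kb single-contig genome, 2000 reads of
150 bp, random methylation, 1% error, defaults everywhere
(k = 16, κ = 2, R = 4, T = 500, τ = 300; simulation seed 7, sketch master
seed 42). These sizes keep the full suite in the minutes range on one CPU
while leaving every per-read quantity (votes, scores, conversions) at its
realistic scale; only the *number* of reads and the genome length are
scaled down relative to a production run, so rate estimates carry
binomial noise of order $1/\sqrt{2000}$.

Several properties are statistical by nature (estimator calibration within
3 standard errors). Such bounds, applied per fixture at a fixed seed,
false-alarm at the few-percent level even for an exact implementation;
the suite therefore pairs them with high-power companions (hundreds of
thousands of draws under an exact binomial test) that separate sampling
flukes from genuine bias. Exact properties — oracle equality of the
Jaccard decomposition, of the DP, coverage, determinism, byte-identical
artifacts across thread counts — are asserted with no tolerance.

## Known limitations

* Single-end, directional libraries only; no paired-end mating, no PBAT.
* Whole-segment, non-banded DP: exact but quadratic per candidate;
  acceptable at T ≈ 500.
* The candidate vote threshold can prefer a boundary segment (see above);
  reported positions are then shifted by the clipped prefix length.
* The mapping-quality surrogate is uncalibrated plumbing.
* The simulator's genome lacks repeats; multi-mapping behaviour on real
  genomes is exercised only through the explicit duplicated-region tests.
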