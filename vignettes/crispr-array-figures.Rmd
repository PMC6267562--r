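---
title: "Comparing and drawing CRISPR arrays with crisprCanvas"
author: "crisprCanvas authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing and drawing CRISPR arrays with crisprCanvas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprCanvas)
```

## The problem

CRISPR arrays grow by inserting spacers — short fragments captured from
phages and plasmids — predominantly at the 5' end of the locus, while the 3'
end retains the oldest, most conserved spacers. A set of isolates can
therefore be typed and chronologically compared by their spacer content.
The conventional display is a grid of colored shapes: one row per strain,
one shape per spacer, identical colors marking identical spacers.
crisprCanvas automates that display starting from the GFF3 output of an
upstream CRISPR miner (CRISPRDetect-style: orientation-predicted
`repeat_region` loci with `binding_site`/`Spacer` children). CRISPR mining
itself, array orientation prediction, and protospacer searches are out of
scope; the pipeline begins where the miner ends.

## Spacer extraction

`readCrisprGff()` records each spacer's sample (the GFF3 seqname), locus
ordinal (file order within the sample), position in the array (numbered
5'→3': ascending coordinates on the plus strand, descending on the minus
strand), coordinates, length, and strand. Minus-strand sequences are
reverse-complemented so everything downstream sees array-oriented 5'→3'
sequences; this leans on the upstream orientation prediction, which is why
alignment later searches only the forward strand.

Sequences are taken from a feature attribute when present (`Note`,
`sequence`, `seq`, or `spacer_sequence` — the exact key varies between
miner versions, so several are accepted; attributes are assumed to hold the
forward genomic strand) and otherwise sliced from a companion genome FASTA;
one of the two must be available. GFF3 lengths (field 6) and coordinates
are cross-checked against the sequence; on disagreement the sequence wins
and a warning is raised.

Two sanity checks support the manual-inspection step that should precede
figure preparation. A spacer whose length is strictly more than 1.5× the
dataset mean (or strictly less than mean/1.5) is flagged — the typical
signature of a fused repeat+spacer from a mis-split upstream. The strict
inequality is deliberate: a length landing exactly on the boundary is not
flagged, so engineered boundary cases behave predictably. Differing locus
counts between samples trigger an informational note, because locus
numbering can silently misalign when some genomes lack a locus; renumbering
is judgment-laden and is left to the user, who can edit the spacer FASTA
(`writeSpacerFasta()` / `readSpacerFasta()`, headers
`sample|locus<k>|spacer<j>|start|end|length|strand`) and restart from it.

## Pairwise similarity: the adjusted mismatch count

Spacers are compared by optimal local alignment under a fixed DNA scoring
scheme (match +5, mismatch −4, gap open −12, gap extend −4 per residue —
sensitivity comparable to common DNA defaults of local aligners). Each pair
is scored by the adjusted number of nucleotide mismatches

\[
\mathrm{adj} = L_q - (L_\mathrm{aln} - \mathrm{mismatches} - \mathrm{gaps})
             = L_q - \mathrm{matched\ columns},
\]

which extends the alignment's error count with the unaligned query
overhang: a 25-column perfect alignment of a 30-nt query still scores 5.
Because the optimal local alignment is symmetric in its two sequences, the
two query directions reduce to
\(\min(L_a, L_b) - \mathrm{matched\ columns}\), and that minimum is the
symmetric pair score used for clustering — a good hit in either direction
links the pair.

Numerical choices worth stating:

* **Tie-break.** Among equal-scoring optimal alignments, the aligner
  reports the one with the most matched columns, then the fewest gap
  columns. Maximizing matched columns makes the reported adjusted count
  canonical — the minimum achievable at optimal score — and keeps it stably
  monotone as sequences diverge. Both criteria are additive per column, so
  the lexicographic objective is a valid dynamic-programming target.
* **Ambiguity codes.** `N` (and all other IUPAC ambiguity codes) match
  nothing, including themselves. This is conservative: an uncertain base
  consumes part of the small mismatch budget rather than silently matching.
* **Verification.** The aligner is checked in the test suite against an
  algorithmically independent exhaustive oracle (best global alignment over
  all substring pairs, one unclamped DP per start position) on both score
  and matched columns, and against `Biostrings::pairwiseAlignment()` on
  score.
* **Duplicates.** Identical sequences are deduplicated before the
  all-vs-all pass; tests assert this changes no result.

An adapter (`readFasta36Hits()`) maps externally produced BLAST-like
tabular hits onto the same adjusted score for users who prefer running
their own aligner; gap columns are recovered from the identity fraction.

## Clustering

`clusterSpacers()` links every pair with adjusted score ≤ cutoff and takes
connected components (union-find): if A is similar to B and B to C, all
three form one cluster even when A and C differ by more than the cutoff.
This chaining is intentional and faithful to how spacer identity is used in
typing figures; no cluster-diameter cap is imposed, and no attempt is made
to distinguish diverged spacers from independent acquisition events — with
typical datasets lacking protospacer matches there is no basis to tell them
apart automatically.

The default cutoff of 2 tolerates occasional sequencing errors or point
mutations per spacer; 0 demands strict identity (useful where single-
nucleotide changes are biologically decisive); larger values are more
permissive. Cluster ids are the lexicographically smallest member identity
(C collation, locale-independent), which makes partitions and ids
reproducible across platforms and reruns — a prerequisite for the append
mode.

## Colors

Each cluster gets a pair of random 3-digit HEX codes: square and center
diamond. Two constraints go beyond plain random draws: the square color is
unique per cluster (so clusters stay distinguishable at a glance, and the
4096-value space minus the reserved white bounds the dataset at 4095
clusters — exceeding it raises an error advising a gray-out display), and a
diamond equal to its square is rejected, since it would hide the diamond.
White square + light-gray diamond (`#fff`/`#ccc`) is reserved for graying
out. Draws come from R's seeded RNG; unseeded runs draw and report a seed
so any figure can be reproduced.

With a prior color store (append mode), each stored representative sequence
is re-aligned against the current dataset's unique sequences; a cluster
containing a sequence within the cutoff of a prior representative inherits
the stored pair, and fresh colors are drawn only for genuinely new
clusters. When appended spacers bridge two prior clusters, the merged
cluster inherits from the prior cluster supported by more current members
(tie: lexicographically smaller prior id) — merges are a boundary case the
append concept itself leaves open, and majority support is the least
surprising resolution. Graying modes (`gray_unique`, `gray_shared`)
partition the spacers exactly complementarily, which the tests assert.

## Strain ordering

Sample rows are ordered so that similar arrays sit together. Shared-spacer
counts use multiset overlap per cluster, \(C_{ij} = \sum_c \min(n_{ic},
n_{jc})\): the standard abundance treatment, degrading to presence/absence
for 0/1 counts. All loci of a sample are pooled (the comparison is
strain-level; a per-locus analysis can be run by subsetting the dataset).
Bray–Curtis dissimilarity \(D_{ij} = 1 - 2C_{ij}/(S_i+S_j)\) then feeds
UPGMA (unweighted average linkage), and the left-to-right leaf order of the
guide tree gives the row order. The tree is a display aid, not a
phylogeny — no support values are computed.

UPGMA is implemented in the package because its tie behavior is pinned
down: among equally close merge candidates, the pair whose members appeared
earliest in the input merges first, and each merge keeps the earlier-input
subtree on the left. With all distances equal this degenerates exactly to
input order, and permuting the input can change the order only through this
rule. `stats::hclust(method = "average")` serves as the independent
cross-check (via cophenetic distances) in the tests. Alternatives are a
custom list (`customOrder()`; unknown ids are skipped with a warning,
missing ids appended in input order) or plain input order.

## Rendering

The SVG scene has one row per sample and one column per locus number, with
CRISPR 1 as the rightmost data column and higher locus numbers leftward (a
flag reverses this). Every locus is right-aligned within its column: since
new spacers enter at the 5' end, the conserved 3'-terminal spacers then
share their vertical position across strains, which is what makes shared
history visible. The sample name sits right of the last column. Geometry
defaults (cell 20, gap 2, column gap 30 user units; diamond vertices at the
square's edge midpoints) were chosen once to match the proportions of
published array figures and are fully parameterized (`renderOptions()`).

Output is plain SVG 1.1 with fixed element order and number formatting, so
identical scenes are byte-identical files — asserted against a golden file
in the tests. Spacer-length labels are drawn over grayed cells (optionally
all cells) as an exploratory aid for spotting loci belonging to different
CRISPR-Cas systems. Fonts are referenced, not embedded, and no whitespace
is auto-inserted to align internal homologous spacers: the intended
workflow finishes figures in a vector editor, where such edits are manual
and cheap because every shape is a vector object.

## The synthetic-data generator

`fixtureSpec()`/`generateFixture()` produce seeded CRISPRDetect-style GFF3
(plus optional pseudo-genome FASTA and ground-truth tables) with the
structure the method exploits: samples assigned round-robin to sharing
pools, each pool's first locus ending in a suffix of a common ancestral
array (3' conservation) with novel spacers 5' of it, per-nucleotide
substitutions on shared spacers, minus-strand loci, and `direct_repeat`
features for parser realism. Defaults — 6 samples, 1–2 loci, 3–10 spacers
per locus, lengths ~N(32, 2) clamped to 28–38 nt, 2 pools, substitution
rate 0.02 (≈0.6 expected changes per spacer copy, comfortably inside the
default cutoff), strand flips at 0.3 — are one fixed choice of a realistic
small typing study.

What the generator does not emulate bounds what green tests prove:
real miner quirks (fused repeats, split loci, inconsistent locus
numbering), long-range homology between unrelated spacers, compositional
bias, and datasets at the hundreds-of-genomes scale. Tests on fixtures
demonstrate correctness of the pipeline's logic, not robustness to every
upstream artifact; the manual-inspection warnings exist precisely because
the upstream can be messy.

Test and verification problem sizes are deliberately desk-scale: the
exhaustive alignment oracle runs on ~8–12-nt sequences (1000 pairs) plus a
smaller spacer-length batch, clustering is checked against a boolean
transitive-closure oracle on graphs of up to 50 nodes, and ordering
recovery uses 100 seeded replicates of 9 samples in 3 pools at mutation
rate 0, where contiguous pool blocks are the expected outcome up to
tie-rule edge cases.

## Known limitations

* Transitive chaining can place spacers differing by more than the cutoff
  in one cluster (inherent to the definition).
* Representative-based re-linking in append mode can in principle miss a
  prior cluster whose representative drifted beyond the cutoff from every
  current member; storing one representative per cluster trades this edge
  case for a compact store.
* Bray–Curtis/UPGMA ordering is a display heuristic; it is not a
  phylogenetic reconstruction.
* The color space caps distinguishable clusters at 4095; very diverse
  datasets should use gray-out modes.
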