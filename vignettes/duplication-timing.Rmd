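---
title: "Tracing a gene family's duplication history from similarity networks and microsynteny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing a gene family's duplication history from similarity networks and microsynteny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntrace)
```

## The problem

Whether two present-day genes are orthologs (separated by speciation) or
paralogs (separated by duplication) decides how functional knowledge
transfers between species. In the budding-yeast family
Saccharomycetaceae the question is complicated by an ancient whole-genome
duplication (WGD): a pair of similar genes in a post-WGD species may be
ohnologs born at the WGD, or products of a much younger duplication. The
two histories imply very different numbers of gene losses on the species
tree, and that asymmetry is testable.

`syntrace` implements a desk-scale version of the comparative-genomics
machinery used to settle such questions for ABC-transporter paralogs in
yeasts: delimit the family on a sequence-similarity network, score the
conservation of each member's chromosomal neighborhood, partition members
into sub-lineages (descendants of one ancestral locus), and rank candidate
duplication branches by the gene losses they imply.

## Family delimitation on the similarity network

All-vs-all protein comparisons (ingested as blast tabular files, or
computed with Smith–Waterman/BLOSUM62 for small sets) form an undirected
network whose edges carry the best e-value of each gene pair. Starting
from a seed gene, `traverse()` returns the connected component of the
network constrained at an e-value threshold. Swept across a grid of
thresholds (default exponents −200…−20 in steps of 2), the component size
traces a curve that typically shows plateaus separated by jumps — a jump
marks the threshold at which the traversal escapes into a neighboring
family. `select_threshold()` formalises the usual visual choice: it takes
the longest run of at least `stability_steps = 5` consecutive grid points
whose counts stay within `tol_frac = 0.01` of the run's start, and returns
the run's most stringent point, breaking ties toward stringency. Runs in
which the traversal retrieves only the seed are not plateaus — they mark
thresholds stricter than the seed's nearest edge — and are skipped. The
plateau parameters are package choices: published analyses of this kind
picked thresholds by inspection and reported only the chosen exponents.
When no plateau exists the function refuses with an explicit error rather
than guessing. Multi-seed families are merged by union (`merge_families()`),
with overlaps reported, and known interlopers are flagged via an exclusion
list rather than removed.

Suspect members are flagged, never deleted: proteins shorter than half the
median member length (`len_frac = 0.5`) as candidate fragments/frameshifts,
and members whose mean pairwise distance exceeds the member median by more
than three (raw) median absolute deviations as long-branch outliers. Both
cutoffs are package defaults chosen to be conservative; the source analyses
applied the same ideas by manual blastp checks without numeric rules.

## Microsynteny scoring

For each unflagged member, `build_block()` collects up to 15 neighbors on
each side of the gene on its contig (rank distance, strand-agnostic), with
contig ends marked. Neighbors are assigned to sequence clusters — connected
components of the network at a conservative E−50 — and two members'
blocks are compared cluster by cluster: neighbor pairs are matched
one-to-one greedily by ascending offset sum, and each matched pair
contributes the product of three evidence terms,

* `w_dist = ((k − off_a + 1) + (k − off_b + 1)) / 2k` — conservation close
  to the query weighs more;
* `w_sim` — the identity fraction of the matched pair (1 when the network
  has no direct edge for it, which is recorded);
* `w_clu = 1 / (1 + log10(cluster size))` — neighbors from small clusters
  are unlikely to flank both queries by chance, so they weigh more.

The literature names these three evidence sources but gives no formula;
the multiplicative form is this package's choice, selected to be monotone
in each stated direction and bounded by 1 per match. The edge category is
`strong` at ≥ 5 shared pairs, `weak` at 1–4, `none` at 0; pairs scoring
`none` whose blocks contain unclustered neighbors are rescored with
clusters formed at the permissive E−40 and marked as corroboration-level
evidence. One-to-one matching per cluster stops a single large family
(epimerase-sized clusters of hundreds of members) from inflating counts,
and the query genes themselves never count as shared neighbors.

## Sub-lineages, copy counts and duplication timing

Synteny edges of category `weak` or better define a graph whose connected
components are the sub-lineages; isolated members are singletons, and
near-adjacent members on one contig (`max_gap = 3`) are reported as tandem
pairs. `presence_matrix()` tabulates copies per species and sub-lineage,
collapsing multiple strains of a species by the maximum count, since the
loss arguments are species-level.

`evaluate_scenario()` tests the hypothesis that a sub-lineage's copy arose
on a given branch of a rooted species tree with one branch marked as the
WGD. It reports both loss metrics used in such arguments: the number of
extant descendant species lacking the copy, and the minimal number of loss
branches explaining the absences under Dollo parsimony (presence at the
duplication node, no regain) — computed as the number of maximal all-absent
subtrees. The parsimony cost of a scenario is `1 + Dollo losses`.
`rank_scenarios()` evaluates every branch from the WGD down to the stem of
the carriers' most recent common ancestor and sorts by cost, breaking ties
toward more recent branches. Both metrics are kept because species-level
loss counts drive the "implausibly many losses" argument against an
ohnolog origin, while the Dollo count is the proper parsimony cost of the
alternative single-ancestral-loss explanation.

The bundled `paper_pattern_fixture()` encodes the qualitative pattern that
motivates all of this: on a 14-species tree, one sub-lineage present in
every species and a second present only in the four Saccharomyces species.
Placing the second sub-lineage's duplication on the WGD branch implies
losses in the five non-Saccharomyces species of the post-WGD core clade
(three Dollo loss events); placing it on the Saccharomyces stem implies
none. The fixture deliberately omits post-WGD genera whose sub-lineage
membership the sources leave open (Vanderwaltozyma, Tetrapisispora), so the
five-species count is exact.

## What the simulator emulates — and what it does not

`simulate_genomes()` evolves an ancestral genome (3 contigs × 50 genes of
length-200 random proteins by default) down the fixture species tree.
Per branch, each gene suffers at most one content event: loss
(probability 0.003), tandem duplication (0.001), dispersed duplication or
translocation (10⁻⁵ each); each contig's order is locally shuffled with
probability 0.05; on the WGD branch every contig is doubled and each new
copy is retained with probability 0.15. Proteins accumulate substitutions
at 0.03 expected substitutions/site per branch, which yields
between-species identities of roughly 75–90% — comfortably inside the
regime where the E−50 clustering threshold keeps true lineages together.
Loss dominating duplication, and relocations being an order of magnitude
rarer still, mirrors the strong gene-order conservation of
Saccharomycetaceae; with ±15-gene windows on 50-gene contigs, chance
synteny from relocations is already scale-inflated relative to real
chromosomes, which is why relocation rates sit at the low end.

The "true hit table" is derived from known homology: only genes of the
same ancestral lineage are homologous, identity is the positionwise match
fraction (no indels by default), and e-values come from a calibrated
bit-score model (`raw = 5·matches − mismatches` with the gapped
Karlin–Altschul constants) so that divergence maps onto a realistic
e-value scale. Planted event lists make specific histories reproducible,
and `protect_lineages` conditions a simulation on the survival of the
focal family — the standard conditioning when the question is whether a
*surviving* history is recovered, not whether it survives.

The simulator does **not** emulate indels, rate heterogeneity, codon
structure, selection, subtelomeric repeat turnover or assembly artifacts.
Passing recovery tests on these genomes therefore demonstrates the
correctness of the graph, synteny and parsimony machinery under
known-truth conditions, not robustness to every pathology of real
assemblies; the fragment/long-branch flags and the E−40 corroboration path
exist precisely because real data are messier.

## Numerical and design choices

* E-value 0 is floored at 10⁻¹⁸⁰ (recorded on the network) before any
  log-scale operation.
* Asymmetric directed hits symmetrize to the minimum e-value — permissive,
  matching the traversal's goal of gathering homologs.
* Greedy synteny matching breaks offset-sum ties by lexicographic neighbor
  ids, making scores independent of argument order.
* Neighbor-joining (via `ape::nj`) clamps the rare negative branch length
  to zero, moving the deficit to the adjacent branch; additive matrices are
  recovered exactly, which the tests check against the path-length-matrix
  oracle rather than against another NJ implementation.
* Rooting picks the leaf with maximal mean distance, ties broken
  lexicographically; bootstrap supports come from column resampling of an
  ingested alignment (they cannot be computed from a hit table, and the
  function says so).
* Distance trees use uncorrected 1 − identity by default (Poisson
  correction optional): the lineage logic consumes topology, not branch
  lengths.
* Simulation scale (14 species, 150 ancestral genes, 50 replicates in the
  recovery studies, 20 in the acceptance script) is the package's chosen
  desk scale; the genuine study-scale inputs (10⁶ ORFs, 3×10⁸ alignments)
  are deliberately out of reach and their headline counts are treated as
  documentary context only.

## Known limitations

* Traversal is component-based; a frontier-limited walk could in principle
  delimit families asymmetrically, but no criterion for one is published.
* Sub-lineage partition counts a single weak edge as connecting; in noisy
  data a chance relocation can bridge two sub-lineages (observed in ~2% of
  simulated replicates). The evidence weights expose such bridges (strength
  ≪ strong edges) but the partition itself does not cut them.
* Orthology labels follow synteny; conflicts with tree position are
  reported, not resolved.
* No gene-tree/species-tree reconciliation, no dating, no detection of the
  WGD itself — the WGD branch is an input.
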