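---
title: "Methods: best-reciprocal-hit delineation of hierarchical orthologous groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: best-reciprocal-hit delineation of hierarchical orthologous groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `orthogs`. It is the place to look when a default needs
justifying or a corner-case behaviour needs a precise statement.

## The delineation model

Orthologs are genes that arose by speciation: the descendants, in today's
species, of a single gene of their last common ancestor. An *orthologous
group* (OG) collects all such descendants at a chosen *level of orthology*
— an internal node of a rooted species tree. Because duplications
accumulate over time, OGs at deeper (older) levels are coarser: a family
that duplicated after a radiation appears as one OG at the ancestral level
and as several finer OGs at younger levels.

`orthogs` reconstructs OGs in three stages.

**Homology scores.** Every cross-species gene pair passing a prefilter
(sharing at least `min_shared_kmers = 2` distinct k-mers of length
`kmer_size = 4`) is scored by Smith–Waterman local alignment with BLOSUM62
and affine gap penalties (`gap_open = 11`, `gap_extend = 1`; a gap of
length $L$ costs $11 + L$). Scores below `min_score = 30` are discarded.
These defaults mirror protein-BLAST conventions; the prefilter keeps the
quadratic DP tractable while being permissive at desk scale (two random
300-residue proteins share about 0.6 four-mers in expectation, so
genuinely related pairs — dozens of shared words — are never lost).
Alignment is delegated to `Biostrings::pairwiseAlignment()`; the test
suite checks it against an independently coded quadratic Gotoh DP on
hundreds of random pairs. `X` residues score 0 against everything, a
neutral treatment of masked segments. Raw substitution-matrix scores are
used rather than bit scores: scores are only ever compared *within* one
hit table, so units need only be internally consistent, and imported BLAST
bit scores (12-column tabular, best row per ordered pair) work
interchangeably.

**Best-reciprocal hits.** For each ordered species pair, each gene's best
hit is the maximal-score target, ties broken by lexicographically smallest
target id (every tie-break in the package is lexicographic, which makes
all outputs bit-reproducible). A pair is a BRH iff each member is the
other's best hit. The BRH criterion acts as a lightweight proxy for
reconciling the gene tree with that species pair, without building either
tree explicitly.

**In-paralogs.** Within-species duplicates that postdate the relevant
speciation are co-orthologous to the partner genes and belong in the OG.
A gene $g$ with no BRH of its own attaches to a same-species anchor $m$
(which has one) iff $\mathrm{score}(g,m) \ge \max_p \mathrm{score}(m,p)$
over $m$'s BRH partners $p$ at the level — the duplicates are closer to
each other than the anchor is to its cross-species orthologs. This is the
classic within-species-closer-than-BRH rule; it is on by default and
flag-controlled (`attach_inparalogs = FALSE` disables it), since
co-ortholog handling is a genuine design choice rather than a forced
consequence of the BRH model. It requires within-species scores, which is
why `all_vs_all()` scores them by default.

**Clustering.** OGs at a level are the connected components of the graph
whose vertices are the genes of the level's species and whose edges are
the BRH pairs within the level plus in-paralog attachments. Components
touching a single species are discarded — an OG represents an ancestral
gene of *at least two* of the level's species — and their genes are
reported as unassigned with a reason code. Components are the simplest
faithful reading of "cluster the BRH candidates", and they are exactly
testable against a brute-force BFS oracle. `min_cross_edges` reserves room
for stricter merging in tree mode (require $\ge m$ crossing BRH edges
before two child units merge; default 1).

**Tree mode.** `mode = "tree"` traverses the species tree post-order; at
each internal node the units are the child-level OGs (leaves contribute
single genes), and units connected by at least one BRH edge crossing
between different child subtrees merge. Child OGs that find no partner
persist unchanged at the parent level. By construction every OG is
contained in exactly one OG per ancestral level (the `parents` table), so
the per-level partitions are nested. When in-paralog attachment is off,
the root-level tree-mode partition coincides with the flat per-level
clustering at the root — both are components of the same edge set — and
the test suite asserts this equality on simulated data. With attachment
on, the modes can differ (attachments are resolved per level); both modes
are exposed rather than guessing a single canonical behaviour.

OG identifiers are `og{n}at{level}` with $n$ assigned by descending size,
then smallest member gene id — deterministic and stable across runs.

## Mapping novel proteomes

Mapping places genes from a new genome into *frozen* precomputed OGs: the
OG set is never altered, so incomplete or noisy inputs (e.g. transcriptome
gene sets) cannot skew the reference orthology. Each novel gene is scored
against OG member sequences passing the k-mer prefilter and assigned to
its best anchor's OG iff

$$\mathrm{score} \ge \texttt{accept\_ratio} \times \mathrm{med},$$

where $\mathrm{med}$ is the median pairwise member–member score of that OG
(subsampled to 50 seeded pairs for large OGs). The ratio form makes
acceptance scale-free with respect to sequence length; the default
`accept_ratio = 0.5` accepts genes at least half as similar to the group
as the members are to each other, which in the simulated easy regime
recovers >90% of held-out single-copy genes while leaving unrelated
sequences unassigned. Raising the ratio can only shrink the assigned set
(asserted as a property test). The acceptance rule is this package's own
calibration — mapping rules are generally not standardized across tools.

## Phyloprofiles

For an OG at a level with $N$ species, of which $P$ contain at least one
member, $S$ exactly one and $M \ge 2$ copies ($S + M = P$):

* universality $= P/N$ — how widely the gene is retained;
* duplicability $= M/P$ — propensity to duplicate *where the gene
  exists*; the denominator is present species, not all level species, so
  a narrowly distributed but duplication-happy family still scores high
  (users wanting $M/N$ can recompute it from the counts, which are all
  exported);
* single-copy fraction $= S/N$.

Filters use strict inequality (`universality * 100 > threshold`),
matching the "present in >90% of species" phrasing; a family present in
exactly 90% of species does not pass a 90% filter. Whether such filters
should be strict or inclusive is genuinely ambiguous; strictness is the
documented choice here, and a threshold of 0 disables a filter entirely.

## Genome sampling

Genome sketches are bottom-$s$ MinHash sets over canonical k-mers
(`k = 21`, `s = 1000`, the common Mash operating point): each k-mer is
read as the lexicographic minimum of itself and its reverse complement,
hashed with a seeded splitmix64 finalizer of the 2-bit packing, and the
$s$ smallest distinct hashes kept. Hash values are truncated to their top
53 bits so they are exactly representable as R doubles — a deliberate
representation choice that keeps sketches plain numeric vectors and JSON
round-trippable without loss. The Jaccard index $j$ is estimated from the
$s$ smallest hashes of the merged union, and converted to a distance via
the Poisson k-mer survival model
$d = -\tfrac{1}{k}\ln\!\frac{2j}{1+j}$, capped at 1 when $j = 0$;
identity $= 100(1-d)$.

Clustering at >96% identity uses single linkage (components of the
identity graph) by default: well-sampled clades form *chains* of
near-identical genomes, and requiring all pairwise identities above
threshold (complete linkage, also available via `linkage = "complete"`)
would shatter them. Each cluster's representative maximizes completeness,
then annotation count, then smallest id; the priority of the two quality
keys is configurable because neither ordering is canonical.

## Benchmarking

Reference OG sets ("refOGs") are expert-curated gene sets. For each refOG
the *best combination* of predicted OGs maximizes F1 of the union — since
same-level OGs are disjoint, subset intersection and size are additive,
and the exhaustive search over all nonempty subsets (up to
`exhaustive_limit = 15` candidates) is exact; beyond that a greedy pass in
decreasing-overlap order stops at the first non-improving candidate.
Categories: *exact* (a single predicted OG identical to the refOG),
*akin* (a single OG with F1 ≥ 0.9, not exact — multi-OG combinations are
never exact or akin however high their F1), *other*. "Akin" has no
standard definition; the 0.9 threshold is an explicit knob reported in
the output header. A refOG is *split* when ≥2 predicted OGs overlap it by
at least `min_overlap = 2` genes; each contributing OG beyond the first
is one split event. Both knobs are configurable for the same reason.

The Variation of Information between the predicted and reference
partitions, $VI = H(X) + H(Y) - 2I(X;Y)$ in nats with $0\ln 0 \equiv 0$,
is computed on the genes covered by *both* partitions: predictions cover
many genes outside any refOG, and the comparison concerns the
classification of the benchmarked genes. VI is a true metric (zero iff
identical, symmetric, triangle inequality), which the tests verify
numerically on random partition triples.

Because per-family difficulty varies enormously, summaries also include
cumulative curves — the number of refOGs whose metric exceeds $x$, as a
function of $x$ — rather than only averaged figures.

## The simulator: what it emulates, and what it does not

`simulate_families()` evolves independent gene families along a species
tree with branch lengths: per branch of length $t$, each copy is lost
with probability $1-e^{-\lambda t}$, each survivor duplicates (one extra
copy) with probability $1-e^{-\delta t}$, and every copy's sequence then
mutates per site with probability $1-e^{-\mu t}$, substituting uniformly
among the 19 other residues. Root sequences are i.i.d. uniform over the
20 standard amino acids with lengths $\sim N(300, 50^2)$ truncated at 50
— typical protein lengths. Losses precede duplications within a branch so
a copy cannot duplicate and then vanish in the same step, and the
expected copy number per branch is $e^{-\lambda t}(2 - e^{-\delta t})$,
which agrees with the continuous birth–death mean $e^{(\delta-\lambda)t}$
to first order (the tests check the Monte-Carlo mean against it with a
small allowance for this discretization). The true OG at every internal
node — the extant descendants of each gene copy present at that node — is
recorded, giving exact ground truth at every level.

The substitution model is deliberately *uniform*, not BLOSUM-like: truth
generation must stay independent of the scorer's BLOSUM62 assumptions, or
recovery tests would be circular. Consequently the simulator does **not**
emulate several properties of real proteomes: biased amino-acid
composition, rate heterogeneity across sites and lineages, domain-level
events (fusion, shuffling, partial duplication), horizontal transfer,
gene conversion, or fragmented/missing gene models from imperfect
annotation. Passing recovery tests therefore demonstrates the
correctness of the pipeline's logic under its own model of divergence,
not field performance on real genomes — for that, external benchmarks
against curated refOGs remain necessary.

Study conditions used by the recovery experiments (also run by
`scripts/acceptance.R`): the balanced five-species tree
`((A,B)ab,(C,(D,E)de)cde)root` with every branch length 1.0 — rates are
per unit branch length, and unit branches put the easy regime
($\delta=\lambda=\mu=0.05$) at roughly 14% expected sequence divergence
root-to-leaf, a realistic "comfortable" distance — with 100 families per
regime. The strict regime ($\delta=\lambda=\mu=0$) must be recovered
exactly (every family exact, VI = 0); the easy regime requires mean
per-family F1 ≥ 0.9. The mapping experiment holds species E out of the
easy regime, delineates root-level OGs on the remaining four species and
maps E back, scoring only genes from families that are single-copy in all
five species (for multi-copy families the "true" target OG is ambiguous).
These sizes keep each experiment around a minute on one CPU while leaving
the statistics stable; refOGs derived from simulations keep only truth
groups with ≥2 genes spanning ≥2 species, because predicted OGs span ≥2
species by definition and singleton families could never be scored
"exact".

## Numerical conventions and degenerate inputs

* All tie-breaks are lexicographic (best hits, OG numbering, anchors,
  representatives); identical inputs in any row order give byte-identical
  outputs.
* Local alignment scores floor at 0 (the empty alignment); sequences are
  validated against the 20+X alphabet with errors naming the offending
  position.
* Unlabeled internal tree nodes receive synthetic preorder labels
  `nd1, nd2, ...` so every level is addressable in OG ids; multifurcations
  are accepted as levels; branch lengths are optional everywhere except
  the simulator, which requires them.
* Newick syntax errors report a character offset; duplicate leaf labels
  and leaf/internal label clashes are rejected.
* VI treats $0\ln 0$ as 0 and errors on an empty common universe; `prf`
  returns (0, 0, 0) for an empty prediction.
* Mash distance caps at 1 when the Jaccard estimate is 0; sketches with
  different k refuse to compare.
* Seeded subsampling (`og_reference_score`) saves and restores the
  caller's RNG state, so library calls never perturb user-level
  reproducibility.

## Known limitations

* Connected-component clustering can chain distinct families through a
  single spurious BRH edge; `min_cross_edges` mitigates this in tree mode
  but no gene-tree reconciliation is attempted.
* The greedy best-combination search above 15 candidates is a heuristic;
  it is exact in every regime the package's experiments produce (overlap
  counts are small) and never worse than the best single OG.
* The built-in aligner is quadratic; beyond a few thousand genes, import
  externally computed hits instead of `all_vs_all()`.
* No E-value model, compositional adjustment, or profile search; no
  functional-annotation transfer — mapping links genes to OG identifiers
  only.
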