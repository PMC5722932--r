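---
title: "Methods: microsynteny detection and cluster-history reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsynteny detection and cluster-history reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camps)
```

`camps` implements the comparative-genomics inference behind conserved
ancestral microsyntenic pairs (CAMPs): pairs of genes from two unrelated
families whose adjacency has been conserved across animal evolution and
which share cis-regulatory enhancer blocks. This vignette explains each
model and procedure, the tunable parameters and their defaults, the
numerical conventions, and what the simulator-based tests do and do not
demonstrate.

## Coordinates and pair detection

All coordinates are 1-based inclusive throughout (the convention of both
the stored gene tables and GFF3). Strand matters everywhere: the packaged
human table carries a single transcription direction per pair
(Forward → `+`, Reverse → `-`), interpreting the published "sense
reading" as the shared strand of both genes — the source states that both
members of every pair read in the same direction, but does not print
per-gene strands, so this mapping is a documented assumption of the
fixture. Records with missing or malformed strands are rejected at the
boundary rather than defaulted, because orientation feeds both pair
detection and TSS logic.

Intergenic distance is the simple difference of the facing boundaries,
`d = max(0, max(starts) − min(ends))`, which equals the minimum
base-to-base distance between the two gene intervals: overlapping or
boundary-sharing genes are at distance 0, and no "−1" gap correction is
applied. At the two-significant-figure reporting precision used for all
printed distances the competing conventions agree on every published
value, so nothing downstream depends on the choice. Reported distances
use half-up rounding to two significant figures (142 bp → "0.14 kb").

Microsynteny is operationalised by three criteria
(`pair_criteria()`): maximum intergenic distance 500 kb, maximum 3
interposed genes, and equal strands. The distance default is chosen to
admit genuinely linked but loosely spaced pairs (the coelacanth pairs sit
at 84.5 and 198.8 kb) while rejecting same-chromosome arrangements more
than a megabase apart, which are classified as disrupted rather than
linked. "No or very few genes interposed" is operationalised as ≤ 3; a
gene counts as interposed when its interval midpoint lies strictly
between the facing boundaries, so genes merely overhanging a boundary do
not count. All three thresholds are configuration, not estimates.

When several candidate pairs share a gene, each gene joins at most one
reported pair: candidates are ranked by ascending intergenic distance
(ties broken lexicographically by gene IDs) and claimed greedily. This
makes detection a pure function of the annotation and criteria,
independent of input row order. One consequence worth knowing: enlarging
the distance threshold can only add pairs, but relaxing the interposed or
orientation criterion can admit a *closer* candidate that wins a shared
gene away from a previously reported pair — the greedy matching and
strict monotonicity cannot both hold, and the matching is the behaviour
we keep (the test suite pins down exactly this semantics).

## Cluster presence, Dollo reconstruction and dating

Cluster state per species is one of `present`, `absent` or `unknown`.
`unknown` is first-class: species whose annotation plausibly missed an
ortholog (e.g. an unannotated gene in an otherwise intact region) must
not be scored as losses, so they constrain nothing during
reconstruction. A separate audit (`classify_disruption()`) explains
`absent` cells: both or one member genuinely missing, both present but
beyond the criteria on one scaffold, or on different scaffolds.

Ancestral states are reconstructed under Dollo parsimony — a cluster
arrangement is complex enough that independent re-origin is not a
credible alternative to retention, so the character is allowed exactly
one gain and any number of losses. The gain edge is the one above the LCA
of all `present` leaves, and the loss set consists of the maximal clades
below the gain containing no `present` leaf and at least one `absent`
leaf. This loss set is unique and minimal for the single-gain constraint;
the tests verify it against an exhaustive search that also minimises over
every admissible gain placement, confirming the LCA placement attains the
global minimum. Node ages are annotations supplied by the user (the
packaged eight-species tree carries 820 My on the cnidarian+bilaterian
ancestor); no molecular dating of any kind is performed.

## Duplication counting by reconciliation

Cluster duplications are counted by standard LCA reconciliation of a
rooted binary paralog-cluster tree against a rooted binary species tree:
every cluster-tree node maps to the species-tree LCA of its descendant
leaves' species, and a node whose image equals the image of at least one
child is a duplication. Polytomies are rejected with an instruction to
resolve them rather than resolved silently — the trees in this domain are
small and binary, and a silent resolution could manufacture or hide
duplications. The packaged three-paralog cluster tree stores one of the
two possible sister resolutions among the clusters; both resolutions give
the same count of two duplications at the vertebrate LCA, which the tests
assert explicitly.

## Enhancer blocks and CAMP calls

Enhancer blocks are intervals with IDs; block size is
`(end − start)/1000` at two significant figures. The TSS is the `start`
of a `+` gene and the `end` of a `-` gene. The signed TSS distance is the
distance to the nearest block boundary (0 if the block spans the TSS),
negative when the block lies upstream in the gene's own reading
direction. A block is shared by a pair when both genes are within
`window_kb` of it; the default window of 100 kb covers every published
pair-to-block distance (maximum 74.1 kb) with margin and is monotone:
enlarging it never removes a shared block.

Two caveats about the packaged block table. The published per-gene TSS
distances come from an external annotation source with its own TSS
definitions, so they are stored as data and are not recomputed from the
gene coordinates; CAMP calls here use the TSSs implied by the packaged
gene table. And one row (GH12F014945) prints a 19.1 kb size against a
666 bp coordinate span; it is flagged `size_consistent = FALSE` and
excluded from size checks rather than silently corrected.

## Expression call coding and qPCR arithmetic

The expression module reproduces a descriptive level of analysis, not a
differential-expression method: no dispersion modelling, no
multiple-testing correction. A gene is `expressed` when its mean over all
samples reaches `min_expr` (default 10, a read-count scale on which
single-digit signals are effectively absent); the fold change is
`log2((mean_treated + 1)/(mean_control + 1))` with pseudocount 1; calls
are `up`/`down` at `|log2fc| ≥ 1` (two-fold) and `0` otherwise. The
original survey states no cutoffs, so all three are declared assumptions
surfaced as arguments. Pair co-regulation requires both calls equal and
non-zero. ΔΔCt fold change is `2^(−(mean ΔCt treated − mean ΔCt
control))` with `ΔCt = Ct(target) − Ct(housekeeping)`, and the ΔCt
regression is ordinary least squares with r² as the squared Pearson
correlation (invariant under affine transforms of either axis; a zero
variance predictor is a degenerate-input error).

## The gene-order simulator

The simulator emulates the generative narrative behind the cluster
history — gain of a linked two-gene cluster on one branch, en-bloc
duplications (both genes, their spacing and strands, copied together),
then stochastic decay — so that every pipeline stage can be tested
against known truth without any external data. Event counts per branch
are Poisson with mean rate × branch length (length 1 where the tree has
none); a loss deletes one random cluster gene, an inversion reverses a
random scaffold window and flips strands, a translocation moves a single
gene (unlinking without loss — exactly the disruption mode the audit
distinguishes), and insertions add background genes. One RNG stream,
seeded once from `sim_params()`, governs everything, so a fixed seed
reproduces the output bit for bit. Leaf genomes are laid out at 10 kb
spacing, which keeps intact simulated pairs comfortably inside the
default criteria. A duplication scheduled on a branch where stochastic
events have already destroyed every cluster is skipped, since there is
nothing to copy.

What the simulator does *not* emulate: sequence evolution, realistic
chromosome counts or gene densities, assembly fragmentation, or
annotation error. Passing recovery tests therefore demonstrates the
correctness of the inference logic under the stated generative model, not
robustness to the failure modes of real genome annotations (those are
exercised separately through the `unknown` state and the disruption
audit).

## Problem sizes and numerical choices

The property tests run at sizes where exhaustive oracles are computable:
the Dollo sweep covers every labelled rooted binary 4-leaf topology (15)
crossed with every non-trivial present/absent assignment, plus seeded
random instances at 6–8 leaves with unknowns; reconciliation is checked
against an ancestor-path-intersection oracle on random trees up to 8
leaves; distance and interposed-count computations are checked against
explicit base-set enumeration on 1,000 random instances; and the
simulator round-trip runs 50 seeded replicates on the eight-species tree
(all recovered exactly at zero rearrangement), with loss-only survival
compared to the closed-form `exp(−rate × path length)` expectation within
binomial error. Half-up rounding is used for all two-significant-figure
formatting (so 84,500 bp reports as "85 kb"), with a 1e-9 guard against
binary floating-point underflow of exact halves; ties in greedy pair
matching break lexicographically; and degenerate inputs (empty files,
zero-variance regressors, absent clusters) raise informative errors
rather than propagating NAs.

## Known limitations

Detection is labelled-family pair detection, not genome-wide synteny
block chaining; orthology is taken as given, never inferred. The Dollo
model cannot represent true independent re-gain, and reconciliation
counts duplications only (no loss-aware reconciliation, no transfer).
Ages are annotations, so dating statements inherit whatever uncertainty
the supplied calibration carries. The packaged fixtures transcribe
published tables digit for digit, including two internal inconsistencies
(one printed distance, one block size) that are flagged and asserted
rather than repaired, and one truncated printed coordinate whose
completion is documented in the fixture source.
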