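---
title: "Join-point signatures at copy-number-gain breakpoint junctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Join-point signatures at copy-number-gain breakpoint junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jctsig)
```

## The problem

Nonrecurrent copy-number gains — such as the duplications of the
dosage-sensitive *PLP1* region on Xq22 that cause Pelizaeus-Merzbacher
disease — are products of replicative repair.  When a replication fork
collapses, the exposed single-stranded 3' end can anneal to another
template and restart synthesis (fork stalling and template switching /
microhomology-mediated break-induced replication).  Each template
switch leaves a *join-point*: a position in the sequenced junction
product where two segments that are discontinuous in the reference
genome have been stitched together.  The sequence immediately around a
join-point carries a mutational signature of the annealing event:

* **blunt** fusion: no shared sequence at all;
* a **1-bp match**;
* **microhomology**: a short (2-9 bp) run of perfect identity present in
  both reference substrates but only once in the product;
* **microhomeology**: a longer (typically 7-14 bp) *imperfect* match,
  at >= 70% identity with at most a short gap — interpreted as imperfect
  strand annealing, with the substrate matching the junction read
  perfectly acting as the **priming** strand and the imperfectly matched
  substrate as the **target annealing** strand;
* **insertions** (1-20 bp "small", larger ones of templated or unknown
  origin) from iterative switches;
* junctions mediated by repeats: chimeric **Alu-Alu** or **LINE-LINE**
  elements, and NAHR-like events between **paralogous** low copy
  repeats (LCRs) or self-chain blocks.

`jctsig` implements the detection and classification of these
signatures, the similarity profiling of the reference sequence around
each join-point, and the classification of per-individual copy-number
profiles into rearrangement patterns (single duplication, DUP-NML-DUP,
DUP-TRP-DUP, other complex rearrangements), together with a seeded
simulator that plants all of the above with known truth.

## Coordinates and containers

Intervals are held 0-based half-open internally.  Printed coordinate
pairs `"start-end"` are parsed and emitted unchanged, so the length of
an interval is `end - start`; this reproduces the arithmetic used for
bracketed lengths in published breakpoint tables (a block printed as
`102,778,586-102,779,195 [609 bp]` has `end - start = 609`).

A junction is a read plus two substrate mappings: the *proximal*
interval supports the 5' part of the read, the *distal* interval the 3'
part; either may lie on the minus strand (inverted joins).  The read is
parsed against the reference by maximal exact prefix/suffix matching;
when several splits are possible (the overlap *is* the microhomology at
read level) the anchor is set to the maximal proximal prefix and the
overlap length recorded separately, so downstream calls do not depend on
the split.  Reads shorter than two flanks are flagged `short_read`,
never rejected; reads with an unmapped end are flagged and withheld from
classification with an explicit reason.

For each join-point, 150 bp of reference on each side of each break
(300-bp windows, minus-strand substrates reverse-complemented first) are
extracted with the join-point at a common anchor column; windows
truncated at contig edges are shortened and flagged.

## Detector definitions and the open choices behind them

**Microhomology** is the maximal contiguous run of identical columns
around the anchor when the two windows are compared position by
position.  `N` matches nothing, including another `N`.

**Microhomeology** is searched as an alignment segment anchored at the
join-point (spanning or abutting it; segments are built independently on
the two sides of the anchor, so no gap column crosses it), within
`mhe_search_radius` (30) columns of the junction.  A qualifying segment
must satisfy, with the default `signature_params()`:

* at least `min_microhomeology_len` (5) columns;
* identity >= `microhomeology_identity_cutoff` (0.70), computed as
  matched columns over *all* segment columns — gap columns count against
  the denominator (a `"nongap"` switch is provided for sensitivity
  analysis);
* at most `max_gap_runs` (1) gap run of at most `max_gap_run` (2) nt,
  followed — moving away from the junction — by at least
  `min_post_gap_match` (2) matched columns (a `"toward"` switch flips
  the direction, which the published wording leaves open);
* first and last columns matched, and at least one non-matched column
  (an all-match block is a microhomology, not a microhomeology);
* an alignment score at least `mhe_min_gain` (2) points above the score
  of the bare exact microhomology at the join-point.

Among qualifying segments the highest-scoring wins (match +1, mismatch
-1, gap open -2, gap column -0.5 — the same scheme as the global
aligner), with ties broken by length, then identity, then segments
spanning the join-point, then the proximal-side extent.

Three of these rules deserve comment, because the verbal definition
("70% identity, at most a 2-nt gap, >= 5 bp") underdetermines an
algorithm:

1. *One gap run, not many.*  If any number of 2-nt gap runs is allowed,
   a segment search on completely random 30-bp flanks almost always
   finds 20-40-column "segments" at 70% identity — the definition
   becomes vacuous.  Reading "a maximum 2-nt gap" as a single short gap
   keeps the false-discovery behaviour of the detector in line with the
   published counts, where microhomology and microhomeology are
   categories of comparable frequency.
2. *Score-first selection.*  A longest-first rule lets any qualifying
   segment absorb score-neutral mismatch padding (append one mismatch
   and one accidental match and the segment grows while staying above
   the cutoff), so no planted block length would ever be recoverable.
   Maximising the alignment score makes the reported block the locally
   best imperfect match; the length/identity tie-breaks only order
   equal-score candidates.
3. *The score margin over the exact microhomology.*  A perfect 7-bp
   microhomology with a one-column imperfect fringe should not be
   re-labelled microhomeology; requiring the segment to beat the bare
   microhomology score by two net matches implements the footnote logic
   by which the two categories stay disjoint, in the same spirit as the
   published requirement of two matched bases after a gap "to lower the
   impact of spurious match".

The **priming side** falls out of the window construction: the read
follows the proximal window left of the anchor and the distal window
right of it, so a segment whose imperfections are confined to the left
flank is primed by the proximal substrate, one with imperfections only
on the right by the distal substrate, and imperfections on both sides
leave the priming side undetermined (as for join-points with a
microhomology in the middle of the microhomeology).  The call also
records whether the exact microhomology sits at an end of the segment or
inside it.

**Chimeric repeat junctions** are called from annotations: both
breakpoints inside elements of the same class (Alu, LINE, or the
paralogous LCR / segmental-duplication / self-chain group), with the
relative orientation (direct/inverted) derived from element orientations
and substrate strands.  Missing annotations yield `none` with an
explicit flag.

**Category precedence** is: chimeric classes > insertion >
microhomeology > microhomology (>= 2 bp) > 1-bp match > blunt.  The
2-bp microhomology threshold follows the reported 2-9-bp size range
(the tabulated row label "> 2 bp" notwithstanding).  Every call retains
all raw measurements regardless of its category; micro-signatures are
not tallied for chimeric junctions.

## Similarity profiles

The two windows are aligned globally (Needleman-Wunsch, affine gaps,
match +1 / mismatch -1 / gap open -2 / gap extend -0.5; the parameters
are unstated in the original workflow, these are conventional nucleotide
settings and every property asserted by the package is robust to them)
with the category-defining block — the microhomeology when present, else
the microhomology, else the bare join-point — constrained to align
column-to-column in the centre.  The aligner is written from scratch and
is cross-checked in the test suite against an independent implementation
over thousands of random pairs; ties are resolved deterministically so
reruns are byte-identical.

Per column, similarity is the fraction of matched columns in a centred
20-column window, over columns where neither sequence has a gap; windows
at the alignment edges use the available columns, and windows containing
only gap columns yield a gap marker (rendered white in heat maps,
between the blue-low/orange-high colour scale).  Each junction yields
two orientations — proximal-as-base and distal-as-base — which form the
two bands of the heat map; both a numeric TSV and a PNG are written.

For the aggregate view, profiles are grouped as in the published
four-group comparison: both sides of blunt junctions, both sides of
microhomology-only junctions, and the priming and target-annealing sides
of microhomeology junctions (undetermined priming sides are skipped).
Mean similarity is reported per group for every bp within 150 bp of the
block edges, plus a centred moving average (width `smooth_width`, 9 by
default) standing in for an unspecified regression smoother —
deterministic and dependency-free.

## The simulator and what passing tests mean

`simulate_reference()` draws i.i.d. bases at a target GC (0.41 by
default, a genome-like composition).  `plant_junction()` writes a window
pair around two sampled loci that carries *exactly* one requested
signature, and verifies the plant with the package's own detectors,
resampling flanks that create any accidental signature exceeding the
planted one; this rejection step is what makes truth-based tests exact
rather than probabilistic.  Planted microhomeologies realise their
identity on the discrete grid k/L (the truth table stores the realized
value) with mismatches only; lengths are drawn from 7-14 columns and
identities from 70-90%, the observed spectrum.  Insertions distinguish
templated (copied from a recorded third locus) from non-templated
(random) origin, both classed "insertion".

`simulate_rearrangement()` builds a replication plan — an ordered list
of oriented reference pieces forming the derived haplotype — for each
supported pattern (`DUP`, `DUP-NML-DUP`, `DUP-TRP-DUP` in its
inverted-triplication form, `DUP-NML-DEL`, `DUP-QUAD-TRP`,
`DUP-NML-DUP-NML-DUP`), derives the copy-number profile from the plan's
per-base coverage, and emits one junction per reference-discontinuous
adjacency, so structure consistency (junction reads are contiguous in
the derived haplotype; coverage equals the profile states) holds by
construction and is asserted in the tests.  Junctions can be withheld as
explicitly "unresolved", mirroring junctions that resist sequencing.

`simulate_cohort()` generates a complete miniature cohort on one shared
60-kb chromosome with a distal LCR cluster (LCRC, LCRA1a, LCR2, LCR3,
LCRA1b, LCRD; LCRA1b is an inverted ~99%-identical copy of LCRA1a).
Mixture fractions are *apportioned* (largest remainder), not drawn, so
the realised cohort equals the mixture exactly: 66/18/6/10% across the
four pattern classes, 56% of individuals with the distal-most breakpoint
in the cluster, one third of DUP-NML-DUP individuals with the
copy-neutral region inside the LCRA1a..LCRA1b span (the
H2-inversion-haplotype candidates), and join-point categories at the
observed spectrum.  The DUP-TRP-DUP inversion junction and the H2-style
LCRA1a/LCRA1b junction are emitted as paralogous-repeat (chimeric LCR)
junctions via the annotations; all other adjacencies receive planted
signatures on their distal side.  Individuals with forced LCR placements
are laid out first so the repeat blocks are not crowded out;
breakpoints are kept 100 bp apart so planted windows never interfere.

What the simulator does *not* emulate: probe-level array noise or
segmentation (profiles are emitted pre-segmented), sequence context
(repeat density, GC structure) of real flanks, SNV/indel replication
errors around junctions, and insertions are absent from the derived
haplotype model (they do not affect copy counts).  Passing the planted
recovery tests therefore demonstrates that the detectors invert the
generator's (faithful but idealised) signature model — it does not
certify calling accuracy on Sanger reads with sequencing artefacts.

`simulate_similarity_fixture()` emulates the similarity landscape around
microhomeology join-points: outside the planted block, the distal window
is a copy of the proximal one mutated with probability growing linearly
with distance (slope 0.005/bp, ceiling 0.75 — the identity floor of
unrelated sequence under alignment).  The aggregate curves on this
fixture fall from ~85% near the block to the alignment background.
Because windowed similarity saturates at that background beyond ~80 bp,
the decay assertion is evaluated on 10-bp binned means over the first
70 bp, where the planted gradient lives; at 120 junctions the binned
means are strictly decreasing across seeds.

## Problem sizes and numerical choices

The test suite checks the microhomology detector against a brute-force
extension oracle on 10,000 random window pairs, the microhomeology
detector against an exhaustive segment-shape enumeration on 1,000 pairs
of 60-bp windows (with the enumeration itself validated against full
recursion on tiny windows), the aligner against an independent global
aligner on 1,000+ random pairs up to 30 bp, and planted-category
recovery on a 1,000-junction fixture spanning all eight categories.
The acceptance script regenerates a 50-individual cohort and the
1,000-junction fixture from its `--seed` and recomputes every reported
number at run time.  Ties everywhere are broken deterministically;
reruns with identical configuration are byte-identical, and every output
file records the package version, seed and parameter fingerprint in its
header.

## Known limitations

* The microhomeology search is anchored at the join-point in both
  substrates; a homeologous block offset from the junction in one
  substrate only would not be reported (nor is it defined by the
  published procedure).
* With the `"nongap"` identity denominator the segment choice still
  maximises matches first, so the reported identity is exact but the
  chosen segment may not be the global optimum under that denominator.
* The H2-haplotype rule is a flag, not a re-classification: array data
  alone cannot distinguish a single duplication on the inverted
  haplotype from two duplications with an inversion between the repeats,
  and the package does not adjudicate.
* Inversion orientation is taken from junction substrate strands; it is
  never inferred from copy-number data alone.
* The meta-analysis aggregate column of published join-point tables
  pools previously published cohorts whose raw data are not shipped
  here; the package reproduces the current-study-style quantities from
  its synthetic cohort instead.
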