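---
title: "Methods: comparative analysis of compact circular mitogenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of compact circular mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its models, conventions and design
choices, in the spirit of the methods vignettes of the established
phylogenetics and expression-analysis packages: what each stage assumes, which
tunable parameters matter, what the synthetic-data generator does and does not
emulate, and where the genuinely open design decisions were settled.

## The data model and its coordinate conventions

A `mito_genome` is a circular molecule annotated with up to 37 genes: 13
protein-coding genes (PCGs), 22 tRNAs and 2 rRNAs, each on the major (J) or
minor (N) strand. Coordinates are 1-based and inclusive throughout, the
dialect of published mitogenome annotation tables; conversion to 0-based
half-open arithmetic happens only inside sequence slicing. A feature spanning
the origin of the circle has `start > end` and `wraps_origin = TRUE`, and its
length gains one genome length.

The genome length is resolved in a fixed order: the sequence length when a
sequence is present, else a declared length, else the maximum feature end.
The packaged *Polypylis* sp. TS-2018 fixture (GenBank OR684570) illustrates
why the rule matters: three lengths circulate for this genome (13,745 bp as
the last annotated coordinate, 13,746 bp in the deposited record's
description, 13,749 bp elsewhere), and the fixture keeps all three in an
attribute while using its own coordinate space (13,745 bp) for arithmetic.
Under that choice the circular wrap junction trnP→nad6 is exactly abutting
(INC = 0); under 13,746 bp it would be a 1 bp spacer. Statistics that depend
on total length therefore always use `genome_length()`, never a hard-coded
constant.

Validation enforces what the biology guarantees: unique gene names drawn from
the canonical vocabulary (warnings for names outside it, so draft annotations
survive ingestion), positive lengths, tRNAs of at least 50 bp, stop codons in
{TAA, TAG, TA, T}, and the polyadenylation arithmetic — a PCG's length modulo
3 must equal the length of its annotated stop remnant (0 for TAA/TAG, 1 for
T, 2 for TA). Gene-name synonyms (COI → cox1, 16S → rrnL, tRNA-Leu + anticodon
→ trnL1/trnL2, …) ship as an editable TSV; labels that cannot be resolved —
for example a trnL without an anticodon — are retained and flagged rather
than guessed or dropped.

## Composition, skews and gene junctions

AT skew = (A − T)/(A + T) and GC skew = (G − C)/(G + C) are computed either
from sequence or from printed base proportions (accepted when they sum to 1
within 0.5%). Whole-genome skews are computed on the major strand; per-gene
statistics are computed on each gene's coding strand, so a minus-strand gene's
skews describe its mRNA-sense composition. Skews with empty denominators
(e.g. a G+C-free sequence) are NA with a warning, not 0. Reports round
percentages to 1 decimal and skews to 3; internal values keep full precision.

The intergenic nucleotide count at a junction is fixed as
INC = start(next) − end(prev) − 1: positive values are spacers, negative
values overlaps, zero abutting genes. In circular mode one wrap junction
(last feature → first, across the origin) is added. "Longest" spacer and
overlap are tie-broken by first occurrence in coordinate order, for
determinism. A conservation identity ties the books together: summed feature
lengths plus summed signed INC over all circular junctions equals the genome
length exactly.

One caveat a user of published annotation tables should know: such tables
sometimes print an INC column that is not consistent with their own
coordinate columns (the packaged fixture's source table disagrees with its
coordinates at 8 of 36 internal junctions, and its prose totals match
neither). This package treats coordinates as the single source of truth and
always recomputes INC from them; on the fixture that yields 13 spacers
(106 bp) and 13 overlaps (69 bp), with the longest spacer (43 bp,
cox3–trnI) and longest overlap (20 bp, nad5–nad1) agreeing with the
published prose.

## Codon usage under the invertebrate mitochondrial code

The genetic code is fixed to NCBI translation table 5 (AGA/AGG = Ser,
ATA = Met, TGA = Trp; stops TAA/TAG only), the code under which these genomes
are annotated; it is deliberately not configurable. Codon extraction
validates the annotated start codon against the first triplet, drops the
terminal stop whether complete or incomplete (T/TA, completed to TAA by
polyadenylation), and tolerates internal in-frame stops with a warning
because draft annotations contain them. Start codons are counted as ordinary
codons; with stop codons removed, the 13 fixture PCGs yield exactly
(10,606 − 31)/3 = 3,525 codons.

RSCU(c) = k · n(c) / Σ n over the synonymous family of size k. Families are
defined by table 5 excluding stops (so serine has 8 members and there are no
single-codon families); within every observed family the mean RSCU is exactly
1, an invariant the tests assert at machine precision. Codons of an entirely
unobserved amino acid get NA with a warning; unobserved codons in an observed
family get 0.

## Ka/Ks by Nei–Gojobori counting

Site counts: each codon position contributes the fraction of its three
possible single-nucleotide changes that are synonymous, with changes creating
stop codons removed from the denominator at that position, so n + s = 3
exactly for every sense codon. Difference counts between two codons average
the synonymous/nonsynonymous step classifications over all orderings of the
differing positions, with equal weights; pathways passing through a stop
codon are excluded, and in the (rare) case that every minimal pathway is
blocked the unrestricted average is used so the codon pair still contributes.
Proportions pN = Nd/N and pS = Sd/S are Jukes–Cantor corrected,
Ka = −¾ ln(1 − 4 pN/3), and pN or pS ≥ 3/4 is reported as saturation (the
correction is undefined there) rather than silently clamped. Codon pairs
containing gaps, ambiguity codes or stops are dropped pairwise.

Classification uses the conventional thresholds — ratio above 1 positive,
below 1 purifying — with a ±0.05 neutral band around 1 because exact equality
never occurs in floating point. The band is a knife edge by construction:
with a few hundred codons the sampling noise of the ratio is an order of
magnitude wider than the band, so sequences generated at a true ratio of 1
land on either side far more often than inside it. Recovery checks therefore
hold the neutral case to the median-accuracy bound only, and assert the
directional classifications where they are well defined.

Genus summaries score every species against a designated reference genome
(the panel's outgroup, matching how such comparisons are usually run), with
an all-pairs mode available; genus means are taken over defined (non-NA)
ratios only, and per-gene overall means are sorted descending. Published
per-gene averages computed with other software are treated as qualitative
rank anchors, not bit-exact targets: the algorithm variant and alignment
behind them are not fully specified, and the packaged data are annotations,
not the full sequence panel.

## Gene-order rearrangements

A genome's order is reduced to a circular signed permutation. Normalization
rotates the circle so cox1 comes first and, if cox1 lies on the minor strand,
reflects the whole reading first — a pure, idempotent canonical form
invariant to the arbitrary linearization of a circle. cox1 anchors the frame
because it is present in every complete mitogenome and is not involved in
the rearrangements this model targets.

Event detection finds the smallest set of genes whose deletion makes the two
normalized circular signed orders identical; each deleted gene is one event,
typed a reverse transposition when its orientation differs between the
normalized orders and a transposition otherwise. The search is exhaustive
over subsets of the candidate genes (those whose signed neighbor context
differs), smallest cardinality first, with one sound pruning: a gene whose
orientation differs must belong to every solution, since deleting other genes
never changes a sign. Beyond 12 events the search stops with a "complex
rearrangement" error — the single-gene event model is not meaningful at that
distance, and dedicated rearrangement-distance algorithms (inversion/DCJ
sorting, tandem-duplication-random-loss inference) are deliberately out of
scope.

Minimality alone does not always determine the event set. Moving a block of
neighbors can be explained equally well by moving the block or by moving the
genes around it: for the panel's types A vs D, {trnC, trnD, trnW} and
{cob, trnD, trnW} are both minimal. Ties are broken by preferring the
solution that moves the fewest protein-coding genes, then lexicographically.
The domain motivates the first key: observed mitogenome rearrangements
overwhelmingly relocate tRNAs and small RNAs, not kilobase protein-coding
genes, and on the packaged panel this preference reproduces the published
event narrative (ten tRNAs and rrnS rearranged across six arrangement
types). Multi-gene blocks are reported as per-gene events, matching how such
events are described in the comparative literature.

Arrangement types are equivalence classes of identical normalized orders,
labelled A, B, C, … by first appearance in input order; the packaged panel
file lists genomes in the published panel order so the labels match. Two
placements the source annotations do not determine — where trnD sits in type
A and where the reversed trnQ lands in type F — are synthetic choices
documented in the data file's comments; they do not affect typing or the
census.

## The phylogeny layer

Tree inference here is deliberately desk-scale: pairwise alignment distances
plus neighbor joining stand in for the Bayesian/ML machinery used in
full-data studies, because the quantity this package can honestly test is
topology recovery, not posterior support. Alignment is global
Needleman–Wunsch with a linear gap penalty and a fixed traceback preference
(substitution, then gap in the second sequence, then gap in the first) so
results are deterministic; protein-coding genes are aligned as amino acids
under table 5 and the codons back-threaded, so nucleotide alignments contain
only whole-codon gaps. Distances are p-distances over gap-free columns with
Jukes–Cantor (nucleotide) or Poisson (amino acid) correction, the corrected
form being the default; saturated pairs are flagged and capped at the largest
finite entry. Neighbor joining is the standard Q-criterion algorithm via
`ape::nj`, with negative branch lengths clamped to zero and counted.
Supermatrices concatenate per-gene alignments in alphabetical order under
four flavors — P123 and P123R (all codon positions, without/with rRNAs), P12
and P12R (third codon positions of protein-coding partitions dropped; rRNA
partitions are never masked) — and emit a partition map whose post-masking
lengths tile the matrix exactly. Published residue counts for such matrices
depend on the aligner and data release and are not reproduction targets.

## What the synthetic-data generator does and does not emulate

`simulate_genome()` draws a sequence honoring an annotation: intergenic and
RNA-gene positions come i.i.d. from a target base composition (default 33.3%
A, 42.0% T, 11.5% C, 13.3% G, the strongly AT-biased composition typical of
these genomes), protein-coding genes get their annotated start and stop
codons and stop-free interiors, and overlapping coding regions — different
frames, sometimes different strands — are reconciled by constraint-repair
sweeps that only ever mutate bases not pinned by a start or stop codon. The
realized A+T fraction lands within about two points of the target; the
rejection of stop codons in coding interiors is the main perturbation.

`evolve_panel()` evolves codon sequences along a tree under an omega-thinned
proposal process: single-nucleotide changes are proposed at a Poisson rate
per codon position (default 1 per unit branch length), proposals creating
stops are discarded, synonymous proposals are accepted at a base probability
and nonsynonymous ones at omega times it, so the realized
nonsynonymous/synonymous rate ratio per opportunity is omega by
construction. Realized accepted counts per branch are recorded as ground
truth. This is deliberately not a full Goldman–Yang model: there are no
indels (alignments are columnar by construction), no transition/transversion
asymmetry, no among-site rate variation, no strand-asymmetric mutation
pressure, and tRNA/rRNA partitions evolve under an unconstrained uniform
process. Passing tests on these data therefore demonstrate that the
estimators recover the parameters of a process satisfying their own
assumptions — not that real snail sequences satisfy those assumptions. The
default tree hard-codes the published 16-taxon topology for this group
(Bulinus sister to all other genera; Polypylis sister to Anisus + Gyraulus;
Planorbella + Biomphalaria sister to that clade; Radix outgroup) with 0.05
substitutions/site per edge, so monophyly checks read naturally.

## Numerical choices and problem sizes

* Neutral classification band: ±0.05 around 1 (see above for its width
  relative to sampling noise).
* Saturation guard: pN or pS ≥ 3/4, and p-distance ≥ 3/4 (nucleotide) or 1
  (amino acid) for the distance corrections.
* Parameter-recovery checks: two-taxon trees of total depth 0.2, 350 codons,
  20 replicates per omega in {0.1, 1.0, 2.0} — sizes at which a run finishes
  in seconds while medians stabilize within a few percent.
* Topology recovery: ten seeded panels on the reference topology, P123R
  supermatrix (~12.3 kb), JC distances; recovery is expected in at least
  9 of 10 seeds and has been observed in 10 of 10.
* Rearrangement search validation: thirty random circular signed orders of
  7–12 genes with 1–3 scripted events, compared against an unrestricted
  brute-force minimal deletion search. Scripted events never move cox1,
  which anchors the normalization frame (in real 37-gene mitogenomes cox1
  does not relocate).
* All randomness flows through a single integer seed per entry point
  (`simulate_genome`, `evolve_panel`, `run_pipeline`,
  `scripts/acceptance.R`), using R's default integer-state generator, so
  outputs are reproducible across platforms.

## Known limitations

* The NG86 estimator is the classical equal-weight counting method; it is
  not a maximum-likelihood codon model and inherits NG86's known mild biases
  at high divergence and extreme base composition.
* Single-gene transposition/reverse transposition is the entire
  rearrangement vocabulary; inversions of multi-gene blocks, duplications
  and TDRL events are out of scope and will surface as multiple single-gene
  events or a "complex rearrangement" error.
* The GenBank reader is a minimal flat-file parser for the feature types
  this pipeline consumes (gene/CDS/tRNA/rRNA with simple or
  complement/join locations); it is not a general GenBank implementation.
* Sequence-free genomes support annotation statistics only; composition,
  codon and selection stages require a sequence (real or simulated).
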