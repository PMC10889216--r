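# mitocompare

Comparative analysis of compact circular mitochondrial genomes in R.

Gastropod mitogenomes — such as those of the ramshorn snails (Planorbidae)
that host human schistosomes — are small (13.5–14.3 kb), strongly AT-biased
circles carrying 37 genes (13 protein-coding OXPHOS genes, 22 tRNAs, 2 rRNAs)
on two strands, with overlapping gene junctions and incomplete stop codons
completed by polyadenylation. Comparative studies of such genomes keep
recomputing the same battery of quantities: base composition and strand
skews, intergenic/overlap bookkeeping, codon usage bias, selection pressure
per gene, gene-order rearrangements and a phylogeny. `mitocompare` packages
that battery as tested, reusable functions for people working on mollusk (or
any compact invertebrate) mitogenomes, exercisable entirely on packaged
fixtures and seeded simulations — no downloads required.

## What it computes

* **Genome model** — an annotated circular genome (`mito_genome`) with
  1-based inclusive coordinates on the major (J) strand, origin-wrapping
  features, GenBank flat-file and TSV feature-table readers/writers, and a
  gene-name synonym table mapping GenBank labels onto the canonical 37-name
  vocabulary (`cox1`…`trnY`, with `trnL1/trnL2`, `trnS1/trnS2` resolved by
  anticodon).
* **Composition and junctions** — AT/GC content,
  AT skew = (A − T)/(A + T), GC skew = (G − C)/(G + C), per gene and
  genome-wide; intergenic nucleotide counts at every gene junction,
  INC = start(next) − end(prev) − 1 (positive = spacer, negative = overlap),
  including the circular wrap junction.
* **Codon usage** — codon extraction under the invertebrate mitochondrial
  code (NCBI table 5: AGA/AGG = Ser, ATA = Met, TGA = Trp) with incomplete
  stop codons (T/TA) handled; pooled counts over the 13 PCGs; amino-acid
  frequencies and relative synonymous codon usage,
  RSCU(c) = k · n(c) / Σ_family n, whose family means are exactly 1.
* **Selection** — pairwise Ka/Ks by the Nei–Gojobori (1986) counting method:
  fractional synonymous/nonsynonymous site counts per codon, equal-weight
  averaging over minimal mutational pathways (stop-crossing pathways
  excluded), Jukes–Cantor correction Ka = −¾ ln(1 − 4pN/3), and
  per-genus aggregation against a designated reference genome.
* **Rearrangements** — circular signed gene orders normalized to a canonical
  `+cox1` frame; detection of the smallest set of single-gene transpositions
  and reverse transpositions explaining two orders; clustering of genomes
  into arrangement types; a census of rearranged genes across a panel.
* **Phylogeny (desk scale)** — Needleman–Wunsch pairwise alignment with
  codon back-threading, supermatrix construction (P123/P123R/P12/P12R codon
  position masks), p/JC/Poisson distances, neighbor joining (via `ape`),
  Robinson–Foulds distances and outgroup-rooted monophyly checks.
* **Synthetic data** — a seeded generator producing genome sequences that
  honor an annotation's coordinates, strands, start/stop codons and
  overlap constraints; codon sequences evolved along a tree under a per-gene
  dN/dS (omega-thinned proposal process) with realized substitution counts
  recorded as ground truth; scripted rearrangement events.

The packaged fixtures are the 37-gene annotation of the *Polypylis* sp.
TS-2018 mitogenome (the first for its genus) and the circular gene orders of
the 15-genome Planorbidae panel with the *Radix auricularia* outgroup.

## Worked example

```r
library(mitocompare)

g <- make_table1_fixture()        # the packaged 37-gene annotation
genome_summary(g)
#> genome OR684570: 13745 bp, 37 genes (25 major / 12 minor strand)
#>   PCG  n=13  10606 bp (77.2%)  range atp8 114..nad5 1656 bp
#>   tRNA n=22   1387 bp (10.1%)  range trnS2 55..trnH 70 bp
#>   rRNA n= 2   1715 bp (12.5%)  range rrnS 709..rrnL 1006 bp

junction_report(g)
#> 13 spacers (106 bp), 13 overlaps (69 bp), 11 abutting
#> longest spacer: 43 bp (cox3 - trnI)
#> longest overlap: 20 bp (nad5 - nad1)
```

The 13 protein-coding genes cover 10,606 bp (77.2% of the genome); the
longest spacer sits between *cox3* and *trnI*, the longest overlap between
*nad5* and *nad1*. A simulated sequence honoring this annotation yields the
full codon-usage stack:

```r
sim <- simulate_genome(1)          # seeded; PCGs satisfy all stop constraints
counts <- count_codons(sim)        # 3525 codons pooled over the 13 PCGs
r <- rscu(counts)
head(r[order(-r$rscu), c("codon", "amino_acid", "rscu")], 1)
#>    codon amino_acid     rscu
#> 27   TTA          L 2.812121
```

TTA (Leu) tops the RSCU table, as expected for a genome simulated at 75%
A+T. Arrangement typing of the study panel:

```r
orders <- planorbidae_gene_orders()
table(cluster_types(orders)$type)
#> A B C D E F
#> 3 8 1 1 1 1
rearranged_gene_census(orders)$genes
#> rrnS plus ten tRNAs: trnC trnD trnE trnL2 trnM trnN trnQ trnR trnS2 trnW
```

`run_pipeline(list(seed = 1, out_dir = "out"))` chains every stage
(stats → codons → Ka/Ks → rearrangements → NJ tree) and writes per-stage
TSV/Newick outputs plus a machine-readable `summary.json`; reruns with the
same seed are byte-identical.

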