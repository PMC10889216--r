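#' The packaged 37-gene ramshorn-snail annotation fixture
#'
#' The complete annotation of the Polypylis sp. TS-2018 mitogenome (accession
#' OR684570) as a feature table: coordinates, strands, gene classes,
#' start/stop codons and anticodons for all 37 genes, without sequence.  The
#' last feature ends at 13,745 bp, which under the genome-length rule (no
#' sequence, no declared length) is the fixture's coordinate space; the
#' deposited record reports 13,746 bp and the 13,749 bp figure also circulates
#' — all three are kept in the \code{reported_lengths} attribute.
#'
#' @return a \code{mito_genome} (complete, sequence-free).
#' @export
#' @examples
#' g <- make_table1_fixture()
#' nrow(g$features)  # 37
make_table1_fixture <- function() {
  f <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
gene   start end   strand class start_codon stop_codon anticodon
nad6   1     450   +      PCG   ATA         TAA        NA
nad5   443   2098  +      PCG   TTG         TAG        NA
nad1   2079  2973  +      PCG   ATG         T          NA
nad4L  2991  3272  +      PCG   ATA         TAA        NA
trnW   3271  3330  +      tRNA  NA          NA         TGA
trnC   3331  3394  +      tRNA  NA          NA         TGC
cob    3410  4468  +      PCG   ATA         TAG        NA
trnD   4464  4527  +      tRNA  NA          NA         GAC
trnF   4524  4591  +      tRNA  NA          NA         TTC
cox2   4593  5237  +      PCG   ATT         TAA        NA
trnY   5241  5303  +      tRNA  NA          NA         TAC
trnG   5298  5363  +      tRNA  NA          NA         GGA
trnH   5357  5426  +      tRNA  NA          NA         CAC
trnQ   5431  5491  -      tRNA  NA          NA         CAA
trnL2  5487  5553  -      tRNA  NA          NA         TTA
atp8   5549  5662  -      PCG   ATC         TAA        NA
trnN   5664  5732  -      tRNA  NA          NA         AAC
atp6   5733  6366  -      PCG   ATT         T          NA
trnR   6370  6433  -      tRNA  NA          NA         CGA
trnE   6437  6492  -      tRNA  NA          NA         GAA
rrnS   6493  7201  +      rRNA  NA          NA         NA
trnM   7202  7264  -      tRNA  NA          NA         ATG
nad3   7267  7611  -      PCG   ATT         TAA        NA
trnS2  7612  7666  -      tRNA  NA          NA         TCA
trnS1  7666  7725  +      tRNA  NA          NA         AGC
nad4   7725  9029  +      PCG   TTG         TAA        NA
trnT   9041  9105  -      tRNA  NA          NA         ACA
cox3   9106  9883  -      PCG   ATG         T          NA
trnI   9927  9990  +      tRNA  NA          NA         ATC
nad2   9992  10901 +      PCG   ATT         T          NA
trnK   10902 10959 +      tRNA  NA          NA         AAA
cox1   10959 12491 +      PCG   ATC         TAA        NA
trnV   12494 12548 +      tRNA  NA          NA         GTA
rrnL   12549 13554 +      rRNA  NA          NA         NA
trnL1  13555 13617 +      tRNA  NA          NA         CTA
trnA   13614 13680 +      tRNA  NA          NA         GCA
trnP   13681 13745 +      tRNA  NA          NA         CCA
")
  g <- mito_genome("OR684570", f, taxon = "Polypylis sp. TS-2018",
                   genus = "Polypylis")
  attr(g, "reported_lengths") <- c(table = 13745L, record = 13746L,
                                   abstract = 13749L)
  g
}

#' Study panel metadata
#'
#' The 15 ramshorn-snail genomes (accession, species, genus) plus the
#' Radix auricularia outgroup used as the Ka/Ks reference and for rooting.
#'
#' @return data.frame: id, taxon, genus, outgroup (logical).
#' @export
planorbidae_panel_info <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = '
id        taxon                        genus        outgroup
OR684570  "Polypylis sp. TS-2018"      Polypylis    FALSE
OX421510  "Anisus vortex"              Anisus       FALSE
MG431964  "Biomphalaria choanomphala"  Biomphalaria FALSE
NC_005439 "Biomphalaria glabrata"      Biomphalaria FALSE
MG431962  "Biomphalaria pfeifferi"     Biomphalaria FALSE
MF480756  "Biomphalaria straminea"     Biomphalaria FALSE
MG431963  "Biomphalaria sudanica"      Biomphalaria FALSE
EF433576  "Biomphalaria tenagophila"   Biomphalaria FALSE
MK414453  "Bulinus globosus"           Bulinus      FALSE
MK414450  "Bulinus nasutus"            Bulinus      FALSE
MK414449  "Bulinus truncatus"          Bulinus      FALSE
MK414451  "Bulinus ugandae"            Bulinus      FALSE
MW357851  "Gyraulus sp."               Gyraulus     FALSE
KY514384  "Planorbella duryi"          Planorbella  FALSE
MW889961  "Planorbella pilsbryi"       Planorbella  FALSE
KP098540  "Radix auricularia"          Radix        TRUE
')
}

#' Fixture gene orders of the 15-genome panel
#'
#' Circular signed gene orders shipped as a plain-text data file.  The
#' Polypylis order (arrangement type E) is read directly from its annotation
#' coordinates and strands; the other five types are reconstructed from the
#' described single-gene transposition / reverse-transposition deltas between
#' types.  Two placements the source material does not state — the type A
#' position of trnD and the type F destination of the reversed trnQ — are
#' synthetic choices documented in the data file's comments.
#'
#' @return named list of \code{gene_order} objects, in arrangement-type order
#'   (type A genomes first).
#' @export
planorbidae_gene_orders <- function() {
  path <- system.file("extdata", "planorbidae_gene_orders.txt",
                      package = "mitocompare")
  read_gene_orders(path)
}

#' Reference phylogeny of the study panel
#'
#' The published topology over the 16 taxa: Bulinus sister to all other
#' ramshorn genera; Polypylis sister to (Anisus, Gyraulus); (Planorbella,
#' Biomphalaria) sister to that clade; Radix as outgroup.  Within-genus
#' resolutions are arbitrary but fixed.  Used as the generating tree for
#' simulations and as the target of topology-recovery checks.
#'
#' @param brlen branch length applied to every edge (default 0.05).
#' @return an \code{ape::phylo} (unrooted, 16 tips labelled by accession).
#' @export
planorbidae_reference_tree <- function(brlen = 0.05) {
  nwk <- paste0(
    "(KP098540,((MK414453,MK414450),(MK414449,MK414451)),",
    "(((KY514384,MW889961),(((MG431964,NC_005439),(MG431962,MF480756)),",
    "(MG431963,EF433576))),(OR684570,(OX421510,MW357851))));")
  tr <- ape::read.tree(text = nwk)
  tr$edge.length <- rep(brlen, nrow(tr$edge))
  tr
}
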