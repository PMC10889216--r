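#' Canonical mitochondrial gene names
#'
#' The 37 genes of a complete metazoan mitochondrial genome in the controlled
#' vocabulary used throughout the package: 13 protein-coding genes (PCGs),
#' 2 ribosomal RNAs and 22 transfer RNAs (with the duplicated leucine and
#' serine tRNAs distinguished as \code{trnL1}/\code{trnL2} and
#' \code{trnS1}/\code{trnS2}).
#'
#' @param class optional filter: one of \code{"PCG"}, \code{"tRNA"},
#'   \code{"rRNA"}; default returns all 37 names.
#' @return character vector of canonical gene names.
#' @export
#' @examples
#' length(mito_gene_names())      # 37
#' mito_gene_names("rRNA")        # rrnS, rrnL
mito_gene_names <- function(class = NULL) {
  pcg  <- c("atp6", "atp8", "cob", "cox1", "cox2", "cox3",
            "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6")
  rrna <- c("rrnS", "rrnL")
  trna <- paste0("trn", c("A", "C", "D", "E", "F", "G", "H", "I", "K",
                          "L1", "L2", "M", "N", "P", "Q", "R", "S1", "S2",
                          "T", "V", "W", "Y"))
  if (is.null(class)) return(c(pcg, rrna, trna))
  switch(match.arg(class, c("PCG", "tRNA", "rRNA")),
         PCG = pcg, rRNA = rrna, tRNA = trna)
}

#' Gene class of a canonical gene name
#' @param name character vector of canonical gene names.
#' @return character vector in \code{c("PCG","tRNA","rRNA")}; NA for unknown.
#' @export
mito_gene_class <- function(name) {
  cls <- rep(NA_character_, length(name))
  cls[name %in% mito_gene_names("PCG")]  <- "PCG"
  cls[name %in% mito_gene_names("tRNA")] <- "tRNA"
  cls[name %in% mito_gene_names("rRNA")] <- "rRNA"
  cls
}

# synonym table cache
.synonym_env <- new.env(parent = emptyenv())

#' Gene-name synonym table
#'
#' Mapping from the gene labels found in GenBank records (COI, ND5, 16S
#' ribosomal RNA, tRNA-Ala, ...) onto the canonical vocabulary.  Shipped as a
#' plain TSV under \code{inst/extdata} so it can be extended without touching
#' code.  Matching is case-insensitive.
#'
#' @param path optional path to an alternative synonym TSV (columns
#'   \code{synonym}, \code{canonical}).
#' @return data.frame with columns \code{synonym}, \code{canonical}.
#' @export
gene_synonyms <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.synonym_env$table)) return(.synonym_env$table)
    path <- system.file("extdata", "gene_synonyms.tsv", package = "mitocompare")
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    .synonym_env$table <- tab
    return(tab)
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Map a gene label to the canonical vocabulary
#'
#' Case-insensitive lookup in the synonym table.  The ambiguous labels
#' \code{trnL} and \code{trnS} (and their GenBank spellings) are resolved by
#' anticodon when one is supplied: leucine CTA/TAG -> \code{trnL1},
#' TTA/TAA -> \code{trnL2}; serine AGC/GCT -> \code{trnS1},
#' TCA/TGA -> \code{trnS2}.  Unresolvable labels are returned as
#' \code{NA} so callers can retain them with a warning flag.
#'
#' @param label character vector of raw gene labels.
#' @param anticodon optional character vector (same length) of anticodons or
#'   recognized codons used for trnL/trnS disambiguation.
#' @return character vector of canonical names (NA where unmapped/ambiguous).
#' @export
#' @examples
#' canonical_gene_name("COI")              # "cox1"
#' canonical_gene_name("trnL", "TTA")      # "trnL2"
canonical_gene_name <- function(label, anticodon = NULL) {
  syn <- gene_synonyms()
  key <- toupper(trimws(label))
  hit <- syn$canonical[match(key, toupper(syn$synonym))]
  # already-canonical names pass through
  canon <- mito_gene_names()
  direct <- canon[match(key, toupper(canon))]
  hit[is.na(hit)] <- direct[is.na(hit)]
  if (!is.null(anticodon)) {
    ac <- toupper(trimws(anticodon))
    amb_l <- !is.na(hit) & hit == "trnL?"
    amb_s <- !is.na(hit) & hit == "trnS?"
    hit[amb_l & ac %in% c("CTA", "TAG")] <- "trnL1"
    hit[amb_l & ac %in% c("TTA", "TAA")] <- "trnL2"
    hit[amb_s & ac %in% c("AGC", "GCT")] <- "trnS1"
    hit[amb_s & ac %in% c("TCA", "TGA")] <- "trnS2"
  }
  hit[!is.na(hit) & hit %in% c("trnL?", "trnS?")] <- NA_character_
  hit
}
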