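#' The invertebrate mitochondrial genetic code (NCBI table 5)
#'
#' Codon-to-amino-acid map used throughout the package (AGA/AGG = Ser,
#' ATA = Met, TGA = Trp; stops are TAA and TAG only).  Fixed by design: the
#' genomes this package targets are annotated under this code.
#'
#' @return named character vector over the 64 codons; stops are \code{"*"}.
#' @export
invertebrate_mito_code <- function() {
  if (is.null(.codon_env$code))
    .codon_env$code <- Biostrings::getGeneticCode("5")
  .codon_env$code
}

.codon_env <- new.env(parent = emptyenv())

#' Sense codons under the invertebrate mitochondrial code
#' @return character vector of the 62 non-stop codons.
#' @export
sense_codons <- function() {
  code <- invertebrate_mito_code()
  names(code)[code != "*"]
}

#' Split a coding sequence into codons
#'
#' Validates the declared start codon against the first triplet, drops the
#' terminal stop codon whether complete (TAA/TAG) or incomplete (TA/T, the
#' forms completed by post-transcriptional polyadenylation), and returns the
#' remaining complete triplets, the start codon included as the first codon.
#' In-frame internal stop codons raise a warning (draft annotations contain
#' them) and are reported in the \code{internal_stops} attribute.
#'
#' @param gene_seq coding-strand DNA string of one protein-coding gene.
#' @param start_codon declared 3-letter start codon.
#' @param stop_codon declared stop, one of TAA, TAG, TA, T.
#' @param gene optional gene name used in messages.
#' @return character vector of codons.
#' @export
#' @examples
#' extract_codons("ATGAAATAA", "ATG", "TAA")  # ATG AAA
extract_codons <- function(gene_seq, start_codon, stop_codon, gene = NULL) {
  gene_seq <- toupper(gene_seq)
  start_codon <- toupper(start_codon)
  stop_codon <- toupper(stop_codon)
  who <- if (is.null(gene)) "" else paste0(" in gene ", gene)
  if (!stop_codon %in% c("TAA", "TAG", "TA", "T"))
    stop("stop codon must be TAA, TAG, TA or T", who)
  n <- nchar(gene_seq)
  if (n %% 3L != nchar(stop_codon) %% 3L)
    stop("sequence length ", n, " incompatible with stop codon '",
         stop_codon, "'", who)
  if (substr(gene_seq, 1L, 3L) != start_codon)
    stop("declared start codon ", start_codon, " does not match first triplet ",
         substr(gene_seq, 1L, 3L), who)
  tail <- substr(gene_seq, n - nchar(stop_codon) + 1L, n)
  if (tail != stop_codon)
    stop("declared stop codon ", stop_codon, " does not match sequence end '",
         tail, "'", who)
  body <- substr(gene_seq, 1L, n - nchar(stop_codon))
  codons <- substring(body, seq(1L, nchar(body) - 2L, by = 3L),
                      seq(3L, nchar(body), by = 3L))
  code <- invertebrate_mito_code()
  internal <- unname(which(code[codons] == "*"))
  if (length(internal))
    warning(length(internal), " internal in-frame stop codon(s)", who,
            " at codon position(s) ", paste(internal, collapse = ", "))
  attr(codons, "internal_stops") <- internal
  codons
}

#' Pooled codon counts over the 13 protein-coding genes
#'
#' Extracts codons from every PCG on its coding strand (per the annotated
#' start/stop codons) and pools the counts.  Stop codons never enter the
#' table: complete and incomplete terminal stops are removed by
#' \code{\link{extract_codons}}, so \code{total} counts sense codons only
#' (start codons are counted as ordinary codons).
#'
#' @param genome a \code{mito_genome} with sequence and all 13 PCGs annotated.
#' @return object of class \code{codon_counts}: named integer vector over the
#'   64 codons with attributes \code{total} and \code{genetic_code}.
#' @export
count_codons <- function(genome) {
  f <- genome$features
  pcgs <- f$gene[f$class == "PCG"]
  missing <- setdiff(mito_gene_names("PCG"), pcgs)
  if (length(missing))
    stop("missing PCG(s): ", paste(missing, collapse = ", "))
  all_codons <- unlist(lapply(pcgs, function(g) {
    i <- match(g, f$gene)
    extract_codons(extract_gene_sequence(genome, g),
                   f$start_codon[i], f$stop_codon[i], gene = g)
  }))
  codon_counts(all_codons)
}

#' Build a codon-count table from codons or named counts
#' @param x character vector of codons, or a named integer vector of counts.
#' @return object of class \code{codon_counts}.
#' @export
codon_counts <- function(x) {
  all64 <- names(invertebrate_mito_code())
  counts <- stats::setNames(integer(64), all64)
  if (is.character(x)) {
    t <- table(factor(toupper(x), levels = all64))
    counts[] <- as.integer(t)
  } else {
    nm <- toupper(names(x))
    if (is.null(nm) || !all(nm %in% all64))
      stop("counts must be named by codons")
    counts[nm] <- as.integer(x)
  }
  code <- invertebrate_mito_code()
  if (any(counts[code == "*"] > 0))
    stop("stop codons cannot appear in a codon-count table")
  structure(counts, total = sum(counts), genetic_code = "5",
            class = "codon_counts")
}

#' Relative synonymous codon usage (RSCU)
#'
#' RSCU(c) = count(c) * k / sum of family counts, where k is the number of
#' synonymous codons encoding the amino acid of c under the invertebrate
#' mitochondrial code (stop codons excluded from families).  Within every
#' observed family the mean RSCU is exactly 1; codons of an entirely
#' unobserved family get NA with a warning.
#'
#' @param counts a \code{codon_counts} table.
#' @return data.frame: codon, amino_acid, family_size, count, rscu, sorted by
#'   amino acid then codon.
#' @export
#' @examples
#' rscu(codon_counts(c(AAA = 3, AAG = 1)))  # Lys: 1.5 and 0.5
rscu <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  if (attr(counts, "total") == 0) stop("empty codon-count table")
  code <- invertebrate_mito_code()
  sense <- names(code)[code != "*"]
  aa <- code[sense]
  fam_size <- stats::setNames(as.integer(table(aa)[aa]), sense)
  fam_tot <- tapply(as.integer(counts[sense]), aa, sum)
  out <- data.frame(codon = sense, amino_acid = unname(aa),
                    family_size = unname(fam_size),
                    count = as.integer(counts[sense]),
                    stringsAsFactors = FALSE)
  out$rscu <- ifelse(fam_tot[out$amino_acid] > 0,
                     out$count * out$family_size / fam_tot[out$amino_acid],
                     NA_real_)
  if (anyNA(out$rscu))
    warning("unobserved amino-acid family(ies): ",
            paste(unique(out$amino_acid[is.na(out$rscu)]), collapse = ", "))
  out <- out[order(out$amino_acid, out$codon), ]
  rownames(out) <- NULL
  out
}

#' Amino-acid usage fractions
#'
#' Translates the pooled codon counts under the invertebrate mitochondrial
#' code and returns each amino acid's fraction of the total.
#'
#' @param counts a \code{codon_counts} table.
#' @return named numeric vector (sums to 1), sorted decreasing.
#' @export
amino_acid_frequencies <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  total <- attr(counts, "total")
  if (total == 0) stop("empty codon-count table")
  code <- invertebrate_mito_code()
  sense <- names(code)[code != "*"]
  tot <- tapply(as.integer(counts[sense]), code[sense], sum)
  sort(tot / total, decreasing = TRUE)
}
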