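#' Construct an annotated circular mitochondrial genome
#'
#' The central container of the package.  Coordinates are 1-based inclusive on
#' the major (J) strand; a feature whose span crosses the origin of the
#' circular molecule has \code{start > end} and \code{wraps_origin = TRUE}.
#'
#' @param id accession-like identifier.
#' @param features data.frame with columns \code{gene}, \code{start},
#'   \code{end}, \code{strand} ("+" major / "-" minor), \code{class}
#'   (PCG/tRNA/rRNA) and optional \code{start_codon}, \code{stop_codon},
#'   \code{anticodon}, \code{wraps_origin}.
#' @param taxon,genus species and genus labels.
#' @param sequence optional major-strand DNA string over A/C/G/T.
#' @param declared_length optional declared genome length in bp, used when no
#'   sequence is available.
#' @param validate run \code{\link{validate_mito_genome}} (default TRUE).
#' @return object of class \code{mito_genome}.
#' @export
mito_genome <- function(id, features, taxon = NA_character_,
                        genus = NA_character_, sequence = NULL,
                        declared_length = NULL, validate = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, is.data.frame(features))
  for (col in c("start_codon", "stop_codon", "anticodon"))
    if (is.null(features[[col]])) features[[col]] <- NA_character_
  if (is.null(features$wraps_origin)) features$wraps_origin <- FALSE
  features$start <- as.integer(features$start)
  features$end   <- as.integer(features$end)
  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (!grepl("^[ACGTNRYSWKMBDHV]+$", sequence))
      stop("sequence contains characters outside the IUPAC DNA alphabet")
  }
  g <- structure(
    list(id = id, taxon = taxon, genus = genus, sequence = sequence,
         declared_length = if (is.null(declared_length)) NULL
                           else as.integer(declared_length),
         features = features),
    class = "mito_genome")
  if (validate) g <- validate_mito_genome(g)
  g
}

#' Length of the circular genome in bp
#'
#' Resolution order: length of the sequence when present, else the declared
#' length, else the maximum feature end coordinate.
#' @param genome a \code{mito_genome}.
#' @return integer length in bp.
#' @export
genome_length <- function(genome) {
  if (!is.null(genome$sequence)) return(nchar(genome$sequence))
  if (!is.null(genome$declared_length)) return(genome$declared_length)
  max(genome$features$end, genome$features$start)
}

#' Feature lengths in bp
#'
#' \code{end - start + 1}, plus the genome length for origin-wrapping features.
#' @param genome a \code{mito_genome}.
#' @return integer vector named by gene.
#' @export
feature_lengths <- function(genome) {
  f <- genome$features
  len <- f$end - f$start + 1L
  if (any(f$wraps_origin)) len[f$wraps_origin] <-
    len[f$wraps_origin] + genome_length(genome)
  stats::setNames(as.integer(len), f$gene)
}

#' Validate a mito_genome against the data-model invariants
#'
#' Errors on hard violations (duplicate canonical gene names, non-positive
#' lengths, illegal stop-codon tokens, protein-coding length incompatible with
#' the declared stop-codon style, coordinates outside the sequence, tRNAs
#' shorter than 50 bp).  Warns on soft issues (names outside the 37-gene
#' vocabulary, incomplete genomes with fewer than 37 features, PCGs lacking
#' codons or tRNAs lacking anticodons).
#'
#' @param genome a \code{mito_genome}.
#' @return the genome, invisibly, with \code{$complete} set.
#' @export
validate_mito_genome <- function(genome) {
  f <- genome$features
  need <- c("gene", "start", "end", "strand", "class")
  if (!all(need %in% names(f)))
    stop("features must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(f$gene))
    stop("duplicate gene name(s): ",
         paste(unique(f$gene[duplicated(f$gene)]), collapse = ", "))
  if (!all(f$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(f$class %in% c("PCG", "tRNA", "rRNA")))
    stop("class must be PCG, tRNA or rRNA")
  unknown <- setdiff(f$gene, mito_gene_names())
  if (length(unknown))
    warning("gene name(s) outside the 37-name vocabulary: ",
            paste(unknown, collapse = ", "))
  len <- feature_lengths(genome)
  if (any(len <= 0L)) stop("non-positive feature length for: ",
                           paste(f$gene[len <= 0L], collapse = ", "))
  small_trna <- f$class == "tRNA" & len < 50L
  if (any(small_trna))
    stop("tRNA shorter than 50 bp: ",
         paste(f$gene[small_trna], collapse = ", "))
  bad_stop <- f$class == "PCG" & !is.na(f$stop_codon) &
    !(f$stop_codon %in% c("TAA", "TAG", "TA", "T"))
  if (any(bad_stop))
    stop("stop codon must be one of TAA/TAG/TA/T: ",
         paste(f$gene[bad_stop], collapse = ", "))
  # incomplete stops are completed by polyadenylation: length mod 3 must leave
  # exactly the missing part of the stop codon
  is_pcg <- f$class == "PCG" & !is.na(f$stop_codon)
  if (any(is_pcg)) {
    want <- nchar(f$stop_codon[is_pcg]) %% 3L
    got  <- len[is_pcg] %% 3L
    off  <- want != got
    if (any(off))
      stop("PCG length incompatible with stop-codon style for: ",
           paste(f$gene[is_pcg][off], collapse = ", "))
  }
  miss_codon <- f$class == "PCG" & (is.na(f$start_codon) | is.na(f$stop_codon))
  if (any(miss_codon))
    warning("PCG(s) without start/stop codon annotation: ",
            paste(f$gene[miss_codon], collapse = ", "))
  miss_ac <- f$class == "tRNA" & is.na(f$anticodon)
  if (any(miss_ac))
    warning("tRNA(s) without anticodon: ",
            paste(f$gene[miss_ac], collapse = ", "))
  L <- genome_length(genome)
  if (!is.null(genome$sequence)) {
    out <- f$start < 1L | f$start > L | f$end < 1L | f$end > L
    if (any(out))
      stop("feature coordinates outside [1, ", L, "] for: ",
           paste(f$gene[out], collapse = ", "))
  }
  genome$complete <- nrow(f) == 37L &&
    setequal(f$gene, mito_gene_names())
  if (!genome$complete)
    warning("genome '", genome$id, "' is not a complete 37-gene annotation (",
            nrow(f), " features)")
  invisible(genome)
}

#' @export
print.mito_genome <- function(x, ...) {
  cls <- table(factor(x$features$class, c("PCG", "tRNA", "rRNA")))
  cat("mito_genome ", x$id,
      if (!is.na(x$taxon)) paste0(" (", x$taxon, ")"), "\n",
      "  length: ", genome_length(x), " bp",
      if (is.null(x$sequence)) " (no sequence)", "\n",
      "  features: ", nrow(x$features),
      sprintf(" (%d PCG, %d tRNA, %d rRNA)", cls[1], cls[2], cls[3]), "\n",
      sep = "")
  invisible(x)
}

.na_marker <- function(x) ifelse(is.na(x) | x == "", ".", x)
.read_marker <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", ".", "-", "—", "NA")] <- NA_character_
  x
}

#' Read a genome from a tab-separated feature table
#'
#' Expected columns (header required): \code{gene}, \code{start}, \code{end},
#' \code{strand}, \code{class}, \code{start_codon}, \code{stop_codon},
#' \code{anticodon} and optionally \code{wraps_origin}.  Missing values may be
#' written as \code{.}, \code{-} or an em dash.
#'
#' @param path path to the TSV file.
#' @param id,taxon,genus,declared_length metadata passed to
#'   \code{\link{mito_genome}}; \code{id} defaults to the file name.
#' @param sequence optional major-strand DNA string (or NULL).
#' @return a \code{mito_genome} with features in file order (sorted by start).
#' @export
read_feature_table <- function(path, id = NULL, taxon = NA_character_,
                               genus = NA_character_, sequence = NULL,
                               declared_length = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) == 0L) stop("no features in ", path)
  need <- c("gene", "start", "end", "strand", "class")
  if (!all(need %in% names(tab)))
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.integer(tab[[col]]))
    if (anyNA(v)) stop("non-integer values in column '", col, "'")
    tab[[col]] <- v
  }
  for (col in c("start_codon", "stop_codon", "anticodon"))
    if (col %in% names(tab)) tab[[col]] <- .read_marker(tab[[col]])
  if ("wraps_origin" %in% names(tab)) {
    tab$wraps_origin <- as.logical(tab$wraps_origin)
    tab$wraps_origin[is.na(tab$wraps_origin)] <- FALSE
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  mito_genome(id, tab, taxon = taxon, genus = genus, sequence = sequence,
              declared_length = declared_length)
}

#' Write a genome's features as a tab-separated table
#'
#' Round-trips with \code{\link{read_feature_table}}: all annotation fields are
#' preserved; missing codon/anticodon values are emitted as \code{.}.
#'
#' @param genome a \code{mito_genome}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(genome, path) {
  f <- genome$features
  out <- data.frame(gene = f$gene, start = f$start, end = f$end,
                    strand = f$strand, class = f$class,
                    start_codon = .na_marker(f$start_codon),
                    stop_codon = .na_marker(f$stop_codon),
                    anticodon = .na_marker(f$anticodon),
                    wraps_origin = f$wraps_origin,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the coding-strand sequence of one gene
#'
#' Major-strand slice for "+" features; reverse complement for "-" features;
#' origin-wrapping spans are concatenated across the origin.
#'
#' @param genome a \code{mito_genome} with sequence.
#' @param name canonical gene name.
#' @return DNA string (character scalar) on the gene's coding strand.
#' @export
extract_gene_sequence <- function(genome, name) {
  if (is.null(genome$sequence))
    stop("genome '", genome$id, "' carries no sequence")
  i <- match(name, genome$features$gene)
  if (is.na(i)) stop("unknown gene: ", name)
  f <- genome$features[i, ]
  s <- genome$sequence
  seq <- if (isTRUE(f$wraps_origin)) {
    paste0(substr(s, f$start, nchar(s)), substr(s, 1L, f$end))
  } else {
    substr(s, f$start, f$end)
  }
  if (f$strand == "-") seq <- reverse_complement(seq)
  seq
}

#' Reverse complement of a DNA string
#' @param seq DNA string.
#' @return reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
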