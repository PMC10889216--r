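#' Read an annotated mitogenome from a GenBank flat file
#'
#' A minimal parser for GenBank records carrying \code{CDS}, \code{tRNA} and
#' \code{rRNA} features (plain \code{gene} features are used only for spans
#' that have no typed feature).  Gene labels are mapped onto the canonical
#' 37-name vocabulary through the synonym table
#' (\code{\link{canonical_gene_name}}); features whose label cannot be mapped
#' are retained under their raw label with a warning rather than dropped.
#' Ambiguous leucine/serine tRNAs are resolved by anticodon when the record
#' provides one.  When the record contains an ORIGIN sequence, start and stop
#' codons of protein-coding genes are derived from it (the stop codon may be
#' the incomplete \code{T}/\code{TA} completed by polyadenylation).
#'
#' @param path path to a GenBank flat file (.gb/.gbk).
#' @return a \code{mito_genome}.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1]))
    stop("not a GenBank flat file (missing LOCUS): ", path)
  locus <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  declared_length <- suppressWarnings(as.integer(locus[3]))
  id <- locus[2]
  acc <- grep("^VERSION|^ACCESSION", lines, value = TRUE)
  if (length(acc))
    id <- strsplit(trimws(acc[1]), "\\s+")[[1]][2]
  org <- grep("^\\s+ORGANISM", lines, value = TRUE)
  taxon <- if (length(org)) trimws(sub("^\\s+ORGANISM", "", org[1]))
           else NA_character_
  genus <- if (!is.na(taxon)) strsplit(taxon, "\\s+")[[1]][1] else NA_character_

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(fstart)) stop("malformed GenBank record: no FEATURES block")
  fend <- if (length(ostart)) ostart[1] - 1L else {
    ee <- grep("^//", lines); if (length(ee)) ee[1] - 1L else length(lines)
  }
  feat_lines <- lines[(fstart[1] + 1L):fend]

  sequence <- NULL
  if (length(ostart)) {
    eend <- grep("^//", lines)
    eend <- if (length(eend)) eend[1] - 1L else length(lines)
    seq_lines <- lines[(ostart[1] + 1L):eend]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    if (!nchar(sequence)) sequence <- NULL
  }

  # split the FEATURES block into individual features: a new feature starts
  # with a key in columns 6-20
  is_key <- grepl("^ {5}\\S", feat_lines)
  if (!any(is_key)) stop("malformed GenBank record: empty FEATURES block")
  idx <- cumsum(is_key)
  feats <- split(feat_lines[idx > 0], idx[idx > 0])

  rows <- list()
  for (fl in feats) {
    key <- sub("^\\s+", "", substr(fl[1], 1, 20))
    key <- strsplit(key, "\\s+")[[1]][1]
    if (!key %in% c("CDS", "tRNA", "rRNA", "gene")) next
    # location may continue over lines until the first qualifier
    qual_at <- grep("^\\s{10,}/", fl)
    loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(fl)
    loc <- gsub("\\s", "", paste(
      c(sub("^\\s*\\S+\\s*", "", fl[1]), trimws(fl[seq_len(loc_end)[-1]])),
      collapse = ""))
    pl <- .parse_gb_location(loc, fl[1])
    qual_text <- paste(trimws(fl[seq_along(fl) >= loc_end + 1L]), collapse = " ")
    label <- .gb_qualifier(qual_text, "gene")
    if (is.na(label)) label <- .gb_qualifier(qual_text, "product")
    anticodon <- .gb_anticodon(qual_text)
    rows[[length(rows) + 1L]] <- data.frame(
      key = key, label = if (is.na(label)) "unknown" else label,
      start = pl$start, end = pl$end, strand = pl$strand,
      wraps_origin = pl$wraps, anticodon = anticodon,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no gene/CDS/tRNA/rRNA features in ", path)
  tab <- do.call(rbind, rows)

  # prefer typed features; keep 'gene' rows only for otherwise-unannotated spans
  typed <- tab[tab$key != "gene", , drop = FALSE]
  plain <- tab[tab$key == "gene", , drop = FALSE]
  if (nrow(plain)) {
    covered <- paste(typed$start, typed$end)
    plain <- plain[!paste(plain$start, plain$end) %in% covered &
                     !toupper(plain$label) %in% toupper(typed$label), ,
                   drop = FALSE]
    tab <- rbind(typed, plain)
  } else tab <- typed

  canon <- canonical_gene_name(tab$label, tab$anticodon)
  unmapped <- is.na(canon)
  if (any(unmapped))
    warning("unmapped gene label(s) retained as-is: ",
            paste(unique(tab$label[unmapped]), collapse = ", "))
  gene <- ifelse(unmapped, tab$label, canon)
  # held-as-ambiguous labels may repeat (e.g. two trnL without anticodons);
  # keep them apart with a suffix rather than failing as duplicates
  if (anyDuplicated(gene[unmapped])) {
    dup <- unmapped & gene %in% gene[unmapped][duplicated(gene[unmapped])]
    gene[dup] <- paste0(gene[dup], ".", stats::ave(seq_along(gene[dup]),
                                                   gene[dup], FUN = seq_along))
  }
  class <- mito_gene_class(gene)
  class[is.na(class)] <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                           gene = "PCG")[tab$key[is.na(class)]]

  features <- data.frame(gene = gene, start = tab$start, end = tab$end,
                         strand = tab$strand, class = class,
                         start_codon = NA_character_,
                         stop_codon = NA_character_,
                         anticodon = tab$anticodon,
                         wraps_origin = tab$wraps_origin,
                         stringsAsFactors = FALSE)
  if (anyDuplicated(features$gene))
    stop("duplicate canonical gene name(s) in ", path, ": ",
         paste(unique(features$gene[duplicated(features$gene)]),
               collapse = ", "))
  g <- mito_genome(id, features, taxon = taxon, genus = genus,
                   sequence = sequence, declared_length = declared_length,
                   validate = FALSE)
  if (!is.null(sequence)) g <- .derive_pcg_codons(g)
  validate_mito_genome(g)
}

.parse_gb_location <- function(loc, line) {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  wraps <- FALSE
  if (grepl("^join\\(", loc)) {
    parts <- strsplit(sub("^join\\((.*)\\)$", "\\1", loc), ",")[[1]]
    m <- regmatches(parts, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", parts))
    if (any(lengths(m) != 3L))
      stop("cannot parse GenBank location on line: ", line)
    s1 <- as.integer(m[[1]][2]); e2 <- as.integer(m[[length(m)]][3])
    return(list(start = s1, end = e2, strand = strand, wraps = TRUE))
  }
  m <- regmatches(loc, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", loc))[[1]]
  if (length(m) != 3L)
    stop("cannot parse GenBank location on line: ", line)
  list(start = as.integer(m[2]), end = as.integer(m[3]),
       strand = strand, wraps = wraps)
}

.gb_qualifier <- function(text, name) {
  m <- regmatches(text,
                  regexec(paste0('/', name, '="([^"]*)"'), text))[[1]]
  if (length(m) == 2L) return(m[2])
  m <- regmatches(text,
                  regexec(paste0('/', name, '=([^ /]+)'), text))[[1]]
  if (length(m) == 2L) m[2] else NA_character_
}

.gb_anticodon <- function(text) {
  m <- regmatches(text, regexec("seq:([acgtuACGTU]{3})", text))[[1]]
  if (length(m) == 2L) return(toupper(chartr("Uu", "Tt", m[2])))
  NA_character_
}

# derive start/stop codons of PCGs from the sequence; stop style follows the
# residue of length mod 3 (0 -> full TAA/TAG, 1 -> T, 2 -> TA)
.derive_pcg_codons <- function(genome) {
  f <- genome$features
  for (i in which(f$class == "PCG")) {
    seq <- extract_gene_sequence(genome, f$gene[i])
    n <- nchar(seq)
    f$start_codon[i] <- substr(seq, 1L, 3L)
    r <- n %% 3L
    stop_cand <- substr(seq, n - c(2L, 0L, 1L)[r + 1L], n)
    ok <- stop_cand %in% c("TAA", "TAG", "TA", "T")
    if (ok) f$stop_codon[i] <- stop_cand
    else warning("gene ", f$gene[i], ": terminal codon '", stop_cand,
                 "' is not a recognized (incomplete) stop; left unset")
  }
  genome$features <- f
  genome
}
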