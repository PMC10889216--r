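#' Nonsynonymous and synonymous site counts of one codon (NG86)
#'
#' Nei-Gojobori (1986) site counting under the invertebrate mitochondrial
#' code: at each of the three codon positions the fraction of possible
#' single-nucleotide changes that are synonymous contributes to the synonymous
#' site count; changes creating stop codons are excluded from the denominator
#' at that position.  The two counts always sum to exactly 3.
#'
#' @param codon a sense codon (3-letter DNA string).
#' @return named numeric vector \code{c(n = ..., s = ...)}.
#' @export
ng86_sites <- function(codon) {
  codon <- toupper(codon)
  code <- invertebrate_mito_code()
  aa <- unname(code[codon])
  if (is.na(aa)) stop("not a codon: ", codon)
  if (aa == "*") stop("stop codon has no NG86 sites: ", codon)
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    syn <- 0L; nonstop <- 0L
    for (b in setdiff(bases, ref)) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (code[[mut]] == "*") next
      nonstop <- nonstop + 1L
      if (code[[mut]] == aa) syn <- syn + 1L
    }
    if (nonstop > 0L) s <- s + syn / nonstop
  }
  c(n = 3 - s, s = s)
}

.kaks_env <- new.env(parent = emptyenv())

# pathway-averaged (nd, sd) between two sense codons: average over all
# orderings of the differing positions, excluding pathways that pass through a
# stop codon (falling back to all pathways if every one is blocked)
.ng86_pathway <- function(c1, c2) {
  code <- invertebrate_mito_code()
  diffpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(diffpos)
  if (d == 0L) return(c(nd = 0, sd = 0))
  perms <- .permutations(diffpos)
  walk <- function(order) {
    cur <- c1
    nd <- 0; sd <- 0
    for (pos in order) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (code[[nxt]] == "*") return(NULL)
      if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(nd, sd)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk))
  if (!length(res)) {
    # every minimal pathway crosses a stop: fall back to unrestricted
    # averaging so the codon pair still contributes
    res <- lapply(perms, function(order) {
      cur <- c1; nd <- 0; sd <- 0
      for (pos in order) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(c2, pos, pos)
        if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(nd, sd)
    })
  }
  m <- colMeans(do.call(rbind, res))
  c(nd = m[[1]], sd = m[[2]])
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(.permutations(x[-i]), function(p) c(x[i], p)))
  out
}

# lazy per-codon caches over the 62 sense codons
.ng86_tables <- function() {
  if (!is.null(.kaks_env$sites)) return(.kaks_env)
  sc <- sense_codons()
  sites <- t(vapply(sc, ng86_sites, numeric(2)))
  nd <- matrix(0, length(sc), length(sc), dimnames = list(sc, sc))
  sd <- nd
  for (i in seq_along(sc)) for (j in seq_along(sc)) {
    if (i == j) next
    p <- .ng86_pathway(sc[i], sc[j])
    nd[i, j] <- p[["nd"]]; sd[i, j] <- p[["sd"]]
  }
  .kaks_env$sites <- sites
  .kaks_env$nd <- nd
  .kaks_env$sd <- sd
  .kaks_env
}

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) method
#'
#' Counts nonsynonymous/synonymous sites (averaged over the two sequences) and
#' pathway-averaged nonsynonymous/synonymous differences per codon, converts
#' the proportions to rates with the Jukes-Cantor correction
#' Ka = -3/4 ln(1 - 4 pN / 3) (likewise Ks), and classifies selection:
#' ratio > 1 positive, < 1 purifying, with a tolerance band
#' |ratio - 1| <= \code{neutral_band} reported as neutral.  The ratio is NA
#' when Ks = 0.
#'
#' @param seq1,seq2 aligned coding sequences (equal length, multiple of 3).
#'   Codon pairs containing gaps, ambiguity codes, or stop codons are dropped
#'   pairwise.
#' @param gene,id1,id2 optional labels carried into the result.
#' @param neutral_band half-width of the neutral classification band
#'   (default 0.05).
#' @return list of class \code{kaks_estimate}: N, S, Nd, Sd, pN, pS, ka, ks,
#'   ratio, classification, codons_compared, saturated.
#' @export
ng86_pair <- function(seq1, seq2, gene = NA_character_,
                      id1 = NA_character_, id2 = NA_character_,
                      neutral_band = 0.05) {
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  if (nchar(seq1) != nchar(seq2))
    stop("sequences must be aligned to equal length")
  if (nchar(seq1) %% 3L != 0L) stop("alignment length must be a multiple of 3")
  starts <- seq(1L, nchar(seq1) - 2L, by = 3L)
  cd1 <- substring(seq1, starts, starts + 2L)
  cd2 <- substring(seq2, starts, starts + 2L)
  tabs <- .ng86_tables()
  sc <- rownames(tabs$sites)
  keep <- cd1 %in% sc & cd2 %in% sc
  cd1 <- cd1[keep]; cd2 <- cd2[keep]
  if (!length(cd1)) stop("zero comparable codons")
  N <- (sum(tabs$sites[cd1, "n"]) + sum(tabs$sites[cd2, "n"])) / 2
  S <- (sum(tabs$sites[cd1, "s"]) + sum(tabs$sites[cd2, "s"])) / 2
  idx <- cbind(match(cd1, sc), match(cd2, sc))
  Nd <- sum(tabs$nd[idx])
  Sd <- sum(tabs$sd[idx])
  pN <- Nd / N
  pS <- Sd / S
  saturated <- pN >= 3 / 4 || pS >= 3 / 4
  jc <- function(p) if (p < 3 / 4) -3 / 4 * log(1 - 4 * p / 3) else NA_real_
  ka <- jc(pN); ks <- jc(pS)
  if (saturated)
    warning("substitution saturation (pN or pS >= 3/4)",
            if (!is.na(gene)) paste0(" in gene ", gene))
  ratio <- if (is.na(ka) || is.na(ks) || ks == 0) NA_real_ else ka / ks
  classification <- if (is.na(ratio)) NA_character_
    else if (abs(ratio - 1) <= neutral_band) "neutral"
    else if (ratio > 1) "positive" else "purifying"
  structure(list(gene = gene, pair = c(id1, id2),
                 codons_compared = length(cd1),
                 N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
                 ka = ka, ks = ks, ratio = ratio,
                 classification = classification, saturated = saturated),
            class = "kaks_estimate")
}

#' @export
print.kaks_estimate <- function(x, ...) {
  cat(sprintf("NG86 %s: %d codons, Ka %.4f, Ks %.4f, Ka/Ks %s (%s)\n",
              if (is.na(x$gene)) "" else x$gene, x$codons_compared,
              x$ka, x$ks,
              if (is.na(x$ratio)) "NA" else sprintf("%.3f", x$ratio),
              if (is.na(x$classification)) "NA" else x$classification))
  invisible(x)
}

#' Species panel
#'
#' A set of genomes (or bare taxon records) analysed together, with an
#' optional outgroup/reference designation.
#'
#' @param genomes list of \code{mito_genome} objects, or a data.frame with
#'   columns \code{id}, \code{taxon}, \code{genus}.
#' @param outgroup_id optional id of the reference/outgroup genome.
#' @return object of class \code{species_panel} with a \code{$info} data.frame.
#' @export
species_panel <- function(genomes, outgroup_id = NULL) {
  info <- if (is.data.frame(genomes)) genomes else
    data.frame(id = vapply(genomes, `[[`, "", "id"),
               taxon = vapply(genomes, `[[`, "", "taxon"),
               genus = vapply(genomes, `[[`, "", "genus"),
               stringsAsFactors = FALSE)
  if (anyDuplicated(info$id)) stop("duplicate genome ids in panel")
  if (!is.null(outgroup_id) && !outgroup_id %in% info$id)
    stop("outgroup_id '", outgroup_id, "' not in panel")
  structure(list(genomes = if (is.data.frame(genomes)) NULL else genomes,
                 info = info, outgroup_id = outgroup_id),
            class = "species_panel")
}

#' Per-genus selection summary over the 13 protein-coding genes
#'
#' Scores every panel species against the reference (outgroup) sequence with
#' \code{\link{ng86_pair}} for each gene, averages the defined (non-NA)
#' Ka/Ks ratios within each genus, and reports the per-gene overall mean
#' across genera, sorted descending.  In \code{mode = "allpairs"} each gene's
#' genus means are taken over all ingroup pairs involving a member of the
#' genus instead of reference-pairwise scores.
#'
#' @param panel a \code{species_panel} with \code{outgroup_id} set.
#' @param alignments named list: gene -> named character vector of aligned
#'   coding sequences (codon-aligned, including the reference).
#' @param mode \code{"reference"} (default) or \code{"allpairs"}.
#' @return list of class \code{genus_selection_summary}: \code{per_species}
#'   data.frame (gene, id, genus, ka, ks, ratio, classification),
#'   \code{genus_means} (gene x genus matrix), \code{overall} named vector of
#'   per-gene means sorted descending.
#' @export
genus_summary <- function(panel, alignments, mode = c("reference", "allpairs")) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "species_panel"))
  if (is.null(panel$outgroup_id))
    stop("panel must designate an outgroup/reference id")
  info <- panel$info
  ref <- panel$outgroup_id
  rows <- list()
  for (gene in names(alignments)) {
    aln <- alignments[[gene]]
    if (mode == "reference") {
      if (!ref %in% names(aln)) {
        warning("gene ", gene, ": reference ", ref, " missing; skipped")
        next
      }
      ids <- setdiff(intersect(names(aln), info$id), ref)
      absent <- setdiff(setdiff(info$id, ref), names(aln))
      if (length(absent))
        warning("gene ", gene, " missing for: ", paste(absent, collapse = ", "))
      for (id in ids) {
        est <- ng86_pair(aln[[id]], aln[[ref]], gene = gene,
                         id1 = id, id2 = ref)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, id = id,
          genus = info$genus[match(id, info$id)],
          ka = est$ka, ks = est$ks, ratio = est$ratio,
          classification = est$classification, stringsAsFactors = FALSE)
      }
    } else {
      ids <- setdiff(intersect(names(aln), info$id), ref)
      if (length(ids) < 2L) next
      prs <- utils::combn(ids, 2L)
      for (k in seq_len(ncol(prs))) {
        a <- prs[1L, k]; b <- prs[2L, k]
        est <- ng86_pair(aln[[a]], aln[[b]], gene = gene, id1 = a, id2 = b)
        for (id in c(a, b))
          rows[[length(rows) + 1L]] <- data.frame(
            gene = gene, id = id,
            genus = info$genus[match(id, info$id)],
            ka = est$ka, ks = est$ks, ratio = est$ratio,
            classification = est$classification, stringsAsFactors = FALSE)
      }
    }
  }
  per_species <- do.call(rbind, rows)
  genera <- sort(unique(per_species$genus))
  genes <- unique(per_species$gene)
  gm <- matrix(NA_real_, length(genes), length(genera),
               dimnames = list(genes, genera))
  for (g in genes) for (gen in genera) {
    v <- per_species$ratio[per_species$gene == g & per_species$genus == gen]
    v <- v[!is.na(v)]
    if (length(v)) gm[g, gen] <- mean(v)
  }
  overall <- sort(rowMeans(gm, na.rm = TRUE), decreasing = TRUE)
  structure(list(per_species = per_species, genus_means = gm,
                 overall = overall, mode = mode),
            class = "genus_selection_summary")
}

#' @export
print.genus_selection_summary <- function(x, ...) {
  cat("per-gene mean Ka/Ks across genera (", x$mode, " mode):\n", sep = "")
  print(round(x$overall, 3))
  invisible(x)
}
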