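#' Global pairwise alignment (Needleman-Wunsch, linear gap penalty)
#'
#' Deterministic traceback: on score ties the diagonal (substitution) move is
#' preferred, then the vertical move (gap in \code{b}), then the horizontal
#' move (gap in \code{a}).
#'
#' @param a,b residue sequences (nucleotide or amino acid strings).
#' @param match,mismatch,gap scoring parameters (defaults 1/-1/-2).
#' @return list: \code{a}, \code{b} (aligned strings with "-"), \code{score},
#'   \code{identity} (fraction of aligned non-gap columns that match).
#' @export
#' @examples
#' align_pair("ACGT", "ACT")$score  # 1
align_pair <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1L] <- gap * 0:n
  S[1L, ] <- gap * 0:m
  for (i in seq_len(n)) {
    sub <- ifelse(bv == av[i], match, mismatch)
    for (j in seq_len(m))
      S[i + 1L, j + 1L] <- max(S[i, j] + sub[j],
                               S[i, j + 1L] + gap,
                               S[i + 1L, j] + gap)
  }
  # traceback, diagonal > up > left on ties
  i <- n; j <- m
  ra <- character(0); rb <- character(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] ==
        S[i, j] + ifelse(av[i] == bv[j], match, mismatch)) {
      ra <- c(av[i], ra); rb <- c(bv[j], rb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1L
    }
  }
  ident <- ra == rb & ra != "-"
  both <- ra != "-" & rb != "-"
  list(a = paste(ra, collapse = ""), b = paste(rb, collapse = ""),
       score = S[n + 1L, m + 1L],
       identity = if (any(both)) sum(ident) / sum(both) else NA_real_)
}

#' Codon-aware alignment of two coding sequences
#'
#' Aligns the translated amino-acid sequences (invertebrate mitochondrial
#' code) with \code{\link{align_pair}} and back-threads the codons, so the
#' nucleotide alignment contains only whole-codon gaps.  Terminal incomplete
#' stop codons should be removed beforehand (see
#' \code{\link{extract_codons}}).
#'
#' @param a,b coding sequences (lengths multiples of 3, no stop codons).
#' @param ... scoring parameters passed to \code{\link{align_pair}}.
#' @return list: \code{a}, \code{b} codon-aligned nucleotide strings.
#' @export
align_codon_pair <- function(a, b, ...) {
  thread <- function(seq, aln_aa) {
    starts <- seq(1L, nchar(seq) - 2L, by = 3L)
    codons <- substring(seq, starts, starts + 2L)
    out <- character(nchar(aln_aa))
    k <- 0L
    for (i in seq_len(nchar(aln_aa))) {
      if (substr(aln_aa, i, i) == "-") out[i] <- "---"
      else { k <- k + 1L; out[i] <- codons[k] }
    }
    paste(out, collapse = "")
  }
  pa <- translate_codons(a); pb <- translate_codons(b)
  aln <- align_pair(pa, pb, ...)
  list(a = thread(a, aln$a), b = thread(b, aln$b))
}

#' Translate a coding sequence under the invertebrate mitochondrial code
#' @param seq DNA string, length a multiple of 3.
#' @return amino-acid string (stops as "*").
#' @export
translate_codons <- function(seq) {
  code <- invertebrate_mito_code()
  starts <- seq(1L, nchar(seq) - 2L, by = 3L)
  paste(code[substring(toupper(seq), starts, starts + 2L)], collapse = "")
}

#' Pairwise distance matrix from a multiple alignment
#'
#' p-distance over columns where neither sequence has a gap, optionally
#' corrected: Jukes-Cantor for nucleotides
#' (d = -3/4 ln(1 - 4p/3)) or Poisson for amino acids (d = -ln(1 - p)).
#' Saturated pairs (correction undefined) are flagged and set to the largest
#' finite corrected distance in the matrix.
#'
#' @param aln named character vector of aligned sequences (equal lengths).
#' @param model "jc" (default), "p" (uncorrected), or "poisson".
#' @return symmetric matrix with zero diagonal; attribute
#'   \code{saturated} lists flagged pairs.
#' @export
dist_matrix <- function(aln, model = c("jc", "p", "poisson")) {
  model <- match.arg(model)
  if (length(unique(nchar(aln))) != 1L)
    stop("sequences must be aligned to equal length")
  n <- length(aln)
  ids <- names(aln)
  if (is.null(ids)) stop("alignment must be named by taxon")
  chars <- lapply(aln, function(s) strsplit(toupper(s), "")[[1]])
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  sat <- character(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- chars[[i]]; b <- chars[[j]]
    ok <- a != "-" & b != "-"
    p <- if (any(ok)) mean(a[ok] != b[ok]) else NA_real_
    d <- switch(model,
                p = p,
                jc = if (!is.na(p) && p < 3 / 4) -3 / 4 * log(1 - 4 * p / 3)
                     else NA_real_,
                poisson = if (!is.na(p) && p < 1) -log(1 - p) else NA_real_)
    if (is.na(d)) sat <- c(sat, paste(ids[i], ids[j], sep = "|"))
    D[i, j] <- D[j, i] <- d
  }
  if (length(sat)) {
    mx <- max(D[is.finite(D)], na.rm = TRUE)
    D[is.na(D)] <- mx
    warning("saturated pair(s) set to max finite distance: ",
            paste(sat, collapse = ", "))
  }
  attr(D, "saturated") <- sat
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining (via \code{ape::nj}) on a symmetric distance
#' matrix; negative branch lengths are clamped to zero with a flag.
#'
#' @param d symmetric numeric matrix (zero diagonal) or \code{dist}.
#' @return an unrooted \code{ape::phylo}; attribute \code{clamped} counts
#'   branches clamped to zero.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(!is.finite(d))) stop("distance matrix has non-finite entries")
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  tr <- ape::nj(as.dist(d))
  neg <- tr$edge.length < 0
  tr$edge.length[neg] <- 0
  attr(tr, "clamped") <- sum(neg)
  tr
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' Number of bipartitions present in exactly one of the two trees (identical
#' leaf sets required).
#'
#' @param t1,t2 \code{phylo} trees.
#' @return non-negative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) stop("leaf sets differ")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)))
}

#' Is a taxon set monophyletic after outgroup rooting?
#'
#' Roots the tree on the declared outgroup and tests whether the group forms
#' a clade.
#'
#' @param tree a \code{phylo}.
#' @param outgroup tip label used to root.
#' @param group character vector of tip labels.
#' @return logical.
#' @export
check_monophyly <- function(tree, outgroup, group) {
  if (!outgroup %in% tree$tip.label) stop("outgroup not in tree")
  if (!all(group %in% tree$tip.label))
    stop("group members missing from tree: ",
         paste(setdiff(group, tree$tip.label), collapse = ", "))
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  if (length(group) <= 1L) return(TRUE)
  ape::is.monophyletic(rooted, group)
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Genes are concatenated in alphabetical order.  The P12 and P12R datasets
#' drop every third codon position of protein-coding partitions; rRNA
#' partitions are never codon-masked.  Taxa missing from a partition are
#' gap-filled with a warning.
#'
#' @param alignments named list: gene -> named character vector of aligned
#'   sequences.
#' @param dataset one of "P123" (PCGs, all positions), "P123R" (plus rRNAs),
#'   "P12" (PCGs, positions 1-2), "P12R" (plus rRNAs).
#' @return list: \code{matrix} named character vector (the concatenated
#'   alignment), \code{partitions} data.frame (gene, start, end in matrix
#'   coordinates).
#' @export
build_supermatrix <- function(alignments,
                              dataset = c("P123", "P123R", "P12", "P12R")) {
  dataset <- match.arg(dataset)
  use_rrna <- grepl("R$", dataset)
  mask3 <- dataset %in% c("P12", "P12R")
  rrna <- mito_gene_names("rRNA")
  genes <- sort(names(alignments))
  if (!use_rrna) genes <- setdiff(genes, rrna)
  taxa <- sort(unique(unlist(lapply(alignments[genes], names))))
  parts <- list()
  chunks <- list()
  pos <- 0L
  for (g in genes) {
    aln <- alignments[[g]]
    w <- unique(nchar(aln))
    if (length(w) != 1L) stop("partition '", g, "' is not aligned")
    missing <- setdiff(taxa, names(aln))
    if (length(missing)) {
      warning("partition '", g, "' gap-filled for: ",
              paste(missing, collapse = ", "))
      aln[missing] <- strrep("-", w)
    }
    aln <- aln[taxa]
    if (mask3 && !g %in% rrna) {
      if (w %% 3L != 0L)
        stop("partition '", g, "' length not a multiple of 3")
      keep <- which(seq_len(w) %% 3L != 0L)
      aln <- vapply(aln, function(s)
        paste(strsplit(s, "")[[1]][keep], collapse = ""), "")
      w <- length(keep)
    }
    chunks[[g]] <- aln
    parts[[g]] <- data.frame(gene = g, start = pos + 1L, end = pos + w,
                             stringsAsFactors = FALSE)
    pos <- pos + w
  }
  mat <- vapply(taxa, function(tx)
    paste(vapply(chunks, `[[`, "", tx), collapse = ""), "")
  list(matrix = mat, partitions = do.call(rbind, parts), dataset = dataset)
}
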