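#' Nucleotide composition and strand skews
#'
#' Computes base counts (or accepts proportions), A+T content, and the strand
#' asymmetry statistics AT skew = (A - T)/(A + T) and
#' GC skew = (G - C)/(G + C).  Ambiguity codes are counted in the total but
#' excluded from the skew numerators and the A/C/G/T tallies.
#'
#' @param x either a DNA string, or a named numeric vector of proportions for
#'   A, C, G, T (summing to 1 within 0.5\%).
#' @return list of class \code{composition_stats}: \code{counts} (or NULL when
#'   built from proportions), \code{proportions}, \code{at_content},
#'   \code{at_skew}, \code{gc_skew}.  Degenerate skews (empty denominator) are
#'   NA with a warning.
#' @export
#' @examples
#' composition(c(A = 0.333, T = 0.420, C = 0.115, G = 0.133))$at_skew
composition <- function(x) {
  if (is.character(x)) {
    if (length(x) != 1L || !nzchar(x)) stop("empty sequence")
    s <- toupper(x)
    counts <- vapply(c("A", "C", "G", "T"), function(b)
      sum(charToRaw(s) == charToRaw(b)), integer(1))
    prop <- counts / nchar(s)
  } else if (is.numeric(x)) {
    if (!all(c("A", "C", "G", "T") %in% names(x)))
      stop("proportions must be named A, C, G, T")
    x <- x[c("A", "C", "G", "T")]
    if (abs(sum(x) - 1) > 0.005)
      stop("proportions must sum to 1 within 0.5%")
    counts <- NULL
    prop <- x
  } else stop("x must be a DNA string or named proportions")
  at <- prop[["A"]] + prop[["T"]]
  gc <- prop[["G"]] + prop[["C"]]
  at_skew <- if (at > 0) (prop[["A"]] - prop[["T"]]) / at else {
    warning("no A/T bases: AT skew undefined"); NA_real_
  }
  gc_skew <- if (gc > 0) (prop[["G"]] - prop[["C"]]) / gc else {
    warning("no G/C bases: GC skew undefined"); NA_real_
  }
  structure(list(counts = counts, proportions = prop,
                 at_content = unname(at), at_skew = unname(at_skew),
                 gc_skew = unname(gc_skew)),
            class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf("A+T %.1f%%  AT skew %.3f  GC skew %.3f\n",
              100 * x$at_content, x$at_skew, x$gc_skew))
  invisible(x)
}

#' Per-gene composition statistics
#'
#' One row per annotated feature, computed on the coding-strand sequence of
#' each gene (reverse complement for minor-strand genes), mirroring the
#' AT\%, AT-skew and GC-skew columns of a genome annotation table.
#'
#' @param genome a \code{mito_genome} with sequence.
#' @return data.frame: gene, class, strand, length, at_content, at_skew,
#'   gc_skew.
#' @export
per_gene_stats <- function(genome) {
  if (is.null(genome$sequence))
    stop("genome carries no sequence; per-gene composition needs one ",
         "(use composition() on printed proportions for sequence-free mode)")
  f <- genome$features
  res <- lapply(f$gene, function(g)
    composition(extract_gene_sequence(genome, g)))
  data.frame(gene = f$gene, class = f$class, strand = f$strand,
             length = unname(feature_lengths(genome)),
             at_content = vapply(res, `[[`, numeric(1), "at_content"),
             at_skew = vapply(res, `[[`, numeric(1), "at_skew"),
             gc_skew = vapply(res, `[[`, numeric(1), "gc_skew"),
             stringsAsFactors = FALSE)
}

#' Gene-junction (intergenic/overlap) report
#'
#' For consecutive features in coordinate order, the intergenic nucleotide
#' count INC = start(next) - end(prev) - 1: positive values are spacers,
#' negative values overlaps, zero abutting genes.  In circular mode one extra
#' wrap junction (last feature to first, across the origin) is added using the
#' genome length rule of \code{\link{genome_length}}.
#'
#' @param genome a \code{mito_genome} with at least two features.
#' @param circular include the origin-wrapping junction (default TRUE).
#' @return list of class \code{junction_report}: \code{junctions} data.frame
#'   (upstream, downstream, inc), spacer/overlap counts and summed lengths,
#'   and the longest spacer and overlap with their flanking genes (first in
#'   coordinate order on ties).
#' @export
junction_report <- function(genome, circular = TRUE) {
  f <- genome$features
  if (nrow(f) < 2L) stop("need at least two features")
  if (anyDuplicated(f[, c("start", "end")]))
    stop("duplicate feature span")
  up <- f$gene[-nrow(f)]
  dn <- f$gene[-1L]
  inc <- f$start[-1L] - f$end[-nrow(f)] - 1L
  if (circular) {
    L <- genome_length(genome)
    up <- c(up, f$gene[nrow(f)])
    dn <- c(dn, f$gene[1L])
    inc <- c(inc, L - f$end[nrow(f)] + f$start[1L] - 1L)
  }
  jx <- data.frame(upstream = up, downstream = dn, inc = as.integer(inc),
                   stringsAsFactors = FALSE)
  sp <- jx[jx$inc > 0L, , drop = FALSE]
  ov <- jx[jx$inc < 0L, , drop = FALSE]
  pick <- function(d, decreasing) {
    if (!nrow(d)) return(NULL)
    d[order(d$inc, decreasing = decreasing)[1L], ]
  }
  structure(list(
    junctions = jx,
    n_spacers = nrow(sp), spacer_total = sum(sp$inc),
    n_overlaps = nrow(ov), overlap_total = sum(abs(ov$inc)),
    n_abutting = sum(jx$inc == 0L),
    longest_spacer = pick(sp, TRUE),
    longest_overlap = pick(ov, FALSE)),
    class = "junction_report")
}

#' @export
print.junction_report <- function(x, ...) {
  cat(sprintf("%d spacers (%d bp), %d overlaps (%d bp), %d abutting\n",
              x$n_spacers, x$spacer_total, x$n_overlaps, x$overlap_total,
              x$n_abutting))
  if (!is.null(x$longest_spacer))
    cat(sprintf("longest spacer: %d bp (%s - %s)\n", x$longest_spacer$inc,
                x$longest_spacer$upstream, x$longest_spacer$downstream))
  if (!is.null(x$longest_overlap))
    cat(sprintf("longest overlap: %d bp (%s - %s)\n",
                abs(x$longest_overlap$inc),
                x$longest_overlap$upstream, x$longest_overlap$downstream))
  invisible(x)
}

#' Whole-genome annotation summary
#'
#' Gene-class totals (count, summed length, fraction of genome length),
#' strand tallies, and the shortest/longest gene per class.
#'
#' @param genome a \code{mito_genome}.
#' @return list of class \code{genome_summary}.
#' @export
genome_summary <- function(genome) {
  f <- genome$features
  len <- feature_lengths(genome)
  L <- genome_length(genome)
  by_class <- lapply(c(PCG = "PCG", tRNA = "tRNA", rRNA = "rRNA"), function(cl) {
    i <- f$class == cl
    if (!any(i)) return(list(n = 0L, total_bp = 0L, fraction = 0,
                             min_gene = NA, max_gene = NA))
    l <- len[i]
    list(n = sum(i), total_bp = sum(l), fraction = sum(l) / L,
         min_gene = stats::setNames(min(l), names(l)[which.min(l)]),
         max_gene = stats::setNames(max(l), names(l)[which.max(l)]))
  })
  structure(list(
    id = genome$id, length = L, n_features = nrow(f),
    by_class = by_class,
    n_major = sum(f$strand == "+"), n_minor = sum(f$strand == "-")),
    class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  cat("genome ", x$id, ": ", x$length, " bp, ", x$n_features, " genes (",
      x$n_major, " major / ", x$n_minor, " minor strand)\n", sep = "")
  for (cl in names(x$by_class)) {
    b <- x$by_class[[cl]]
    if (b$n == 0) next
    cat(sprintf("  %-4s n=%2d  %5d bp (%.1f%%)  range %s %d..%s %d bp\n",
                cl, b$n, b$total_bp, 100 * b$fraction,
                names(b$min_gene), b$min_gene, names(b$max_gene), b$max_gene))
  }
  invisible(x)
}
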