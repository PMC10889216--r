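#' Simulate a sequence for an annotated mitogenome
#'
#' Generates a major-strand sequence honoring a genome's annotation: every
#' protein-coding gene begins with its annotated start codon, ends with its
#' annotated (possibly incomplete) stop codon and contains no internal
#' in-frame stop, including inside regions where protein-coding genes overlap
#' in different frames or on opposite strands; all other positions are drawn
#' independently from the target base composition.  Fully deterministic under
#' the seed.
#'
#' @param seed integer RNG seed.
#' @param template annotated \code{mito_genome} providing coordinates, strands
#'   and codons (default: the packaged 37-gene fixture).
#' @param base_comp named target base composition (A/C/G/T proportions;
#'   default the strongly AT-biased composition typical of these genomes:
#'   33.3\% A, 42.0\% T, 11.5\% C, 13.3\% G).
#' @param id id of the simulated genome.
#' @param max_sweeps cap on constraint-repair sweeps over overlapping genes.
#' @return a \code{mito_genome} with sequence.
#' @export
simulate_genome <- function(seed, template = make_table1_fixture(),
                            base_comp = c(A = 0.333, T = 0.420,
                                          C = 0.115, G = 0.133),
                            id = sprintf("SIM_%d", seed),
                            max_sweeps = 500L) {
  stopifnot(abs(sum(base_comp) - 1) < 0.005)
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  p <- base_comp[bases]
  f <- template$features
  L <- genome_length(template)
  seqv <- sample(bases, L, replace = TRUE, prob = p)

  # major-strand positions of a feature in coding orientation
  coding_idx <- function(i) {
    span <- if (isTRUE(f$wraps_origin[i]))
      c(f$start[i]:L, 1L:f$end[i]) else f$start[i]:f$end[i]
    if (f$strand[i] == "-") rev(span) else span
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  write_coding <- function(idx, codon_str, strand) {
    b <- strsplit(codon_str, "")[[1]]
    if (strand == "-") b <- comp[b]
    seqv[idx] <<- b
  }
  read_coding <- function(idx, strand) {
    b <- seqv[idx]
    if (strand == "-") b <- comp[b]
    b
  }
  draw_sense_codon <- function() {
    repeat {
      cd <- paste(sample(bases, 3L, replace = TRUE, prob = p), collapse = "")
      if (!cd %in% c("TAA", "TAG")) return(cd)
    }
  }

  pcg <- which(f$class == "PCG")
  # interiors first, then starts/stops, whose positions become protected
  for (i in pcg) {
    idx <- coding_idx(i)
    n <- length(idx)
    stop_len <- nchar(f$stop_codon[i])
    body <- seq(4L, n - stop_len, by = 3L)
    for (s in body)
      write_coding(idx[s:(s + 2L)], draw_sense_codon(), f$strand[i])
  }
  protected <- logical(L)
  for (i in pcg) {
    idx <- coding_idx(i)
    n <- length(idx)
    stop_len <- nchar(f$stop_codon[i])
    write_coding(idx[1:3], f$start_codon[i], f$strand[i])
    write_coding(idx[(n - stop_len + 1L):n], f$stop_codon[i], f$strand[i])
    protected[idx[c(1:3, (n - stop_len + 1L):n)]] <- TRUE
  }

  # repair sweeps: overlapping frames can re-create stops; mutate a free base
  for (sweep in seq_len(max_sweeps)) {
    clean <- TRUE
    for (i in pcg) {
      idx <- coding_idx(i)
      n <- length(idx)
      stop_len <- nchar(f$stop_codon[i])
      starts <- seq(4L, n - stop_len - 2L, by = 3L)
      for (s in starts) {
        pos3 <- idx[s:(s + 2L)]
        cd <- paste(read_coding(pos3, f$strand[i]), collapse = "")
        if (!cd %in% c("TAA", "TAG")) next
        clean <- FALSE
        free <- which(!protected[pos3])
        if (!length(free))
          stop("infeasible overlap: stop codon fully pinned in ", f$gene[i])
        k <- free[sample.int(length(free), 1L)]
        cur <- read_coding(pos3[k], f$strand[i])
        # any change of one base of TAA/TAG away from the stop pair works
        # unless it recreates the other stop (third position A<->G)
        alt <- setdiff(bases, if (k == 3L) c("A", "G", cur) else cur)
        newb <- sample(alt, 1L, prob = p[alt] / sum(p[alt]))
        b <- newb
        if (f$strand[i] == "-") b <- comp[b]
        seqv[pos3[k]] <- b
      }
    }
    if (clean) break
    if (sweep == max_sweeps)
      stop("constraint repair did not converge in ", max_sweeps, " sweeps")
  }

  mito_genome(id, f, taxon = sprintf("simulated (%s template)", template$id),
              genus = "Simulatus", sequence = paste(seqv, collapse = ""))
}

#' Evolve codon sequences along a tree with per-gene dN/dS
#'
#' A deliberately simple omega-thinned codon process (not a full
#' Goldman-Yang model): along each branch, single-nucleotide changes are
#' proposed at a Poisson rate per codon position; proposals creating stop
#' codons are discarded, synonymous proposals are accepted with the base
#' acceptance probability, and nonsynonymous proposals at omega times that
#' probability, so the realized nonsynonymous/synonymous rate ratio per
#' opportunity is omega by construction.  No indels, so leaf sequences are
#' already columnar alignments.  Realized accepted substitution counts are
#' recorded per branch and gene as ground truth.
#'
#' @param seed integer RNG seed.
#' @param tree \code{ape::phylo} with branch lengths (default
#'   \code{\link{planorbidae_reference_tree}()}).
#' @param omega per-gene dN/dS: scalar or vector named by gene (>= 0; 0 means
#'   no nonsynonymous change is ever accepted).
#' @param n_codons per-gene codon counts: named integer vector (default: the
#'   13 protein-coding genes at the fixture's codon counts).
#' @param rate substitution-proposal rate per codon position per unit branch
#'   length (default 1).
#' @param base_comp root-sequence composition target.
#' @param include_rrna also evolve two unconstrained nucleotide partitions
#'   (rrnS 709 bp, rrnL 1006 bp) under the same proposal rate.
#' @param genus_map optional named vector tip label -> genus for the panel
#'   metadata (default: the study panel mapping when the tips match it, else
#'   the tip label itself).
#' @return list of class \code{evolved_panel}: \code{panel}
#'   (\code{\link{species_panel}}), \code{alignments} (gene -> named character
#'   vector), \code{tree}, \code{realized} (data.frame gene, parent, child,
#'   syn, nonsyn).
#' @export
evolve_panel <- function(seed, tree = planorbidae_reference_tree(),
                         omega = 0.2, n_codons = NULL, rate = 1,
                         base_comp = c(A = 0.333, T = 0.420,
                                       C = 0.115, G = 0.133),
                         include_rrna = FALSE, genus_map = NULL) {
  set.seed(as.integer(seed))
  if (any(omega < 0)) stop("omega must be >= 0")
  if (is.null(n_codons)) {
    fx <- make_table1_fixture()$features
    fx <- fx[fx$class == "PCG", ]
    n_codons <- stats::setNames(
      (fx$end - fx$start + 1L - nchar(fx$stop_codon)) %/% 3L, fx$gene)
  }
  genes <- names(n_codons)
  if (is.null(genes)) stop("n_codons must be named by gene")
  om <- if (length(omega) == 1L)
    stats::setNames(rep(omega, length(genes)), genes) else omega[genes]
  if (anyNA(om)) stop("omega missing for some genes")

  code <- invertebrate_mito_code()
  bases <- c("A", "C", "G", "T")
  p <- base_comp[bases]
  draw_root <- function(n) {
    cd <- character(n)
    for (i in seq_len(n)) {
      repeat {
        x <- paste(sample(bases, 3L, replace = TRUE, prob = p), collapse = "")
        if (code[[x]] != "*") break
      }
      cd[i] <- x
    }
    cd
  }
  a_syn <- stats::setNames(pmin(1, 1 / pmax(om, 1e-12)), genes)
  a_non <- stats::setNames(pmin(1, om), genes)  # a_non / a_syn = omega

  ntip <- length(tree$tip.label)
  edges <- tree$edge[order(tree$edge[, 1L]), , drop = FALSE]
  # preorder traversal: process edges parent-first
  preord <- ape::reorder.phylo(tree, "cladewise")$edge
  elen <- tree$edge.length[match(paste(preord[, 1], preord[, 2]),
                                 paste(tree$edge[, 1], tree$edge[, 2]))]

  alignments <- list()
  realized <- list()
  for (g in genes) {
    nc <- n_codons[[g]]
    node_seq <- vector("list", max(tree$edge))
    root <- ntip + 1L
    node_seq[[root]] <- draw_root(nc)
    for (e in seq_len(nrow(preord))) {
      par <- preord[e, 1L]; child <- preord[e, 2L]
      cd <- node_seq[[par]]
      t <- elen[e]
      nprop <- stats::rpois(1L, 3 * nc * rate * t)
      syn <- 0L; non <- 0L
      if (nprop > 0) for (k in seq_len(nprop)) {
        ci <- sample.int(nc, 1L)
        pos <- sample.int(3L, 1L)
        cur <- cd[ci]
        curb <- substr(cur, pos, pos)
        newb <- sample(setdiff(bases, curb), 1L)
        mut <- cur
        substr(mut, pos, pos) <- newb
        if (code[[mut]] == "*") next
        if (code[[mut]] == code[[cur]]) {
          if (stats::runif(1L) < a_syn[[g]]) { cd[ci] <- mut; syn <- syn + 1L }
        } else {
          if (stats::runif(1L) < a_non[[g]]) { cd[ci] <- mut; non <- non + 1L }
        }
      }
      node_seq[[child]] <- cd
      realized[[length(realized) + 1L]] <- data.frame(
        gene = g, parent = par, child = child, syn = syn, nonsyn = non,
        stringsAsFactors = FALSE)
    }
    alignments[[g]] <- stats::setNames(
      vapply(seq_len(ntip), function(i) paste(node_seq[[i]], collapse = ""), ""),
      tree$tip.label)
  }

  if (include_rrna) {
    rr <- c(rrnS = 709L, rrnL = 1006L)
    for (g in names(rr)) {
      n <- rr[[g]]
      node_seq <- vector("list", max(tree$edge))
      node_seq[[ntip + 1L]] <- sample(bases, n, replace = TRUE, prob = p)
      for (e in seq_len(nrow(preord))) {
        par <- preord[e, 1L]; child <- preord[e, 2L]
        s <- node_seq[[par]]
        nsub <- stats::rpois(1L, n * rate * elen[e])
        if (nsub > 0) for (k in seq_len(nsub)) {
          i <- sample.int(n, 1L)
          s[i] <- sample(setdiff(bases, s[i]), 1L)
        }
        node_seq[[child]] <- s
      }
      alignments[[g]] <- stats::setNames(
        vapply(seq_len(ntip), function(i) paste(node_seq[[i]], collapse = ""), ""),
        tree$tip.label)
    }
  }

  info <- planorbidae_panel_info()
  tips <- tree$tip.label
  genus <- if (!is.null(genus_map)) unname(genus_map[tips])
    else if (all(tips %in% info$id)) info$genus[match(tips, info$id)]
    else tips
  panel_info <- data.frame(id = tips, taxon = tips, genus = genus,
                           stringsAsFactors = FALSE)
  outgroup <- if (all(tips %in% info$id))
    intersect(tips, info$id[info$outgroup]) else character(0)
  panel <- species_panel(panel_info,
                         outgroup_id = if (length(outgroup)) outgroup[1]
                                       else NULL)
  structure(list(panel = panel, alignments = alignments, tree = tree,
                 realized = do.call(rbind, realized)),
            class = "evolved_panel")
}
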