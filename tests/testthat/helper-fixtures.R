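# helpers shared across test files: GenBank fixture writer and independent
# oracles (brute-force pathway enumeration, exhaustive alignment scoring,
# unrestricted minimal-event search)

# write a GenBank flat file for a mito_genome, using GenBank-style labels so
# the synonym mapping is exercised
write_genbank_fixture <- function(genome, path,
                                  drop_anticodon = character(0)) {
  gb_label <- c(cox1 = "COI", cox2 = "COII", cox3 = "COIII", cob = "CYTB",
                atp6 = "ATP6", atp8 = "ATP8",
                nad1 = "ND1", nad2 = "ND2", nad3 = "ND3", nad4 = "ND4",
                nad4L = "ND4L", nad5 = "ND5", nad6 = "ND6",
                rrnS = "12S ribosomal RNA", rrnL = "16S ribosomal RNA")
  trn_label <- c(A = "Ala", C = "Cys", D = "Asp", E = "Glu", F = "Phe",
                 G = "Gly", H = "His", I = "Ile", K = "Lys", L1 = "Leu",
                 L2 = "Leu", M = "Met", N = "Asn", P = "Pro", Q = "Gln",
                 R = "Arg", S1 = "Ser", S2 = "Ser", T = "Thr", V = "Val",
                 W = "Trp", Y = "Tyr")
  L <- genome_length(genome)
  lines <- c(sprintf("LOCUS       %s %d bp    DNA     circular INV", genome$id, L),
             sprintf("ACCESSION   %s", genome$id),
             "  ORGANISM  Simulatus syntheticus",
             "FEATURES             Location/Qualifiers")
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    loc <- if (isTRUE(f$wraps_origin[i]))
      sprintf("join(%d..%d,%d..%d)", f$start[i], L, 1L, f$end[i])
    else sprintf("%d..%d", f$start[i], f$end[i])
    if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    key <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA")[[f$class[i]]]
    g <- f$gene[i]
    if (f$class[i] == "tRNA") {
      aa <- trn_label[[substring(g, 4)]]
      lines <- c(lines,
                 sprintf("     %-16s%s", key, loc),
                 sprintf('                     /product="tRNA-%s"', aa))
      if (!is.na(f$anticodon[i]) && !g %in% drop_anticodon)
        lines <- c(lines, sprintf(
          '                     /anticodon=(pos:complement(0..0),aa:%s,seq:%s)',
          aa, tolower(f$anticodon[i])))
    } else {
      lines <- c(lines,
                 sprintf("     %-16s%s", key, loc),
                 sprintf('                     /gene="%s"', gb_label[[g]]))
    }
  }
  if (!is.null(genome$sequence)) {
    lines <- c(lines, "ORIGIN")
    s <- tolower(genome$sequence)
    for (off in seq(1L, nchar(s), by = 60L)) {
      chunk <- substr(s, off, min(off + 59L, nchar(s)))
      blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      lines <- c(lines, sprintf("%9d %s", off, paste(blocks, collapse = " ")))
    }
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

# independent NG86 pathway oracle: recursive DFS over all orderings of the
# differing positions, skipping pathways through stops (all pathways when
# every one is blocked), classifying each step with the genetic code
oracle_pathway <- function(c1, c2) {
  code <- invertebrate_mito_code()
  diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(diffs)) return(c(nd = 0, sd = 0))
  paths <- list()
  dfs <- function(cur, remaining, nd, sd, blocked) {
    if (!length(remaining)) {
      paths[[length(paths) + 1L]] <<- c(nd, sd, blocked)
      return(invisible())
    }
    for (pos in remaining) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      is_stop <- code[[nxt]] == "*"
      step_syn <- !is_stop && code[[nxt]] == code[[cur]]
      # when the intermediate is a stop the step classification is moot; we
      # still count it for the unrestricted fallback (nonsyn by definition:
      # a stop differs from any sense amino acid)
      dfs(nxt, setdiff(remaining, pos),
          nd + ifelse(step_syn, 0, 1), sd + ifelse(step_syn, 1, 0),
          blocked || is_stop)
    }
  }
  dfs(c1, diffs, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  ok <- m[, 3] == 0
  if (any(ok)) m <- m[ok, , drop = FALSE]
  c(nd = mean(m[, 1]), sd = mean(m[, 2]))
}

# exhaustive global-alignment score oracle for short sequences
oracle_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0)
      best <- max(best, rec(i - 1, j - 1) +
                    ifelse(av[i] == bv[j], match, mismatch))
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(length(av), length(bv))
}

# unrestricted brute-force minimal deletion set over ALL gene subsets
oracle_min_events <- function(reference, query, max_size = 6L) {
  r <- normalize_gene_order(reference)
  q <- normalize_gene_order(query)
  tok_r <- order_tokens(r); tok_q <- order_tokens(q)
  equal_after <- function(drop) {
    k1 <- tok_r[!r$genes %in% drop]
    k2 <- tok_q[!q$genes %in% drop]
    if (!length(k1)) return(TRUE)
    j <- match(k1[1], k2)
    if (is.na(j)) return(FALSE)
    n <- length(k2)
    identical(k1, k2[c(j:n, seq_len(j - 1))[seq_len(n)]])
  }
  genes <- sort(r$genes)
  for (k in 0:max_size) {
    sets <- if (k == 0) list(character(0)) else combn(genes, k, simplify = FALSE)
    for (s in sets) if (equal_after(s)) return(s)
  }
  NULL
}

# random gene order over a small synthetic vocabulary (always contains cox1)
random_small_order <- function(n_genes, id = "rand") {
  genes <- c("cox1", paste0("g", seq_len(n_genes - 1L)))
  perm <- sample(genes)
  gene_order(id, perm, sample(c("+", "-"), n_genes, replace = TRUE))
}

expect_no_warning <- function(expr) testthat::expect_warning(expr, regexp = NA)
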