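test_that("global alignment scores and traceback are correct", {
  same <- align_pair("ACGTACGT", "ACGTACGT")
  expect_equal(same$score, 8)
  expect_equal(same$identity, 1)
  expect_false(grepl("-", same$a))

  # 4x3 dynamic-programming table worked by hand: one gap, score 1
  a <- align_pair("ACGT", "ACT")
  expect_equal(a$score, 1)
  expect_equal(sum(strsplit(a$b, "")[[1]] == "-"), 1)
  expect_error(align_pair("", "ACGT"), "empty")
})

test_that("alignment scores match the exhaustive oracle and Biostrings", {
  set.seed(5)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = TRUE)
  for (k in 1:15) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(3:8, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(3:8, 1), TRUE),
               collapse = "")
    s <- align_pair(a, b)$score
    expect_equal(s, oracle_align_score(a, b))
    expect_equal(s, Biostrings::score(Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = submat,
      gapOpening = 0, gapExtension = 2)))
  }
})

test_that("codon-aware alignment back-threads whole-codon gaps", {
  a <- "ATGAAATTTGGA"         # M K F G
  b <- "ATGTTTGGA"            # M F G
  al <- align_codon_pair(a, b)
  expect_equal(nchar(al$a), nchar(al$b))
  expect_equal(nchar(al$a) %% 3, 0)
  expect_identical(gsub("-", "", al$a), a)
  expect_identical(gsub("-", "", al$b), b)
  # the gap is one whole codon, aligned at the lysine position
  expect_identical(substr(al$b, 4, 6), "---")
})

test_that("supermatrix construction masks third positions and maps partitions", {
  taxa <- c("t1", "t2")
  aln <- list(
    nad1 = stats::setNames(c(strrep("ATG", 100), strrep("ATA", 100)), taxa),
    cox1 = stats::setNames(c(strrep("GGA", 200), strrep("GGC", 200)), taxa),
    rrnS = stats::setNames(c(strrep("A", 500), strrep("T", 500)), taxa))

  p123 <- build_supermatrix(aln[c("nad1", "cox1")], "P123")
  expect_equal(unique(nchar(p123$matrix)), 900)
  p12 <- build_supermatrix(aln[c("nad1", "cox1")], "P12")
  expect_equal(unique(nchar(p12$matrix)), 600)
  p12r <- build_supermatrix(aln, "P12R")
  expect_equal(unique(nchar(p12r$matrix)), 1100)   # rRNA never masked
  p123r <- build_supermatrix(aln, "P123R")
  expect_equal(unique(nchar(p123r$matrix)), 1400)

  # partition bookkeeping: post-masking lengths tile the matrix
  parts <- p12r$partitions
  expect_identical(parts$gene, sort(names(aln)))   # alphabetical order
  expect_equal(parts$start[1], 1L)
  expect_true(all(parts$start[-1] == head(parts$end, -1) + 1L))
  expect_equal(parts$end[nrow(parts)], 1100L)
  # masking keeps codon positions 1-2 only
  p12parts <- p12$partitions
  nad1_span <- p12parts[p12parts$gene == "nad1", ]
  expect_identical(substr(p12$matrix[["t2"]], nad1_span$start, nad1_span$end),
                   strrep("AT", 100))   # ATA with third positions dropped

  # taxa missing from a partition are gap-filled with a warning
  aln2 <- aln
  aln2$nad1 <- aln2$nad1["t1"]
  expect_warning(sm <- build_supermatrix(aln2, "P123R"), "gap-filled")
  # nad1 sits after cox1 alphabetically: columns 601-900 are gaps for t2
  expect_identical(substr(sm$matrix[["t2"]], 601, 900), strrep("-", 300))
  expect_error(build_supermatrix(list(g = c(a = "AT", b = "ATG")), "P123"),
               "not aligned")
})

test_that("distance matrices implement p, JC and Poisson corrections", {
  aln <- c(a = "AAAA", b = "AAAT", c = "AATT")
  P <- dist_matrix(aln, "p")
  expect_equal(unname(P["a", "b"]), 0.25)
  expect_true(isSymmetric(P))
  expect_true(all(diag(P) == 0))
  J <- dist_matrix(aln, "jc")
  expect_equal(unname(J["a", "b"]), -3 / 4 * log(1 - 4 * 0.25 / 3))
  W <- dist_matrix(c(x = "AR", y = "AK"), "poisson")
  expect_equal(unname(W["x", "y"]), -log(1 - 0.5))
  # gapped columns are excluded pairwise
  G <- dist_matrix(c(a = "A-AA", b = "ATAA"), "p")
  expect_equal(unname(G["a", "b"]), 0)
  # saturation is flagged and capped
  expect_warning(S <- dist_matrix(c(a = "AAAA", b = "TTTT", c = "AAAT"), "jc"),
                 "saturated")
  expect_length(attr(S, "saturated"), 2)   # a-b (p = 1) and b-c (p = 3/4)
})

test_that("neighbor joining solves the three-taxon case in closed form", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  # three-point formulas: a = (dab + dac - dbc)/2, etc.
  expect_equal(unname(bl["a"]), 0.5)
  expect_equal(unname(bl["b"]), 1.5)
  expect_equal(unname(bl["c"]), 2.5)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|3 taxa")
})

test_that("neighbor joining recovers additive-matrix topologies exactly", {
  set.seed(8)
  for (n in c(4, 6, 8)) {
    for (k in 1:5) {
      true <- ape::rtree(n, rooted = FALSE)
      true$edge.length <- stats::runif(nrow(true$edge), 0.05, 0.5)
      D <- ape::cophenetic.phylo(true)
      est <- nj_tree(D[true$tip.label, true$tip.label])
      expect_identical(robinson_foulds(est, true), 0L)
      # and the negative-branch clamp never fires on additive input
      expect_identical(attr(est, "clamped"), 0L)
    }
  }
})

test_that("Robinson-Foulds counts bipartitions unique to one tree", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  expect_identical(robinson_foulds(t1, t1), 0L)
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_identical(robinson_foulds(t1, t2), 2L)   # one split each, unshared
  # 6-taxon caterpillar vs balanced, by bipartition enumeration:
  # caterpillar splits {ab, abc, abcd}; balanced {ab, cd, ef}; ab is shared
  # and abcd|ef equals ef|abcd, so exactly one split is unique to each tree
  cat6 <- ape::read.tree(text = "(((((a,b),c),d),e),f);")
  bal6 <- ape::read.tree(text = "((a,b),(c,d),(e,f));")
  expect_identical(robinson_foulds(cat6, bal6), 2L)
  t3 <- ape::read.tree(text = "((a,b),(c,e));")
  expect_error(robinson_foulds(t1, t3), "leaf sets differ")
})

test_that("Newick serialization round-trips topology and branch lengths", {
  tr <- planorbidae_reference_tree(0.07)
  tmp <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, tmp)
  back <- ape::read.tree(tmp)
  expect_identical(robinson_foulds(tr, back), 0L)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-10)
})

test_that("monophyly checks after outgroup rooting match the study topology", {
  tr <- planorbidae_reference_tree()
  info <- planorbidae_panel_info()
  og <- info$id[info$outgroup]
  for (gen in unique(info$genus[!info$outgroup])) {
    ids <- info$id[info$genus == gen]
    expect_true(check_monophyly(tr, og, ids))
  }
  # all ingroup leaves form a clade; single leaves are trivially monophyletic
  expect_true(check_monophyly(tr, og, info$id[!info$outgroup]))
  expect_true(check_monophyly(tr, og, "OR684570"))
  # Planorbini + Polypylis clade holds; a cross-genus pick does not
  expect_true(check_monophyly(tr, og, c("OR684570", "OX421510", "MW357851")))
  expect_false(check_monophyly(tr, og, c("OR684570", "MK414453")))
  expect_error(check_monophyly(tr, "nope", "OR684570"), "outgroup")
  expect_error(check_monophyly(tr, og, "nope"), "missing from tree")
})
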