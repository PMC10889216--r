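test_that("normalization is idempotent, rotation- and reflection-invariant", {
  orders <- planorbidae_gene_orders()
  o <- orders$OR684570
  n1 <- normalize_gene_order(o)
  expect_identical(order_tokens(normalize_gene_order(n1)), order_tokens(n1))
  expect_identical(n1$genes[1], "cox1")
  expect_identical(n1$strand[1], "+")

  # same circle written from another start gene
  rot <- gene_order(o$id, c(o$genes[10:37], o$genes[1:9]),
                    c(o$strand[10:37], o$strand[1:9]))
  expect_identical(order_tokens(normalize_gene_order(rot)), order_tokens(n1))

  # full reverse-complement reading: reversed order, flipped signs
  refl <- gene_order(o$id, rev(o$genes),
                     rev(ifelse(o$strand == "+", "-", "+")))
  expect_identical(order_tokens(normalize_gene_order(refl)), order_tokens(n1))

  no_cox1 <- gene_order("x", c("nad1", "nad2"), c("+", "+"))
  expect_error(normalize_gene_order(no_cox1), "cox1")
})

test_that("event detection reproduces the described type-to-type deltas", {
  orders <- planorbidae_gene_orders()
  typeA <- orders$MK414453; typeB <- orders$MK414449
  typeC <- orders$EF433576; typeD <- orders$OX421510
  typeE <- orders$OR684570; typeF <- orders$MW357851

  expect_identical(nrow(detect_events(typeA, typeA)), 0L)

  ab <- detect_events(typeA, typeB)
  expect_identical(ab$gene, "trnD")
  expect_identical(ab$kind, "transposition")
  expect_identical(ab$dst_left, "+cob")   # trnD lands between cob and trnC
  expect_identical(ab$dst_right, "+trnC")

  bc <- detect_events(typeB, typeC)
  expect_setequal(bc$gene, c("trnE", "trnL2", "trnM", "trnN", "trnQ",
                             "trnR", "trnS2"))
  expect_true(all(bc$kind == "reverse_transposition"))

  de <- detect_events(typeD, typeE)
  expect_identical(de$gene, "rrnS")
  expect_identical(de$kind, "reverse_transposition")

  ef <- detect_events(typeE, typeF)
  expect_identical(ef$gene, "trnQ")
  expect_identical(ef$kind, "reverse_transposition")

  # symmetry: same events (by gene and kind) in both directions
  ba <- detect_events(typeB, typeA)
  expect_identical(nrow(ba), nrow(ab))
  expect_setequal(ba$gene, ab$gene)
  ca <- detect_events(typeC, typeA)
  expect_identical(nrow(ca), 8L)  # trnD move plus seven reversals

  expect_error(detect_events(typeA,
                             gene_order("q", c("cox1", "nad1"), c("+", "+"))),
               "gene sets differ")
})

test_that("minimal event search agrees with unrestricted brute force", {
  set.seed(19)
  kinds <- c("transposition", "reverse_transposition")
  for (rep in 1:25) {
    n <- sample(8:12, 1)
    base <- random_small_order(n, "base")
    k <- sample(1:3, 1)
    q <- base
    for (e in seq_len(k)) {
      # cox1 anchors the circular normalization and never moves in these
      # genomes, so scripted events draw from the other genes
      g <- sample(setdiff(q$genes, "cox1"), 1)
      after <- sample(setdiff(q$genes, g), 1)
      q <- apply_scripted_rearrangements(
        q, list(list(gene = g, kind = sample(kinds, 1), after = after)),
        new_id = "query")
    }
    found <- detect_events(base, q)
    oracle <- oracle_min_events(base, q, max_size = min(k, 6))
    expect_identical(nrow(found), length(oracle))
    # round-trip: applying the described events reconstructs the query
    rebuilt <- apply_scripted_rearrangements(normalize_gene_order(base), found)
    expect_identical(order_tokens(normalize_gene_order(rebuilt)),
                     order_tokens(normalize_gene_order(q)))
  }
})

test_that("round-trip reconstruction holds for the fixture panel", {
  orders <- planorbidae_gene_orders()
  ref <- orders$MK414453
  for (id in c("MK414449", "EF433576", "OX421510", "OR684570", "MW357851")) {
    ev <- detect_events(ref, orders[[id]])
    rebuilt <- apply_scripted_rearrangements(normalize_gene_order(ref), ev)
    expect_identical(order_tokens(normalize_gene_order(rebuilt)),
                     order_tokens(normalize_gene_order(orders[[id]])))
  }
})

test_that("arrangement typing groups the panel into the six published types", {
  orders <- planorbidae_gene_orders()
  types <- cluster_types(orders)
  expect_identical(sort(unique(types$type)), LETTERS[1:6])
  expect_identical(unname(c(table(types$type))), c(3L, 8L, 1L, 1L, 1L, 1L))
  expect_identical(types$type[types$id == "OR684570"], "E")
  expect_identical(types$type[types$id == "EF433576"], "C")

  single <- cluster_types(orders["OR684570"])
  expect_identical(single$type, "A")
  # a rotated copy lands in the same type
  o <- orders$OR684570
  rot <- gene_order("copy", c(o$genes[5:37], o$genes[1:4]),
                    c(o$strand[5:37], o$strand[1:4]))
  two <- cluster_types(list(o, rot))
  expect_identical(unique(two$type), "A")
})

test_that("the rearranged-gene census spans ten tRNAs and rrnS", {
  orders <- planorbidae_gene_orders()
  cen <- rearranged_gene_census(orders, reference_type = "A")
  expect_setequal(cen$by_class$tRNA,
                  c("trnC", "trnD", "trnE", "trnL2", "trnM", "trnN",
                    "trnQ", "trnR", "trnS2", "trnW"))
  expect_identical(cen$by_class$rRNA, "rrnS")
  expect_length(cen$by_class$PCG, 0)

  # single-type panel: empty census
  sub <- orders[c("MK414453", "MK414450")]
  cen0 <- rearranged_gene_census(sub)
  expect_length(cen0$genes, 0)

  # a single scripted transposition is recovered verbatim
  o <- orders$MK414453
  moved <- apply_scripted_rearrangements(
    o, list(list(gene = "trnV", kind = "transposition", after = "trnP")),
    new_id = "moved")
  cen1 <- rearranged_gene_census(list(o, moved))
  expect_identical(cen1$genes, "trnV")
})

test_that("scripted rearrangements validate their junctions", {
  o <- planorbidae_gene_orders()$MK414453
  expect_identical(order_tokens(apply_scripted_rearrangements(o, list())),
                   order_tokens(o))
  # the described A -> B delta produces the type-B arrangement
  b <- apply_scripted_rearrangements(
    o, list(list(gene = "trnD", kind = "transposition", after = "cob",
                 before = "trnC")), new_id = "b")
  expect_identical(order_tokens(normalize_gene_order(b)),
                   order_tokens(normalize_gene_order(
                     planorbidae_gene_orders()$MK414449)))
  expect_error(apply_scripted_rearrangements(
    o, list(list(gene = "nope", kind = "transposition", after = "cob"))),
    "absent gene")
  expect_error(apply_scripted_rearrangements(
    o, list(list(gene = "trnD", kind = "transposition", after = "cob",
                 before = "trnF"))),
    "ambiguous")
  expect_error(apply_scripted_rearrangements(
    o, list(list(gene = "trnD", kind = "inversion", after = "cob"))),
    "unknown event kind")
})

test_that("gene-order files round-trip", {
  orders <- planorbidae_gene_orders()
  tmp <- withr::local_tempfile(fileext = ".txt")
  write_gene_orders(orders, tmp)
  back <- read_gene_orders(tmp)
  expect_identical(names(back), names(orders))
  expect_identical(lapply(back, order_tokens), lapply(orders, order_tokens))
  writeLines("X cox1 nad1", tmp)
  expect_error(read_gene_orders(tmp), "signed")
})
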