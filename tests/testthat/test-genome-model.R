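test_that("gene vocabulary and synonym mapping behave canonically", {
  expect_length(mito_gene_names(), 37)
  expect_length(mito_gene_names("PCG"), 13)
  expect_length(mito_gene_names("tRNA"), 22)
  expect_identical(mito_gene_names("rRNA"), c("rrnS", "rrnL"))

  expect_identical(canonical_gene_name("COI"), "cox1")
  expect_identical(canonical_gene_name("coi"), "cox1")       # case-insensitive
  expect_identical(canonical_gene_name("16S ribosomal RNA"), "rrnL")
  # idempotence: canonical names map to themselves
  expect_identical(canonical_gene_name(mito_gene_names()), mito_gene_names())
  expect_identical(canonical_gene_name(canonical_gene_name("ND5")), "nad5")
  # trnL/trnS resolved only by anticodon
  expect_identical(canonical_gene_name("tRNA-Leu", "CTA"), "trnL1")
  expect_identical(canonical_gene_name("tRNA-Leu", "TTA"), "trnL2")
  expect_identical(canonical_gene_name("trnS", "TCA"), "trnS2")
  expect_true(is.na(canonical_gene_name("tRNA-Leu")))
})

test_that("feature-table write/read round-trips all annotation fields", {
  g <- make_table1_fixture()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(g, tmp)
  g2 <- read_feature_table(tmp, id = g$id)
  cols <- c("gene", "start", "end", "strand", "class",
            "start_codon", "stop_codon", "anticodon", "wraps_origin")
  expect_identical(g2$features[cols], g$features[cols])

  # genome without codon columns: emitted as missing markers, read back as NA
  f <- data.frame(gene = c("rrnS", "rrnL"), start = c(1L, 800L),
                  end = c(700L, 1800L), strand = "+", class = "rRNA")
  bare <- suppressWarnings(mito_genome("X1", f))
  write_feature_table(bare, tmp)
  raw <- read.delim(tmp, colClasses = "character")
  expect_true(all(raw$start_codon == "."))
  b2 <- suppressWarnings(read_feature_table(tmp, id = "X1"))
  expect_true(all(is.na(b2$features$start_codon)))

  # origin-wrapping feature round-trips through the wraps flag column
  fw <- data.frame(gene = c("cox1", "rrnL"), start = c(900L, 100L),
                   end = c(121L, 850L), strand = "+",
                   class = c("PCG", "rRNA"),
                   start_codon = c("ATG", NA), stop_codon = c("TAA", NA),
                   anticodon = NA_character_,
                   wraps_origin = c(TRUE, FALSE))
  gw <- suppressWarnings(mito_genome("W1", fw, declared_length = 1000L))
  write_feature_table(gw, tmp)
  gw2 <- suppressWarnings(read_feature_table(tmp, id = "W1",
                                             declared_length = 1000L))
  expect_identical(gw2$features$wraps_origin, gw$features$wraps_origin)
  expect_identical(unname(feature_lengths(gw2)["cox1"]), 222L)  # 121-900+1+L
})

test_that("feature-table reader rejects malformed input", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene\tstart\tend\tstrand\tclass", tmp)
  expect_error(read_feature_table(tmp), "no features")
  writeLines(c("gene\tstart\tend\tstrand\tclass",
               "cox1\tabc\t10\t+\tPCG"), tmp)
  expect_error(read_feature_table(tmp), "non-integer")
  writeLines(c("gene\tstart\tend\tstrand\tclass\tstart_codon\tstop_codon",
               "cox1\t1\t12\t+\tPCG\tATG\tTGA"), tmp)
  expect_error(read_feature_table(tmp), "TAA/TAG/TA/T")
  writeLines(c("gene\tstart\tend\tstrand\tclass",
               "rrnS\t1\t700\t+\trRNA", "rrnS\t800\t1500\t+\trRNA"), tmp)
  expect_error(read_feature_table(tmp), "duplicate")
})

test_that("genome validation enforces the coding-length and tRNA invariants", {
  f <- data.frame(gene = "nad1", start = 1L, end = 894L, strand = "+",
                  class = "PCG", start_codon = "ATG", stop_codon = "T")
  expect_error(suppressWarnings(mito_genome("B", f)),
               "incompatible with stop-codon style")
  f$end <- 895L  # 895 mod 3 == 1 matches incomplete stop T
  expect_silent(suppressWarnings(mito_genome("B", f)))
  f2 <- data.frame(gene = "trnA", start = 1L, end = 40L, strand = "+",
                   class = "tRNA", anticodon = "GCA")
  expect_error(suppressWarnings(mito_genome("B", f2)), "shorter than 50")
})

test_that("extract_gene_sequence honors strand and circular wrap", {
  seq <- "ATGAAACCCGGGTTT"
  f <- data.frame(gene = c("cox1", "rrnS"), start = c(1L, 7L),
                  end = c(6L, 15L), strand = c("+", "-"),
                  class = c("PCG", "rRNA"),
                  start_codon = c("ATG", NA), stop_codon = c("TAA", NA))
  g <- suppressWarnings(mito_genome("T", f, sequence = seq, validate = FALSE))
  expect_identical(extract_gene_sequence(g, "cox1"), "ATGAAA")
  # minus strand: reverse complement of positions 7..15
  expect_identical(extract_gene_sequence(g, "rrnS"),
                   reverse_complement("CCCGGGTTT"))
  expect_error(extract_gene_sequence(g, "nad1"), "unknown gene")

  # wrapping feature equals the doubled-string oracle
  fw <- data.frame(gene = "rrnL", start = 11L, end = 5L, strand = "+",
                   class = "rRNA", wraps_origin = TRUE)
  gw <- suppressWarnings(mito_genome("T2", fw, sequence = seq,
                                     validate = FALSE))
  doubled <- paste0(seq, seq)
  expect_identical(extract_gene_sequence(gw, "rrnL"),
                   substr(doubled, 11, nchar(seq) + 5))

  g_noseq <- suppressWarnings(mito_genome("T3", f, validate = FALSE))
  expect_error(extract_gene_sequence(g_noseq, "cox1"), "no sequence")
})

test_that("non-wrapping coding sequences have length end - start + 1", {
  sim <- simulate_genome(11)
  f <- sim$features
  for (i in seq_len(nrow(f)))
    expect_identical(nchar(extract_gene_sequence(sim, f$gene[i])),
                     f$end[i] - f$start[i] + 1L)
})

test_that("GenBank records round-trip through the synonym mapping", {
  sim <- simulate_genome(5)
  tmp <- withr::local_tempfile(fileext = ".gb")
  write_genbank_fixture(sim, tmp)
  g <- read_genbank(tmp)
  expect_true(g$complete)
  expect_identical(g$sequence, sim$sequence)
  m <- merge(sim$features, g$features, by = "gene")
  expect_equal(nrow(m), 37)
  expect_identical(m$start.x, m$start.y)
  expect_identical(m$end.x, m$end.y)
  expect_identical(m$strand.x, m$strand.y)  # complement() mapped to "-"
  expect_identical(m$start_codon.x, m$start_codon.y)
  expect_identical(m$stop_codon.x, m$stop_codon.y)

  # a GenBank read written as a feature table and re-read is unchanged
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(g, tsv)
  g2 <- read_feature_table(tsv, id = g$id, sequence = g$sequence)
  cols <- c("gene", "start", "end", "strand", "class")
  expect_identical(g2$features[cols], g$features[cols])
})

test_that("ambiguous trnL without anticodon is held, not guessed or dropped", {
  sim <- simulate_genome(5)
  tmp <- withr::local_tempfile(fileext = ".gb")
  write_genbank_fixture(sim, tmp, drop_anticodon = c("trnL1", "trnL2"))
  w <- capture_warnings(g <- read_genbank(tmp))
  expect_true(any(grepl("unmapped", w)))
  expect_true(any(grepl("not a complete", w)))
  held <- grep("Leu", g$features$gene, value = TRUE)
  expect_length(held, 2)
  expect_false(any(c("trnL1", "trnL2") %in% g$features$gene))
  expect_false(g$complete)
})

test_that("malformed GenBank input names the problem", {
  tmp <- withr::local_tempfile(fileext = ".gb")
  writeLines("not a genbank file", tmp)
  expect_error(read_genbank(tmp), "LOCUS")
  writeLines(c("LOCUS       X 100 bp", "FEATURES",
               "     CDS             oops..location",
               '                     /gene="COI"', "//"), tmp)
  expect_error(read_genbank(tmp), "location")
})
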