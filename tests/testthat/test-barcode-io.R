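test_that("barcode map TSV parsing validates and preserves rows", {
  tsv <- tempfile(fileext = ".tsv")
  bcs <- c("ACGTACGTACGTACGTACGT", "TTTTACGTACGTACGTACGT",
           "GGGGACGTACGTACGTACGT")
  writeLines(c("barcode\tstrain_id\tgene\tstrain_class",
               paste(bcs, c("s1", "s2", "s3"), c("G1", "G2", "G3"),
                     c("mutant", "mutant", "wildtype"), sep = "\t")), tsv)
  map <- load_barcode_map(tsv)
  expect_s3_class(map, "barcode_map")
  expect_equal(nrow(map), 3L)
  expect_equal(attr(map, "barcode_length"), 20L)
  expect_identical(map$barcode, bcs)  # row order preserved

  writeLines(c("barcode\tstrain_id\tgene\tstrain_class",
               paste(bcs[c(1, 1)], c("s1", "s2"), c("G1", "G2"),
                     "mutant", sep = "\t")), tsv)
  expect_error(load_barcode_map(tsv), "duplicate barcode")

  writeLines(c("barcode\tstrain_id\tgene\tstrain_class",
               paste("ACGTACGTACGTACGTACGN", "s1", "G1", "mutant",
                     sep = "\t")), tsv)
  expect_error(load_barcode_map(tsv), "invalid alphabet")

  writeLines(c("barcode\tstrain_id\tgene\tstrain_class",
               paste(c(bcs[1], "ACGT"), c("s1", "s2"), c("G1", "G2"),
                     "mutant", sep = "\t")), tsv)
  expect_error(load_barcode_map(tsv), "length")
})

test_that("barcode map rejects multi-barcode mutant genes but allows wildtype sharing", {
  expect_error(
    barcode_map(c("AAAA", "CCCC"), c("s1", "s2"), c("G1", "G1"),
                c("mutant", "mutant")),
    "multiple mutant barcodes")
  map <- barcode_map(c("AAAA", "CCCC"), c("w1", "w2"), c("WT", "WT"),
                     c("wildtype", "wildtype"))
  expect_equal(nrow(map), 2L)
})

test_that("extract_barcode resolves exact, corrected, and unassignable reads", {
  map <- toy_map()
  strc <- read_structure(anchor = "CGTACGCTGC", barcode_length = 20)
  b1 <- map$barcode[1]

  r <- extract_barcode(paste0("CGTACGCTGC", b1, "ACGTC"), strc, map)
  expect_identical(r$barcode, b1)
  expect_true(is.na(r$reason))

  ## one substitution in the barcode; brute force confirms the corrected
  ## barcode is the unique map entry at Hamming distance 1
  mut <- b1
  substr(mut, 10, 10) <- "A"  # position 10 is C in b1
  expect_true(mut != b1)
  d <- hamming(mut, map$barcode)
  expect_equal(sum(d == 1), 1L)
  expect_equal(map$barcode[d == 1], b1)
  read <- paste0("CGTACGCTGC", mut, "ACGTC")
  r_exact <- extract_barcode(read, strc, map, policy = "exact")
  expect_true(is.na(r_exact$barcode))
  expect_identical(r_exact$reason, "unknown_barcode")
  r_h1 <- extract_barcode(read, strc, map, policy = "hamming1")
  expect_identical(r_h1$barcode, b1)

  ## anchorless read
  r <- extract_barcode(strrep("A", 40), strc, map)
  expect_identical(r$reason, "no_anchor")

  ## anchor too close to the end of the read
  r <- extract_barcode(paste0("CGTACGCTGC", substr(b1, 1, 10)), strc, map)
  expect_identical(r$reason, "short_read")
})

test_that("ambiguous hamming1 corrections are left unassigned", {
  ## two map barcodes at distance 2 from each other; a candidate midway
  ## is at distance 1 from both
  map <- barcode_map(c("AAAA", "AATT"), c("s1", "s2"), c("G1", "G2"),
                     c("mutant", "mutant"))
  strc <- read_structure(anchor = "CG", barcode_length = 4)
  r <- extract_barcode("CGAATA", strc, map, policy = "hamming1")
  expect_true(is.na(r$barcode))
  expect_identical(r$reason, "ambiguous_correction")
})

test_that("leftmost acceptable anchor position wins", {
  map <- barcode_map(c("AAAA", "TTTT"), c("s1", "s2"), c("G1", "G2"),
                     c("mutant", "mutant"))
  strc <- read_structure(anchor = "GC", barcode_length = 4)
  ## two anchor occurrences; the first is followed by AAAA, the second by TTTT
  r <- extract_barcode("GCAAAAGCTTTT", strc, map)
  expect_identical(r$barcode, "AAAA")
  ## a restricted window can skip the first occurrence
  strc2 <- read_structure(anchor = "GC", barcode_length = 4,
                          search_window = c(3, 8))
  r2 <- extract_barcode("GCAAAAGCTTTT", strc2, map)
  expect_identical(r2$barcode, "TTTT")
})

test_that("mismatch-tolerant anchor search finds degenerate anchors", {
  map <- barcode_map(c("AAAA", "TTTT"), c("s1", "s2"), c("G1", "G2"),
                     c("mutant", "mutant"))
  strc0 <- read_structure(anchor = "GGGG", barcode_length = 4)
  strc1 <- read_structure(anchor = "GGGG", barcode_length = 4,
                          anchor_max_mismatch = 1)
  read <- "GGTGAAAACC"
  expect_identical(extract_barcode(read, strc0, map)$reason, "no_anchor")
  expect_identical(extract_barcode(read, strc1, map)$barcode, "AAAA")
})

test_that("count_barcodes tallies reads and conserves totals", {
  map <- toy_map()
  strc <- read_structure(anchor = "CGTACGCTGC", barcode_length = 20)
  b1 <- map$barcode[1]; b2 <- map$barcode[2]

  reads <- rep(paste0("CGTACGCTGC", b1, "ACGTC"), 10)
  sc <- count_barcodes(reads, map, strc)
  expect_equal(unname(sc$counts[b1]), 10L)
  expect_equal(sc$assigned_reads, 10L)
  expect_equal(sc$unassigned_reads, 0L)

  reads <- c(rep(paste0("CGTACGCTGC", b1, "A"), 6),
             rep(paste0("CGTACGCTGC", b2, "A"), 3),
             strrep("T", 35))
  sc <- count_barcodes(reads, map, strc)
  oracle <- naive_count(reads, "CGTACGCTGC", 20, 0, 0, 35,
                        map$barcode, "exact")
  expect_equal(sc$counts, oracle$counts)
  expect_equal(sc$unassigned_reads, oracle$unassigned)
  expect_equal(sc$total_reads, 10L)
  ## conservation and zero-count presence
  expect_equal(sc$assigned_reads + sc$unassigned_reads, sc$total_reads)
  expect_equal(sum(sc$counts), sc$assigned_reads)
  expect_true(all(map$barcode %in% names(sc$counts)))

  sc0 <- count_barcodes(character(0), map, strc)
  expect_equal(sc0$total_reads, 0L)
  expect_true(all(sc0$counts == 0L))
})

test_that("FASTQ reading round-trips and rejects malformed records", {
  map <- toy_map()
  strc <- read_structure(anchor = "CGTACGCTGC", barcode_length = 20)
  fq <- tempfile(fileext = ".fastq.gz")
  reads <- paste0("CGTACGCTGC", map$barcode[c(1, 1, 2)], "TT")
  con <- gzfile(fq, "wb")
  writeLines(c(rbind(paste0("@r", 1:3), reads, "+",
                     strrep("I", nchar(reads)))), con)
  close(con)
  expect_identical(read_fastq_sequences(fq), reads)
  sc <- count_barcodes(fq, map, strc)
  expect_equal(unname(sc$counts[map$barcode[1]]), 2L)
  expect_equal(unname(sc$counts[map$barcode[2]]), 1L)

  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), bad)
  expect_error(read_fastq_sequences(bad), "truncated record 2")
  writeLines(c("@r1", "ACGT", "+", "IIII", "r2", "ACGT", "+", "IIII"), bad)
  expect_error(read_fastq_sequences(bad), "record 2 header")
})

test_that("counting matches the naive per-read oracle on random reads", {
  set.seed(42)
  map <- barcode_map(random_dna(30, 12), sprintf("s%02d", 1:30),
                     sprintf("G%02d", 1:30), rep("mutant", 30))
  anchor <- "TGCA"
  strc <- read_structure(anchor = anchor, barcode_length = 12,
                         anchor_max_mismatch = 1)
  ## a mix of clean reads, mutated reads and random junk
  clean <- paste0(anchor, sample(map$barcode, 400, replace = TRUE),
                  random_dna(400, 6))
  noisy <- vapply(paste0(anchor, sample(map$barcode, 300, replace = TRUE),
                         random_dna(300, 6)), function(r) {
    p <- sample.int(nchar(r), 1)
    substr(r, p, p) <- sample(c("A", "C", "G", "T"), 1)
    r
  }, character(1), USE.NAMES = FALSE)
  junk <- random_dna(300, 22)
  reads <- sample(c(clean, noisy, junk))

  for (policy in c("exact", "hamming1")) {
    sc <- count_barcodes(reads, map, strc, policy = policy)
    oracle <- naive_count(reads, anchor, 12, 1, 0, 22, map$barcode, policy)
    expect_equal(sc$counts, oracle$counts)
    expect_equal(sc$unassigned_reads, oracle$unassigned)
  }
})

test_that("hamming1 never assigns fewer reads than exact", {
  set.seed(7)
  map <- barcode_map(random_dna(20, 10), sprintf("s%02d", 1:20),
                     sprintf("G%02d", 1:20), rep("mutant", 20))
  strc <- read_structure(anchor = "ACGT", barcode_length = 10)
  for (i in 1:5) {
    reads <- vapply(paste0("ACGT", sample(map$barcode, 200, replace = TRUE)),
                    function(r) {
      if (runif(1) < 0.5) {
        p <- sample.int(nchar(r), 1)
        substr(r, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      r
    }, character(1), USE.NAMES = FALSE)
    a_exact <- count_barcodes(reads, map, strc, policy = "exact")
    a_h1 <- count_barcodes(reads, map, strc, policy = "hamming1")
    expect_gte(a_h1$assigned_reads, a_exact$assigned_reads)
  }
})

test_that("counts TSVs round-trip through write_counts/read_counts", {
  map <- toy_map()
  strc <- read_structure(anchor = "CGTACGCTGC", barcode_length = 20)
  reads <- c(rep(paste0("CGTACGCTGC", map$barcode[1], "A"), 5),
             strrep("G", 35))
  sc <- count_barcodes(reads, map, strc,
                       sample = sample_meta("x", "input", 40, 1))
  tsv <- tempfile(fileext = ".tsv")
  write_counts(sc, map, tsv)
  back <- read_counts(tsv, map, sample = sc$sample,
                      total_reads = sc$total_reads)
  expect_equal(back$counts, sc$counts)
  expect_equal(back$total_reads, sc$total_reads)
  expect_equal(back$unassigned_reads, sc$unassigned_reads)
})
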