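barcode_tbl <- function(...) {
  bc <- c(...)
  tibble::tibble(sample_id = names(bc), barcode = unname(bc))
}

test_that("demultiplex assigns by barcode + remnant, longest barcode first", {
  bcs <- barcode_tbl(s1 = "ACGT", s2 = "ACG")
  reads <- tibble::tibble(
    read_id = c("r1", "r2", "r3", "r4"),
    sequence = c("ACGTCAGCAAAA",   # matches ACGT + CAGC (also ACG + TCAG? no: remnant fails)
                 "ACGCTGCTTTTT",   # ACG + CTGC
                 "GGGGCAGCAAAA",   # no barcode
                 "ACGTTTTTTTTT"))  # barcode but no remnant
  dm <- demultiplex(reads, bcs)
  expect_equal(dm$sample_id, c("s1", "s2", NA, NA))
  expect_equal(dm$sequence[1], "CAGCAAAA")
  expect_equal(dm$sequence[2], "CTGCTTTTT")
  expect_equal(dm$sequence[3], "GGGGCAGCAAAA") # untouched
})

test_that("duplicate barcodes are rejected at load", {
  bcs <- tibble::tibble(sample_id = c("a", "b"), barcode = c("ACGT", "ACGT"))
  reads <- tibble::tibble(read_id = "r", sequence = "ACGTCAGCAA")
  expect_error(demultiplex(reads, bcs), "duplicate")
})

test_that("assigned and unassigned reads partition arbitrary inputs", {
  set.seed(5)
  bcs <- make_barcodes(8)
  for (i in 1:5) {
    n <- 200
    reads <- tibble::tibble(
      read_id = sprintf("r%03d", 1:n),
      sequence = vapply(1:n, function(j) {
        if (runif(1) < 0.7)
          paste0(sample(bcs$barcode, 1), sample(c("CAGC", "CTGC", "AAAA"), 1),
                 random_seq(20))
        else random_seq(28)
      }, character(1)))
    dm <- demultiplex(reads, bcs)
    expect_equal(nrow(dm), n)
    expect_setequal(dm$read_id, reads$read_id)
    # unassigned reads kept verbatim; assigned reads are suffixes
    un <- is.na(dm$sample_id)
    expect_identical(dm$sequence[un], reads$sequence[un])
    expect_true(all(nchar(dm$sequence[!un]) == nchar(reads$sequence[!un]) - 6))
  }
})

test_that("demultiplex tolerates barcode mismatches only when asked", {
  bcs <- barcode_tbl(s1 = "ACGTAA", s2 = "TTTTTT")
  reads <- tibble::tibble(read_id = "r1", sequence = "ACGTATCAGCAAAA") # 1 mismatch
  expect_true(is.na(demultiplex(reads, bcs)$sample_id))
  expect_equal(demultiplex(reads, bcs, max_mismatch = 1)$sample_id, "s1")
})

test_that("count_alleles counts exact k-mer hits per sample and locus", {
  placed <- tibble::tibble(
    marker_id = c("P1a", "P1b"), pair_id = "P1", parent = c("A", "B"),
    kmer = c("CAGCTTACGGATCCA", "CAGCTTACGAATCCA"),
    contig = "ctg", start = 30L, strand = "+", snv_offset = 9L)
  k <- 15
  reads <- tibble::tibble(
    read_id = sprintf("r%d", 1:6),
    sample_id = c("s1", "s1", "s1", "s1", "s2", NA),
    sequence = c(rep(paste0("CAGCTTACGGATCCA", "TTT"), 3),  # A kmer x3
                 paste0("AAA", "CAGCTTACGAATCCA"),          # B kmer x1
                 "CAGCTTACGGATCGA",                         # 1 sub: no hit
                 paste0("CAGCTTACGGATCCA", "GG")))          # unassigned: ignored
  counts <- count_alleles(reads, placed, k = k)
  s1 <- counts[counts$individual == "s1", ]
  expect_equal(s1$count_a, 3L)
  expect_equal(s1$count_b, 1L)
  expect_false("s2" %in% counts$individual) # no exact hit
  expect_equal(s1$pos, 30L)
})

test_that("a read hitting markers in reverse complement still counts", {
  placed <- tibble::tibble(
    marker_id = c("P1a", "P1b"), pair_id = "P1", parent = c("A", "B"),
    kmer = c("CAGCTTACGGATCCA", "CAGCTTACGAATCCA"),
    contig = "ctg", start = 0L, strand = "+", snv_offset = 9L)
  reads <- tibble::tibble(read_id = "r1", sample_id = "s1",
                          sequence = revcomp("CAGCTTACGGATCCA"))
  counts <- count_alleles(reads, placed, k = 15)
  expect_equal(counts$count_a, 1L)
})

test_that("call_genotypes applies the threshold rule", {
  counts <- tibble::tibble(
    individual = "s", contig = "c", pos = 0L,
    count_a = c(5L, 3L, 1L, 0L, 0L, 2L),
    count_b = c(0L, 4L, 0L, 7L, 1L, 0L))
  calls <- call_genotypes(counts, min_allele = 2)
  expect_equal(calls$call, c("AA", "AB", NA, "BB", NA, "AA"))
})

test_that("bin_consensus majority and tie rules match the worked examples", {
  lens <- c(ctg = 30000L)
  mk_calls <- function(calls, poss) {
    tibble::tibble(individual = "s1", contig = "ctg", pos = poss,
                   count_a = 2L, count_b = 2L, call = calls)
  }
  # {AA x3, AB x1} at well-separated loci -> A
  cons <- bin_consensus(mk_calls(c("AA", "AA", "AA", "AB"),
                                 c(100L, 300L, 500L, 700L)), lens)
  expect_equal(cons$genotype[cons$individual == "s1" & cons$window_index == 0], "A")
  # {AA x2, BB x2} -> U (tie)
  cons2 <- bin_consensus(mk_calls(c("AA", "AA", "BB", "BB"),
                                  c(100L, 300L, 500L, 700L)), lens)
  expect_equal(cons2$genotype[1], "U")
  # windows tile the contig: length 30000 -> [0,14000), [14000,28000), [28000,30000)
  cons3 <- bin_consensus(mk_calls(rep("AA", 6),
                                  c(0L, 200L, 14500L, 15000L, 28100L, 29000L)), lens)
  expect_equal(cons3$window_index, 0:2)
  expect_equal(cons3$start, c(0L, 14000L, 28000L))
  expect_equal(cons3$end, c(14000L, 28000L, 30000L))
})

test_that("bin_consensus agrees with a brute-force per-window tally", {
  set.seed(23)
  lens <- c(c1 = 50000L, c2 = 33000L)
  for (rep in 1:5) {
    n <- 400
    calls <- tibble::tibble(
      individual = sample(sprintf("i%02d", 1:6), n, TRUE),
      contig = sample(names(lens), n, TRUE),
      pos = NA_integer_, count_a = 2L, count_b = 2L,
      call = sample(c("AA", "AB", "BB", NA), n, TRUE))
    calls$pos <- as.integer(floor(runif(n) * (lens[calls$contig] - 1)))
    # loci far enough apart that each is its own site cluster
    calls$pos <- calls$pos - (calls$pos %% 120L)
    calls <- dplyr::distinct(calls, individual, contig, pos, .keep_all = TRUE)
    cons <- bin_consensus(calls, lens, window = 14000L, min_calls = 2L)
    # brute force: per (individual, window) strict plurality with support >= 2
    oracle <- function(ind, ctg, wi) {
      sub <- calls[!is.na(calls$call) & calls$individual == ind &
                     calls$contig == ctg & calls$pos %/% 14000L == wi, ]
      if (!nrow(sub)) return("U")
      tab <- table(factor(sub$call, c("AA", "AB", "BB")))
      top <- which.max(tab)
      if (sum(tab == max(tab)) > 1 || max(tab) < 2) "U"
      else c("A", "H", "B")[top]
    }
    idx <- sample(nrow(cons), min(80, nrow(cons)))
    for (i in idx) {
      expect_identical(cons$genotype[i],
                       oracle(cons$individual[i], cons$contig[i],
                              cons$window_index[i]),
                       info = sprintf("rep %d row %d", rep, i))
    }
  }
})

test_that("site-cluster voting keeps one aberrant site from outvoting clean ones", {
  lens <- c(ctg = 14000L)
  # dropout site: 40 overlapping loci all (wrongly) BB; two clean sites say AB
  calls <- dplyr::bind_rows(
    tibble::tibble(individual = "s1", contig = "ctg", pos = 1000L + 0:39,
                   count_a = 0L, count_b = 5L, call = "BB"),
    tibble::tibble(individual = "s1", contig = "ctg", pos = c(5000L, 9000L),
                   count_a = 3L, count_b = 3L, call = "AB"))
  cons <- bin_consensus(calls, lens)
  expect_equal(cons$genotype, "H")
})

test_that("consensus_matrix is a complete loci-by-individuals matrix", {
  cons <- small_consensus()$consensus
  m <- consensus_matrix(cons)
  expect_true(all(m %in% c("A", "H", "B", "U")))
  expect_setequal(colnames(m), unique(cons$individual))
  expect_equal(nrow(m), nrow(dplyr::distinct(cons, contig, window_index)))
})

test_that("high-depth error-free consensus equals truth at every scored window", {
  res <- small_consensus()
  ev <- evaluate_against_truth(small_truth(), consensus = res$consensus)
  expect_gt(ev$n_calls_scored, 500)
  expect_equal(ev$genotype_accuracy, 1.0)
})
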