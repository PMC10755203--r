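test_that("simulated parents differ exactly at the SNV table positions", {
  cfg <- sim_config(n_chromosomes = 2, chromosome_length = 5000, snv_rate = 0.01,
                    n_individuals = 4, seed = 3)
  tr <- simulate_parents(cfg)
  expect_length(tr$haplotype_a, 2)
  expect_equal(unname(nchar(tr$haplotype_a)), c(5000L, 5000L))
  expect_equal(nchar(tr$haplotype_a), nchar(tr$haplotype_b))
  for (chr in names(tr$haplotype_a)) {
    a <- strsplit(tr$haplotype_a[[chr]], "")[[1]]
    b <- strsplit(tr$haplotype_b[[chr]], "")[[1]]
    snv <- tr$snv[tr$snv$chromosome == chr, ]
    expect_equal(which(a != b) - 1L, snv$position)
    expect_equal(a[snv$position + 1L], snv$allele_a)
    expect_equal(b[snv$position + 1L], snv$allele_b)
  }
})

test_that("snv_rate 0 gives identical haplotypes and an empty SNV table", {
  tr <- simulate_parents(sim_config(n_chromosomes = 1, chromosome_length = 1000,
                                    snv_rate = 0, n_individuals = 2, seed = 1))
  expect_identical(tr$haplotype_a, tr$haplotype_b)
  expect_equal(nrow(tr$snv), 0L)
})

test_that("SNV count falls within binomial bounds", {
  n <- 100000; p <- 0.01
  tr <- simulate_parents(sim_config(n_chromosomes = 1, chromosome_length = n,
                                    snv_rate = p, n_individuals = 2, seed = 11))
  expect_lt(abs(nrow(tr$snv) - n * p), 3 * sqrt(n * p * (1 - p)))
})

test_that("same seed gives bit-identical outputs, different seed does not", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length = 20000,
                    n_individuals = 4, seed = 5, mean_depth = 2,
                    n_contigs = 2, min_contig_length = 5000)
  run1 <- simulate_gbs_run(simulate_f2_population(simulate_parents(cfg)))
  run2 <- simulate_gbs_run(simulate_f2_population(simulate_parents(cfg)))
  expect_identical(run1$reads, run2$reads)
  cfg2 <- sim_config(n_chromosomes = 1, chromosome_length = 20000,
                     n_individuals = 4, seed = 6, mean_depth = 2,
                     n_contigs = 2, min_contig_length = 5000)
  run3 <- simulate_gbs_run(simulate_f2_population(simulate_parents(cfg2)))
  expect_false(identical(run1$reads$sequence, run3$reads$sequence))
})

test_that("crossover_mean 0 gives pure parental gametes; A+B gametes give full hets", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length = 5000, snv_rate = 0.01,
                    n_individuals = 20, crossover_mean = 0, seed = 9)
  tr <- simulate_f2_population(simulate_parents(cfg))
  segs_per_gamete <- dplyr::count(tr$gametes, individual, chromosome, gamete)
  expect_true(all(segs_per_gamete$n == 1L))
  # an individual with one pure-A and one pure-B gamete is het at every SNV
  g <- dplyr::distinct(tr$gametes, individual, gamete, founder)
  wide <- tidyr::pivot_wider(g, names_from = gamete, values_from = founder)
  het <- wide$individual[wide$`1` != wide$`2`]
  expect_gt(length(het), 0)
})

test_that("F2 genotype frequencies at a locus are consistent with 1:2:1", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length = 2000, snv_rate = 0.005,
                    n_individuals = 2000, crossover_mean = 1, seed = 13)
  tr <- simulate_f2_population(simulate_parents(cfg))
  pos <- tr$snv$position[1]
  founders <- tr$gametes |>
    dplyr::filter(start <= pos, end > pos) |>
    dplyr::arrange(individual, gamete)
  geno <- tapply(founders$founder, founders$individual,
                 function(f) sum(f == "B"))
  counts <- tabulate(geno + 1L, 3L)
  expect_equal(sum(counts), 2000L)
  chisq <- sum((counts - 2000 * c(.25, .5, .25))^2 / (2000 * c(.25, .5, .25)))
  expect_lt(chisq, qchisq(0.999, df = 2))
})

test_that("ApeKI digestion cuts at G^CWGC including overlapping sites", {
  fr <- digest_genome("TTGCAGCTT")
  expect_equal(fr$start, c(0L, 3L))
  expect_equal(fr$end, c(3L, 9L))
  expect_equal(fr$sequence, c("TTG", "CAGCTT"))

  fr2 <- digest_genome("GCAGCTGC")
  expect_equal(fr2$sequence, c("G", "CAG", "CTGC"))

  fr3 <- digest_genome("AAATTTCCC")
  expect_equal(fr3$sequence, "AAATTTCCC")
})

test_that("digestion fragments always tile the input exactly", {
  set.seed(42)
  for (i in 1:25) {
    s <- random_seq(sample(50:400, 1))
    fr <- digest_genome(s)
    expect_identical(paste(fr$sequence, collapse = ""), s)
    expect_equal(fr$start[1], 0L)
    expect_equal(fr$end[nrow(fr)], nchar(s))
    if (nrow(fr) > 1)
      expect_equal(fr$start[-1], fr$end[-nrow(fr)])
  }
})

test_that("error-free reads are fragment-derived and remnant-anchored", {
  run <- small_run()
  tr <- small_truth()
  cfg <- tr$config
  reads <- run$reads[seq_len(500), ]
  bc <- setNames(cfg$barcodes$barcode, cfg$barcodes$sample_id)
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    b <- bc[[r$sample_id]]
    expect_identical(substr(r$sequence, 1, nchar(b)), b)
    genomic <- substr(r$sequence, nchar(b) + 1, nchar(r$sequence))
    expect_match(substr(genomic, 1, 4), "^C[AT]GC")
    segs <- tr$gametes[tr$gametes$individual == r$sample_id &
                         tr$gametes$chromosome == r$chromosome &
                         tr$gametes$gamete == r$gamete, ]
    mosaic <- paste(vapply(seq_len(nrow(segs)), function(j) {
      src <- if (segs$founder[j] == "A") tr$haplotype_a[[r$chromosome]]
             else tr$haplotype_b[[r$chromosome]]
      substring(src, segs$start[j] + 1, segs$end[j])
    }, character(1)), collapse = "")
    target <- if (r$read_end == "L") genomic else revcomp(genomic)
    expect_true(grepl(target, mosaic, fixed = TRUE))
  }
})

test_that("full-length reads have the configured read length", {
  run <- small_run()
  cfg <- small_truth()$config
  lens <- nchar(run$reads$sequence)
  expect_lte(max(lens), cfg$read_length)
  expect_gt(mean(lens == cfg$read_length), 0.5)
})

test_that("reads are conserved: each attributed to one sample and fragment", {
  run <- small_run()
  expect_false(any(is.na(run$reads$sample_id)))
  expect_false(any(is.na(run$reads$frag_start)))
  expect_equal(anyDuplicated(run$reads$read_id), 0L)
  # fragment span within the chromosome
  lens <- small_truth()$config$chromosome_length
  expect_true(all(run$reads$frag_end <= max(lens)))
})

test_that("fragmenting the reference round-trips to the genome", {
  tr <- small_truth()
  lay <- tr$contig_layout
  expect_equal(sum(lay$end - lay$start), sum(nchar(tr$haplotype_a)))
  for (chr in names(tr$haplotype_a)) {
    rows <- lay[lay$chromosome == chr, ]
    rows <- rows[order(rows$start), ]
    rebuilt <- paste(vapply(seq_len(nrow(rows)), function(i) {
      piece <- substring(tr$contigs[[rows$contig[i]]],
                         rows$contig_start[i] + 1, rows$contig_end[i])
      if (rows$strand[i] == "-") revcomp(piece) else piece
    }, character(1)), collapse = "")
    expect_identical(rebuilt, tr$haplotype_a[[chr]])
  }
})

test_that("planted chimeras are recorded and cross-chromosome", {
  cfg <- sim_config(n_chromosomes = 3, chromosome_length = 100000,
                    n_individuals = 4, n_contigs = 9, chimeras = 3,
                    min_contig_length = 10000, seed = 21)
  tr <- fragment_reference(simulate_parents(cfg))
  expect_equal(nrow(tr$chimera_truth), 3L)
  expect_length(tr$contigs, 9L)
  for (ctg in tr$chimera_truth$contig) {
    rows <- tr$contig_layout[tr$contig_layout$contig == ctg, ]
    expect_equal(nrow(rows), 2L)
    expect_false(rows$chromosome[1] == rows$chromosome[2])
    off <- tr$chimera_truth$junction_offset[tr$chimera_truth$contig == ctg]
    expect_equal(off, rows$contig_end[1])
  }
  # total sequence conserved
  expect_equal(sum(nchar(tr$contigs)), sum(nchar(tr$haplotype_a)))
})

test_that("invalid chimera specs are rejected with a message", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length = 100000,
                    n_individuals = 4, n_contigs = 4, chimeras = 1,
                    min_contig_length = 10000, seed = 2)
  expect_error(fragment_reference(simulate_parents(cfg)),
               "different chromosomes|min_contig_length|n_contigs",
               ignore.case = TRUE)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(snv_rate = 1.2), "snv_rate")
  expect_error(sim_config(error_rate = -0.1), "error_rate")
  expect_error(sim_config(read_length = 8), "read_length")
  bc <- make_barcodes(4)
  bc$barcode[2] <- bc$barcode[1]
  expect_error(sim_config(n_individuals = 4, barcodes = bc), "unique")
})
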