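# Shared fixtures. Expensive simulations are memoised so several test files
# can reuse them within one run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small two-chromosome study used by several module tests
small_config <- function(...) {
  sim_config(n_chromosomes = 2, chromosome_length = 150000, snv_rate = 0.002,
             n_individuals = 48, crossover_mean = 1, error_rate = 0,
             mean_depth = 6, n_contigs = 8, chimeras = 0,
             min_contig_length = 15000, seed = 7, ...)
}

small_truth <- function() {
  memo("small_truth", {
    tr <- simulate_parents(small_config())
    tr <- simulate_f2_population(tr)
    fragment_reference(tr)
  })
}

small_run <- function() memo("small_run", simulate_gbs_run(small_truth()))

# dense single-study fixture: clean markers through consensus
small_consensus <- function() {
  memo("small_consensus", {
    tr <- small_truth()
    ka <- count_kmers(unname(tr$haplotype_a), 51)
    kb <- count_kmers(unname(tr$haplotype_b), 51)
    mk <- discover_markers(ka, kb, k = 51, min_count = 1, max_other = 0)
    mk <- filter_markers_gbs(mk, tr$haplotype_a, tr$haplotype_b, k = 51)
    pl <- place_markers(mk, tr$contigs, k = 51)
    dm <- demultiplex(small_run()$reads, small_run()$barcodes)
    calls <- call_genotypes(count_alleles(dm, pl$placed, k = 51))
    list(placed = pl$placed, calls = calls,
         consensus = bin_consensus(calls, setNames(nchar(tr$contigs),
                                                   names(tr$contigs))))
  })
}

# brute-force canonical k-mer counter, the oracle for count_kmers()
oracle_count_kmers <- function(seqs, k) {
  canon <- function(x) {
    rc <- revcomp(x)
    ifelse(x <= rc, x, rc)
  }
  out <- character()
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", w)) next
      out <- c(out, canon(w))
    }
  }
  tab <- table(out)
  tibble::tibble(kmer = names(tab), count = as.integer(tab)) |>
    dplyr::arrange(kmer)
}

# brute-force diagnostic-pair discovery on tiny genomes
oracle_discover <- function(genome_a, genome_b, k, min_count = 1, max_other = 0) {
  ca <- oracle_count_kmers(genome_a, k)
  cb <- oracle_count_kmers(genome_b, k)
  cnt <- function(tbl, x) {
    i <- match(x, tbl$kmer)
    ifelse(is.na(i), 0L, tbl$count[i])
  }
  canon <- function(x) {
    rc <- revcomp(x)
    ifelse(x <= rc, x, rc)
  }
  bases <- c("A", "C", "G", "T")
  pairs <- list()
  for (x in ca$kmer) {
    if (cnt(ca, x) < min_count || cnt(cb, x) > max_other) next
    for (p in seq_len(k)) {
      for (b in setdiff(bases, substr(x, p, p))) {
        y <- x
        substr(y, p, p) <- b
        y <- canon(y)
        if (cnt(cb, y) >= min_count && cnt(ca, y) <= max_other)
          pairs[[length(pairs) + 1]] <- sort(c(x, y))
      }
    }
  }
  unique(pairs)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# two F2 loci at true recombination fraction r: each individual is the union
# of two parental gametes, each recombinant with probability r
simulate_locus_pair <- function(n, r, seed) {
  set.seed(seed)
  gam <- function() {
    g1 <- sample(c("A", "B"), n, TRUE)
    rec <- runif(n) < r
    g2 <- ifelse(rec, ifelse(g1 == "A", "B", "A"), g1)
    cbind(g1, g2)
  }
  m <- gam(); p <- gam()
  code <- function(a, b) ifelse(a == b, ifelse(a == "A", "A", "B"), "H")
  list(x = code(m[, 1], p[, 1]), y = code(m[, 2], p[, 2]))
}
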