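# build a consensus tibble from a windows-by-individuals matrix
consensus_from_matrix <- function(m, contig = "ctg", window = 14000L) {
  df <- expand.grid(window_index = seq_len(nrow(m)) - 1L,
                    ind = seq_len(ncol(m)), stringsAsFactors = FALSE)
  tibble::tibble(contig = contig, window_index = df$window_index,
                 start = df$window_index * window,
                 end = (df$window_index + 1L) * window,
                 individual = sprintf("i%03d", df$ind),
                 genotype = m[cbind(df$window_index + 1L, df$ind)])
}

test_that("detect_misjoins reports a population-wide haplotype switch", {
  set.seed(3)
  n_ind <- 50
  # windows 0-3 one unlinked block, windows 4-7 another
  g1 <- sample(c("A", "H", "B"), n_ind, TRUE, prob = c(.25, .5, .25))
  g2 <- sample(c("A", "H", "B"), n_ind, TRUE, prob = c(.25, .5, .25))
  m <- rbind(g1, g1, g1, g1, g2, g2, g2, g2)
  cons <- consensus_from_matrix(m)
  bp <- detect_misjoins(cons, min_switch = 0.5, min_informative = 20)
  expect_equal(nrow(bp), 1L)
  expect_equal(bp$boundary_bp, 4L * 14000L)
  expect_gt(bp$switch_fraction, 0.5)
  # theoretical switch fraction for unlinked blocks is 0.625
  expect_lt(abs(bp$switch_fraction - 0.625), 3 * sqrt(0.625 * 0.375 / n_ind))
})

test_that("clean contigs yield no breakpoints; thin boundaries are suppressed", {
  n_ind <- 50
  g <- rep("A", n_ind)
  m <- rbind(g, g, g, g)
  expect_equal(nrow(detect_misjoins(consensus_from_matrix(m))), 0L)
  # switch present but only 5 informative individuals -> suppressed
  g1 <- c(rep("A", 5), rep("U", 45))
  g2 <- c(rep("B", 5), rep("U", 45))
  m2 <- rbind(g1, g2)
  expect_equal(nrow(detect_misjoins(consensus_from_matrix(m2),
                                    min_informative = 20)), 0L)
  expect_equal(nrow(detect_misjoins(consensus_from_matrix(m2),
                                    min_informative = 5)), 1L)
})

test_that("adjacent qualifying boundaries merge to the strongest one", {
  n_ind <- 40
  a <- rep(c("A", "B"), each = n_ind / 2)
  b <- rep(c("B", "A"), each = n_ind / 2)           # switch 1.0 vs a
  c_ <- c(rep("B", 25), rep("A", 15))               # switch 0.625 vs b
  m <- rbind(a, a, b, c_, c_)
  bp <- detect_misjoins(consensus_from_matrix(m), min_switch = 0.5)
  expect_equal(nrow(bp), 1L)
  expect_equal(bp$boundary_bp, 2L * 14000L) # the full switch wins
})

test_that("split_contigs splits at boundaries and round-trips", {
  contigs <- c(big = paste(rep("ACGTACGTACGTAC", 10000), collapse = ""),
               small = "ACGTACGT")
  len <- nchar(contigs[["big"]])
  bp <- tibble::tibble(contig = "big", boundary_bp = 70000L,
                       switch_fraction = 0.9, n_informative = 40L)
  sp <- split_contigs(contigs, bp, window = 14000L)
  expect_setequal(names(sp$contigs), c("big.1", "big.2", "small"))
  expect_equal(nchar(sp$contigs[["big.1"]]), 70000L)
  expect_equal(nchar(sp$contigs[["big.2"]]), len - 70000L)
  expect_identical(paste0(sp$contigs[["big.1"]], sp$contigs[["big.2"]]),
                   unname(contigs[["big"]]))
  expect_equal(sp$provenance$start[sp$provenance$part == "big.2"], 70000L)
  # no breakpoints: output identical to input
  sp0 <- split_contigs(contigs, bp[0, ], window = 14000L)
  expect_identical(sp0$contigs[names(contigs)], unname(contigs) |>
                     setNames(names(contigs)))
  # off-boundary breakpoint errors
  bp_bad <- dplyr::mutate(bp, boundary_bp = 70001L)
  expect_error(split_contigs(contigs, bp_bad), "window boundary")
})

test_that("apply_breakpoints relabels windows into part coordinates", {
  x <- tibble::tibble(contig = rep("c1", 4), window_index = c(0L, 4L, 5L, 9L),
                      start = c(0L, 4L, 5L, 9L) * 14000L,
                      end = c(1L, 5L, 6L, 10L) * 14000L,
                      locus = paste0("c1:", c(0L, 4L, 5L, 9L)))
  bp <- tibble::tibble(contig = "c1", boundary_bp = 5L * 14000L,
                       switch_fraction = 1, n_informative = 30L)
  y <- apply_breakpoints(x, bp, window = 14000L)
  expect_equal(y$contig, c("c1.1", "c1.1", "c1.2", "c1.2"))
  expect_equal(y$window_index, c(0L, 4L, 0L, 4L))
  expect_equal(y$start, c(0L, 4L, 0L, 4L) * 14000L)
  expect_equal(y$locus, c("c1.1:0", "c1.1:4", "c1.2:0", "c1.2:4"))
})

make_map <- function(loci_tbl, rf = NULL) {
  structure(list(loci = loci_tbl, rf = rf), class = "genetic_map")
}

test_that("assign_contigs uses the majority group and flags conflicts", {
  loci <- tibble::tibble(
    group = c("3", "3", "3", "2", "2", "2", "2", "1"),
    order_index = 1:8,
    locus = paste0(c("p1", "p1", "p1", "p2", "p2", "p2", "p2", "p2"), ":",
                   c(0:2, 0:3, 4)),
    contig = c(rep("p1", 3), rep("p2", 5)),
    window_index = c(0:2, 0:4),
    adj_r = NA_real_, position_cm = c(0, 5, 10, 0, 5, 10, 15, 20))
  contigs <- c(p1 = "AAAA", p2 = "CCCC", p3 = "GGGG")
  asg <- assign_contigs(make_map(loci), contigs)
  expect_equal(asg$group[asg$part == "p1"], "3")
  expect_false(asg$conflict[asg$part == "p1"])
  expect_equal(asg$group[asg$part == "p2"], "2") # 4 of 5 windows
  expect_true(asg$conflict[asg$part == "p2"])
  expect_false(asg$placed[asg$part == "p3"])
})

test_that("orient_contigs follows the bp-vs-cM Kendall sign", {
  loci <- tibble::tibble(
    group = "1", order_index = 1:7,
    locus = c(paste0("up:", 0:2), paste0("down:", 0:2), "single:0"),
    contig = c(rep("up", 3), rep("down", 3), "single"),
    window_index = c(0:2, 0:2, 0L),
    adj_r = NA_real_,
    position_cm = c(0, 4, 8, 20, 16, 12, 30))
  contigs <- c(up = "A", down = "C", single = "G")
  asg <- orient_contigs(make_map(loci), assign_contigs(make_map(loci), contigs))
  expect_equal(asg$orientation[asg$part == "up"], "+")
  expect_equal(asg$orientation[asg$part == "down"], "-")
  expect_equal(asg$orientation[asg$part == "single"], "?")
})

test_that("order_contigs sorts by median cM with deterministic ties", {
  loci <- tibble::tibble(
    group = "1", order_index = 1:6,
    locus = paste0(rep(c("b", "a", "z"), each = 2), ":", rep(0:1, 3)),
    contig = rep(c("b", "a", "z"), each = 2),
    window_index = rep(0:1, 3), adj_r = NA_real_,
    position_cm = c(10, 12, 0, 2, 10, 12)) # b and z tie on median 11
  contigs <- c(a = "A", b = "C", z = "G")
  asg <- order_contigs(make_map(loci), assign_contigs(make_map(loci), contigs))
  placed <- asg[asg$placed, ]
  expect_equal(placed$part[order(placed$order_index)], c("a", "b", "z"))
})

test_that("build_pseudomolecules joins parts with gaps and valid AGP", {
  placements <- tibble::tibble(
    part = c("p1", "p2", "p3"), group = c("1", "1", NA),
    n_windows = c(3L, 3L, 0L), conflict = FALSE,
    placed = c(TRUE, TRUE, FALSE), orientation = c("+", "-", NA),
    position_cm = c(0, 10, NA), order_index = c(1L, 2L, NA))
  contigs <- c(p1 = "ACGTACGTAA", p2 = "GGGTTTCCCA", p3 = "TTTT")
  pm <- build_pseudomolecules(placements, contigs, gap = 100L)
  expect_length(pm$sequences, 1L)
  expect_equal(nchar(pm$sequences[[1]]), 10 + 100 + 10)
  expect_identical(pm$sequences[[1]],
                   paste0("ACGTACGTAA", strrep("N", 100), revcomp("GGGTTTCCCA")))
  expect_equal(names(pm$unplaced), "p3")
  agp_obj <- pm$agp[pm$agp$object == names(pm$sequences)[1], ]
  expect_equal(nrow(agp_obj), 3L)
  expect_equal(agp_obj$component_type, c("W", "U", "W"))
  expect_silent(validate_agp(pm$agp, contigs))
  # round trip through AGP and through files
  rebuilt <- agp_to_fasta(pm$agp, contigs)
  expect_identical(rebuilt[[names(pm$sequences)[1]]], pm$sequences[[1]])
  tmp <- tempfile(fileext = ".agp")
  write_agp(pm$agp, tmp)
  agp2 <- read_agp(tmp)
  expect_equal(as.data.frame(agp2), as.data.frame(pm$agp))
  expect_error(build_pseudomolecules(placements, contigs[-1]), "missing")
})

test_that("validate_agp catches corrupted layouts", {
  placements <- tibble::tibble(
    part = c("p1", "p2"), group = "1", n_windows = 2L, conflict = FALSE,
    placed = TRUE, orientation = "+", position_cm = c(0, 5),
    order_index = 1:2)
  contigs <- c(p1 = "ACGTACGTAA", p2 = "GGGTTTCCCA")
  agp <- build_pseudomolecules(placements, contigs)$agp
  bad <- agp
  bad$object_beg[2] <- bad$object_beg[2] + 1L
  expect_error(validate_agp(bad, contigs), "tile")
  bad2 <- agp
  bad2$part_number[3] <- 5L
  expect_error(validate_agp(bad2, contigs), "part_number")
})

test_that("chimeric contigs are detected, broken and scored end to end", {
  cfg <- sim_config(n_chromosomes = 2, chromosome_length = 150000,
                    snv_rate = 0.002, n_individuals = 48, crossover_mean = 1.5,
                    error_rate = 0, mean_depth = 6, n_contigs = 6, chimeras = 2,
                    min_contig_length = 15000, seed = 19)
  tr <- fragment_reference(simulate_f2_population(simulate_parents(cfg)))
  run <- simulate_gbs_run(tr)
  mk <- discover_markers(count_kmers(unname(tr$haplotype_a), 51),
                         count_kmers(unname(tr$haplotype_b), 51),
                         k = 51, min_count = 1, max_other = 0)
  mk <- filter_markers_gbs(mk, tr$haplotype_a, tr$haplotype_b, k = 51)
  pl <- place_markers(mk, tr$contigs, k = 51)
  dm <- demultiplex(run$reads, run$barcodes)
  calls <- call_genotypes(count_alleles(dm, pl$placed, k = 51))
  cons <- bin_consensus(calls, setNames(nchar(tr$contigs), names(tr$contigs)))
  bp <- detect_misjoins(cons)
  ev <- evaluate_against_truth(tr, breakpoints = bp)
  expect_equal(ev$breakpoint_recall, 1.0)
  expect_equal(ev$breakpoint_precision, 1.0)
  expect_setequal(bp$contig, tr$chimera_truth$contig)
  sp <- split_contigs(tr$contigs, bp)
  expect_length(sp$contigs, 6L + nrow(bp))
})
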