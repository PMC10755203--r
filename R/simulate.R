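#' Simulation configuration
#'
#' Bundles every parameter of the synthetic study: two fully inbred parents
#' differing only by SNVs, an F2 intercross population, an ApeKI
#' genotyping-by-sequencing (GBS) run with inline barcodes, and a fragmented
#' (optionally chimeric) draft assembly of the parent-A genome.
#'
#' Defaults mirror the study design the package targets: 9 chromosomes,
#' single-end 100-bp reads, and an F2 population genotyped at modest depth.
#' Chromosome length and population size default to a desk-scale study
#' (500 kb, 96 individuals); the historical experiment used 288 individuals.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Length of each chromosome in bp (scalar or one
#'   value per chromosome).
#' @param snv_rate Per-bp probability that the parents differ (substitutions
#'   only).
#' @param n_individuals Number of F2 individuals.
#' @param crossover_mean Expected crossovers per chromosome per gamete
#'   (Poisson, no interference). 1.5 gives a 150-cM chromosome.
#' @param read_length Total read length in bp, barcode included (default 100).
#' @param error_rate Per-base substitution error rate of simulated reads.
#' @param mean_depth Expected reads per retained fragment end per haplotype
#'   copy per individual.
#' @param size_selection Two-element `c(min, max)` fragment-length window in
#'   bp retained by the library prep.
#' @param barcodes Tibble with `sample_id` and `barcode` columns, or `NULL` to
#'   generate `n_individuals` fixed-length barcodes with [make_barcodes()].
#' @param n_contigs Number of contigs the draft assembly is fragmented into.
#' @param chimeras Either a count of cross-chromosome chimeric joins to plant,
#'   or a tibble of explicit specs (see [fragment_reference()]).
#' @param min_contig_length Minimum contig length enforced when fragmenting.
#' @param seed Integer seed; identical configs give bit-identical outputs.
#' @return A `sim_config` object (validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_chromosomes = 2, chromosome_length = 5e4,
#'                   n_individuals = 12, seed = 42)
sim_config <- function(n_chromosomes = 9, chromosome_length = 5e5,
                       snv_rate = 0.002, n_individuals = 96,
                       crossover_mean = 1.5, read_length = 100,
                       error_rate = 0.001, mean_depth = 4,
                       size_selection = c(60, 400), barcodes = NULL,
                       n_contigs = 60, chimeras = 0,
                       min_contig_length = 20000, seed = 1L) {
  if (n_chromosomes < 1) abort("n_chromosomes must be >= 1")
  chromosome_length <- as.integer(rep(chromosome_length, length.out = n_chromosomes))
  if (any(chromosome_length < 1000)) abort("chromosome_length must be >= 1000 bp")
  if (snv_rate < 0 || snv_rate >= 1) abort("snv_rate must be in [0, 1)")
  if (error_rate < 0 || error_rate >= 1) abort("error_rate must be in [0, 1)")
  if (n_individuals < 1) abort("n_individuals must be >= 1")
  if (crossover_mean < 0) abort("crossover_mean must be >= 0")
  if (length(size_selection) != 2 || size_selection[1] > size_selection[2])
    abort("size_selection must be c(min, max) with min <= max")
  if (is.null(barcodes)) barcodes <- make_barcodes(n_individuals)
  if (!all(c("sample_id", "barcode") %in% names(barcodes)))
    abort("barcodes must have sample_id and barcode columns")
  if (anyDuplicated(barcodes$barcode)) abort("barcodes must be unique")
  if (anyDuplicated(barcodes$sample_id)) abort("sample ids must be unique")
  if (nrow(barcodes) < n_individuals)
    abort("need at least one barcode per individual")
  if (read_length <= max(nchar(barcodes$barcode)) + 4)
    abort("read_length must exceed max barcode length + 4-bp restriction remnant")
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = chromosome_length,
    snv_rate = snv_rate, n_individuals = as.integer(n_individuals),
    crossover_mean = crossover_mean, read_length = as.integer(read_length),
    error_rate = error_rate, mean_depth = mean_depth,
    size_selection = as.integer(size_selection),
    barcodes = as_tibble(barcodes)[seq_len(n_individuals), ],
    n_contigs = as.integer(n_contigs), chimeras = chimeras,
    min_contig_length = as.integer(min_contig_length),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate deterministic sample barcodes
#'
#' Fixed-length (and therefore prefix-free) 6-bp inline barcodes, enumerated
#' in base-4 over `ACGT`; no randomness involved.
#'
#' @param n Number of barcodes (max 4096).
#' @param length Barcode length in bp.
#' @return Tibble with `sample_id` and `barcode`.
#' @export
make_barcodes <- function(n, length = 6L) {
  if (n > 4^length) abort("too many barcodes for this length")
  bases <- c("A", "C", "G", "T")
  codes <- vapply(seq_len(n) - 1L, function(i) {
    digits <- integer(length)
    for (j in seq_len(length)) {
      digits[length - j + 1L] <- i %% 4L
      i <- i %/% 4L
    }
    paste(bases[digits + 1L], collapse = "")
  }, character(1))
  tibble(sample_id = sprintf("F2_%03d", seq_len(n)), barcode = codes)
}

chrom_names <- function(config) sprintf("chr%02d", seq_len(config$n_chromosomes))

#' Simulate two inbred parental genomes
#'
#' Parent A is drawn uniformly over `ACGT`; parent B differs by independent
#' substitutions at `snv_rate` per bp (each mutated to one of the other three
#' bases, uniformly). The two haplotypes differ at exactly the positions
#' listed in the SNV table.
#'
#' @param config A [sim_config()].
#' @return A `truth_set`: list with named character vectors `haplotype_a`,
#'   `haplotype_b`, the tibble `snv` (`chromosome`, `position` 0-based,
#'   `allele_a`, `allele_b`), and the config.
#' @export
simulate_parents <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  bases <- c("A", "C", "G", "T")
  chroms <- chrom_names(config)
  hap_a <- hap_b <- setNames(character(length(chroms)), chroms)
  snv <- vector("list", length(chroms))
  with_seed(derive_seed(config$seed, "parents"), {
    for (i in seq_along(chroms)) {
      len <- config$chromosome_length[i]
      av <- sample(bases, len, replace = TRUE)
      idx <- which(runif(len) < config$snv_rate)
      bv <- av
      if (length(idx)) {
        shift <- sample.int(3L, length(idx), replace = TRUE)
        bv[idx] <- bases[(match(av[idx], bases) - 1L + shift) %% 4L + 1L]
      }
      hap_a[i] <- paste(av, collapse = "")
      hap_b[i] <- paste(bv, collapse = "")
      snv[[i]] <- tibble(chromosome = chroms[i], position = idx - 1L,
                         allele_a = av[idx], allele_b = bv[idx])
    }
  })
  structure(list(haplotype_a = hap_a, haplotype_b = hap_b,
                 snv = bind_rows(snv), config = config),
            class = "truth_set")
}

#' Simulate an F2 intercross population
#'
#' Each individual is the fusion of two independent gametes. Per gamete and
#' chromosome, the crossover count is Poisson(`crossover_mean`), breakpoints
#' are uniform (no interference), and the founder of the first segment is a
#' fair coin; founders alternate across breakpoints. At any locus the
#' population segregates 1 AA : 2 AB : 1 BB in expectation.
#'
#' @param truth A `truth_set` from [simulate_parents()].
#' @param config Optional override of `truth$config`.
#' @return The `truth_set` with a `gametes` tibble added: one row per mosaic
#'   segment (`individual`, `chromosome`, `gamete`, `seg_index`, `start`,
#'   `end` 0-based half-open, `founder` in `{A,B}`) plus `samples`.
#' @export
simulate_f2_population <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "truth_set"))
  chroms <- chrom_names(config)
  samples <- config$barcodes$sample_id[seq_len(config$n_individuals)]
  rows <- vector("list", length(samples) * length(chroms) * 2L)
  k <- 0L
  with_seed(derive_seed(config$seed, "f2"), {
    for (s in samples) {
      for (ci in seq_along(chroms)) {
        len <- config$chromosome_length[ci]
        for (g in 1:2) {
          ncx <- rpois(1L, config$crossover_mean)
          bps <- sort(unique(pmin(pmax(floor(runif(ncx) * (len - 1)) + 1L, 1L), len - 1L)))
          founder0 <- sample(c("A", "B"), 1L)
          nseg <- length(bps) + 1L
          founders <- rep(c(founder0, setdiff(c("A", "B"), founder0)),
                          length.out = nseg)
          k <- k + 1L
          rows[[k]] <- tibble(
            individual = s, chromosome = chroms[ci], gamete = g,
            seg_index = seq_len(nseg),
            start = as.integer(c(0L, bps)), end = as.integer(c(bps, len)),
            founder = founders)
        }
      }
    }
  })
  truth$gametes <- bind_rows(rows[seq_len(k)])
  truth$samples <- samples
  truth$config <- config
  truth
}

#' In-silico ApeKI digestion
#'
#' Scans the forward strand for the ApeKI recognition site `GCWGC`
#' (`W` = A or T) and cuts between the leading G and the `CWGC` remnant
#' (`G^CWGC`). The site set is its own reverse complement, so forward-strand
#' scanning finds every site; overlapping sites each produce a cut. Fragments
#' tile the sequence exactly.
#'
#' @param sequence A single nucleotide string over `ACGTN`.
#' @return Tibble of fragments: `start`, `end` (0-based half-open),
#'   `sequence`.
#' @export
#' @examples
#' digest_genome("TTGCAGCTT") # cuts after the G of GCAGC
digest_genome <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (grepl("[^ACGTNacgtn]", sequence)) abort("sequence must be over ACGTN")
  m <- gregexpr("(?=GC[AT]GC)", sequence, perl = TRUE)[[1]]
  cuts <- if (m[1] == -1L) integer() else as.integer(m) # 1-based site start == 0-based cut
  n <- nchar(sequence)
  starts <- c(0L, cuts)
  ends <- c(cuts, n)
  tibble(start = starts, end = ends,
         sequence = substring(sequence, starts + 1L, ends))
}

# Assemble one gamete's mosaic sequence from the parental haplotypes.
mosaic_sequence <- function(truth, chrom, segs) {
  pieces <- character(nrow(segs))
  for (i in seq_len(nrow(segs))) {
    src <- if (segs$founder[i] == "A") truth$haplotype_a[[chrom]] else truth$haplotype_b[[chrom]]
    pieces[i] <- substring(src, segs$start[i] + 1L, segs$end[i])
  }
  paste(pieces, collapse = "")
}

#' Simulate a multiplexed GBS sequencing run
#'
#' For every individual, both haplotype mosaics of every chromosome are
#' ApeKI-digested; fragments inside the size-selection window whose ends are
#' genuine cut sites yield Poisson(`mean_depth`) reads per end. A read is the
#' sample barcode followed by fragment sequence starting at the `CWGC`
#' remnant, truncated to `read_length` total; the right-hand end is read off
#' the bottom strand and therefore includes the 3-bp overhang of its cut
#' site, so both ends begin with the remnant. Substitution errors are applied
#' to the genomic portion at `error_rate`; barcodes are error-free. Reads
#' from all individuals are interleaved in one deterministic shuffle.
#'
#' @param truth A `truth_set` with an F2 population
#'   (see [simulate_f2_population()]).
#' @param config Optional override of `truth$config`.
#' @return A `gbs_run`: list with `reads` (tibble `read_id`, `sample_id`,
#'   `sequence`, and per-read truth columns `chromosome`, `gamete`,
#'   `frag_start`, `frag_end`, `read_end`) and `barcodes`.
#' @export
simulate_gbs_run <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "truth_set"), !is.null(truth$gametes))
  chroms <- chrom_names(config)
  samples <- truth$samples
  bc <- setNames(config$barcodes$barcode, config$barcodes$sample_id)
  out <- vector("list", length(samples))
  gam_split <- split(truth$gametes,
                     list(truth$gametes$individual, truth$gametes$chromosome,
                          truth$gametes$gamete), drop = TRUE)
  with_seed(derive_seed(config$seed, "gbs"), {
    for (si in seq_along(samples)) {
      s <- samples[si]
      glen <- config$read_length - nchar(bc[[s]])
      acc_seq <- list(); acc_meta <- list(); ai <- 0L
      for (ci in seq_along(chroms)) {
        chrom <- chroms[ci]
        len <- config$chromosome_length[ci]
        for (g in 1:2) {
          segs <- gam_split[[paste(s, chrom, g, sep = ".")]]
          mosaic <- mosaic_sequence(truth, chrom, segs)
          fr <- digest_genome(mosaic)
          flen <- fr$end - fr$start
          keep <- flen >= config$size_selection[1] & flen <= config$size_selection[2]
          fr <- fr[keep, , drop = FALSE]
          if (!nrow(fr)) next
          left_ok <- fr$start > 0L
          right_ok <- fr$end < len
          # left-end reads: forward strand, start at the CWGC remnant
          nl <- rpois(nrow(fr), config$mean_depth) * left_ok
          # right-end reads: bottom strand, include the 3-bp overhang
          nr <- rpois(nrow(fr), config$mean_depth) * right_ok
          li <- rep.int(seq_len(nrow(fr)), nl)
          ri <- rep.int(seq_len(nrow(fr)), nr)
          lseq <- substring(mosaic, fr$start[li] + 1L,
                            pmin(fr$start[li] + glen, fr$end[li]))
          rsrc_start <- pmax(fr$start[ri], fr$end[ri] + 3L - glen)
          rseq <- revcomp_cpp(substring(mosaic, rsrc_start + 1L, fr$end[ri] + 3L))
          ai <- ai + 1L
          acc_seq[[ai]] <- c(lseq, rseq)
          acc_meta[[ai]] <- list(chrom = chrom, gamete = g,
                                 fs = c(fr$start[li], fr$start[ri]),
                                 fe = c(fr$end[li], fr$end[ri]),
                                 end = rep(c("L", "R"), c(length(li), length(ri))))
        }
      }
      seqs <- unlist(acc_seq, use.names = FALSE)
      if (is.null(seqs)) seqs <- character()
      if (config$error_rate > 0) seqs <- inject_errors_cpp(seqs, config$error_rate)
      nper <- vapply(acc_seq, length, integer(1))
      out[[si]] <- tibble(
        sample_id = s,
        sequence = paste0(bc[[s]], seqs),
        chromosome = rep(vapply(acc_meta, `[[`, character(1), "chrom"), nper),
        gamete = rep(vapply(acc_meta, `[[`, integer(1), "gamete"), nper),
        frag_start = unlist(lapply(acc_meta, `[[`, "fs"), use.names = FALSE) %||% integer(),
        frag_end = unlist(lapply(acc_meta, `[[`, "fe"), use.names = FALSE) %||% integer(),
        read_end = unlist(lapply(acc_meta, `[[`, "end"), use.names = FALSE) %||% character())
    }
    reads <- bind_rows(out)
    reads <- reads[sample.int(nrow(reads)), , drop = FALSE]
  })
  reads$read_id <- sprintf("r%08d", seq_len(nrow(reads)))
  reads <- reads[, c("read_id", "sample_id", "sequence", "chromosome",
                     "gamete", "frag_start", "frag_end", "read_end")]
  structure(list(reads = reads,
                 barcodes = config$barcodes[seq_len(config$n_individuals), ]),
            class = "gbs_run")
}

#' Fragment the parent-A genome into a draft assembly
#'
#' Cuts the parent-A genome into `n_contigs` pieces at uniform positions
#' (minimum length enforced), reverse-complements each resulting contig with
#' probability 1/2, and shuffles contig order. Chimeras are planted by
#' concatenating two pieces from *different* chromosomes into one contig
#' (the genome is cut into `n_contigs + n_chimeras` pieces first, so the
#' layout still covers every chromosome); the junction offset of each is
#' recorded in `chimera_truth`.
#'
#' `config$chimeras` may be a count (pairs picked at random, cross-chromosome
#' enforced) or a tibble with columns `chromosome_1`, `start_1`, `end_1`,
#' `chromosome_2`, `start_2`, `end_2` naming piece coordinates exactly; specs
#' that reuse a piece, name a non-existent piece, or join segments of the
#' same chromosome are rejected with a message.
#'
#' @param truth A `truth_set` from [simulate_parents()].
#' @param config Optional override of `truth$config`.
#' @return The `truth_set` augmented with `contigs` (named character vector),
#'   `contig_layout` (tibble `contig`, `part_index`, `contig_start`,
#'   `contig_end`, `chromosome`, `start`, `end`, `strand`; all coordinates
#'   0-based half-open) and `chimera_truth` (`contig`, `junction_offset`).
#' @export
fragment_reference <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "truth_set"))
  chroms <- chrom_names(config)
  lens <- config$chromosome_length
  explicit <- is.data.frame(config$chimeras)
  n_chim <- if (explicit) nrow(config$chimeras) else as.integer(config$chimeras)
  n_pieces <- config$n_contigs + n_chim
  if (n_pieces < length(chroms)) abort("n_contigs must be >= n_chromosomes")
  min_len <- config$min_contig_length
  if (sum(lens) < n_pieces * min_len)
    abort("genome too short for n_contigs at min_contig_length")

  with_seed(derive_seed(config$seed, "assembly"), {
    n_internal <- n_pieces - length(chroms)
    # spread internal cuts over chromosomes proportional to length
    cuts_per <- as.vector(table(factor(
      sample(seq_along(chroms), n_internal, replace = TRUE, prob = lens),
      levels = seq_along(chroms))))
    # a chromosome can host at most floor(len/min_len) - 1 internal cuts
    cap <- pmax(lens %/% min_len - 1L, 0L)
    while (any(cuts_per > cap)) {
      over <- which(cuts_per > cap)[1]
      room <- which(cuts_per < cap)
      if (!length(room)) abort("min_contig_length too large for this layout")
      cuts_per[over] <- cuts_per[over] - 1L
      take <- sample(room, 1L, prob = lens[room])
      cuts_per[take] <- cuts_per[take] + 1L
    }
    pieces <- vector("list", length(chroms))
    for (ci in seq_along(chroms)) {
      kc <- cuts_per[ci]
      repeat {
        pos <- sort(sample.int(lens[ci] - 1L, kc))
        bounds <- c(0L, pos, lens[ci])
        if (kc == 0L || all(diff(bounds) >= min_len)) break
      }
      pieces[[ci]] <- tibble(chromosome = chroms[ci],
                             start = head(bounds, -1L), end = bounds[-1])
    }
    pieces <- bind_rows(pieces)
    pieces$piece_id <- seq_len(nrow(pieces))

    # choose / validate chimera pairs
    pairs <- NULL
    if (n_chim > 0 && explicit) {
      spec <- as_tibble(config$chimeras)
      need <- c("chromosome_1", "start_1", "end_1", "chromosome_2", "start_2", "end_2")
      if (!all(need %in% names(spec))) abort("chimera spec is missing columns")
      find_piece <- function(chr, s, e) {
        hit <- which(pieces$chromosome == chr & pieces$start == s & pieces$end == e)
        if (!length(hit))
          abort(sprintf("chimera segment %s:[%d,%d) does not match an assembly piece", chr, s, e))
        hit
      }
      p1 <- mapply(find_piece, spec$chromosome_1, spec$start_1, spec$end_1)
      p2 <- mapply(find_piece, spec$chromosome_2, spec$start_2, spec$end_2)
      if (any(pieces$chromosome[p1] == pieces$chromosome[p2]))
        abort("chimera segments must come from different chromosomes")
      if (anyDuplicated(c(p1, p2)))
        abort("chimera segment overlaps an already-consumed region")
      pairs <- cbind(p1, p2)
    } else if (n_chim > 0) {
      if (length(unique(pieces$chromosome)) < 2L)
        abort("chimera segments must come from different chromosomes")
      avail <- pieces$piece_id
      pairs <- matrix(0L, n_chim, 2)
      for (i in seq_len(n_chim)) {
        tries <- 0L
        repeat {
          pick <- sample(avail, 2L)
          if (pieces$chromosome[pick[1]] != pieces$chromosome[pick[2]]) break
          tries <- tries + 1L
          if (tries > 1000L) abort("could not pick cross-chromosome chimera segments")
        }
        pairs[i, ] <- pick
        avail <- setdiff(avail, pick)
      }
    }

    chim_of <- integer(0) # piece_id -> chimera index (first/second slot)
    # assemble contig part lists: each contig = list of piece ids in order
    part_sets <- as.list(pieces$piece_id)
    if (n_chim > 0) {
      drop <- logical(nrow(pieces))
      for (i in seq_len(n_chim)) {
        part_sets[[pairs[i, 1]]] <- c(pairs[i, 1], pairs[i, 2])
        drop[pairs[i, 2]] <- TRUE
      }
      part_sets <- part_sets[!drop]
    }
    n_ctg <- length(part_sets)
    stopifnot(n_ctg == config$n_contigs)
    flip <- runif(n_ctg) < 0.5
    ord <- sample.int(n_ctg) # shuffled naming order
  })

  ids <- sprintf("ctg_%03d", seq_len(n_ctg))[order(ord)]
  seqs <- setNames(character(n_ctg), ids)
  layout <- vector("list", n_ctg)
  chim <- list()
  for (i in seq_len(n_ctg)) {
    ps <- pieces[match(part_sets[[i]], pieces$piece_id), , drop = FALSE]
    piece_seqs <- substring(truth$haplotype_a[ps$chromosome], ps$start + 1L, ps$end)
    strand <- rep("+", nrow(ps))
    if (flip[i]) {
      ps <- ps[rev(seq_len(nrow(ps))), , drop = FALSE]
      piece_seqs <- rev(revcomp_cpp(piece_seqs))
      strand <- rep("-", nrow(ps))
    }
    seqs[i] <- paste(piece_seqs, collapse = "")
    plens <- ps$end - ps$start
    offs <- cumsum(c(0L, head(plens, -1L)))
    layout[[i]] <- tibble(contig = ids[i], part_index = seq_len(nrow(ps)),
                          contig_start = as.integer(offs),
                          contig_end = as.integer(offs + plens),
                          chromosome = ps$chromosome, start = ps$start,
                          end = ps$end, strand = strand)
    if (nrow(ps) > 1L)
      chim[[length(chim) + 1L]] <- tibble(contig = ids[i],
                                          junction_offset = as.integer(plens[1]))
  }
  truth$contigs <- seqs
  truth$contig_layout <- bind_rows(layout) |> arrange(.data$contig, .data$part_index)
  truth$chimera_truth <- if (length(chim)) bind_rows(chim) |> arrange(.data$contig) else
    tibble(contig = character(), junction_offset = integer())
  truth$config <- config
  truth
}

#' @export
print.truth_set <- function(x, ...) {
  cat("<truth_set>\n")
  cat(sprintf("  chromosomes: %d (%s bp total)\n", length(x$haplotype_a),
              format(sum(nchar(x$haplotype_a)), big.mark = ",")))
  cat(sprintf("  parental SNVs: %s\n", format(nrow(x$snv), big.mark = ",")))
  if (!is.null(x$gametes))
    cat(sprintf("  F2 individuals: %d\n", length(x$samples)))
  if (!is.null(x$contigs))
    cat(sprintf("  draft contigs: %d (%d chimeric)\n", length(x$contigs),
                nrow(x$chimera_truth)))
  invisible(x)
}

#' @export
print.gbs_run <- function(x, ...) {
  cat("<gbs_run>\n")
  cat(sprintf("  reads: %s from %d samples\n",
              format(nrow(x$reads), big.mark = ","),
              length(unique(x$reads$sample_id))))
  invisible(x)
}
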