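#' Demultiplex a barcoded GBS run
#'
#' Assigns each read to the unique sample whose inline barcode, immediately
#' followed by a base pattern matching the restriction remnant, prefixes the
#' read. Barcodes are tried longest-first; the barcode is trimmed and the
#' remnant retained. Reads matching no barcode (or failing the remnant
#' check) go to the unassigned set; assigned and unassigned reads partition
#' the input.
#'
#' @param reads Tibble with `read_id` and `sequence` (e.g. from
#'   [read_fastq()] or `simulate_gbs_run()$reads`), or a FASTQ path.
#' @param barcodes Tibble with `sample_id` and `barcode`.
#' @param remnant IUPAC pattern the bases after the barcode must match
#'   (default `"CWGC"`, the ApeKI remnant).
#' @param max_mismatch Barcode mismatches tolerated (0 = exact, the default;
#'   with mismatches a read is assigned only when a single barcode of that
#'   length matches best).
#' @return Tibble `read_id`, `sample_id` (`NA` for unassigned), `sequence`
#'   (barcode trimmed for assigned reads, untouched otherwise).
#' @export
demultiplex <- function(reads, barcodes, remnant = "CWGC", max_mismatch = 0L) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  if (anyDuplicated(barcodes$barcode)) abort("duplicate barcode sequences")
  iupac <- c(A = "A", C = "C", G = "G", T = "T", W = "[AT]", S = "[CG]",
             R = "[AG]", Y = "[CT]", K = "[GT]", M = "[AC]", N = "[ACGT]")
  rem_re <- paste0("^", paste(iupac[strsplit(remnant, "")[[1]]], collapse = ""))
  seqs <- reads$sequence
  sample_id <- rep(NA_character_, length(seqs))
  trimmed <- seqs
  unassigned <- rep(TRUE, length(seqs))
  for (len in sort(unique(nchar(barcodes$barcode)), decreasing = TRUE)) {
    bcs <- barcodes[nchar(barcodes$barcode) == len, ]
    idx <- which(unassigned)
    if (!length(idx)) break
    prefix <- substr(seqs[idx], 1L, len)
    if (max_mismatch == 0L) {
      hit <- match(prefix, bcs$barcode)
    } else {
      hit <- hamming_assign(prefix, bcs$barcode, max_mismatch)
    }
    ok <- !is.na(hit) &
      grepl(rem_re, substr(seqs[idx], len + 1L, len + nchar(remnant)))
    take <- idx[ok]
    sample_id[take] <- bcs$sample_id[hit[ok]]
    trimmed[take] <- substr(seqs[take], len + 1L, nchar(seqs[take]))
    unassigned[take] <- FALSE
  }
  tibble(read_id = reads$read_id, sample_id = sample_id, sequence = trimmed)
}

# unique best-scoring barcode within max_mismatch, else NA
hamming_assign <- function(prefix, barcodes, max_mismatch) {
  bc_mat <- do.call(rbind, strsplit(barcodes, ""))
  n <- length(prefix)
  best <- rep(NA_integer_, n)
  pm <- do.call(rbind, strsplit(prefix, ""))
  for (i in seq_len(n)) {
    d <- rowSums(bc_mat != matrix(pm[i, ], nrow(bc_mat), ncol(bc_mat), byrow = TRUE))
    dm <- min(d)
    if (dm <= max_mismatch && sum(d == dm) == 1L) best[i] <- which.min(d)
  }
  best
}

#' Count diagnostic-allele observations per individual and locus
#'
#' Every length-`k` window of every demultiplexed read is checked (in
#' canonical form) against the placed-marker lookup; each exact hit
#' increments the matching parent's count at that marker locus for that
#' sample. A read may hit several loci and is counted at each. No partial or
#' mismatched matches are counted.
#'
#' @param reads Tibble with `sample_id` and `sequence` (unassigned rows,
#'   `sample_id = NA`, are ignored).
#' @param placed `placed` tibble from [place_markers()].
#' @param k K-mer size.
#' @return Tibble `individual`, `contig`, `pos` (marker start, 0-based),
#'   `count_a`, `count_b`.
#' @export
count_alleles <- function(reads, placed, k = 51L) {
  stopifnot(all(c("sample_id", "sequence") %in% names(reads)))
  keep <- !is.na(reads$sample_id)
  samples <- sort(unique(reads$sample_id[keep]))
  loci <- placed |> distinct(.data$contig, .data$start) |>
    arrange(.data$contig, .data$start)
  locus_key <- paste(loci$contig, loci$start)
  locus_idx <- match(paste(placed$contig, placed$start), locus_key)
  res <- count_alleles_cpp(reads$sequence[keep],
                           match(reads$sample_id[keep], samples),
                           placed$kmer, locus_idx,
                           as.integer(placed$parent == "B"), as.integer(k))
  tibble(individual = samples[res$sample],
         contig = loci$contig[res$locus],
         pos = loci$start[res$locus],
         count_a = res$count_a, count_b = res$count_b)
}

#' Call raw genotypes from allele counts
#'
#' `AA` when `count_a >= min_allele` and `count_b == 0`; `BB` symmetrically;
#' `AB` when both alleles are seen at least once; otherwise `NA` (uncalled).
#' The homozygote threshold suppresses singleton sequencing-error k-mers
#' while keeping heterozygotes callable at modest depth.
#'
#' @param counts Tibble from [count_alleles()].
#' @param min_allele Minimum count to call a homozygote.
#' @return The input with a `call` column in `{AA, AB, BB, NA}`.
#' @export
call_genotypes <- function(counts, min_allele = 2L) {
  counts |> mutate(call = case_when(
    .data$count_a >= min_allele & .data$count_b == 0L ~ "AA",
    .data$count_b >= min_allele & .data$count_a == 0L ~ "BB",
    .data$count_a >= 1L & .data$count_b >= 1L ~ "AB",
    TRUE ~ NA_character_))
}

#' Majority-rule consensus genotypes in tiling windows
#'
#' Windows of fixed width (default 14 kb) are anchored at position 0 of each
#' contig, half-open, the last one truncated. Raw calls are first collapsed
#' to one vote per *marker site*: loci whose k-mer windows overlap (start
#' positions within `cluster_gap` bp along the contig, chained) cover the
#' same underlying SNV and vote once, with the site's plurality call (ties
#' discard the site). The window consensus is then the strict plurality of
#' site votes; it must beat every rival outright and the winning class must
#' be supported by at least `min_calls` raw calls, otherwise the window is
#' `U` (uncalled).
#'
#' The site-level collapse matters on real(istic) GBS data: an SNV that
#' creates or destroys a restriction site in one parent silences one allele
#' at every marker locus of a nearby SNV (allele-specific fragment dropout),
#' and a dropout site contributes up to k correlated wrong calls. One vote
#' per site keeps a single aberrant site from outvoting clean ones.
#'
#' @param calls Tibble from [call_genotypes()].
#' @param contig_lengths Named integer vector of contig lengths.
#' @param window Window width in bp (default 14000).
#' @param min_calls Minimum raw calls supporting the winning class.
#' @param cluster_gap Loci whose starts are within this many bp (chained)
#'   form one marker site; the default (51) chains the windows of one SNV.
#' @return Tibble `contig`, `window_index` (0-based), `start`, `end`,
#'   `individual`, `genotype` in `{A, H, B, U}`. Only windows with at least
#'   one informative call for at least one individual appear; individuals
#'   without calls in such a window are filled in as `U`.
#' @export
bin_consensus <- function(calls, contig_lengths, window = 14000L, min_calls = 2L,
                          cluster_gap = 51L) {
  stopifnot(!is.null(names(contig_lengths)))
  window <- as.integer(window)
  inf <- calls |> filter(!is.na(.data$call))
  if (!nrow(inf)) {
    return(tibble(contig = character(), window_index = integer(),
                  start = integer(), end = integer(),
                  individual = character(), genotype = character()))
  }
  # chain loci into marker-site clusters per contig
  sites <- inf |> distinct(.data$contig, .data$pos) |>
    arrange(.data$contig, .data$pos) |>
    group_by(.data$contig) |>
    mutate(site = cumsum(c(1L, as.integer(diff(.data$pos) > cluster_gap)))) |>
    ungroup()
  # per (individual, window, site): plurality vote; ties discard the site
  site_tally <- inf |>
    inner_join(sites, by = c("contig", "pos")) |>
    mutate(window_index = .data$pos %/% window) |>
    count(.data$contig, .data$window_index, .data$site, .data$individual,
          .data$call)
  ranked <- site_tally |>
    group_by(.data$contig, .data$window_index, .data$site, .data$individual) |>
    arrange(desc(.data$n), .data$call, .by_group = TRUE) |>
    mutate(rk = row_number(), n_top = max(.data$n),
           tied = sum(.data$n == max(.data$n)) > 1L) |>
    ungroup()
  votes <- ranked |>
    filter(.data$rk == 1L, !.data$tied) |>
    transmute(.data$contig, .data$window_index, .data$site, .data$individual,
              vote = .data$call, support = .data$n)
  # per (individual, window): strict plurality of site votes
  wt <- votes |>
    count(.data$contig, .data$window_index, .data$individual, .data$vote,
          wt = NULL, name = "n_sites") |>
    left_join(votes |>
                group_by(.data$contig, .data$window_index, .data$individual,
                         vote = .data$vote) |>
                summarise(raw_support = sum(.data$support), .groups = "drop"),
              by = c("contig", "window_index", "individual", "vote"))
  cons <- wt |>
    tidyr::pivot_wider(names_from = "vote",
                       values_from = c("n_sites", "raw_support"),
                       values_fill = 0L)
  for (cl in c("AA", "AB", "BB")) {
    for (pre in c("n_sites_", "raw_support_"))
      if (!paste0(pre, cl) %in% names(cons)) cons[[paste0(pre, cl)]] <- 0L
  }
  nmat <- as.matrix(cons[, c("n_sites_AA", "n_sites_AB", "n_sites_BB")])
  smat <- as.matrix(cons[, c("raw_support_AA", "raw_support_AB", "raw_support_BB")])
  top <- max.col(nmat, ties.method = "first")
  ri <- seq_len(nrow(nmat))
  best <- nmat[cbind(ri, top)]
  runner <- apply(nmat, 1L, function(x) max(x[-which.max(x)]))
  ok <- best > runner & smat[cbind(ri, top)] >= min_calls
  cons$genotype <- ifelse(ok, c("A", "H", "B")[top], "U")
  # complete the window x individual grid with U for covered windows
  grid <- cons |>
    distinct(.data$contig, .data$window_index) |>
    tidyr::crossing(individual = sort(unique(calls$individual)))
  out <- grid |>
    left_join(cons |> select("contig", "window_index", "individual", "genotype"),
              by = c("contig", "window_index", "individual")) |>
    mutate(genotype = tidyr::replace_na(.data$genotype, "U"),
           start = .data$window_index * window,
           end = pmin((.data$window_index + 1L) * window,
                      as.integer(contig_lengths[.data$contig]))) |>
    select("contig", "window_index", "start", "end", "individual", "genotype") |>
    arrange(.data$contig, .data$window_index, .data$individual)
  out
}

#' Consensus genotypes as a loci-by-individuals matrix
#'
#' @param consensus Tibble from [bin_consensus()].
#' @return Character matrix over `{A,H,B,U}`; rownames are
#'   `"contig:window_index"` locus ids, columns are individuals.
#' @export
consensus_matrix <- function(consensus) {
  wide <- consensus |>
    mutate(locus = paste0(.data$contig, ":", .data$window_index)) |>
    select("locus", "individual", "genotype") |>
    tidyr::pivot_wider(names_from = "individual", values_from = "genotype",
                       values_fill = "U") |>
    arrange(.data$locus)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$locus
  m[is.na(m)] <- "U"
  m
}
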