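#' Count canonical k-mers
#'
#' Counts every length-`k` window of the input sequences under canonical form
#' (the lexicographic minimum of a k-mer and its reverse complement). Windows
#' containing non-`ACGT` bases are skipped. `k` must be odd so no k-mer is
#' its own reverse complement.
#'
#' @param sequences Character vector of reads or genome sequences (a tibble
#'   with a `sequence` column is also accepted).
#' @param k Odd k-mer size, 3..63 (default 51).
#' @return Tibble with `kmer` and `count`, sorted by `kmer`.
#' @export
#' @examples
#' count_kmers("ACGTA", k = 3) # CGT canonicalises to ACG
count_kmers <- function(sequences, k = 51L) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  stopifnot(is.character(sequences))
  as_tibble(kmer_count_cpp(sequences, as.integer(k)))
}

#' Discover parent-diagnostic k-mer pairs
#'
#' A k-mer `x` is A-diagnostic when it is abundant in parent A
#' (`count >= min_count`), rare in parent B (`count <= max_other`), and some
#' single-base substitution `y` of it is the mirror image: abundant in B,
#' rare in A. Every qualifying pair is retained (one SNV yields up to `k`
#' pairs, one per covering window), deduplicated on the canonical pair.
#'
#' Suggested thresholds: `min_count = 1, max_other = 0` when counting from
#' assembled genomes; `min_count = 3, max_other = 0` (the defaults) when
#' counting from reads, to suppress sequencing-error k-mers.
#'
#' @param counts_a,counts_b Count tables from [count_kmers()] built with the
#'   same `k`.
#' @param k K-mer size used to build the tables.
#' @param min_count Minimum count in the diagnostic parent.
#' @param max_other Maximum count tolerated in the other parent.
#' @return Tibble of markers, two rows per pair: `marker_id`, `kmer`
#'   (canonical), `parent` (`A`/`B`), `partner_id`, `count_self`,
#'   `count_other`, `pair_id`, `snv_offset` (SNV position within the stored
#'   A k-mer, 0-based).
#' @export
discover_markers <- function(counts_a, counts_b, k = 51L,
                             min_count = 3L, max_other = 0L) {
  stopifnot(is.data.frame(counts_a), is.data.frame(counts_b))
  pairs <- as_tibble(discover_markers_cpp(
    counts_a$kmer, as.integer(counts_a$count),
    counts_b$kmer, as.integer(counts_b$count),
    as.integer(k), as.integer(min_count), as.integer(max_other)))
  n <- nrow(pairs)
  pair_id <- sprintf("P%06d", seq_len(n))
  a <- tibble(marker_id = paste0(pair_id, "a"), kmer = pairs$kmer_a,
              parent = "A", partner_id = paste0(pair_id, "b"),
              count_self = pairs$count_a_in_a, count_other = pairs$count_a_in_b,
              pair_id = pair_id, snv_offset = pairs$snv_offset)
  b <- tibble(marker_id = paste0(pair_id, "b"), kmer = pairs$kmer_b,
              parent = "B", partner_id = paste0(pair_id, "a"),
              count_self = pairs$count_b_in_b, count_other = pairs$count_b_in_a,
              pair_id = pair_id, snv_offset = pairs$snv_offset)
  bind_rows(a, b) |> arrange(.data$pair_id, .data$parent)
}

#' Place markers on a draft assembly by exact unique match
#'
#' A marker pair is placed when exactly one of its two k-mers occurs exactly
#' once (in either orientation) across all contigs; the partner inherits that
#' placement. Because the assembly derives from parent A, the A allele is the
#' one expected to match. Pairs hitting no contig or more than one location
#' are rejected with a reason.
#'
#' @param markers Marker tibble from [discover_markers()].
#' @param contigs Named character vector of contig sequences (or a path to a
#'   FASTA file).
#' @param k K-mer size.
#' @return List with `placed` (tibble `marker_id`, `pair_id`, `parent`,
#'   `kmer`, `contig`, `start` 0-based, `strand`, `snv_offset`) and
#'   `rejected` (`pair_id`, `reason`).
#' @export
place_markers <- function(markers, contigs, k = 51L) {
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs))
    contigs <- read_fasta(contigs)
  stopifnot(is.character(contigs), !is.null(names(contigs)))
  kmers <- unique(c(markers$kmer))
  hits <- place_kmers_cpp(kmers, unname(contigs), as.integer(k))
  hit_tbl <- tibble(kmer = kmers, n_hits = hits$n_hits,
                    contig = names(contigs)[hits$contig],
                    start = hits$start, strand = hits$strand)
  m <- markers |> left_join(hit_tbl, by = "kmer")
  ma <- m |> filter(.data$parent == "A") |> arrange(.data$pair_id)
  mb <- m |> filter(.data$parent == "B") |> arrange(.data$pair_id)
  stopifnot(identical(ma$pair_id, mb$pair_id))
  total_hits <- ma$n_hits + mb$n_hits
  unique_hit <- total_hits == 1L # exactly one of the pair, exactly once
  use_a <- ma$n_hits == 1L
  loc <- tibble(pair_id = ma$pair_id,
                contig = ifelse(use_a, ma$contig, mb$contig),
                start = ifelse(use_a, ma$start, mb$start),
                strand = ifelse(use_a, ma$strand, mb$strand))[unique_hit, ]
  placed <- m |>
    select(-"n_hits", -"contig", -"start", -"strand") |>
    inner_join(loc, by = "pair_id") |>
    select("marker_id", "pair_id", "parent", "kmer", "contig", "start",
           "strand", "snv_offset") |>
    arrange(.data$contig, .data$start, .data$pair_id, .data$parent)
  rejected <- tibble(pair_id = ma$pair_id[!unique_hit],
                     reason = ifelse(total_hits[!unique_hit] == 0L,
                                     "no-hit", "multi-mapping")) |>
    arrange(.data$pair_id)
  list(placed = placed, rejected = rejected)
}

#' Write or read a marker table as TSV
#'
#' @param markers Marker tibble from [discover_markers()].
#' @param path File path.
#' @return The path (write) or a tibble (read).
#' @export
write_markers_tsv <- function(markers, path) {
  readr::write_tsv(markers, path)
  invisible(path)
}

#' @rdname write_markers_tsv
#' @export
read_markers_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write placed markers as BED6
#'
#' 0-based half-open intervals; the score column carries the SNV offset
#' within the k-mer.
#'
#' @param placed `placed` tibble from [place_markers()].
#' @param path File path.
#' @param k K-mer size (interval width).
#' @export
write_placed_bed <- function(placed, path, k = 51L) {
  bed <- placed |>
    transmute(.data$contig, .data$start, end = .data$start + as.integer(k),
              name = .data$marker_id, score = .data$snv_offset, .data$strand)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Restrict markers to the GBS-visible fraction of the genome
#'
#' Genotyping-by-sequencing only observes fragment ends: a marker can be
#' scored only if its k-mer sits within `genomic_read_length` bp of an ApeKI
#' cut on a size-selected fragment. Crucially this is allele-specific - an
#' SNV that creates or destroys a `GCWGC` site in one parent moves that
#' haplotype's fragment out of the size-selection window and silently drops
#' one allele, which at genotyping time masquerades as a homozygote. This
#' filter performs an in-silico digest of both parental genomes, emits the
#' deterministic fragment-end read set each would produce, and keeps only
#' marker pairs whose A k-mer occurs in parent A's reads and whose B k-mer
#' occurs in parent B's reads.
#'
#' @param markers Marker tibble from [discover_markers()].
#' @param genome_a,genome_b Named character vectors: the parental genomes.
#' @param k K-mer size.
#' @param size_selection `c(min, max)` fragment length window in bp.
#' @param genomic_read_length Genomic bases per read (read length minus the
#'   longest barcode).
#' @return The filtered marker tibble (complete pairs only).
#' @export
filter_markers_gbs <- function(markers, genome_a, genome_b, k = 51L,
                               size_selection = c(60, 400),
                               genomic_read_length = 94L) {
  visible <- function(genome) {
    reads <- unlist(lapply(unname(genome), gbs_end_reads,
                           size_selection = size_selection,
                           glen = genomic_read_length), use.names = FALSE)
    count_kmers(reads, k = k)$kmer
  }
  vis_a <- visible(genome_a)
  vis_b <- visible(genome_b)
  ok_a <- markers |> filter(.data$parent == "A", .data$kmer %in% vis_a)
  ok_b <- markers |> filter(.data$parent == "B", .data$kmer %in% vis_b)
  keep <- intersect(ok_a$pair_id, ok_b$pair_id)
  markers |> filter(.data$pair_id %in% keep)
}

# Deterministic fragment-end reads of one sequence: one read per qualifying
# end of each size-selected, cut-flanked fragment. Right-end reads run off
# the bottom strand and include the 3-bp overhang, as in the simulator.
gbs_end_reads <- function(sequence, size_selection, glen) {
  fr <- digest_genome(sequence)
  len <- nchar(sequence)
  flen <- fr$end - fr$start
  fr <- fr[flen >= size_selection[1] & flen <= size_selection[2], , drop = FALSE]
  if (!nrow(fr)) return(character())
  left <- fr[fr$start > 0L, , drop = FALSE]
  right <- fr[fr$end < len, , drop = FALSE]
  c(substring(sequence, left$start + 1L, pmin(left$start + glen, left$end)),
    revcomp_cpp(substring(sequence, pmax(right$start, right$end + 3L - glen) + 1L,
                          right$end + 3L)))
}
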