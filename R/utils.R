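#' Reverse-complement nucleotide sequences
#'
#' Vectorised reverse complement over `A/C/G/T` (case preserved); any other
#' character becomes `N`.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "GCAGC"))
revcomp <- function(x) {
  stopifnot(is.character(x))
  revcomp_cpp(x)
}

#' Read and write FASTA files
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] that work with named character vectors,
#' the representation used throughout this package.
#'
#' @param path File path.
#' @param seqs Named character vector of sequences.
#' @return `read_fasta()` returns a named character vector; `write_fasta()`
#'   returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read and write FASTQ files
#'
#' Reads are carried as a tibble with `read_id` and `sequence` columns.
#' Qualities are written as a constant character (Phred+33 "I" = Q40), the
#' convention used by the simulator.
#'
#' @param path File path.
#' @param reads Tibble with at least `read_id` and `sequence` columns.
#' @param quality_char Single quality character to emit for every base.
#' @return `read_fastq()` returns a tibble (`read_id`, `sequence`);
#'   `write_fastq()` returns `path` invisibly.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) abort("malformed FASTQ: line count not a multiple of 4")
  ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1L, length(lines), by = 4L)]))
  tibble(read_id = ids, sequence = lines[seq(2L, length(lines), by = 4L)])
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  n <- nrow(reads)
  out <- character(4L * n)
  out[seq(1L, by = 4L, length.out = n)] <- paste0("@", reads$read_id)
  out[seq(2L, by = 4L, length.out = n)] <- reads$sequence
  out[seq(3L, by = 4L, length.out = n)] <- "+"
  out[seq(4L, by = 4L, length.out = n)] <-
    vapply(nchar(reads$sequence), function(w) strrep(quality_char, w), character(1))
  con <- file(path, open = "wb") # fixed newline convention => stable checksums
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

# Deterministic per-stage seed: polynomial hash of the stage name folded into
# the run seed, kept below 2^31 so set.seed() accepts it.
derive_seed <- function(seed, stage) {
  h <- 0
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% 2147462143
  as.integer((abs(as.numeric(seed)) + h) %% 2147483629)
}

# Run code with a temporary RNG state seeded from `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# all permutations of 1..n, n <= 7; cached
perms_cache <- new.env(parent = emptyenv())
permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(perms_cache[[key]])) return(perms_cache[[key]])
  if (n == 1L) out <- matrix(1L, 1L, 1L)
  else {
    sub <- permutations(n - 1L)
    out <- do.call(rbind, lapply(seq_len(n), function(i) {
      rest <- seq_len(n)[-i]
      cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
    }))
  }
  storage.mode(out) <- "integer"
  perms_cache[[key]] <- out
  out
}
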