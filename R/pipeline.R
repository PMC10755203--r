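PIPELINE_STAGES <- c("simulate", "discover", "demux", "genotype", "bin",
                     "map", "qc", "scaffold", "evaluate")

#' Pipeline configuration
#'
#' One structured object holding every stage parameter plus the simulation
#' settings; serialisable to YAML with [write_pipeline_config()]. Unknown
#' keys are rejected.
#'
#' @param sim A [sim_config()] describing the synthetic inputs.
#' @param k K-mer size for markers (odd; default 51).
#' @param min_count,max_other Marker-discovery thresholds (genome counting
#'   defaults).
#' @param min_allele Homozygote calling threshold.
#' @param window Consensus window width in bp.
#' @param min_calls Minimum calls per consensus window.
#' @param max_rf,min_lod Linkage-grouping thresholds.
#' @param min_switch,min_informative Misjoin-detection thresholds.
#' @param gap Pseudomolecule gap length in Ns.
#' @param seed Run seed; every stage derives its own stream from it.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(sim = sim_config(), k = 51L, min_count = 1L,
                            max_other = 0L, min_allele = 2L, window = 14000L,
                            min_calls = 2L, max_rf = 0.35, min_lod = 6,
                            min_switch = 0.5, min_informative = 20L,
                            gap = 100L, seed = sim$seed) {
  stopifnot(inherits(sim, "sim_config"))
  if (k %% 2L == 0L) abort("k must be odd")
  structure(list(sim = sim, k = as.integer(k), min_count = as.integer(min_count),
                 max_other = as.integer(max_other), min_allele = as.integer(min_allele),
                 window = as.integer(window), min_calls = as.integer(min_calls),
                 max_rf = max_rf, min_lod = min_lod, min_switch = min_switch,
                 min_informative = as.integer(min_informative),
                 gap = as.integer(gap), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read and write pipeline configs as YAML
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x$sim$barcodes <- as.list(setNames(x$sim$barcodes$barcode, x$sim$barcodes$sample_id))
  x$sim$chimeras <- if (is.data.frame(x$sim$chimeras)) as.list(as.data.frame(x$sim$chimeras)) else x$sim$chimeras
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(x), known)
  if (length(extra)) abort(sprintf("unknown config key: %s", extra[1]))
  sim_known <- names(formals(sim_config))
  sim_extra <- setdiff(names(x$sim), sim_known)
  if (length(sim_extra)) abort(sprintf("unknown sim config key: %s", sim_extra[1]))
  sim <- x$sim
  if (!is.null(sim$barcodes))
    sim$barcodes <- tibble(sample_id = names(sim$barcodes),
                           barcode = unlist(sim$barcodes, use.names = FALSE))
  if (is.list(sim$chimeras) && !is.null(sim$chimeras$chromosome_1))
    sim$chimeras <- as_tibble(sim$chimeras)
  x$sim <- do.call(sim_config, sim)
  do.call(pipeline_config, x)
}

stage_outputs <- function(stage) {
  switch(stage,
    simulate = c("parents.fa", "contigs.fa", "gbs.fastq", "barcodes.tsv",
                 "truth_snv.tsv", "truth_gametes.tsv", "truth_layout.tsv",
                 "truth_chimeras.tsv"),
    discover = c("markers.tsv", "placed.tsv", "rejected.tsv"),
    demux = c("demux_assign.tsv", "demux_counts.tsv"),
    genotype = "genotypes_raw.tsv",
    bin = "consensus.tsv",
    map = c("map.tsv", "rf.tsv"),
    qc = c("breakpoints.tsv", "contigs_split.fa", "provenance.tsv"),
    scaffold = c("pseudomolecules.fa", "assembly.agp", "placements.tsv"),
    evaluate = "evaluation.tsv")
}

stage_deps <- function(stage) {
  switch(stage,
    simulate = character(),
    discover = "simulate",
    demux = "simulate",
    genotype = c("discover", "demux"),
    bin = "genotype",
    map = "bin",
    qc = "bin",
    scaffold = c("map", "qc"),
    evaluate = c("map", "qc", "scaffold", "bin", "simulate"))
}

#' Run the full pipeline (or a subset of stages)
#'
#' Stages run in dependency order: simulate, discover, demux, genotype, bin,
#' map, qc, scaffold, evaluate. Each stage writes its declared files under
#' `out_dir` and a manifest (`manifest.json`) recording the config hash,
#' seed, package version and the md5 checksum of every output, so a rerun
#' with an identical config reproduces identical checksums. Requesting a
#' stage whose inputs are absent (not produced in this run and not on disk)
#' raises an error naming the stage to run first.
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector of stages, or `"all"`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage objects computed in this run and
#'   the manifest.
#' @export
run_pipeline <- function(config, stages = "all", out_dir = ".") {
  stopifnot(inherits(config, "pipeline_config"))
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) abort(sprintf("unknown stage: %s", bad[1]))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  st <- new.env(parent = emptyenv())

  have_stage <- function(stage) {
    all(file.exists(p(stage_outputs(stage))))
  }
  require_deps <- function(stage) {
    for (d in stage_deps(stage)) {
      if (!d %in% stages && !have_stage(d))
        abort(sprintf("stage '%s' needs outputs of stage '%s'; run '%s' first",
                      stage, d, d))
    }
  }

  get_truth <- function() {
    if (is.null(st$truth)) st$truth <- load_truth(out_dir)
    st$truth
  }
  get_contigs <- function() get_truth()$contigs
  get_reads <- function() {
    if (is.null(st$reads)) {
      message("[pipeline] loading gbs.fastq")
      st$reads <- read_fastq(p("gbs.fastq"))
    }
    st$reads
  }
  get_assign <- function() {
    if (is.null(st$assign))
      st$assign <- readr::read_tsv(p("demux_assign.tsv"), show_col_types = FALSE,
                                   progress = FALSE)
    st$assign
  }
  get_placed <- function() {
    if (is.null(st$placed))
      st$placed <- readr::read_tsv(p("placed.tsv"), show_col_types = FALSE,
                                   progress = FALSE)
    st$placed
  }
  get_consensus <- function() {
    if (is.null(st$consensus))
      st$consensus <- read_consensus_tsv(p("consensus.tsv"), get_contigs(),
                                         config$window)
    st$consensus
  }
  get_breakpoints <- function() {
    if (is.null(st$breakpoints))
      st$breakpoints <- readr::read_tsv(p("breakpoints.tsv"),
                                        col_types = "cidi", progress = FALSE)
    st$breakpoints
  }
  get_map <- function() {
    if (is.null(st$map)) {
      loci <- readr::read_tsv(p("map.tsv"), show_col_types = FALSE, progress = FALSE) |>
        mutate(group = as.character(.data$group))
      rf <- readr::read_tsv(p("rf.tsv"), show_col_types = FALSE, progress = FALSE)
      st$map <- structure(list(loci = loci, rf = rf), class = "genetic_map")
    }
    st$map
  }

  run_stage <- list(
    simulate = function() {
      truth <- simulate_parents(config$sim)
      truth <- simulate_f2_population(truth)
      truth <- fragment_reference(truth)
      run <- simulate_gbs_run(truth)
      st$truth <- truth
      st$reads <- run$reads
      write_fasta(c(setNames(truth$haplotype_a,
                             paste0(names(truth$haplotype_a), "_A")),
                    setNames(truth$haplotype_b,
                             paste0(names(truth$haplotype_b), "_B"))),
                  p("parents.fa"))
      write_fasta(truth$contigs, p("contigs.fa"))
      write_fastq(run$reads, p("gbs.fastq"))
      readr::write_tsv(run$barcodes, p("barcodes.tsv"))
      readr::write_tsv(truth$snv, p("truth_snv.tsv"))
      readr::write_tsv(truth$gametes, p("truth_gametes.tsv"))
      readr::write_tsv(truth$contig_layout, p("truth_layout.tsv"))
      readr::write_tsv(truth$chimera_truth, p("truth_chimeras.tsv"))
    },
    discover = function() {
      truth <- get_truth()
      ka <- count_kmers(unname(truth$haplotype_a), config$k)
      kb <- count_kmers(unname(truth$haplotype_b), config$k)
      markers <- discover_markers(ka, kb, k = config$k,
                                  min_count = config$min_count,
                                  max_other = config$max_other)
      glen <- config$sim$read_length - max(nchar(config$sim$barcodes$barcode))
      markers <- filter_markers_gbs(markers, truth$haplotype_a, truth$haplotype_b,
                                    k = config$k,
                                    size_selection = config$sim$size_selection,
                                    genomic_read_length = glen)
      pl <- place_markers(markers, truth$contigs, k = config$k)
      st$placed <- pl$placed
      write_markers_tsv(markers, p("markers.tsv"))
      readr::write_tsv(pl$placed, p("placed.tsv"))
      readr::write_tsv(pl$rejected, p("rejected.tsv"))
      write_placed_bed(pl$placed, p("placed.bed"), k = config$k)
    },
    demux = function() {
      barcodes <- readr::read_tsv(p("barcodes.tsv"), col_types = "cc",
                                  progress = FALSE)
      dm <- demultiplex(get_reads(), barcodes)
      st$assign <- dm
      readr::write_tsv(dm |> select("read_id", "sample_id"), p("demux_assign.tsv"))
      readr::write_tsv(dm |> filter(!is.na(.data$sample_id)) |>
                         count(.data$sample_id, name = "n_reads"),
                       p("demux_counts.tsv"))
    },
    genotype = function() {
      dm <- get_assign()
      if (!"sequence" %in% names(dm)) {
        barcodes <- readr::read_tsv(p("barcodes.tsv"), col_types = "cc",
                                    progress = FALSE)
        dm <- demultiplex(get_reads(), barcodes)
      }
      counts <- count_alleles(dm, get_placed(), k = config$k)
      st$counts <- counts
      calls <- call_genotypes(counts, min_allele = config$min_allele)
      st$calls <- calls
      readr::write_tsv(calls, p("genotypes_raw.tsv"))
    },
    bin = function() {
      if (is.null(st$calls))
        st$calls <- readr::read_tsv(p("genotypes_raw.tsv"), show_col_types = FALSE,
                                    progress = FALSE)
      lens <- setNames(nchar(get_contigs()), names(get_contigs()))
      cons <- bin_consensus(st$calls, lens, window = config$window,
                            min_calls = config$min_calls)
      st$consensus <- cons
      write_consensus_tsv(cons, p("consensus.tsv"))
    },
    map = function() {
      map <- fit_genetic_map(get_consensus(), max_rf = config$max_rf,
                             min_lod = config$min_lod)
      st$map <- map
      readr::write_tsv(map$loci, p("map.tsv"))
      readr::write_tsv(map$rf, p("rf.tsv"))
    },
    qc = function() {
      bp <- detect_misjoins(get_consensus(), min_switch = config$min_switch,
                            min_informative = config$min_informative)
      st$breakpoints <- bp
      sp <- split_contigs(get_contigs(), bp, window = config$window)
      st$split <- sp
      readr::write_tsv(bp, p("breakpoints.tsv"))
      write_fasta(sp$contigs, p("contigs_split.fa"))
      readr::write_tsv(sp$provenance, p("provenance.tsv"))
    },
    scaffold = function() {
      if (is.null(st$split)) {
        st$split <- list(contigs = read_fasta(p("contigs_split.fa")),
                         provenance = readr::read_tsv(p("provenance.tsv"),
                                                      col_types = "ccii",
                                                      progress = FALSE))
      }
      map <- get_map()
      map$loci <- apply_breakpoints(map$loci, get_breakpoints(), config$window)
      pl <- place_contigs(map, st$split$contigs, window = config$window)
      st$placements <- pl
      pm <- build_pseudomolecules(pl, st$split$contigs, gap = config$gap)
      st$pseudomolecules <- pm
      write_fasta(c(pm$sequences, pm$unplaced), p("pseudomolecules.fa"))
      write_agp(pm$agp, p("assembly.agp"))
      readr::write_tsv(pl, p("placements.tsv"))
    },
    evaluate = function() {
      truth <- get_truth()
      map <- get_map()
      if (is.null(st$split))
        st$split <- list(provenance = readr::read_tsv(p("provenance.tsv"),
                                                      col_types = "ccii",
                                                      progress = FALSE))
      if (is.null(st$placements))
        st$placements <- readr::read_tsv(p("placements.tsv"), show_col_types = FALSE,
                                         progress = FALSE) |>
          mutate(group = as.character(.data$group))
      map$loci <- apply_breakpoints(map$loci, get_breakpoints(), config$window)
      ev <- evaluate_against_truth(truth, consensus = get_consensus(),
                                   map = map, breakpoints = get_breakpoints(),
                                   placements = st$placements,
                                   provenance = st$split$provenance,
                                   window = config$window)
      st$evaluation <- ev
      readr::write_tsv(tidy(ev), p("evaluation.tsv"))
    })

  manifest_path <- p("manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list(files = list())
  cfg_tmp <- tempfile(fileext = ".yaml")
  write_pipeline_config(config, cfg_tmp)
  manifest$config_hash <- unname(tools::md5sum(cfg_tmp))
  unlink(cfg_tmp)
  manifest$seed <- config$seed
  manifest$package_version <- as.character(utils::packageVersion("gbsmapr"))

  for (stage in stages) {
    require_deps(stage)
    message(sprintf("[pipeline] %s", stage))
    run_stage[[stage]]()
    files <- stage_outputs(stage)
    sums <- tools::md5sum(p(files))
    manifest$files[files] <- unname(sums)
    manifest$stages_run <- union(unlist(manifest$stages_run), stage)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(state = as.list(st), manifest = manifest))
}

#' Rebuild a truth set from pipeline output files
#'
#' @param out_dir Directory written by the simulate stage.
#' @return A `truth_set`.
#' @export
load_truth <- function(out_dir) {
  p <- function(f) file.path(out_dir, f)
  parents <- read_fasta(p("parents.fa"))
  a <- parents[grepl("_A$", names(parents))]
  b <- parents[grepl("_B$", names(parents))]
  names(a) <- sub("_A$", "", names(a))
  names(b) <- sub("_B$", "", names(b))
  truth <- structure(list(
    haplotype_a = a, haplotype_b = b,
    snv = readr::read_tsv(p("truth_snv.tsv"), col_types = "cicc", progress = FALSE),
    config = NULL), class = "truth_set")
  if (file.exists(p("truth_gametes.tsv"))) {
    truth$gametes <- readr::read_tsv(p("truth_gametes.tsv"), col_types = "cciiiic",
                                     progress = FALSE)
    truth$samples <- unique(truth$gametes$individual)
  }
  if (file.exists(p("contigs.fa"))) {
    truth$contigs <- read_fasta(p("contigs.fa"))
    truth$contig_layout <- readr::read_tsv(p("truth_layout.tsv"),
                                           col_types = "ciiiciic", progress = FALSE)
    truth$chimera_truth <- readr::read_tsv(p("truth_chimeras.tsv"),
                                           col_types = "ci", progress = FALSE)
  }
  truth
}

# consensus.tsv: wide matrix, rows contig:window, columns individuals
write_consensus_tsv <- function(consensus, path) {
  geno <- consensus_matrix(consensus)
  out <- as_tibble(geno) |> mutate(locus = rownames(geno), .before = 1)
  readr::write_tsv(out, path)
  invisible(path)
}

read_consensus_tsv <- function(path, contigs, window) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  long <- wide |>
    tidyr::pivot_longer(-"locus", names_to = "individual", values_to = "genotype") |>
    mutate(contig = sub(":[0-9]+$", "", .data$locus),
           window_index = as.integer(sub("^.*:", "", .data$locus)),
           start = .data$window_index * as.integer(window),
           end = pmin((.data$window_index + 1L) * as.integer(window),
                      nchar(contigs[.data$contig]))) |>
    select("contig", "window_index", "start", "end", "individual", "genotype") |>
    arrange(.data$contig, .data$window_index, .data$individual)
  long
}
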