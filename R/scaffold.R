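#' Detect chimeric contigs from population-wide haplotype switches
#'
#' A misjoin announces itself when most F2 individuals change consensus
#' genotype at the same window boundary of a contig: across a true
#' cross-chromosome junction the two sides segregate independently, so the
#' expected switch fraction is 1 - (1/16 + 1/4 + 1/16)... = 0.625, while
#' across a genuine 14-kb step it is roughly the per-window recombination
#' fraction (<< 0.1). For each boundary between consecutive informative
#' windows, the switch fraction is computed over individuals called (non-U)
#' in both; boundaries with `switch_fraction >= min_switch` and at least
#' `min_informative` such individuals are reported, runs of adjacent
#' qualifying boundaries merged to the single strongest one.
#'
#' @param consensus Consensus tibble from [bin_consensus()].
#' @param min_switch Minimum fraction of informative individuals switching.
#' @param min_informative Minimum informative individuals at the boundary.
#' @return Tibble `contig`, `boundary_bp` (a window-tiling boundary),
#'   `switch_fraction`, `n_informative`.
#' @export
detect_misjoins <- function(consensus, min_switch = 0.5, min_informative = 20L) {
  out <- list()
  for (ctg in unique(consensus$contig)) {
    cw <- consensus |> filter(.data$contig == ctg)
    geno <- consensus_matrix(cw |> mutate(contig = "x"))
    wi <- as.integer(sub("^x:", "", rownames(geno)))
    o <- order(wi)
    geno <- geno[o, , drop = FALSE]
    wi <- wi[o]
    starts <- (cw |> distinct(.data$window_index, .data$start) |>
                 arrange(.data$window_index))$start
    if (nrow(geno) < 2L) next
    nb <- nrow(geno) - 1L
    frac <- nobs <- numeric(nb)
    for (b in seq_len(nb)) {
      g1 <- geno[b, ]; g2 <- geno[b + 1L, ]
      inf <- g1 != "U" & g2 != "U"
      nobs[b] <- sum(inf)
      frac[b] <- if (nobs[b]) mean(g1[inf] != g2[inf]) else 0
    }
    qual <- frac >= min_switch & nobs >= min_informative
    if (!any(qual)) next
    runs <- rle(qual)
    stops <- cumsum(runs$lengths)
    begins <- stops - runs$lengths + 1L
    for (ri in which(runs$values)) {
      idx <- begins[ri]:stops[ri]
      b <- idx[which.max(frac[idx])]
      out[[length(out) + 1L]] <- tibble(
        contig = ctg, boundary_bp = starts[b + 1L],
        switch_fraction = frac[b], n_informative = as.integer(nobs[b]))
    }
  }
  if (!length(out)) {
    return(tibble(contig = character(), boundary_bp = integer(),
                  switch_fraction = numeric(), n_informative = integer()))
  }
  bind_rows(out) |> arrange(.data$contig, .data$boundary_bp)
}

#' Split contigs at detected misjoin boundaries
#'
#' Each broken contig is replaced by parts named `<contig>.1`, `<contig>.2`,
#' ... split at `boundary_bp`; concatenating the parts reproduces the
#' original sequence exactly. Breakpoints must lie on window-tiling
#' boundaries (the detection resolution).
#'
#' @param contigs Named character vector of contig sequences.
#' @param breakpoints Tibble from [detect_misjoins()].
#' @param window Window width the boundaries must be multiples of.
#' @return List with `contigs` (revised named vector) and `provenance`
#'   (tibble `part`, `contig`, `start`, `end` in original coordinates).
#' @export
split_contigs <- function(contigs, breakpoints, window = 14000L) {
  stopifnot(is.character(contigs), !is.null(names(contigs)))
  prov <- list()
  out <- list()
  bps <- split(breakpoints$boundary_bp, breakpoints$contig)
  for (ctg in names(contigs)) {
    len <- nchar(contigs[[ctg]])
    b <- sort(unique(bps[[ctg]]))
    if (length(b)) {
      if (any(b %% window != 0L))
        abort(sprintf("breakpoint in %s is not on a window boundary", ctg))
      if (any(b <= 0L | b >= len))
        abort(sprintf("breakpoint outside contig %s", ctg))
      bounds <- c(0L, b, len)
      parts <- paste0(ctg, ".", seq_len(length(b) + 1L))
      for (i in seq_along(parts)) {
        out[[parts[i]]] <- substring(contigs[[ctg]], bounds[i] + 1L, bounds[i + 1L])
        prov[[length(prov) + 1L]] <- tibble(part = parts[i], contig = ctg,
                                            start = bounds[i], end = bounds[i + 1L])
      }
    } else {
      out[[ctg]] <- unname(contigs[[ctg]])
      prov[[length(prov) + 1L]] <- tibble(part = ctg, contig = ctg,
                                          start = 0L, end = len)
    }
  }
  list(contigs = unlist(out), provenance = bind_rows(prov))
}

#' Relabel consensus windows (or map loci) after contig splitting
#'
#' Because splits happen on window boundaries, the window tiling of each
#' part is the original tiling re-anchored: windows left of the break keep
#' their indices under `<contig>.1`, windows right of it are shifted to
#' start at 0 under `<contig>.2`, and so on.
#'
#' @param x A tibble with `contig` and `window_index` columns (consensus
#'   rows or map loci).
#' @param breakpoints Tibble from [detect_misjoins()].
#' @param window Window width in bp.
#' @return `x` with `contig`/`window_index` (and `start`/`end`, `locus` if
#'   present) rewritten to part coordinates.
#' @export
apply_breakpoints <- function(x, breakpoints, window = 14000L) {
  if (!nrow(breakpoints)) return(x)
  bps <- split(breakpoints$boundary_bp, breakpoints$contig)
  for (ctg in names(bps)) {
    b <- sort(unique(bps[[ctg]]))
    if (any(b %% window != 0L)) abort("breakpoint not on a window boundary")
    wbounds <- c(0L, as.integer(b %/% window)) # first window index of each part
    rows <- which(x$contig == ctg)
    if (!length(rows)) next
    part_no <- findInterval(x$window_index[rows], wbounds)
    shift <- wbounds[part_no]
    x$window_index[rows] <- x$window_index[rows] - shift
    if ("start" %in% names(x)) x$start[rows] <- x$start[rows] - shift * window
    if ("end" %in% names(x)) x$end[rows] <- x$end[rows] - shift * window
    x$contig[rows] <- paste0(ctg, ".", part_no)
  }
  if ("locus" %in% names(x))
    x$locus <- paste0(x$contig, ":", x$window_index)
  x
}

#' Assign contig parts to linkage groups
#'
#' Each part goes to the group holding the majority of its mapped windows;
#' parts with mapped windows in two or more groups are flagged as conflicts
#' (candidate undetected chimeras), and parts with no mapped windows land in
#' the unplaced bin.
#'
#' @param map A `genetic_map` whose loci are part windows.
#' @param contigs Named character vector of all part sequences.
#' @return Tibble `part`, `group` (`NA` if unplaced), `n_windows`,
#'   `conflict`, `placed`.
#' @export
assign_contigs <- function(map, contigs) {
  per <- map$loci |>
    count(part = .data$contig, .data$group, name = "n") |>
    group_by(.data$part) |>
    summarise(group = .data$group[which.max(.data$n)],
              n_windows = sum(.data$n),
              conflict = n() > 1L, .groups = "drop")
  tibble(part = names(contigs)) |>
    left_join(per, by = "part") |>
    mutate(n_windows = coalesce(.data$n_windows, 0L),
           conflict = coalesce(.data$conflict, FALSE),
           placed = !is.na(.data$group))
}

#' Orient contig parts from the genetic map
#'
#' Orientation is the sign of the Kendall correlation between window
#' midpoints (bp, in part coordinates) and map positions (cM) of the part's
#' windows in its assigned group. Zero correlation, a single mapped window,
#' or fewer than 2 distinct cM positions give `"?"` (emitted as `+` in AGP
#' output, with a flag).
#'
#' @param map A `genetic_map`.
#' @param assignments Tibble from [assign_contigs()].
#' @param window Window width in bp (for midpoints).
#' @return `assignments` with `orientation` in `{+, -, ?}` added.
#' @export
orient_contigs <- function(map, assignments, window = 14000L) {
  ori <- vapply(seq_len(nrow(assignments)), function(i) {
    if (!assignments$placed[i]) return(NA_character_)
    sub <- map$loci |>
      filter(.data$contig == assignments$part[i],
             .data$group == assignments$group[i])
    if (nrow(sub) < 2L || length(unique(sub$position_cm)) < 2L) return("?")
    bp <- (sub$window_index + 0.5) * window
    tau <- suppressWarnings(cor(bp, sub$position_cm, method = "kendall"))
    if (is.na(tau) || tau == 0) "?" else if (tau > 0) "+" else "-"
  }, character(1))
  assignments |> mutate(orientation = ori)
}

#' Order contig parts within their linkage groups
#'
#' Parts are ranked by the median cM position of their mapped windows; ties
#' break lexicographically on the part id, so the layout is deterministic.
#'
#' @param map A `genetic_map`.
#' @param assignments Tibble from [assign_contigs()] (orientation column
#'   optional).
#' @return `assignments` with `position_cm` and `order_index` (within
#'   group) added, sorted by group and order.
#' @export
order_contigs <- function(map, assignments) {
  med <- map$loci |>
    group_by(part = .data$contig, .data$group) |>
    summarise(position_cm = median(.data$position_cm), .groups = "drop")
  assignments |>
    left_join(med, by = c("part", "group")) |>
    arrange(.data$group, .data$position_cm, .data$part) |>
    group_by(.data$group) |>
    mutate(order_index = ifelse(.data$placed, row_number(), NA_integer_)) |>
    ungroup()
}

#' Assign, orient and order contig parts in one call
#'
#' @inheritParams assign_contigs
#' @param window Window width in bp.
#' @return Placement tibble: `part`, `group`, `n_windows`, `conflict`,
#'   `placed`, `orientation`, `position_cm`, `order_index`.
#' @export
place_contigs <- function(map, contigs, window = 14000L) {
  assign_contigs(map, contigs) |>
    orient_contigs(map = map, window = window) |>
    order_contigs(map = map)
}

#' Join placed contigs into pseudomolecules with AGP output
#'
#' Within each linkage group, parts are concatenated in map order (reverse
#' complemented when oriented `-`; `?` is treated as `+` and flagged),
#' separated by gaps of `gap` Ns. The AGP (v2.1) alternates `W` component
#' rows and `U` gap rows (`gap_type` "map", linkage "yes", evidence "map").
#' Unplaced parts are emitted as standalone scaffolds under their own names.
#'
#' @param placements Tibble from [place_contigs()].
#' @param contigs Named character vector of part sequences.
#' @param gap Gap length in Ns between consecutive parts.
#' @param prefix Name prefix for pseudomolecule objects.
#' @return A `pseudomolecule_set`: list with `sequences` (pseudomolecules),
#'   `unplaced` (standalone scaffolds), `agp` (tibble covering both) and
#'   `placements`.
#' @export
build_pseudomolecules <- function(placements, contigs, gap = 100L, prefix = "pm") {
  missing <- setdiff(placements$part, names(contigs))
  if (length(missing))
    abort(sprintf("part sequence missing: %s", missing[1]))
  placed <- placements |> filter(.data$placed) |>
    arrange(.data$group, .data$order_index)
  groups <- unique(placed$group)
  seqs <- setNames(character(length(groups)),
                   sprintf("%s_%02d", prefix, as.integer(groups)))
  agp <- list()
  for (gi in seq_along(groups)) {
    sub <- placed |> filter(.data$group == groups[gi])
    obj <- names(seqs)[gi]
    pieces <- character(nrow(sub))
    pos <- 0L
    pn <- 0L
    for (i in seq_len(nrow(sub))) {
      s <- contigs[[sub$part[i]]]
      ori <- sub$orientation[i]
      if (identical(ori, "-")) s <- revcomp_cpp(s)
      pieces[i] <- s
      len <- nchar(s)
      if (i > 1L) {
        pn <- pn + 1L
        agp[[length(agp) + 1L]] <- tibble(
          object = obj, object_beg = pos + 1L, object_end = pos + gap,
          part_number = pn, component_type = "U",
          component_id = as.character(gap), component_beg = "map",
          component_end = "yes", orientation = "map")
        pos <- pos + gap
      }
      pn <- pn + 1L
      agp[[length(agp) + 1L]] <- tibble(
        object = obj, object_beg = pos + 1L, object_end = pos + len,
        part_number = pn, component_type = "W",
        component_id = sub$part[i], component_beg = "1",
        component_end = as.character(len),
        orientation = if (identical(ori, "-")) "-" else "+")
      pos <- pos + len
    }
    seqs[gi] <- paste(pieces, collapse = strrep("N", gap))
  }
  unplaced_parts <- placements$part[!placements$placed]
  unplaced <- setNames(unname(contigs[unplaced_parts]), unplaced_parts)
  for (p in unplaced_parts) {
    agp[[length(agp) + 1L]] <- tibble(
      object = p, object_beg = 1L, object_end = nchar(contigs[[p]]),
      part_number = 1L, component_type = "W", component_id = p,
      component_beg = "1", component_end = as.character(nchar(contigs[[p]])),
      orientation = "+")
  }
  structure(list(sequences = seqs, unplaced = unplaced,
                 agp = bind_rows(agp), placements = placements),
            class = "pseudomolecule_set")
}

#' Write, read and validate AGP v2.1
#'
#' The 9-column AGP layout: for `W` rows columns 6-9 are component id,
#' begin, end, orientation; for `U` gap rows they are gap length, gap type,
#' linkage, evidence.
#'
#' @param agp AGP tibble (e.g. from [build_pseudomolecules()]).
#' @param path File path.
#' @return `write_agp()` the path, invisibly; `read_agp()` an AGP tibble.
#' @export
write_agp <- function(agp, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  readr::write_tsv(agp, con, col_names = FALSE)
  invisible(path)
}

#' @rdname write_agp
#' @export
read_agp <- function(path) {
  readr::read_tsv(path, comment = "#", col_names = c(
    "object", "object_beg", "object_end", "part_number", "component_type",
    "component_id", "component_beg", "component_end", "orientation"),
    col_types = "ciiiccccc", progress = FALSE)
}

#' @rdname write_agp
#' @param contigs Optional named vector of component sequences for
#'   coordinate checks.
#' @return `validate_agp()` returns `TRUE` invisibly or aborts with the
#'   first violation found.
#' @export
validate_agp <- function(agp, contigs = NULL) {
  for (obj in unique(agp$object)) {
    sub <- agp |> filter(.data$object == obj) |> arrange(.data$part_number)
    if (!identical(sub$part_number, seq_len(nrow(sub))))
      abort(sprintf("%s: part_number not consecutive from 1", obj))
    if (sub$object_beg[1] != 1L) abort(sprintf("%s: does not start at 1", obj))
    if (any(sub$object_end < sub$object_beg))
      abort(sprintf("%s: empty or inverted span", obj))
    if (nrow(sub) > 1L &&
        any(sub$object_beg[-1] != sub$object_end[-nrow(sub)] + 1L))
      abort(sprintf("%s: components do not tile the object", obj))
    w <- sub |> filter(.data$component_type == "W")
    if (any(as.integer(w$component_beg) != 1L))
      abort(sprintf("%s: component_beg must be 1", obj))
    if (any(as.integer(w$component_end) - as.integer(w$component_beg) + 1L !=
            w$object_end - w$object_beg + 1L))
      abort(sprintf("%s: component span does not match object span", obj))
    if (!is.null(contigs)) {
      if (!all(w$component_id %in% names(contigs)))
        abort(sprintf("%s: unknown component", obj))
      if (any(as.integer(w$component_end) > nchar(contigs[w$component_id])))
        abort(sprintf("%s: component coordinates exceed sequence length", obj))
    }
    u <- sub |> filter(.data$component_type == "U")
    if (any(u$object_end - u$object_beg + 1L != as.integer(u$component_id)))
      abort(sprintf("%s: gap length mismatch", obj))
  }
  invisible(TRUE)
}

#' Rebuild object sequences from an AGP and component sequences
#'
#' @param agp AGP tibble.
#' @param contigs Named character vector of component sequences.
#' @return Named character vector of object sequences.
#' @export
agp_to_fasta <- function(agp, contigs) {
  objs <- unique(agp$object)
  out <- setNames(character(length(objs)), objs)
  for (obj in objs) {
    sub <- agp |> filter(.data$object == obj) |> arrange(.data$part_number)
    pieces <- vapply(seq_len(nrow(sub)), function(i) {
      if (sub$component_type[i] == "U") return(strrep("N", as.integer(sub$component_id[i])))
      s <- substring(contigs[[sub$component_id[i]]],
                     as.integer(sub$component_beg[i]),
                     as.integer(sub$component_end[i]))
      if (sub$orientation[i] == "-") revcomp_cpp(s) else s
    }, character(1))
    out[obj] <- paste(pieces, collapse = "")
  }
  out
}

#' @export
print.pseudomolecule_set <- function(x, ...) {
  cat(sprintf("<pseudomolecule_set> %d pseudomolecules (%s bp), %d unplaced scaffolds (%s bp)\n",
              length(x$sequences), format(sum(nchar(x$sequences)), big.mark = ","),
              length(x$unplaced),
              format(sum(nchar(x$unplaced)), big.mark = ",")))
  invisible(x)
}
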