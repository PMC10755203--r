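# Map a window midpoint in contig coordinates back to the source genome.
# Returns NA chromosome for windows spanning a layout junction (chimeras).
window_truth_coords <- function(layout, windows) {
  res <- windows |> mutate(chromosome = NA_character_, genome_mid = NA_real_)
  lay <- split(layout, layout$contig)
  for (i in seq_len(nrow(res))) {
    L <- lay[[res$contig[i]]]
    if (is.null(L)) next
    ws <- res$start[i]; we <- res$end[i]
    hit <- which(L$contig_start <= ws & L$contig_end >= we)
    if (length(hit) != 1L) next # spans a junction (or off the end)
    mid <- (ws + we) / 2
    if (L$strand[hit] == "+") {
      g <- L$start[hit] + (mid - L$contig_start[hit])
    } else {
      g <- L$end[hit] - (mid - L$contig_start[hit])
    }
    res$chromosome[i] <- L$chromosome[hit]
    res$genome_mid[i] <- g
  }
  res
}

# Truth genotype of each individual at given (chromosome, position) points.
# Returns codes in {A, H, B}. `clean_span`: if start/end supplied, only
# positions whose whole window lies in single gamete segments (no crossover
# inside the window, either gamete) are scored; others get NA.
truth_genotype_at <- function(truth, pts) {
  gam <- truth$gametes
  out <- matrix(NA_character_, nrow(pts), length(truth$samples),
                dimnames = list(NULL, truth$samples))
  clean <- matrix(TRUE, nrow(pts), length(truth$samples),
                  dimnames = list(NULL, truth$samples))
  by_chr <- split(seq_len(nrow(pts)), pts$chromosome)
  for (chrom in names(by_chr)) {
    idx <- by_chr[[chrom]]
    for (s in truth$samples) {
      codes <- character(2)
      for (g in 1:2) {
        segs <- gam |> filter(.data$individual == s, .data$chromosome == chrom,
                              .data$gamete == g)
        seg_at <- findInterval(pts$genome_mid[idx], segs$start)
        codes_g <- segs$founder[seg_at]
        if (g == 1L) f1 <- codes_g else f2 <- codes_g
        if (all(c("win_start", "win_end") %in% names(pts))) {
          a <- segs$founder[findInterval(pts$win_start[idx], segs$start)]
          b <- segs$founder[findInterval(pmax(pts$win_end[idx] - 1, 0), segs$start)]
          sa <- findInterval(pts$win_start[idx], segs$start)
          sb <- findInterval(pmax(pts$win_end[idx] - 1, 0), segs$start)
          clean[idx, s] <- clean[idx, s] & (sa == sb) & (a == b)
        }
      }
      out[idx, s] <- ifelse(f1 == f2, ifelse(f1 == "A", "A", "B"), "H")
    }
  }
  list(genotype = out, clean = clean)
}

#' Score pipeline outputs against simulator ground truth
#'
#' Any subset of pipeline outputs can be scored:
#' \itemize{
#'   \item `consensus`: genotype accuracy, the fraction of non-missing
#'     consensus calls equal to the truth. Only windows that map cleanly to
#'     the source genome (no chimera junction inside) and contain no
#'     crossover for the scored individual are compared, since only there is
#'     a single true genotype defined.
#'   \item `map`: per linkage group, |Kendall tau| between inferred locus
#'     order and true genome position (absolute value: a map is defined up
#'     to reversal).
#'   \item `breakpoints`: recall and precision of detected misjoins against
#'     planted chimera junctions, with a +/- one-window tolerance.
#'   \item `placements`: contig orientation accuracy over oriented parts
#'     with known truth, per group up to map reversal.
#' }
#'
#' @param truth A `truth_set` with contigs (see [fragment_reference()]).
#' @param consensus Optional tibble from [bin_consensus()].
#' @param map Optional `genetic_map`.
#' @param breakpoints Optional tibble from [detect_misjoins()].
#' @param placements Optional tibble from [place_contigs()].
#' @param provenance Optional part provenance from [split_contigs()] (needed
#'   to score placements of split parts).
#' @param window Window width in bp.
#' @return A `truth_eval` object; see [glance.truth_eval()].
#' @export
evaluate_against_truth <- function(truth, consensus = NULL, map = NULL,
                                   breakpoints = NULL, placements = NULL,
                                   provenance = NULL, window = 14000L) {
  stopifnot(inherits(truth, "truth_set"))
  if (is.null(truth$contig_layout))
    abort("truth has no contig layout; run fragment_reference() first")
  layout <- truth$contig_layout
  res <- list()

  if (!is.null(consensus) && nrow(consensus)) {
    bad <- setdiff(unique(consensus$contig), layout$contig)
    if (length(bad)) abort(sprintf("unknown contig in consensus: %s", bad[1]))
    wins <- consensus |> distinct(.data$contig, .data$window_index,
                                  .data$start, .data$end)
    coords <- window_truth_coords(layout, wins) |>
      rename(win_start_c = "start", win_end_c = "end")
    ok <- !is.na(coords$chromosome)
    pts <- coords[ok, ] |>
      mutate(win_start = .data$genome_mid - (.data$win_end_c - .data$win_start_c) / 2,
             win_end = .data$genome_mid + (.data$win_end_c - .data$win_start_c) / 2)
    # on '-' strand parts mid maps linearly; window span length is the same
    tg <- truth_genotype_at(truth, pts)
    calls <- consensus |>
      inner_join(pts |> select("contig", "window_index") |>
                   mutate(row = row_number()),
                 by = c("contig", "window_index")) |>
      filter(.data$genotype != "U")
    col <- match(calls$individual, truth$samples)
    keep <- tg$clean[cbind(calls$row, col)]
    match_ok <- calls$genotype[keep] == tg$genotype[cbind(calls$row, col)][keep]
    res$genotype_accuracy <- mean(match_ok)
    res$n_calls_scored <- sum(keep)
  }

  if (!is.null(map)) {
    wins <- map$loci |>
      mutate(start = .data$window_index * window,
             end = (.data$window_index + 1L) * window) |>
      select("contig", "window_index", "start", "end", "group", "order_index")
    if (!is.null(provenance)) {
      wins <- wins |>
        inner_join(provenance, by = c(contig = "part"),
                   suffix = c("", "_orig")) |>
        mutate(start = .data$start + .data$start_orig,
               end = .data$end + .data$start_orig,
               contig = .data$contig_orig) |>
        select("contig", "window_index", "start", "end", "group", "order_index")
    }
    ctg_max <- layout |> group_by(.data$contig) |>
      summarise(len = sum(.data$end - .data$start), .groups = "drop")
    wins <- wins |>
      left_join(ctg_max, by = "contig") |>
      mutate(end = pmin(.data$end, coalesce(.data$len, .data$end))) |>
      select(-"len")
    coords <- window_truth_coords(layout, wins)
    tau_tbl <- coords |>
      filter(!is.na(.data$chromosome)) |>
      group_by(.data$group) |>
      summarise(
        n_loci = n(),
        tau = {
          chr <- .data$chromosome
          sel <- chr == names(which.max(table(chr)))
          if (sum(sel) < 2L) NA_real_ else
            abs(suppressWarnings(cor(.data$order_index[sel],
                                     .data$genome_mid[sel],
                                     method = "kendall")))
        },
        chromosome = names(which.max(table(.data$chromosome))),
        .groups = "drop") |>
      select("group", "chromosome", "n_loci", "tau")
    res$map_concordance <- tau_tbl
    res$mean_abs_tau <- mean(tau_tbl$tau, na.rm = TRUE)
  }

  if (!is.null(breakpoints)) {
    tr <- truth$chimera_truth
    if (nrow(tr)) {
      d <- tr |>
        left_join(breakpoints, by = "contig") |>
        mutate(hit = !is.na(.data$boundary_bp) &
                 abs(.data$boundary_bp - .data$junction_offset) <= window) |>
        group_by(.data$contig, .data$junction_offset) |>
        summarise(recovered = any(.data$hit), .groups = "drop")
      res$breakpoint_recall <- mean(d$recovered)
    } else {
      res$breakpoint_recall <- NA_real_
    }
    if (nrow(breakpoints)) {
      m <- breakpoints |>
        left_join(tr, by = "contig",
                  relationship = "many-to-many") |>
        group_by(.data$contig, .data$boundary_bp) |>
        summarise(true_pos = any(!is.na(.data$junction_offset) &
                                   abs(.data$boundary_bp - .data$junction_offset) <= window),
                  .groups = "drop")
      res$breakpoint_precision <- mean(m$true_pos)
      res$n_breakpoints <- nrow(m)
    } else {
      res$breakpoint_precision <- NA_real_
      res$n_breakpoints <- 0L
    }
  }

  if (!is.null(placements)) {
    prov <- provenance %||% tibble(part = names(truth$contigs),
                                   contig = names(truth$contigs),
                                   start = 0L,
                                   end = nchar(truth$contigs))
    bad <- setdiff(placements$part, prov$part)
    if (length(bad)) abort(sprintf("unknown part in placements: %s", bad[1]))
    pl <- placements |>
      filter(.data$placed, .data$orientation %in% c("+", "-")) |>
      inner_join(prov, by = "part")
    # truth strand: the layout row covering most of the part
    pl$truth_strand <- vapply(seq_len(nrow(pl)), function(i) {
      L <- layout |> filter(.data$contig == pl$contig[i],
                            .data$contig_start < pl$end[i],
                            .data$contig_end > pl$start[i])
      if (!nrow(L)) return(NA_character_)
      L$strand[which.max(pmin(L$contig_end, pl$end[i]) -
                           pmax(L$contig_start, pl$start[i]))]
    }, character(1))
    ori_tbl <- pl |>
      filter(!is.na(.data$truth_strand)) |>
      group_by(.data$group) |>
      summarise(n_oriented = n(),
                agree = mean(.data$orientation == .data$truth_strand),
                .groups = "drop") |>
      mutate(accuracy = pmax(.data$agree, 1 - .data$agree)) # map reversal freedom
    res$orientation_by_group <- ori_tbl |> select(-"agree")
    res$orientation_accuracy <-
      sum(ori_tbl$accuracy * ori_tbl$n_oriented) / sum(ori_tbl$n_oriented)
  }

  structure(res, class = "truth_eval")
}

#' @export
print.truth_eval <- function(x, ...) {
  cat("<truth_eval>\n")
  if (!is.null(x$genotype_accuracy))
    cat(sprintf("  genotype accuracy: %.4f (%s calls)\n", x$genotype_accuracy,
                format(x$n_calls_scored, big.mark = ",")))
  if (!is.null(x$mean_abs_tau))
    cat(sprintf("  map order |tau|: %.3f (mean over %d groups)\n",
                x$mean_abs_tau, nrow(x$map_concordance)))
  if (!is.null(x$breakpoint_recall))
    cat(sprintf("  breakpoints: recall %.2f, precision %.2f (%d detected)\n",
                x$breakpoint_recall, x$breakpoint_precision, x$n_breakpoints))
  if (!is.null(x$orientation_accuracy))
    cat(sprintf("  orientation accuracy: %.3f\n", x$orientation_accuracy))
  invisible(x)
}

#' Tidy and glance methods for truth evaluations
#'
#' `tidy()` returns one row per metric; `glance()` a one-row summary.
#'
#' @param x A `truth_eval`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.truth_eval <- function(x, ...) {
  scalars <- x[vapply(x, function(v) is.numeric(v) && length(v) == 1L, logical(1))]
  tibble(metric = names(scalars), value = as.numeric(unlist(scalars)))
}

#' @rdname tidy.truth_eval
#' @export
glance.truth_eval <- function(x, ...) {
  tidy(x) |> tidyr::pivot_wider(names_from = "metric", values_from = "value")
}
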