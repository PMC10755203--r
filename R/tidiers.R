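#' Tidy and glance methods for genetic maps
#'
#' `tidy()` returns the locus table (one row per mapped locus with its
#' group, order and cM position); `glance()` one row per map with group
#' counts and total length.
#'
#' @param x A `genetic_map`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.genetic_map <- function(x, ...) {
  as_tibble(x$loci)
}

#' @rdname tidy.genetic_map
#' @export
glance.genetic_map <- function(x, ...) {
  per <- x$loci |> group_by(.data$group) |>
    summarise(cm = max(.data$position_cm), .groups = "drop")
  tibble(n_groups = nrow(per), n_loci = nrow(x$loci),
         total_cm = sum(per$cm),
         n_singletons = length(x$singletons %||% character()))
}

#' Tidy and glance methods for pseudomolecule sets
#'
#' `tidy()` returns the AGP table; `glance()` a one-row summary of object
#' counts and total lengths.
#'
#' @param x A `pseudomolecule_set`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pseudomolecule_set <- function(x, ...) {
  as_tibble(x$agp)
}

#' @rdname tidy.pseudomolecule_set
#' @export
glance.pseudomolecule_set <- function(x, ...) {
  tibble(n_pseudomolecules = length(x$sequences),
         pseudomolecule_bp = sum(nchar(x$sequences)),
         n_unplaced = length(x$unplaced),
         unplaced_bp = sum(nchar(x$unplaced)))
}

#' Plot a genetic map
#'
#' One horizontal track per linkage group with a tick at every mapped locus.
#'
#' @param object A `genetic_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.genetic_map <- function(object, ...) {
  df <- object$loci
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position_cm,
                                   y = factor(.data$group))) +
    ggplot2::geom_line(ggplot2::aes(group = .data$group), linewidth = 2,
                       colour = "grey80") +
    ggplot2::geom_point(shape = 124, size = 4) +
    ggplot2::labs(x = "position (cM, Kosambi)", y = "linkage group") +
    ggplot2::theme_minimal()
}

#' Plot per-individual haplotype tracks along a contig
#'
#' Consensus genotypes as a windows-by-individuals tile plot; a chimeric
#' contig shows as a vertical stripe where most individuals change colour.
#'
#' @param consensus Tibble from [bin_consensus()].
#' @param contig Contig to display (default: the first).
#' @return A ggplot.
#' @export
plot_haplotypes <- function(consensus, contig = NULL) {
  contig <- contig %||% consensus$contig[1]
  ctg <- contig
  df <- consensus |> filter(.data$contig == ctg)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window_index, y = .data$individual,
                                   fill = .data$genotype)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(A = "#d95f02", H = "#7570b3",
                                          B = "#1b9e77", U = "grey90")) +
    ggplot2::labs(x = sprintf("window along %s", ctg), y = NULL,
                  fill = "genotype") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
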