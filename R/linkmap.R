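#' Kosambi map function and its inverse
#'
#' `kosambi_cm()` converts a recombination fraction r in `[0, 0.5)` to a map
#' distance d = 25 ln((1 + 2r) / (1 - 2r)) centimorgans; `kosambi_r()` is
#' the exact inverse, r = tanh(d / 50) / 2.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @param d Map distance(s) in cM, `>= 0`.
#' @return Numeric vector.
#' @export
#' @examples
#' kosambi_cm(0.25) # 25 * log(3)
#' kosambi_r(kosambi_cm(0.1))
kosambi_cm <- function(r) {
  if (any(r < 0 | r >= 0.5)) abort("r must be in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cm
#' @export
kosambi_r <- function(d) {
  if (any(d < 0)) abort("d must be >= 0")
  tanh(d / 50) / 2
}

geno_code <- function(x) {
  out <- match(x, c("A", "H", "B", "U")) - 1L
  if (anyNA(out)) abort("genotype codes must be in {A, H, B, U}")
  out
}

# F2 two-locus class log-likelihood, vectorised over pairs.
# n9: 9 x P matrix of joint genotype counts, classes ordered (g1, g2) with
# g in {A,H,B}; r: vector of length P (or 1). The double-heterozygote class
# pools the two phase configurations.
f2_loglik <- function(n9, r) {
  mn <- 1e-300
  lpar <- log(pmax((1 - r)^2 / 4, mn))
  lmix <- log(pmax(r * (1 - r) / 2, mn))
  lrec <- log(pmax(r^2 / 4, mn))
  lhh <- log(pmax(((1 - r)^2 + r^2) / 2, mn))
  (n9[1, ] + n9[9, ]) * lpar +
    (n9[2, ] + n9[4, ] + n9[6, ] + n9[8, ]) * lmix +
    (n9[3, ] + n9[7, ]) * lrec +
    n9[5, ] * lhh
}

# Maximum-likelihood r per pair: dense grid (step 0.001) then vectorised
# golden-section refinement. Deterministic; no EM.
rf_from_counts <- function(n9, grid_step = 0.001, r_max = 0.5) {
  P <- ncol(n9)
  grid <- seq(0, r_max, by = grid_step)
  logp <- vapply(grid, function(r) {
    mn <- 1e-300
    c(log(pmax((1 - r)^2 / 4, mn)), log(pmax(r * (1 - r) / 2, mn)),
      log(pmax(r^2 / 4, mn)), log(pmax(((1 - r)^2 + r^2) / 2, mn)))
  }, numeric(4))
  # collapse the 9 classes to the 4 distinct probabilities first
  n4 <- rbind(n9[1, ] + n9[9, ], n9[2, ] + n9[4, ] + n9[6, ] + n9[8, ],
              n9[3, ] + n9[7, ], n9[5, ])
  ll_grid <- crossprod(n4, logp) # P x G
  best <- max.col(ll_grid, ties.method = "first")
  r0 <- grid[best]
  ll0 <- ll_grid[cbind(seq_len(P), best)]
  # golden-section around the best grid point
  lo <- pmax(r0 - grid_step, 0)
  hi <- pmin(r0 + grid_step, r_max)
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- f2_loglik(n9, x1); f2 <- f2_loglik(n9, x2)
  for (it in 1:35) {
    take2 <- f2 > f1
    lo <- ifelse(take2, x1, lo)
    hi <- ifelse(take2, hi, x2)
    x1n <- ifelse(take2, x2, hi - gr * (hi - lo))
    x2n <- ifelse(take2, lo + gr * (hi - lo), x1)
    f1n <- ifelse(take2, f2, NA_real_)
    f2n <- ifelse(take2, NA_real_, f1)
    miss1 <- is.na(f1n); miss2 <- is.na(f2n)
    if (any(miss1)) f1n[miss1] <- f2_loglik(n9[, miss1, drop = FALSE], x1n[miss1])
    if (any(miss2)) f2n[miss2] <- f2_loglik(n9[, miss2, drop = FALSE], x2n[miss2])
    x1 <- x1n; x2 <- x2n; f1 <- f1n; f2 <- f2n
  }
  r_ref <- (x1 + x2) / 2
  ll_ref <- f2_loglik(n9, r_ref)
  r_hat <- ifelse(ll_ref > ll0, r_ref, r0)
  ll_hat <- pmax(ll_ref, ll0)
  ll_null <- f2_loglik(n9, rep(0.5, P))
  lod <- pmax((ll_hat - ll_null) / log(10), 0)
  # identifiability guard: a locus observed in fewer than 2 genotype classes
  # carries no linkage information (its margin cannot distinguish r from 0.5,
  # yet degenerate tables would otherwise score r = 0 with runaway LOD)
  m1 <- rbind(n9[1, ] + n9[2, ] + n9[3, ], n9[4, ] + n9[5, ] + n9[6, ],
              n9[7, ] + n9[8, ] + n9[9, ])
  m2 <- rbind(n9[1, ] + n9[4, ] + n9[7, ], n9[2, ] + n9[5, ] + n9[8, ],
              n9[3, ] + n9[6, ] + n9[9, ])
  degenerate <- colSums(m1 > 0) < 2L | colSums(m2 > 0) < 2L
  r_hat <- ifelse(degenerate, 0.5, pmin(r_hat, 0.5))
  lod <- ifelse(degenerate, 0, lod)
  list(r = r_hat, lod = lod, degenerate = degenerate)
}

#' Flag segregation distortion at consensus loci
#'
#' Per-locus chi-square test of the observed A/H/B consensus counts against
#' the 1:2:1 F2 expectation. This is a report-only diagnostic: strongly
#' distorted loci (tiny p-values, often with a whole genotype class missing)
#' usually indicate allele-specific restriction-site dropout rather than
#' biology, and are worth inspecting before trusting a map region.
#'
#' @param geno Genotype matrix from [consensus_matrix()].
#' @return Tibble `locus`, `n_a`, `n_h`, `n_b`, `chisq`, `p_value`,
#'   `missing_class`.
#' @export
segregation_chisq <- function(geno) {
  stopifnot(is.matrix(geno))
  counts <- t(apply(geno, 1L, function(x) {
    c(sum(x == "A"), sum(x == "H"), sum(x == "B"))
  }))
  n <- rowSums(counts)
  expd <- cbind(n / 4, n / 2, n / 4)
  chisq <- rowSums((counts - expd)^2 / pmax(expd, 1e-12))
  tibble(locus = rownames(geno), n_a = counts[, 1], n_h = counts[, 2],
         n_b = counts[, 3], chisq = chisq,
         p_value = stats::pchisq(chisq, df = 2, lower.tail = FALSE),
         missing_class = rowSums(counts == 0) > 0)
}

#' Estimate the recombination fraction between two loci
#'
#' Maximum-likelihood estimate of r for an F2 intercross with codominant
#' markers, maximising the multinomial likelihood of the 3x3 joint genotype
#' table (the double-heterozygote class pools both phase configurations).
#' Individuals uncalled (`U`) at either locus are dropped. The LOD score is
#' log10 L(r-hat) / L(0.5).
#'
#' @param x,y Genotype vectors over `{A, H, B, U}`, same length.
#' @param min_informative Pairs with fewer informative individuals are
#'   flagged unreliable.
#' @return One-row tibble: `r`, `lod`, `n_informative`, `reliable`.
#' @export
estimate_rf <- function(x, y, min_informative = 10L) {
  stopifnot(length(x) == length(y))
  cx <- geno_code(x); cy <- geno_code(y)
  keep <- cx < 3L & cy < 3L
  n9 <- matrix(tabulate(cx[keep] * 3L + cy[keep] + 1L, 9L), ncol = 1)
  fit <- rf_from_counts(n9)
  tibble(r = fit$r, lod = fit$lod, n_informative = sum(keep),
         reliable = sum(keep) >= min_informative)
}

#' All pairwise recombination fractions of a genotype matrix
#'
#' @param geno Character matrix from [consensus_matrix()] (loci x
#'   individuals over `{A,H,B,U}`).
#' @param min_informative Minimum informative individuals for a reliable
#'   estimate.
#' @return Tibble `locus_i`, `locus_j` (rowname pairs, i < j in matrix
#'   order), `r`, `lod`, `n_informative`, `reliable`.
#' @export
estimate_rf_matrix <- function(geno, min_informative = 10L) {
  stopifnot(is.matrix(geno), !is.null(rownames(geno)))
  codes <- matrix(geno_code(geno), nrow(geno), ncol(geno))
  n <- nrow(geno)
  if (n < 2L) {
    return(tibble(locus_i = character(), locus_j = character(), r = numeric(),
                  lod = numeric(), n_informative = integer(), reliable = logical()))
  }
  np <- n * (n - 1L) / 2L
  ii <- integer(np); jj <- integer(np)
  n9 <- matrix(0, 9L, np)
  ninf <- integer(np)
  p <- 0L
  for (i in seq_len(n - 1L)) {
    xi <- codes[i, ]
    for (j in (i + 1L):n) {
      p <- p + 1L
      ii[p] <- i; jj[p] <- j
      yj <- codes[j, ]
      keep <- xi < 3L & yj < 3L
      ninf[p] <- sum(keep)
      n9[, p] <- tabulate(xi[keep] * 3L + yj[keep] + 1L, 9L)
    }
  }
  fit <- rf_from_counts(n9)
  tibble(locus_i = rownames(geno)[ii], locus_j = rownames(geno)[jj],
         r = fit$r, lod = fit$lod, n_informative = ninf,
         reliable = ninf >= min_informative)
}

#' Partition loci into linkage groups
#'
#' Single-linkage: connected components of the graph with an edge wherever
#' `r <= max_rf` and `lod >= min_lod`. Defaults separate chromosomes cleanly
#' for populations of ~100+ individuals.
#'
#' @param rf Pairwise tibble from [estimate_rf_matrix()].
#' @param loci Character vector of all locus ids (so edgeless loci appear as
#'   singleton groups); defaults to the loci present in `rf`.
#' @param max_rf Maximum recombination fraction for an edge.
#' @param min_lod Minimum LOD for an edge.
#' @return Tibble `locus`, `group`, `group_size`, `singleton`. Groups are
#'   numbered by decreasing size (ties: first locus id).
#' @export
group_loci <- function(rf, loci = NULL, max_rf = 0.35, min_lod = 6) {
  loci <- loci %||% sort(unique(c(rf$locus_i, rf$locus_j)))
  edges <- rf |> filter(.data$r <= max_rf, .data$lod >= min_lod)
  g <- igraph::graph_from_data_frame(
    edges |> select("locus_i", "locus_j"), directed = FALSE,
    vertices = tibble(name = loci))
  comp <- igraph::components(g)
  member <- comp$membership[loci]
  sizes <- comp$csize[member]
  first_locus <- tapply(loci, member, function(x) sort(x)[1])
  first_locus <- first_locus[as.character(seq_along(comp$csize))]
  rank <- order(-comp$csize, first_locus)
  renum <- match(seq_along(comp$csize), rank)
  tibble(locus = loci, group = renum[member],
         group_size = as.integer(sizes), singleton = sizes == 1L) |>
    arrange(.data$group, .data$locus)
}

# objective: sum of adjacent recombination fractions (expected crossover
# count per meiosis along the order)
order_objective <- function(ord, rmat) {
  sum(rmat[cbind(ord[-length(ord)], ord[-1])])
}

#' Order the loci of one linkage group
#'
#' Builds the minimum spanning tree of the complete r-weighted graph, takes
#' its longest (weighted diameter) path as the backbone, inserts the
#' remaining loci at the position minimising the adjacent-r sum, and
#' polishes with a windowed ripple (all permutations of a sliding window,
#' default width 5) that monotonically decreases the objective. The
#' orientation of the final order is arbitrary: a map is defined up to
#' reversal.
#'
#' @param loci Character vector of locus ids in the group.
#' @param rf Pairwise tibble from [estimate_rf_matrix()] (superset ok).
#' @param ripple_window Width of the ripple window (2..6).
#' @return Character vector: the loci in map order.
#' @export
order_loci <- function(loci, rf, ripple_window = 5L) {
  n <- length(loci)
  if (n <= 2L) return(loci)
  ripple_window <- max(2L, min(as.integer(ripple_window), 6L, n))
  rmat <- rf_submatrix(rf, loci)
  g <- igraph::graph_from_adjacency_matrix(rmat, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  tree <- igraph::mst(g, weights = igraph::E(g)$weight)
  backbone <- as.integer(igraph::get_diameter(tree))
  ord <- backbone
  for (v in sort(setdiff(seq_len(n), backbone))) {
    costs <- vapply(seq_len(length(ord) + 1L), function(slot) {
      order_objective(append(ord, v, after = slot - 1L), rmat)
    }, numeric(1))
    ord <- append(ord, v, after = which.min(costs) - 1L)
  }
  # windowed ripple: strict-improvement 2-opt over window permutations
  obj <- order_objective(ord, rmat)
  pm <- permutations(ripple_window)
  repeat {
    improved <- FALSE
    for (s in seq_len(n - ripple_window + 1L)) {
      win <- s:(s + ripple_window - 1L)
      base <- ord
      for (pi in seq_len(nrow(pm))) {
        cand <- base
        cand[win] <- base[win][pm[pi, ]]
        o <- order_objective(cand, rmat)
        if (o < obj - 1e-12) {
          ord <- cand
          obj <- o
          improved <- TRUE
          base <- cand
        }
      }
    }
    if (!improved) break
  }
  loci[ord]
}

rf_submatrix <- function(rf, loci) {
  n <- length(loci)
  rmat <- matrix(0.5, n, n, dimnames = list(loci, loci))
  sub <- rf |> filter(.data$locus_i %in% loci, .data$locus_j %in% loci)
  i <- match(sub$locus_i, loci); j <- match(sub$locus_j, loci)
  rmat[cbind(i, j)] <- sub$r
  rmat[cbind(j, i)] <- sub$r
  diag(rmat) <- 0
  rmat
}

#' Assemble a genetic map from ordered groups
#'
#' Cumulative cM positions are prefix sums of the Kosambi distance over
#' adjacent recombination fractions; the first locus of each group sits at
#' 0 cM. Adjacent fractions of 0.5 or more are clamped to 0.499 with a
#' warning.
#'
#' @param ordered_groups Named list of character vectors: loci of each group
#'   in map order (names become group labels; unnamed lists are numbered).
#' @param rf Pairwise tibble from [estimate_rf_matrix()].
#' @return A `genetic_map` object: list with `loci` (tibble `group`,
#'   `order_index`, `locus`, `contig`, `window_index`, `adj_r`,
#'   `position_cm`) and `rf`.
#' @export
build_genetic_map <- function(ordered_groups, rf) {
  if (length(ordered_groups) == 0L) {
    loci_tbl <- tibble(group = character(), order_index = integer(),
                       locus = character(), contig = character(),
                       window_index = integer(), adj_r = numeric(),
                       position_cm = numeric())
    return(structure(list(loci = loci_tbl, rf = rf), class = "genetic_map"))
  }
  if (is.null(names(ordered_groups)))
    names(ordered_groups) <- as.character(seq_along(ordered_groups))
  out <- vector("list", length(ordered_groups))
  for (gi in seq_along(ordered_groups)) {
    loci <- ordered_groups[[gi]]
    if (length(loci) > 1L) {
      rmat <- rf_submatrix(rf, loci)
      adj <- rmat[cbind(seq_len(length(loci) - 1L), 2:length(loci))]
      if (any(adj >= 0.5)) {
        warning("adjacent recombination fraction >= 0.5 clamped to 0.499")
        adj <- pmin(adj, 0.499)
      }
      pos <- cumsum(c(0, kosambi_cm(adj)))
      adj_r <- c(NA, adj)
    } else {
      pos <- 0
      adj_r <- NA_real_
    }
    out[[gi]] <- tibble(group = names(ordered_groups)[gi],
                        order_index = seq_along(loci), locus = loci,
                        adj_r = adj_r, position_cm = pos)
  }
  # "contig:window" locus ids split back into coordinates; other id styles
  # keep an NA window_index
  loci_tbl <- bind_rows(out) |>
    mutate(contig = sub(":[0-9]+$", "", .data$locus),
           window_index = as.integer(
             ifelse(grepl(":[0-9]+$", .data$locus),
                    sub("^.*:", "", .data$locus), NA_character_))) |>
    select("group", "order_index", "locus", "contig", "window_index",
           "adj_r", "position_cm")
  structure(list(loci = loci_tbl, rf = rf), class = "genetic_map")
}

#' Build linkage groups and an ordered genetic map from consensus genotypes
#'
#' Convenience wrapper chaining [estimate_rf_matrix()], [group_loci()],
#' [order_loci()] and [build_genetic_map()]. Singleton groups are excluded
#' from the map and reported separately.
#'
#' @param consensus Consensus tibble from [bin_consensus()] (or a genotype
#'   matrix from [consensus_matrix()]).
#' @param max_rf,min_lod Grouping thresholds, see [group_loci()].
#' @param min_informative See [estimate_rf_matrix()].
#' @param ripple_window See [order_loci()].
#' @return A `genetic_map` with additional elements `groups` (group
#'   membership tibble) and `singletons` (character vector).
#' @export
fit_genetic_map <- function(consensus, max_rf = 0.35, min_lod = 6,
                            min_informative = 10L, ripple_window = 5L) {
  geno <- if (is.matrix(consensus)) consensus else consensus_matrix(consensus)
  rf <- estimate_rf_matrix(geno, min_informative = min_informative)
  grp <- group_loci(rf, loci = rownames(geno), max_rf = max_rf, min_lod = min_lod)
  real <- grp |> filter(!.data$singleton)
  groups <- split(real$locus, real$group)
  ordered <- lapply(groups, order_loci, rf = rf, ripple_window = ripple_window)
  map <- build_genetic_map(ordered, rf)
  map$groups <- grp
  map$singletons <- grp$locus[grp$singleton]
  map
}

#' @export
print.genetic_map <- function(x, ...) {
  g <- x$loci |> group_by(.data$group) |>
    summarise(n = n(), cm = max(.data$position_cm), .groups = "drop")
  cat(sprintf("<genetic_map> %d linkage groups, %d loci\n",
              nrow(g), nrow(x$loci)))
  for (i in seq_len(nrow(g)))
    cat(sprintf("  group %s: %d loci, %.1f cM\n", g$group[i], g$n[i], g$cm[i]))
  if (length(x$singletons %||% character()))
    cat(sprintf("  (+%d unlinked singleton loci)\n", length(x$singletons)))
  invisible(x)
}
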