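#' Nei standard genetic distance between populations
#'
#' `D = -ln(I)` with the normalized identity
#' `I = Jxy / sqrt(Jx * Jy)`, where `Jxy`, `Jx`, `Jy` are the locus-averaged
#' allele-frequency products `sum(p_x * p_y)`, `sum(p_x^2)`, `sum(p_y^2)`.
#'
#' @param table a `genotype_table`.
#' @param loci optional subset of locus indices (used by the bootstrap).
#' @return a `pairwise_matrix` of Nei distances.
#' @export
nei_distance <- function(table, loci = NULL) {
  pops <- pop_levels(table)
  loci <- loci %||% seq_len(n_loci(table))
  k <- length(pops)
  # per-locus frequency matrices on a common allele space
  fr <- lapply(loci, function(l) locus_freqs(table, l))
  D <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    jxy <- jx <- jy <- 0
    for (f in fr) {
      px <- f[i, ]; py <- f[j, ]
      if (anyNA(px) || anyNA(py)) next
      jxy <- jxy + sum(px * py)
      jx <- jx + sum(px^2)
      jy <- jy + sum(py^2)
    }
    I <- jxy / sqrt(jx * jy)
    D[i, j] <- D[j, i] <- -log(pmin(I, 1))
  }
  pairwise_matrix(D, "zero", "Nei standard distance")
}

#' Neighbour-joining tree on Nei distances with locus bootstrap
#'
#' Builds the NJ tree (`ape::nj`) from [nei_distance()] and attaches
#' bootstrap support (percent of trees over loci resampled with replacement
#' that contain each internal bipartition, via `ape::prop.clades`).
#'
#' @param table a `genotype_table` with >= 3 populations.
#' @param n_bootstrap bootstrap replicates over loci (default 100; 0 = none).
#' @param seed optional integer seed.
#' @return an `ape::phylo` tree; node labels carry bootstrap percentages.
#' @export
nei_nj_tree <- function(table, n_bootstrap = 100, seed = NULL) {
  pops <- pop_levels(table)
  stop_if(length(pops) < 3, "NJ needs >= 3 populations")
  if (!is.null(seed)) set.seed(seed)
  D <- nei_distance(table)
  tree <- ape::nj(stats::as.dist(D))
  if (n_bootstrap > 0) {
    L <- n_loci(table)
    boots <- vector("list", n_bootstrap)
    for (b in seq_len(n_bootstrap)) {
      Db <- nei_distance(table, loci = sample(L, L, replace = TRUE))
      boots[[b]] <- ape::nj(stats::as.dist(Db))
    }
    counts <- ape::prop.clades(tree, boots, rooted = FALSE)
    counts[is.na(counts)] <- 0
    tree$node.label <- round(100 * counts / n_bootstrap)
  }
  tree
}
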