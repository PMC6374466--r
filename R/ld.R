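#' Genotypic linkage-disequilibrium permutation test
#'
#' Tests association between the genotypes at two loci with the
#' log-likelihood-ratio (G) statistic on the genotype x genotype
#' contingency table, summed over populations, against its permutation
#' distribution obtained by shuffling the second locus's genotypes among
#' individuals within each population.
#'
#' @param table a `genotype_table`.
#' @param pair_of_loci two locus names or indices.
#' @param n_perm permutations (must be >= 1).
#' @param seed optional integer seed.
#' @return list `G` (observed statistic), `p` (permutation p-value), or a
#'   result with `p = NA` and a note when a locus is monomorphic.
#' @export
linkage_disequilibrium_test <- function(table, pair_of_loci, n_perm = 999,
                                        seed = NULL) {
  stop_if(n_perm < 1, "n_perm must be >= 1")
  li <- vapply(pair_of_loci, function(l)
    if (is.character(l)) match(l, table$loci) else as.integer(l), 1L)
  stop_if(anyNA(li) || length(li) != 2, "pair_of_loci must name two loci")
  if (!is.null(seed)) set.seed(seed)
  g1 <- paste(table$a1[, li[1]], table$a2[, li[1]])
  g2 <- paste(table$a1[, li[2]], table$a2[, li[2]])
  ok <- !is.na(table$a1[, li[1]]) & !is.na(table$a1[, li[2]])
  g1 <- g1[ok]; g2 <- g2[ok]; pop <- table$pop[ok]
  if (length(unique(g1)) < 2 || length(unique(g2)) < 2) {
    return(list(G = NA_real_, p = NA_real_, note = "monomorphic_locus"))
  }
  gstat <- function(g2v) {
    G <- 0
    for (p in unique(pop)) {
      idx <- pop == p
      tab <- table(g1[idx], g2v[idx])
      if (nrow(tab) < 2 || ncol(tab) < 2) next
      E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      nz <- tab > 0
      G <- G + 2 * sum(tab[nz] * log(tab[nz] / E[nz]))
    }
    G
  }
  obs <- gstat(g2)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    g2p <- g2
    for (p in unique(pop)) {
      idx <- which(pop == p)
      g2p[idx] <- g2[sample(idx)]
    }
    if (gstat(g2p) >= obs - 1e-12) hits <- hits + 1L
  }
  list(G = obs, p = (1 + hits) / (n_perm + 1), note = "")
}
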