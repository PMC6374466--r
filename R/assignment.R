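#' Bayesian individual assignment (Rannala-Mountain)
#'
#' For each individual and each candidate population, the likelihood of the
#' multilocus genotype under the population's posterior allele frequencies:
#' a Dirichlet prior adds `1/k` to every allele count, `k` being the number
#' of distinct alleles observed at the locus across the whole dataset, so an
#' allele unseen in a reference population still has nonzero likelihood.
#' Drawing the unordered diploid genotype from the Dirichlet-multinomial
#' gives, with `alpha_a = n_a + 1/k` and `alpha_0 = sum(alpha)`,
#' `P(aa) = alpha_a (alpha_a + 1) / (alpha_0 (alpha_0 + 1))` and
#' `P(ab) = 2 alpha_a alpha_b / (alpha_0 (alpha_0 + 1))`. The individual's
#' own alleles are removed from its home population's counts (leave-one-out)
#' before scoring. Probabilities are normalized over candidate populations;
#' an individual is assigned when its best probability exceeds `threshold`,
#' and flagged as a putative immigrant when the assigned population's region
#' class differs from its sampling region.
#'
#' @param table a `genotype_table` (clones removed).
#' @param threshold assignment probability cutoff (default 0.70, exclusive).
#' @return an `assignment_result` data.frame: `id`, `pop`, `best_pop`,
#'   `best_prob`, `assigned` (population or `"unassigned"`), `immigrant`
#'   (NA without region metadata); attribute `prob` holds the full
#'   individual x population probability matrix.
#' @export
assign_individuals <- function(table, threshold = 0.70) {
  pops <- pop_levels(table)
  stop_if(length(pops) < 2, "need >= 2 candidate populations")
  L <- n_loci(table)
  counts <- lapply(seq_len(L), function(l) locus_counts(table, l))
  n <- n_ind(table)
  ll <- matrix(0, n, length(pops), dimnames = list(table$id, pops))
  for (l in seq_len(L)) {
    lc <- counts[[l]]
    k <- length(lc$alleles)
    if (k == 0) next
    prior <- 1 / k
    for (i in seq_len(n)) {
      x <- table$a1[i, l]; y <- table$a2[i, l]
      if (is.na(x)) next
      xi <- match(x, lc$alleles); yi <- match(y, lc$alleles)
      home <- match(table$pop[i], pops)
      for (pj in seq_along(pops)) {
        cnt_x <- lc$counts[pj, xi]; cnt_y <- lc$counts[pj, yi]
        tot <- sum(lc$counts[pj, ])
        if (pj == home) { # leave own alleles out
          cnt_x <- cnt_x - 1L; cnt_y <- cnt_y - 1L
          if (xi == yi) { cnt_x <- cnt_x - 1L; cnt_y <- cnt_x }
          tot <- tot - 2L
        }
        ax <- cnt_x + prior; ay <- cnt_y + prior
        a0 <- tot + 1 # k alleles x prior 1/k
        ll[i, pj] <- ll[i, pj] +
          if (xi == yi) log(ax * (ax + 1)) - log(a0 * (a0 + 1)) else
            log(2 * ax * ay) - log(a0 * (a0 + 1))
      }
    }
  }
  prob <- t(apply(ll, 1, function(z) { w <- exp(z - max(z)); w / sum(w) }))
  best <- max.col(prob, ties.method = "first")
  best_prob <- prob[cbind(seq_len(n), best)]
  assigned <- ifelse(best_prob > threshold, pops[best], "unassigned")
  immigrant <- rep(NA, n)
  if (!is.null(table$region)) {
    pop_region <- vapply(pops, function(p) table$region[match(p, table$pop)], "")
    immigrant <- ifelse(assigned == "unassigned", NA,
                        pop_region[match(assigned, pops)] !=
                          table$region)
  }
  out <- data.frame(id = table$id, pop = table$pop,
                    best_pop = pops[best], best_prob = best_prob,
                    assigned = assigned, immigrant = immigrant)
  attr(out, "prob") <- prob
  class(out) <- c("assignment_result", "data.frame")
  out
}
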