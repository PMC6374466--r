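#' Exact test of genic differentiation between two populations
#'
#' Per locus, a Monte-Carlo exact test on the 2 x k allele-count contingency
#' table: random tables with the observed margins are drawn
#' (`stats::r2dtable`) and the p-value is the fraction whose conditional
#' (multivariate hypergeometric) probability does not exceed the observed
#' table's. Loci are combined by Fisher's method
#' (`-2 * sum(log p) ~ chi^2` with `2L` degrees of freedom).
#'
#' @param table a `genotype_table`.
#' @param pair character vector of two population labels.
#' @param n_resample Monte-Carlo tables per locus (default 10000).
#' @param seed optional integer seed.
#' @return list `per_locus` (data.frame locus, p, note), `fisher_chi2`,
#'   `df`, `p_combined`.
#' @export
exact_differentiation_test <- function(table, pair, n_resample = 10000,
                                       seed = NULL) {
  stop_if(length(pair) != 2, "pair must name two populations")
  stop_if(!all(pair %in% table$pop), "unknown population in pair")
  if (!is.null(seed)) set.seed(seed)
  res <- list()
  for (l in seq_len(n_loci(table))) {
    lc <- locus_counts(table, l, pops = pair)
    tab <- lc$counts[, colSums(lc$counts) > 0, drop = FALSE]
    if (ncol(tab) < 2 || any(rowSums(tab) == 0)) {
      res[[l]] <- data.frame(locus = table$loci[l], p = NA_real_,
                             note = "monomorphic_or_empty")
      next
    }
    p <- mc_exact_p(tab, n_resample)
    res[[l]] <- data.frame(locus = table$loci[l], p = p, note = "")
  }
  per_locus <- do.call(rbind, res)
  ps <- per_locus$p[!is.na(per_locus$p)]
  stop_if(length(ps) == 0, "no polymorphic locus for pair %s-%s",
          pair[1], pair[2])
  chi2 <- -2 * sum(log(ps))
  df <- 2 * length(ps)
  list(per_locus = per_locus, fisher_chi2 = chi2, df = df,
       p_combined = stats::pchisq(chi2, df, lower.tail = FALSE))
}

# log conditional probability of an r x c table given its margins
log_table_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

# Monte-Carlo exact p for one contingency table (fixed margins)
mc_exact_p <- function(tab, n_resample) {
  lp_obs <- log_table_prob(tab)
  sims <- stats::r2dtable(n_resample, rowSums(tab), colSums(tab))
  lp <- vapply(sims, log_table_prob, 1)
  (1 + sum(lp <= lp_obs + 1e-9)) / (n_resample + 1)
}

#' Sequential Bonferroni (Holm) significance flags
#'
#' Step-down Holm procedure over a family of p-values: sorted ascending,
#' `p_(i)` is compared with `alpha/(m - i + 1)` and testing stops at the
#' first failure. Implemented through `stats::p.adjust(method = "holm")`.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @param alpha family-wise error rate (default 0.05).
#' @return logical significance flags, with the Holm-adjusted p-values as
#'   attribute `adjusted`.
#' @export
sequential_bonferroni <- function(pvals, alpha = 0.05) {
  stop_if(any(pvals < 0 | pvals > 1, na.rm = TRUE), "p-values outside [0, 1]")
  adj <- stats::p.adjust(pvals, method = "holm")
  structure(adj <= alpha, adjusted = adj)
}
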