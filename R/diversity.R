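#' Per-population genetic diversity summary
#'
#' For each population and locus (missing calls dropped locus-wise): allele
#' count `Na`; observed heterozygosity `Ho`; expected heterozygosity
#' `He = 1 - sum(p^2)` and its small-sample-corrected variant
#' `He * 2N/(2N - 1)`; allelic richness `A` rarefied by hypergeometric
#' sampling of `2g` gene copies; and `FIS = (He - Ho)/He` (undefined at a
#' fixed locus). Population summaries are means over loci, plus the count of
#' fixed (monomorphic) loci and the carriers of private alleles (alleles
#' found in exactly one population).
#'
#' Run on clone-corrected data ([clone_correct()]): ramets would otherwise
#' inflate homozygosity and deflate richness.
#'
#' @param table a `genotype_table` (clones removed).
#' @param rarefaction_g rarefaction depth in genets; default the smallest
#'   population size. Must not exceed the smallest population.
#' @return a `diversity_summary`: list with `per_locus` (data.frame
#'   pop x locus metrics), `per_pop` (population means, fixed-locus counts),
#'   `private` (data.frame of private-allele carriers), `rarefaction_g`.
#' @export
diversity <- function(table, rarefaction_g = NULL) {
  pops <- pop_levels(table)
  sizes <- vapply(pops, function(p) sum(table$pop == p), 1L)
  g <- rarefaction_g %||% min(sizes)
  too_small <- names(sizes)[sizes < g]
  stop_if(length(too_small) > 0,
          "rarefaction_g = %d exceeds population(s): %s", g,
          paste(too_small, collapse = ", "))

  res <- list()
  for (p in pops) {
    for (l in seq_len(n_loci(table))) {
      lc <- locus_counts(table, l, pops = p)
      cnt <- lc$counts[1, ]; n <- lc$n[[1]]
      if (n == 0) {
        res[[length(res) + 1L]] <- data.frame(
          pop = p, locus = table$loci[l], n = 0L, Na = NA, Ho = NA, He = NA,
          He_corr = NA, A = NA, Fis = NA)
        next
      }
      cnt <- cnt[cnt > 0]
      freq <- cnt / (2 * n)
      Na <- length(cnt)
      rows <- which(table$pop == p & !is.na(table$a1[, l]))
      Ho <- mean(table$a1[rows, l] != table$a2[rows, l])
      He <- 1 - sum(freq^2)
      He_corr <- He * 2 * n / (2 * n - 1)
      A <- rarefied_richness(cnt, 2 * min(g, n))
      Fis <- if (He > 0) (He - Ho) / He else NA_real_
      res[[length(res) + 1L]] <- data.frame(
        pop = p, locus = table$loci[l], n = n, Na = Na, Ho = Ho, He = He,
        He_corr = He_corr, A = A, Fis = Fis)
    }
  }
  per_locus <- do.call(rbind, res)

  per_pop <- do.call(rbind, lapply(pops, function(p) {
    d <- per_locus[per_locus$pop == p & !is.na(per_locus$Na), ]
    data.frame(pop = p, n = sizes[[p]],
               Na = mean(d$Na), Ho = mean(d$Ho), He = mean(d$He),
               He_corr = mean(d$He_corr), A = mean(d$A),
               Fis = mean(d$Fis, na.rm = TRUE),
               fixed_loci = sum(d$Na == 1))
  }))

  private <- private_alleles(table)
  structure(list(per_locus = per_locus, per_pop = per_pop,
                 private = private, rarefaction_g = g),
            class = "diversity_summary")
}

#' Hypergeometric rarefied allele count
#'
#' Expected number of distinct alleles in a random draw of `gsize` gene
#' copies from a sample with allele copy counts `counts`:
#' `sum_i [1 - C(2N - n_i, gsize)/C(2N, gsize)]`.
#'
#' @param counts integer allele copy counts (sum = 2N).
#' @param gsize number of gene copies drawn (<= 2N).
#' @return expected allele count.
#' @export
rarefied_richness <- function(counts, gsize) {
  tot <- sum(counts)
  stop_if(gsize > tot, "rarefaction draw exceeds sample (%d > %d)", gsize, tot)
  sum(1 - exp(lchoose(tot - counts, gsize) - lchoose(tot, gsize)))
}

#' Private alleles and their carriers
#'
#' @param table a `genotype_table`.
#' @return data.frame `locus`, `allele`, `pop`, `ids` (carrier identifiers,
#'   comma-separated); zero rows if none.
#' @export
private_alleles <- function(table) {
  pops <- pop_levels(table)
  out <- list()
  for (l in seq_len(n_loci(table))) {
    lc <- locus_counts(table, l)
    present <- lc$counts > 0
    priv <- which(colSums(present) == 1)
    for (a in priv) {
      p <- rownames(lc$counts)[present[, a]]
      allele <- lc$alleles[a]
      carriers <- table$id[table$pop == p &
                             (!is.na(table$a1[, l]) &
                                (table$a1[, l] == allele |
                                   table$a2[, l] == allele))]
      out[[length(out) + 1L]] <- data.frame(
        locus = table$loci[l], allele = allele, pop = p,
        ids = paste(carriers, collapse = ","))
    }
  }
  if (length(out) == 0) {
    return(data.frame(locus = character(), allele = integer(),
                      pop = character(), ids = character()))
  }
  do.call(rbind, out)
}
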