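#' Labelled symmetric pairwise matrix
#'
#' Carrier for pairwise FST, DEST, p-values or distances between populations.
#'
#' @param values symmetric numeric matrix with population dimnames.
#' @param diagonal `"zero"` or `"undefined"` (NA) semantics.
#' @param what short description of the quantity.
#' @return a `pairwise_matrix` (the matrix, with attributes).
#' @export
pairwise_matrix <- function(values, diagonal = c("zero", "undefined"),
                            what = "") {
  diagonal <- match.arg(diagonal)
  stop_if(nrow(values) != ncol(values), "matrix not square")
  stop_if(is.null(rownames(values)), "matrix needs population labels")
  off <- values[row(values) != col(values)]
  stop_if(any(abs(values - t(values)) > 1e-9, na.rm = TRUE),
          "matrix not symmetric")
  diag(values) <- if (diagonal == "zero") 0 else NA_real_
  structure(values, diagonal = diagonal, what = what,
            class = c("pairwise_matrix", "matrix", "array"))
}

# Weir-Cockerham variance components, one locus: returns c(a, b, c) summed
# over alleles, or NULL when the locus is uninformative for these pops
wc_locus_components <- function(table, locus, pops) {
  lc <- locus_counts(table, locus, pops)
  use <- lc$n > 0
  if (sum(use) < 2 || length(lc$alleles) < 2) return(NULL)
  n <- lc$n[use]
  r <- length(n)
  counts <- lc$counts[use, , drop = FALSE]
  hets <- lc$het[use, , drop = FALSE]
  p <- counts / (2 * n)          # rows recycle n
  h <- hets / n
  nbar <- mean(n)
  if (nbar <= 1) return(NULL)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  if (nc <= 0) return(NULL)
  abc <- c(0, 0, 0)
  for (al in seq_along(lc$alleles)) {
    pbar <- sum(n * p[, al]) / sum(n)
    s2 <- sum(n * (p[, al] - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h[, al]) / sum(n)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    abc <- abc + c(a, b, cc)
  }
  abc
}

# multilocus theta over a set of populations (components summed over loci)
wc_theta <- function(table, pops = NULL) {
  pops <- pops %||% pop_levels(table)
  tot <- c(0, 0, 0)
  for (l in seq_len(n_loci(table))) {
    abc <- wc_locus_components(table, l, pops)
    if (!is.null(abc)) tot <- tot + abc
  }
  denom <- sum(tot)
  if (denom == 0) return(0)
  tot[1] / denom
}

check_pops_have_data <- function(table, pops) {
  for (p in pops) {
    rows <- table$pop == p
    stop_if(sum(!is.na(table$a1[rows, , drop = FALSE])) == 0,
            "population %s has no non-missing calls at any locus", p)
  }
}

#' Global multilocus Weir-Cockerham FST
#'
#' Variance-components estimator theta across all populations, with the
#' components summed over alleles and loci. An optional permutation test
#' reallocates individuals among populations.
#'
#' @param table a `genotype_table` (clones removed, >= 2 populations).
#' @param n_perm permutations for the p-value (0 = none).
#' @param seed optional integer seed for the permutations.
#' @return list `theta` and (when `n_perm > 0`) `p_value`.
#' @export
global_fst <- function(table, n_perm = 0, seed = NULL) {
  pops <- pop_levels(table)
  stop_if(length(pops) < 2, "need >= 2 populations")
  check_pops_have_data(table, pops)
  obs <- wc_theta(table)
  out <- list(theta = obs)
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    perm <- table
    for (b in seq_len(n_perm)) {
      perm$pop <- sample(table$pop)
      if (wc_theta(perm) >= obs) hits <- hits + 1L
    }
    out$p_value <- (1 + hits) / (n_perm + 1)
  }
  out
}

#' Pairwise multilocus Weir-Cockerham FST
#'
#' @inheritParams global_fst
#' @return list `fst` (a `pairwise_matrix`) and, when `n_perm > 0`, `p`
#'   (permutation p-values, `pairwise_matrix` with undefined diagonal).
#' @export
pairwise_fst <- function(table, n_perm = 0, seed = NULL) {
  pops <- pop_levels(table)
  stop_if(length(pops) < 2, "need >= 2 populations")
  check_pops_have_data(table, pops)
  if (!is.null(seed)) set.seed(seed)
  k <- length(pops)
  fst <- matrix(0, k, k, dimnames = list(pops, pops))
  pmat <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    sub <- gt_subset(table, ind = table$pop %in% pops[c(i, j)])
    obs <- wc_theta(sub)
    fst[i, j] <- fst[j, i] <- obs
    if (n_perm > 0) {
      hits <- 0L
      perm <- sub
      for (b in seq_len(n_perm)) {
        perm$pop <- sample(sub$pop)
        if (wc_theta(perm) >= obs) hits <- hits + 1L
      }
      pmat[i, j] <- pmat[j, i] <- (1 + hits) / (n_perm + 1)
    }
  }
  out <- list(fst = pairwise_matrix(fst, "zero", "WC theta"))
  if (n_perm > 0) out$p <- pairwise_matrix(pmat, "undefined", "FST perm p")
  out
}

#' Pairwise Jost's DEST
#'
#' Differentiation in terms of effective allele numbers:
#' `D = (k/(k-1)) * (Ht' - Hs')/(1 - Hs')` per locus, with Hs and Ht carrying
#' the Nei-Chesser small-sample corrections based on the harmonic mean sample
#' size. Loci are combined by the harmonic mean of per-locus D when all are
#' positive, otherwise by the arithmetic mean.
#'
#' @param table a `genotype_table` (clones removed, >= 2 populations).
#' @return a `pairwise_matrix` of multilocus DEST values.
#' @export
jost_dest <- function(table) {
  pops <- pop_levels(table)
  stop_if(length(pops) < 2, "need >= 2 populations")
  check_pops_have_data(table, pops)
  k <- length(pops)
  d <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    d[i, j] <- d[j, i] <- dest_pair(table, pops[c(i, j)])
  }
  pairwise_matrix(d, "zero", "Jost DEST")
}

# multilocus DEST for an arbitrary set of populations
dest_pair <- function(table, pops) {
  vals <- c()
  for (l in seq_len(n_loci(table))) {
    lc <- locus_counts(table, l, pops)
    use <- lc$n > 0
    if (sum(use) < 2) next
    n <- lc$n[use]
    kpop <- length(n)
    p <- lc$counts[use, , drop = FALSE] / (2 * n)
    nh <- harmonic_mean(n)
    hs <- 1 - sum(colMeans(p^2))
    ht <- 1 - sum(colMeans(p)^2)
    hs_est <- (2 * nh / (2 * nh - 1)) * hs
    ht_est <- ht + hs_est / (2 * nh * kpop)
    if (1 - hs_est <= 0) next
    vals <- c(vals, (ht_est - hs_est) / (1 - hs_est) * kpop / (kpop - 1))
  }
  if (length(vals) == 0) return(0)
  if (all(vals > 0)) harmonic_mean(vals) else mean(vals)
}
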