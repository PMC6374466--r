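#' Pairwise allelic distance between diploid individuals
#'
#' Distance between two multilocus genotypes = number of non-shared alleles
#' per locus (0, 1 or 2; multiset comparison of the unordered pair), summed
#' over loci scored in both individuals. This allele-identity metric is the
#' quantity whose sums of squares AMOVA decomposes, and doubles as an
#' individual-level genetic distance for ordination.
#'
#' @param table a `genotype_table`.
#' @return symmetric numeric matrix (individuals x individuals).
#' @export
allelic_distance <- function(table) {
  n <- n_ind(table)
  D <- matrix(0, n, n, dimnames = list(table$id, table$id))
  for (l in seq_len(n_loci(table))) {
    g1 <- table$a1[, l]; g2 <- table$a2[, l]
    ok <- !is.na(g1)
    idx <- which(ok)
    if (length(idx) < 2) next
    h1 <- g1[idx]; h2 <- g2[idx]
    m11 <- outer(h1, h1, "==");  m22 <- outer(h2, h2, "==")
    m12 <- outer(h1, h2, "==");  m21 <- outer(h2, h1, "==")
    shared <- pmax(m11 + m22, m12 + m21)  # max bipartite matching, 2x2
    D[idx, idx] <- D[idx, idx] + (2 - shared)
  }
  D
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Decomposes the allelic-distance sums of squares into among-group,
#' among-population-within-group and within-population components, with the
#' fixation indices FCT, FSC, FST and their permutation p-values under the
#' standard schemes: whole populations permuted among groups for FCT,
#' individuals permuted among populations within groups for FSC, and
#' individuals permuted among all populations for FST. With a single group
#' (or `grouping = NULL`) a two-level decomposition (among / within
#' populations) is returned and FCT/FSC are undefined.
#'
#' @param table a `genotype_table` (>= 2 populations).
#' @param grouping named character vector mapping population -> group, or
#'   `NULL` for the global two-level test.
#' @param n_perm permutations per index (0 = no p-values).
#' @param seed optional integer seed.
#' @return an `amova_result`: data.frame `components` (source, df, sigma2,
#'   percent), named list `indices`, named list `p_values`.
#' @export
amova <- function(table, grouping = NULL, n_perm = 0, seed = NULL) {
  pops <- pop_levels(table)
  stop_if(length(pops) < 2, "need >= 2 populations")
  if (!is.null(grouping)) {
    miss <- setdiff(pops, names(grouping))
    stop_if(length(miss) > 0, "grouping missing population(s): %s",
            paste(miss, collapse = ", "))
    if (length(unique(grouping[pops])) < 2) grouping <- NULL
  }
  if (!is.null(seed)) set.seed(seed)
  D2 <- allelic_distance(table)
  pop <- table$pop

  if (is.null(grouping)) {
    fit <- amova_two_level(D2, pop)
    p <- list()
    if (n_perm > 0) {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        f <- amova_two_level(D2, sample(pop))
        if (f$indices[["FST"]] >= fit$indices[["FST"]]) hits <- hits + 1L
      }
      p$FST <- (1 + hits) / (n_perm + 1)
    }
    fit$p_values <- p
    class(fit) <- "amova_result"
    return(fit)
  }

  group <- unname(grouping[pop])
  fit <- amova_three_level(D2, pop, group)
  p <- list()
  if (n_perm > 0) {
    hit <- c(FCT = 0L, FSC = 0L, FST = 0L)
    pop_group <- grouping[pops]
    for (b in seq_len(n_perm)) {
      # FCT: permute whole populations among groups
      pg <- stats::setNames(sample(unname(pop_group)), pops)
      f1 <- amova_three_level(D2, pop, unname(pg[pop]))
      if (f1$indices[["FCT"]] >= fit$indices[["FCT"]]) hit["FCT"] <- hit["FCT"] + 1L
      # FSC: permute individuals among populations within their group
      pop2 <- pop
      for (g in unique(group)) {
        idx <- which(group == g)
        pop2[idx] <- pop[sample(idx)]
      }
      f2 <- amova_three_level(D2, pop2, group)
      if (!is.na(fit$indices[["FSC"]]) &&
          f2$indices[["FSC"]] >= fit$indices[["FSC"]]) hit["FSC"] <- hit["FSC"] + 1L
      # FST: permute individuals among all populations (groups follow pops)
      ord <- sample(length(pop))
      f3 <- amova_three_level(D2, pop[ord], unname(grouping[pop[ord]]))
      if (f3$indices[["FST"]] >= fit$indices[["FST"]]) hit["FST"] <- hit["FST"] + 1L
    }
    p <- as.list((1 + hit) / (n_perm + 1))
    if (is.na(fit$indices[["FSC"]])) p$FSC <- NA_real_
  }
  fit$p_values <- p
  class(fit) <- "amova_result"
  fit
}

# sum over within-cluster pairs of d2/size, the AMOVA SS for one level
ss_within <- function(D2, labels) {
  ss <- 0
  for (u in unique(labels)) {
    idx <- which(labels == u)
    ss <- ss + sum(D2[idx, idx]) / (2 * length(idx))
  }
  ss
}

amova_two_level <- function(D2, pop) {
  N <- nrow(D2); P <- length(unique(pop))
  ss_t <- sum(D2) / (2 * N)
  ss_wp <- ss_within(D2, pop)
  ss_ap <- ss_t - ss_wp
  df_ap <- P - 1; df_wp <- N - P
  ms_ap <- ss_ap / df_ap; ms_wp <- ss_wp / df_wp
  n_p <- as.numeric(table(pop))
  n0 <- (N - sum(n_p^2) / N) / (P - 1)
  sig_w <- ms_wp
  sig_a <- (ms_ap - ms_wp) / n0
  tot <- sig_a + sig_w
  comp <- data.frame(
    source = c("among_populations", "within_populations"),
    df = c(df_ap, df_wp),
    sigma2 = c(sig_a, sig_w),
    percent = 100 * c(sig_a, sig_w) / tot)
  list(components = comp,
       indices = list(FST = sig_a / tot))
}

amova_three_level <- function(D2, pop, group) {
  N <- nrow(D2)
  pops <- unique(pop); P <- length(pops)
  groups <- unique(group); G <- length(groups)
  ss_t <- sum(D2) / (2 * N)
  ss_wp <- ss_within(D2, pop)
  ss_wg <- ss_within(D2, group)
  ss_ag <- ss_t - ss_wg
  ss_ap <- ss_wg - ss_wp
  df_ag <- G - 1; df_ap <- P - G; df_wp <- N - P
  ms_ag <- ss_ag / df_ag; ms_wp <- ss_wp / df_wp
  ms_ap <- if (df_ap > 0) ss_ap / df_ap else NA_real_
  # population sizes and the n-coefficients of the expected mean squares
  n_p <- vapply(pops, function(p) sum(pop == p), 1)
  pg <- vapply(pops, function(p) group[match(p, pop)], "")
  N_g <- vapply(groups, function(g) sum(group == g), 1)
  sum_np2_by_g <- vapply(groups, function(g) sum(n_p[pg == g]^2), 1)
  n1 <- if (df_ap > 0) (N - sum(sum_np2_by_g / N_g)) / (P - G) else NA_real_
  n2 <- (sum(sum_np2_by_g / N_g) - sum(n_p^2) / N) / (G - 1)
  n3 <- (N - sum(N_g^2) / N) / (G - 1)
  sig_c <- ms_wp
  # one population per group: no among-population-within-group level
  sig_b <- if (df_ap > 0) (ms_ap - sig_c) / n1 else 0
  sig_a <- (ms_ag - sig_c - n2 * sig_b) / n3
  tot <- sig_a + sig_b + sig_c
  comp <- data.frame(
    source = c("among_groups", "among_populations_within_groups",
               "within_populations"),
    df = c(df_ag, df_ap, df_wp),
    sigma2 = c(sig_a, sig_b, sig_c),
    percent = 100 * c(sig_a, sig_b, sig_c) / tot)
  list(components = comp,
       indices = list(FCT = sig_a / tot,
                      FSC = if (df_ap > 0) sig_b / (sig_b + sig_c) else NA_real_,
                      FST = (sig_a + sig_b) / tot))
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA\n")
  print(transform(x$components, percent = round(percent, 2),
                  sigma2 = signif(sigma2, 4)), row.names = FALSE)
  for (nm in names(x$indices)) {
    cat(sprintf("  %s = %.4f", nm, x$indices[[nm]]))
    if (!is.null(x$p_values[[nm]]))
      cat(sprintf("  (P = %.4g)", x$p_values[[nm]]))
    cat("\n")
  }
  invisible(x)
}
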