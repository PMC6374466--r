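#' Detect clonal groups (shared multilocus genotypes)
#'
#' Within each population, individuals with identical calls at every locus
#' where both have data are grouped into one multilocus genotype (MLG);
#' ramets of one genet. Missing calls act as wildcards and groups are merged
#' transitively. A duplicate group is flagged as a true clone only when its
#' probability of identity — the chance two independent sexual recruits share
#' an MLG, computed per locus as `sum(p_i^4) + sum_{i<j} (2 p_i p_j)^2` from
#' that population's allele frequencies and multiplied over the group's
#' scored loci — falls below `pid_threshold`.
#'
#' @param table a `genotype_table`.
#' @param pid_threshold probability-of-identity cutoff for flagging a
#'   duplicate group as clonal (default 0.001).
#' @return a `clone_partition`: list with `groups` (list of identifier
#'   vectors, one per genet), `pi` (per-group probability of identity),
#'   `is_clone` (flag per group), `mlg_per_pop`, `n_per_pop`,
#'   `clonal_fraction` (`1 - MLG/N` per population), and `keep` (identifiers
#'   retained downstream: one representative per flagged clone group).
#' @export
detect_clones <- function(table, pid_threshold = 0.001) {
  stop_if(n_ind(table) < 1, "empty genotype table")
  all_missing <- rowSums(!is.na(table$a1)) == 0
  if (any(all_missing)) {
    warning(sprintf("excluding %d individual(s) with no scored locus: %s",
                    sum(all_missing),
                    paste(table$id[all_missing], collapse = ", ")))
    table <- gt_subset(table, ind = !all_missing)
  }
  pops <- pop_levels(table)
  groups <- list(); gi <- list(); gpop <- character()
  for (p in pops) {
    rows <- which(table$pop == p)
    n <- length(rows)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    a1 <- table$a1[rows, , drop = FALSE]; a2 <- table$a2[rows, , drop = FALSE]
    if (n > 1) {
      for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        both <- !is.na(a1[i, ]) & !is.na(a1[j, ])
        if (!any(both)) next
        if (all(a1[i, both] == a1[j, both] & a2[i, both] == a2[j, both])) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
    roots <- vapply(seq_len(n), find, 1L)
    for (r in unique(roots)) {
      members <- rows[roots == r]
      groups[[length(groups) + 1L]] <- table$id[members]
      gi[[length(gi) + 1L]] <- members
      gpop <- c(gpop, p)
    }
  }

  # per-locus probability of identity from population allele frequencies
  pid_locus <- function(p) sum(p^4) + sum((2 * outer(p, p))[upper.tri(
    diag(length(p)))]^2)
  pi_vals <- vapply(seq_along(groups), function(g) {
    rep1 <- gi[[g]][1]
    loci_ok <- which(!is.na(table$a1[rep1, ]))
    prod(vapply(loci_ok, function(l) {
      f <- locus_freqs(table, l, pops = gpop[g])[1, ]
      f <- f[!is.na(f) & f > 0]
      if (length(f) == 0) return(1)
      pid_locus(f)
    }, 1))
  }, 1)

  sizes <- lengths(groups)
  is_clone <- sizes > 1 & pi_vals < pid_threshold
  keep_ids <- unlist(lapply(seq_along(groups), function(g) {
    if (is_clone[g]) groups[[g]][1] else groups[[g]]
  }))
  mlg <- vapply(pops, function(p) sum(gpop == p), 1L)
  npp <- vapply(pops, function(p) sum(table$pop == p), 1L)
  structure(list(groups = groups, pi = pi_vals, is_clone = is_clone,
                 group_pop = gpop,
                 mlg_per_pop = mlg, n_per_pop = npp,
                 clonal_fraction = 1 - mlg / npp,
                 keep = keep_ids),
            class = "clone_partition")
}

#' @export
print.clone_partition <- function(x, ...) {
  cat(sprintf("clone_partition: %d genets over %d individuals; %d clonal group(s)\n",
              length(x$groups), sum(x$n_per_pop), sum(x$is_clone)))
  print(round(x$clonal_fraction, 3))
  invisible(x)
}

#' Collapse clonal groups to one representative each
#'
#' @param table a `genotype_table`.
#' @param partition a [detect_clones()] result (computed if omitted).
#' @return the clone-corrected `genotype_table`.
#' @export
clone_correct <- function(table, partition = NULL) {
  part <- partition %||% detect_clones(table)
  gt_subset(table, ind = table$id %in% part$keep)
}
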