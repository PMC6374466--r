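#' Multilocus microsatellite genotype table
#'
#' The universal population-genetic input: diploid allele calls (microsatellite
#' fragment sizes) for a set of individuals at a set of loci, together with the
#' population each individual was sampled from, an optional biogeographic
#' region class per individual, and optional per-population site coordinates.
#'
#' Allele pairs are stored in canonical (sorted) order because microsatellite
#' genotypes are unphased; a missing genotype is `NA` in both allele slots.
#'
#' @param a1,a2 integer matrices (individuals x loci) of allele labels
#'   (fragment sizes, positive integers); `NA` marks a missing call. The pair
#'   is reordered so that `a1 <= a2` element-wise.
#' @param loci character vector of locus names (columns of `a1`/`a2`).
#' @param id character vector of individual identifiers (rows).
#' @param pop character vector, sampling population of each individual.
#' @param region optional character vector per individual, one of
#'   `"recent_temperate"`, `"pre_existing_temperate"`, `"subtropical"`.
#' @param coords optional data.frame with columns `pop`, `lat`, `lon`
#'   (decimal degrees) giving one site position per population.
#'
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(a1, a2, loci, id, pop, region = NULL, coords = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  n <- nrow(a1); L <- ncol(a1)
  stop_if(!all(dim(a2) == c(n, L)), "a1 and a2 must have identical dimensions")
  stop_if(length(loci) != L, "loci length (%d) != number of call columns (%d)",
          length(loci), L)
  stop_if(length(id) != n, "id length != number of individuals")
  stop_if(length(pop) != n, "pop length != number of individuals")
  stop_if(anyDuplicated(id) > 0, "duplicated individual identifiers")
  bad <- which((is.na(a1) != is.na(a2)))
  stop_if(length(bad) > 0, "half-missing genotype at %d call(s)", length(bad))
  stop_if(any(a1 <= 0, na.rm = TRUE) || any(a2 <= 0, na.rm = TRUE),
          "allele labels must be positive integers")
  # canonical unordered storage
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(id, loci)
  if (!is.null(region)) {
    stop_if(length(region) != n, "region length != number of individuals")
    bad <- setdiff(unique(region[!is.na(region)]), REGION_CLASSES)
    stop_if(length(bad) > 0, "unknown region class: %s",
            paste(bad, collapse = ", "))
  }
  if (!is.null(coords)) {
    stop_if(!all(c("pop", "lat", "lon") %in% names(coords)),
            "coords needs columns pop, lat, lon")
    miss <- setdiff(unique(pop), coords$pop)
    stop_if(length(miss) > 0, "coords missing population(s): %s",
            paste(miss, collapse = ", "))
  }
  structure(list(a1 = a1, a2 = a2, loci = as.character(loci),
                 id = as.character(id), pop = as.character(pop),
                 region = region, coords = coords),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals, %d loci, %d populations\n",
              n_ind(x), n_loci(x), length(pop_levels(x))))
  nm <- sum(is.na(x$a1))
  cat(sprintf("  missing calls: %d (%.1f%%)\n", nm,
              100 * nm / length(x$a1)))
  invisible(x)
}

#' @rdname genotype_table
#' @param x a `genotype_table`.
#' @export
n_ind <- function(x) nrow(x$a1)

#' @rdname genotype_table
#' @export
n_loci <- function(x) ncol(x$a1)

#' Population labels in order of first appearance
#' @param x a `genotype_table`.
#' @export
pop_levels <- function(x) unique(x$pop)

#' Subset a genotype table
#'
#' @param x a `genotype_table`.
#' @param ind logical/integer/character index over individuals (optional).
#' @param loci logical/integer/character index over loci (optional).
#' @return a `genotype_table`.
#' @export
gt_subset <- function(x, ind = NULL, loci = NULL) {
  ri <- seq_len(n_ind(x)); ci <- seq_len(n_loci(x))
  if (!is.null(ind)) {
    ri <- if (is.character(ind)) match(ind, x$id) else ri[ind]
    stop_if(anyNA(ri), "unknown individual identifiers in subset")
  }
  if (!is.null(loci)) {
    ci <- if (is.character(loci)) match(loci, x$loci) else ci[loci]
    stop_if(anyNA(ci), "unknown locus names in subset")
  }
  stop_if(length(ci) == 0, "refusing to drop every locus")
  stop_if(length(ri) == 0, "refusing to drop every individual")
  genotype_table(x$a1[ri, ci, drop = FALSE], x$a2[ri, ci, drop = FALSE],
                 x$loci[ci], x$id[ri], x$pop[ri],
                 region = if (!is.null(x$region)) x$region[ri],
                 coords = x$coords)
}

#' Per-population allele counts at one locus
#'
#' Missing genotypes are dropped locus-wise (pairwise deletion). Returns the
#' ingredients every frequency-based statistic needs.
#'
#' @param x a `genotype_table`.
#' @param locus locus name or index.
#' @param pops optional subset of populations (default: all, in order).
#' @return list with `counts` (pops x alleles matrix of allele copy counts),
#'   `het` (pops x alleles count of heterozygous carriers of each allele),
#'   `n` (per-population number of genotyped individuals), `alleles`
#'   (sorted allele labels).
#' @export
locus_counts <- function(x, locus, pops = NULL) {
  ci <- if (is.character(locus)) match(locus, x$loci) else locus
  stop_if(is.na(ci), "unknown locus: %s", locus)
  pops <- pops %||% pop_levels(x)
  keep <- x$pop %in% pops
  a1 <- x$a1[keep, ci]; a2 <- x$a2[keep, ci]; pp <- x$pop[keep]
  ok <- !is.na(a1)
  alleles <- sort(unique(c(a1[ok], a2[ok])))
  k <- length(alleles)
  counts <- matrix(0L, length(pops), k, dimnames = list(pops, alleles))
  het <- matrix(0L, length(pops), k, dimnames = list(pops, alleles))
  nvec <- integer(length(pops)); names(nvec) <- pops
  if (k > 0) {
    pi_ <- match(pp[ok], pops)
    i1 <- match(a1[ok], alleles); i2 <- match(a2[ok], alleles)
    for (j in seq_along(pi_)) {
      counts[pi_[j], i1[j]] <- counts[pi_[j], i1[j]] + 1L
      counts[pi_[j], i2[j]] <- counts[pi_[j], i2[j]] + 1L
      if (i1[j] != i2[j]) {
        het[pi_[j], i1[j]] <- het[pi_[j], i1[j]] + 1L
        het[pi_[j], i2[j]] <- het[pi_[j], i2[j]] + 1L
      }
    }
    nvec <- tabulate(pi_, nbins = length(pops))
    names(nvec) <- pops
  }
  list(counts = counts, het = het, n = nvec, alleles = alleles)
}

#' Per-population allele frequencies at one locus
#' @inheritParams locus_counts
#' @return pops x alleles matrix of frequencies (rows sum to 1 where n > 0).
#' @export
locus_freqs <- function(x, locus, pops = NULL) {
  lc <- locus_counts(x, locus, pops)
  tot <- rowSums(lc$counts)
  f <- lc$counts / ifelse(tot == 0, NA_real_, tot)
  f
}
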