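#' Configuration for the synthetic genotype generator
#'
#' Describes a set of diploid microsatellite populations with a known
#' (planted) level of differentiation, optional clonal replication, optional
#' cryptic-lineage admixture, and missing data.
#'
#' Two spatial layouts are offered. `"island"` draws each population's
#' allele frequencies from a Balding-Nichols/Dirichlet distribution around a
#' shared ancestral frequency vector with concentration `(1 - F)/F`, which
#' makes the planted `fst_target` the analytic expectation of Weir-Cockerham
#' theta. `"linear"` builds a stepping-stone chain by serial drift: each
#' population's frequencies are a multinomial resample of its neighbour's,
#' so diversity erodes toward the far end of the chain, the pattern expected
#' at a poleward range edge.
#'
#' @param n_pops number of populations.
#' @param n_per_pop diploid individuals sampled per population (scalar or
#'   vector of length `n_pops`).
#' @param n_loci number of microsatellite loci.
#' @param alleles_per_locus ancestral allele count per locus.
#' @param fst_target planted differentiation in `[0, 1)`: the Balding-Nichols
#'   divergence parameter (island) or the per-step drift intensity (linear).
#' @param layout `"island"` or `"linear"` (stepping stone).
#' @param clone_spec optional named list: for each population, an integer
#'   vector of ramet counts (each >= 2); each entry turns one genet into that
#'   many identical ramets. Total individuals per population is unchanged.
#' @param lineage_spec optional list describing a second, cryptic lineage:
#'   `prop` (fraction of individuals per population drawn from the second
#'   allele-frequency pool), `q1` (membership of those individuals in
#'   lineage 1; default 0 = pure second lineage). The true per-individual
#'   lineage-1 membership is returned as truth.
#' @param missing_rate per-call missing probability in `[0, 1)`.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return a `sim_genotype_config` list.
#' @export
sim_genotype_config <- function(n_pops = 13, n_per_pop = 20, n_loci = 8,
                                alleles_per_locus = 8, fst_target = 0.10,
                                layout = c("island", "linear"),
                                clone_spec = NULL, lineage_spec = NULL,
                                missing_rate = 0, seed = 1L) {
  layout <- match.arg(layout)
  stop_if(fst_target < 0 || fst_target >= 1, "fst_target must be in [0, 1)")
  stop_if(missing_rate < 0 || missing_rate >= 1, "missing_rate must be in [0, 1)")
  stop_if(any(n_per_pop < 1), "n_per_pop must be >= 1")
  n_per_pop <- rep_len(n_per_pop, n_pops)
  pops <- sprintf("P%02d", seq_len(n_pops))
  names(n_per_pop) <- pops
  if (!is.null(clone_spec)) {
    bad <- setdiff(names(clone_spec), pops)
    stop_if(length(bad) > 0, "clone_spec names unknown populations: %s",
            paste(bad, collapse = ", "))
    for (p in names(clone_spec)) {
      cs <- clone_spec[[p]]
      stop_if(any(cs < 2), "clone_spec ramet counts must be >= 2")
      stop_if(sum(cs) > n_per_pop[[p]],
              "clone_spec for %s asks for %d ramets but n_per_pop is %d",
              p, sum(cs), n_per_pop[[p]])
    }
  }
  if (!is.null(lineage_spec)) {
    lineage_spec$prop <- lineage_spec$prop %||% 0.3
    lineage_spec$q1 <- lineage_spec$q1 %||% 0
    stop_if(lineage_spec$prop < 0 || lineage_spec$prop > 1,
            "lineage_spec$prop must be in [0, 1]")
  }
  structure(list(n_pops = n_pops, n_per_pop = n_per_pop, n_loci = n_loci,
                 alleles_per_locus = alleles_per_locus,
                 fst_target = fst_target, layout = layout,
                 clone_spec = clone_spec, lineage_spec = lineage_spec,
                 missing_rate = missing_rate, seed = as.integer(seed),
                 pops = pops),
            class = "sim_genotype_config")
}

# population frequency matrices (pops x alleles) for one locus
sim_locus_freqs <- function(config, ancestral) {
  F <- config$fst_target
  r <- config$n_pops
  if (config$layout == "island") {
    if (F == 0) {
      matrix(ancestral, r, length(ancestral), byrow = TRUE)
    } else {
      t(vapply(seq_len(r),
               function(i) rdirichlet1(ancestral * (1 - F) / F),
               numeric(length(ancestral))))
    }
  } else {
    # serial drift along the chain: repeated multinomial resampling with an
    # effective size chosen so one step plants roughly F between neighbours
    out <- matrix(0, r, length(ancestral))
    out[1, ] <- ancestral
    if (F == 0) {
      for (i in seq_len(r - 1)) out[i + 1, ] <- out[i, ]
    } else {
      two_ne <- max(2L, round(1 / F))
      for (i in seq_len(r - 1)) {
        out[i + 1, ] <- as.numeric(
          stats::rmultinom(1, size = two_ne, prob = out[i, ])) / two_ne
      }
    }
    out
  }
}

#' Generate a synthetic genotype table with known truth
#'
#' Produces a [genotype_table()] whose allele-frequency structure, clonal
#' replication, lineage admixture and missing data follow the configuration,
#' plus the generating truth (ancestral and population frequencies, true
#' lineage memberships, planted clone groups) as the `"truth"` attribute.
#' Populations are laid out along a poleward coastline (south-west to
#' north-east) and split into subtropical / pre-existing temperate / recently
#' expanded temperate region classes along the chain.
#'
#' @param config a [sim_genotype_config()].
#' @return a `genotype_table` with attribute `truth`.
#' @export
generate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_genotype_config"))
  set.seed(config$seed)
  r <- config$n_pops; L <- config$n_loci; A <- config$alleles_per_locus
  pops <- config$pops
  n <- config$n_per_pop
  N <- sum(n)

  # allele labels: microsatellite-like fragment sizes per locus
  labels <- lapply(seq_len(L), function(l) 100L + 20L * l + 2L * seq_len(A))
  ancestral <- replicate(L, rdirichlet1(rep(1, A)), simplify = FALSE)
  freqs1 <- lapply(seq_len(L), function(l) {
    f <- sim_locus_freqs(config, ancestral[[l]])
    dimnames(f) <- list(pops, labels[[l]])
    f
  })
  freqs2 <- NULL
  if (!is.null(config$lineage_spec)) {
    anc2 <- replicate(L, rdirichlet1(rep(1, A)), simplify = FALSE)
    freqs2 <- lapply(seq_len(L), function(l) {
      f <- sim_locus_freqs(config, anc2[[l]])
      dimnames(f) <- list(pops, labels[[l]])
      f
    })
  }

  pop_vec <- rep(pops, times = n)
  id <- unlist(lapply(seq_len(r), function(i) sprintf("%s_%02d", pops[i],
                                                      seq_len(n[i]))))
  # true lineage-1 membership per individual
  q1 <- rep(1, N)
  if (!is.null(config$lineage_spec)) {
    off <- 0L
    for (i in seq_len(r)) {
      n2 <- round(config$lineage_spec$prop * n[i])
      if (n2 > 0) q1[off + n[i] - seq_len(n2) + 1L] <- config$lineage_spec$q1
      off <- off + n[i]
    }
  }

  a1 <- matrix(NA_integer_, N, L); a2 <- matrix(NA_integer_, N, L)
  off <- 0L
  clone_groups <- list()
  for (i in seq_len(r)) {
    rows <- off + seq_len(n[i])
    for (l in seq_len(L)) {
      draw <- function(qv) { # one allele per individual in this pop
        pool2 <- stats::runif(length(qv)) > qv
        al <- integer(length(qv))
        if (any(!pool2)) al[!pool2] <- sample(labels[[l]], sum(!pool2),
                                              replace = TRUE,
                                              prob = freqs1[[l]][i, ])
        if (any(pool2)) al[pool2] <- sample(labels[[l]], sum(pool2),
                                            replace = TRUE,
                                            prob = freqs2[[l]][i, ])
        al
      }
      qv <- q1[rows]
      a1[rows, l] <- draw(qv)
      a2[rows, l] <- draw(qv)
    }
    # clonal replication: genet g's calls copied over the following ramets
    cs <- config$clone_spec[[pops[i]]]
    if (!is.null(cs)) {
      pos <- 1L
      for (k in seq_along(cs)) {
        src <- rows[pos]
        dup <- rows[pos + seq_len(cs[k] - 1L)]
        a1[dup, ] <- matrix(a1[src, ], length(dup), L, byrow = TRUE)
        a2[dup, ] <- matrix(a2[src, ], length(dup), L, byrow = TRUE)
        clone_groups[[length(clone_groups) + 1L]] <- id[c(src, dup)]
        pos <- pos + cs[k]
      }
    }
    off <- off + n[i]
  }

  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(N * L) < config$missing_rate, N, L)
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    # guard: an all-missing individual is re-granted its first locus
    allm <- rowSums(!is.na(a1)) == 0
    if (any(allm)) {
      for (j in which(allm)) {
        a1[j, 1] <- labels[[1]][1]; a2[j, 1] <- labels[[1]][1]
      }
    }
  }

  # coastline from subtropical SW to temperate NE, mirroring the study region
  lat <- seq(24, 34, length.out = r)
  lon <- seq(124, 139, length.out = r)
  coords <- data.frame(pop = pops, lat = lat, lon = lon)
  thirds <- cut(seq_len(r), breaks = c(0, r / 3, 2 * r / 3, r),
                labels = c("subtropical", "pre_existing_temperate",
                           "recent_temperate"))
  region <- as.character(thirds)[match(pop_vec, pops)]

  tab <- genotype_table(a1, a2, sprintf("L%02d", seq_len(L)), id, pop_vec,
                        region = region, coords = coords)
  attr(tab, "truth") <- list(
    fst_target = config$fst_target, layout = config$layout,
    ancestral = ancestral, freqs = freqs1, freqs2 = freqs2,
    q1 = stats::setNames(q1, id), clone_groups = clone_groups)
  tab
}

#' True lineage memberships as a Q-matrix block
#'
#' Formats the generator's true per-individual lineage-1 membership as a
#' cluster-membership (Q) matrix for a given K, the shape produced by
#' admixture-clustering software. For `K = 2` the columns are
#' `(q1, 1 - q1)`; larger K split the residual evenly (sufficient for
#' threshold-filter tests).
#'
#' @param table a `genotype_table` from [generate_genotypes()].
#' @param K number of clusters.
#' @return matrix (individuals x K) with rownames = identifiers, rows sum to 1.
#' @export
true_qmatrix <- function(table, K = 2) {
  truth <- attr(table, "truth")
  stop_if(is.null(truth), "table carries no generator truth")
  q1 <- truth$q1[table$id]
  rest <- (1 - q1) / (K - 1)
  q <- cbind(q1, matrix(rest, length(q1), K - 1))
  rownames(q) <- table$id
  colnames(q) <- paste0("cluster", seq_len(K))
  q
}
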