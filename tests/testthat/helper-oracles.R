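# Fixtures built in code and independent brute-force oracles used to verify
# the package's estimators on tiny instances.

# small genotype table from a list of per-individual calls
# calls: list of integer matrices 2 x L (rows = the two alleles)
tiny_table <- function(calls, pop, id = NULL, loci = NULL, region = NULL,
                       coords = NULL) {
  L <- ncol(calls[[1]])
  a1 <- t(vapply(calls, function(m) m[1, ], integer(L)))
  a2 <- t(vapply(calls, function(m) m[2, ], integer(L)))
  if (L == 1) { a1 <- matrix(a1, ncol = 1); a2 <- matrix(a2, ncol = 1) }
  genotype_table(a1, a2, loci %||% sprintf("L%d", seq_len(L)),
                 id %||% sprintf("i%02d", seq_along(calls)), pop,
                 region = region, coords = coords)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- Weir-Cockerham theta via the nested-ANOVA mean-squares route ---------
# (alleles within individuals within populations), an algebraically
# equivalent but independently coded estimator
oracle_wc_theta <- function(tab) {
  pops <- unique(tab$pop)
  num <- den <- 0
  for (l in seq_len(ncol(tab$a1))) {
    ok <- !is.na(tab$a1[, l])
    if (sum(ok) == 0) next
    alleles <- sort(unique(c(tab$a1[ok, l], tab$a2[ok, l])))
    if (length(alleles) < 2) next
    use_pops <- pops[vapply(pops, function(p) any(ok & tab$pop == p), TRUE)]
    r <- length(use_pops)
    if (r < 2) next
    n_p <- vapply(use_pops, function(p) sum(ok & tab$pop == p), 1)
    N <- sum(n_p)
    nc <- (N - sum(n_p^2) / N) / (r - 1)
    for (A in alleles) {
      # y[p][i, k]: indicator that gamete k of individual i in pop p is A
      ybar <- mean(c(tab$a1[ok, l] == A, tab$a2[ok, l] == A))
      ssp <- ssi <- ssg <- 0
      for (p in use_pops) {
        rows <- which(ok & tab$pop == p)
        yi <- cbind(tab$a1[rows, l] == A, tab$a2[rows, l] == A)
        ybar_pi <- rowMeans(yi)
        ybar_p <- mean(yi)
        ssg <- ssg + sum((yi - ybar_pi)^2)
        ssi <- ssi + 2 * sum((ybar_pi - ybar_p)^2)
        ssp <- ssp + 2 * length(rows) * (ybar_p - ybar)^2
      }
      msg <- ssg / N
      msi <- ssi / (N - r)
      msp <- ssp / (r - 1)
      sc <- msg
      sb <- (msi - msg) / 2
      sa <- (msp - msi) / (2 * nc)
      num <- num + sa
      den <- den + sa + sb + sc
    }
  }
  if (den == 0) 0 else num / den
}

# --- AMOVA sums of squares by explicit pair loops -------------------------
oracle_amova3 <- function(D2, pop, group) {
  N <- nrow(D2)
  ss_among <- function(labels) { # SS total within each cluster
    tot <- 0
    for (u in unique(labels)) {
      idx <- which(labels == u)
      s <- 0
      for (i in idx) for (j in idx) s <- s + D2[i, j]
      tot <- tot + s / (2 * length(idx))
    }
    tot
  }
  sst <- sum(D2) / (2 * N)
  sswp <- ss_among(pop)
  sswg <- ss_among(group)
  pops <- unique(pop); groups <- unique(group)
  P <- length(pops); G <- length(groups)
  n_p <- sapply(pops, function(p) sum(pop == p))
  pg <- sapply(pops, function(p) unique(group[pop == p]))
  N_g <- sapply(groups, function(g) sum(group == g))
  msw <- sswp / (N - P)
  msap <- (sswg - sswp) / (P - G)
  msag <- (sst - sswg) / (G - 1)
  n1 <- (N - sum(sapply(groups, function(g) sum(n_p[pg == g]^2) / N_g[groups == g]))) / (P - G)
  n2 <- (sum(sapply(groups, function(g) sum(n_p[pg == g]^2) / N_g[groups == g])) -
           sum(n_p^2) / N) / (G - 1)
  n3 <- (N - sum(N_g^2) / N) / (G - 1)
  sc <- msw
  sb <- (msap - sc) / n1
  sa <- (msag - sc - n2 * sb) / n3
  c(sa = sa, sb = sb, sc = sc)
}

# --- Holm rule applied literally ------------------------------------------
oracle_holm <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  flags <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= alpha / (m - i + 1)) flags[ord[i]] <- TRUE else break
  }
  flags
}

# --- Mantel r from the definition -----------------------------------------
oracle_mantel_r <- function(A, B) {
  x <- c(); y <- c()
  n <- nrow(A)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    x <- c(x, A[i, j]); y <- c(y, B[i, j])
  }
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# --- Dijkstra on a sea-cell lattice, coded from scratch -------------------
# cells: data.frame ix, iy, lon, lat for sea cells; returns distance between
# two sea-cell indices (rows of cells)
oracle_sea_dijkstra <- function(cells, from, to) {
  n <- nrow(cells)
  hav <- function(i, j) {
    rad <- pi / 180
    dlat <- (cells$lat[j] - cells$lat[i]) * rad
    dlon <- (cells$lon[j] - cells$lon[i]) * rad
    a <- sin(dlat / 2)^2 + cos(cells$lat[i] * rad) * cos(cells$lat[j] * rad) *
      sin(dlon / 2)^2
    2 * 6371 * asin(sqrt(a))
  }
  dist <- rep(Inf, n); dist[from] <- 0
  done <- rep(FALSE, n)
  repeat {
    u <- which(!done & is.finite(dist))
    if (length(u) == 0) break
    u <- u[which.min(dist[u])]
    if (u == to) break
    done[u] <- TRUE
    nb <- which(abs(cells$ix - cells$ix[u]) <= 1 &
                  abs(cells$iy - cells$iy[u]) <= 1)
    nb <- nb[nb != u]
    for (v in nb) {
      alt <- dist[u] + hav(u, v)
      if (alt < dist[v]) dist[v] <- alt
    }
  }
  dist[to]
}

# --- generation iteration by naive scalar loops ---------------------------
oracle_iterate <- function(C, n_gen) {
  k <- nrow(C)
  rs <- rowSums(C)
  Ch <- C
  for (i in seq_len(k)) if (rs[i] > 0) Ch[i, ] <- C[i, ] / rs[i]
  A <- C
  for (g in seq_len(n_gen - 1)) {
    B <- matrix(0, k, k)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      s <- 0
      for (m in seq_len(k)) s <- s + A[i, m] * Ch[m, j]
      v <- A[i, j] + s - A[i, j] * s
      B[i, j] <- min(v, 1)
    }
    if (max(abs(B - A)) < 1e-12) { A <- B; break }
    A <- B
  }
  A
}

# --- rarefied allele count by exhaustive gene-subset enumeration ----------
oracle_rarefaction <- function(counts, gsize) {
  genes <- rep(seq_along(counts), counts)
  combs <- utils::combn(length(genes), gsize)
  mean(apply(combs, 2, function(ix) length(unique(genes[ix]))))
}

# --- daily degree-day accumulation, brute force ---------------------------
oracle_exceedance <- function(sst, year, t_base = 13, threshold = 1000) {
  start <- as.Date(sprintf("%d-02-01", year))
  d <- start
  acc <- 0
  repeat {
    temp <- sst$temp[sst$date == d]
    if (length(temp) == 0) return(as.Date(NA))
    acc <- acc + max(temp - t_base, 0)
    if (acc >= threshold) return(d + 1)
    d <- d + 1
  }
}

# --- Jost D from the published formula, direct evaluation -----------------
oracle_dest_locus <- function(counts) { # counts: pops x alleles
  n <- rowSums(counts) / 2
  k <- nrow(counts)
  p <- sweep(counts, 1, 2 * n, "/")
  nh <- k / sum(1 / n)
  hs <- 1 - mean(rowSums(p^2))
  ht <- 1 - sum(colMeans(p)^2)
  hs_e <- 2 * nh / (2 * nh - 1) * hs
  ht_e <- ht + hs_e / (2 * nh * k)
  (ht_e - hs_e) / (1 - hs_e) * k / (k - 1)
}
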