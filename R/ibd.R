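#' Great-circle distance matrix between sites
#'
#' Haversine distances (sphere radius 6371 km) between population
#' coordinates: the "Euclidean" straight-line predictor of
#' isolation-by-distance.
#'
#' @param coords data.frame `pop` (or `site`), `lat`, `lon` in decimal
#'   degrees.
#' @return a `pairwise_matrix` of distances in km (zero diagonal).
#' @export
great_circle_matrix <- function(coords) {
  lab <- coords[[if ("pop" %in% names(coords)) "pop" else "site"]]
  stop_if(any(abs(coords$lat) > 90), "latitude outside [-90, 90]")
  stop_if(any(abs(coords$lon) > 360), "longitude outside [-360, 360]")
  n <- nrow(coords)
  D <- matrix(0, n, n, dimnames = list(lab, lab))
  p <- cbind(coords$lon, coords$lat)
  for (i in seq_len(n - 1)) {
    d <- geosphere::distHaversine(p[i, , drop = FALSE],
                                  p[seq(i + 1, n), , drop = FALSE],
                                  r = 6371000) / 1000
    D[i, seq(i + 1, n)] <- d
    D[seq(i + 1, n), i] <- d
  }
  pairwise_matrix(D, "zero", "great-circle km")
}

#' Shortest sea-path distance matrix
#'
#' Replaces hand-measured "oceanographic" distances with a reproducible
#' computation: sites are snapped to their nearest sea cell and Dijkstra
#' shortest paths are taken on the 8-connected sea-cell lattice with
#' great-circle edge weights, so routes cannot cross land.
#'
#' @param coords data.frame `pop`/`site`, `lat`, `lon`.
#' @param field a `current_field` (its `land` mask and grid are used), or a
#'   list with `lon`, `lat`, `land`.
#' @return a `pairwise_matrix` of sea distances in km.
#' @export
sea_path_matrix <- function(coords, field) {
  lab <- coords[[if ("pop" %in% names(coords)) "pop" else "site"]]
  lon <- field$lon; lat <- field$lat; land <- field$land
  nx <- length(lon); ny <- length(lat)
  sea <- which(!land) # column-major cell ids
  stop_if(length(sea) == 0, "mask has no sea cells")
  node_id <- match(seq_len(nx * ny), sea) # cell -> node or NA

  # 8-connected edges between sea cells, weighted by great-circle length
  edges <- list(); wts <- list()
  cell_xy <- function(cid) cbind((cid - 1) %% nx + 1, (cid - 1) %/% nx + 1)
  xy <- cell_xy(sea)
  for (sh in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    x2 <- xy[, 1] + sh[1]; y2 <- xy[, 2] + sh[2]
    ok <- x2 >= 1 & x2 <= nx & y2 >= 1 & y2 <= ny
    cid2 <- (y2[ok] - 1) * nx + x2[ok]
    from <- node_id[sea[ok]]; to <- node_id[cid2]
    keep <- !is.na(to)
    if (!any(keep)) next
    a <- xy[ok, , drop = FALSE][keep, , drop = FALSE]
    b <- cell_xy(cid2[keep])
    w <- geosphere::distHaversine(cbind(lon[a[, 1]], lat[a[, 2]]),
                                  cbind(lon[b[, 1]], lat[b[, 2]]),
                                  r = 6371000) / 1000
    edges[[length(edges) + 1L]] <- rbind(from[keep], to[keep])
    wts[[length(wts) + 1L]] <- w
  }
  g <- igraph::make_empty_graph(n = length(sea), directed = FALSE)
  g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  igraph::E(g)$weight <- unlist(wts)

  # snap each site to the nearest sea cell
  snap <- integer(nrow(coords))
  for (i in seq_len(nrow(coords))) {
    d2 <- (lon[xy[, 1]] - coords$lon[i])^2 + (lat[xy[, 2]] - coords$lat[i])^2
    snap[i] <- which.min(d2)
  }
  D <- igraph::distances(g, v = snap, to = snap, algorithm = "dijkstra")
  dimnames(D) <- list(lab, lab)
  if (any(!is.finite(D))) {
    bad <- which(!is.finite(D), arr.ind = TRUE)[1, ]
    stop(sprintf("no sea path between %s and %s (site enclosed by land)",
                 lab[bad[1]], lab[bad[2]]), call. = FALSE)
  }
  diag(D) <- 0
  pairwise_matrix(D, "zero", "sea-path km")
}

#' Connectivity-derived dissimilarity matrix
#'
#' Converts an (iterated) connectivity matrix into a distance-like predictor:
#' the symmetrized flow `s = (C_ij + C_ji)/2` is mapped to `-log(s + eps)`
#' with `eps` half the smallest positive symmetrized flow, which keeps
#' zero-flow pairs strictly farthest without infinities. Distance decreases
#' monotonically with flow.
#'
#' @param C square connectivity matrix with site/population labels.
#' @return a `pairwise_matrix` dissimilarity.
#' @export
connectivity_distance <- function(C) {
  C <- unclass(C)
  stop_if(nrow(C) != ncol(C), "matrix not square")
  s <- (C + t(C)) / 2
  diag(s) <- 0
  pos <- s[s > 0]
  stop_if(length(pos) == 0, "all-zero connectivity matrix")
  eps <- min(pos) / 2
  d <- -log(s + eps)
  diag(d) <- 0
  pairwise_matrix(d, "zero", "-log accumulated flow")
}

#' Mantel permutation test of matrix correlation
#'
#' Pearson correlation of the off-diagonal lower triangles of two labelled
#' distance matrices; significance from jointly permuting the row/column
#' order of the second matrix. One-tailed for positive association
#' (`p = (1 + #{r_perm >= r_obs}) / (n_perm + 1)`), the conventional tail
#' for isolation-by-distance. Optionally linearizes genetic distance as
#' `FST/(1 - FST)` before correlating (off by default: the raw regression).
#'
#' @param genetic labelled symmetric matrix (e.g. pairwise FST).
#' @param geographic labelled symmetric distance matrix; labels must match
#'   `genetic` after exclusions.
#' @param n_perm permutations (default 10000).
#' @param exclude labels to drop from both matrices first (e.g. a site whose
#'   larval exchange is blocked by artificial structures).
#' @param linearize apply the `FST/(1 - FST)` transform to `genetic`.
#' @param seed optional integer seed.
#' @return a `mantel_result`: list `r`, `p`, `n_perm`, `n`, `excluded`.
#' @export
mantel <- function(genetic, geographic, n_perm = 10000, exclude = NULL,
                   linearize = FALSE, seed = NULL) {
  g <- as.matrix(genetic); d <- as.matrix(geographic)
  keep <- setdiff(rownames(g), exclude)
  stop_if(length(keep) < 4, "need >= 4 populations for a Mantel test")
  miss <- setdiff(keep, rownames(d))
  stop_if(length(miss) > 0, "labels absent from geographic matrix: %s",
          paste(miss, collapse = ", "))
  g <- g[keep, keep]; d <- d[keep, keep]
  if (linearize) g <- g / (1 - g)
  if (!is.null(seed)) set.seed(seed)
  lt <- lower.tri(g)
  r_obs <- stats::cor(g[lt], d[lt])
  hits <- 0L
  n <- length(keep)
  for (b in seq_len(n_perm)) {
    o <- sample(n)
    if (stats::cor(g[lt], d[o, o][lt]) >= r_obs - 1e-12) hits <- hits + 1L
  }
  structure(list(r = r_obs, p = (1 + hits) / (n_perm + 1), n_perm = n_perm,
                 n = n, excluded = exclude %||% character()),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4f, one-tailed P = %.4g (%d permutations, n = %d)\n",
              x$r, x$p, x$n_perm, x$n))
  if (length(x$excluded))
    cat("excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
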