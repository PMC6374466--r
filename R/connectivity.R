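#' Annual connectivity matrix from particle fates
#'
#' Entry (i, j) is the fraction of particles released from site i that
#' settled at site j: settled(i -> j) / released(i). Released counts come
#' from the schedule (window length x particles per day); a site with no
#' spawning that year contributes a zero row with a warning.
#'
#' @param fates a `particle_fates` data.frame ([advect()]).
#' @param schedule the `spawning_schedule` the fates were produced from.
#' @param sites character vector fixing matrix order (default: schedule
#'   sites in order of appearance).
#' @return a `connectivity_matrix` (source x sink) with attribute
#'   `released` (per-source release counts).
#' @export
build_connectivity <- function(fates, schedule, sites = NULL) {
  sites <- sites %||% unique(schedule$site)
  k <- length(sites)
  released <- stats::setNames(numeric(k), sites)
  for (r in seq_len(nrow(schedule))) {
    s <- schedule$site[r]
    if (!s %in% sites || !schedule$spawned[r]) next
    ndays <- as.numeric(schedule$window_end[r] - schedule$window_start[r]) + 1
    released[s] <- released[s] + ndays * schedule$particles_per_day[r]
  }
  if (any(released == 0)) {
    warning(sprintf("no particles released from: %s",
                    paste(sites[released == 0], collapse = ", ")))
  }
  C <- matrix(0, k, k, dimnames = list(sites, sites))
  st <- fates[fates$outcome == "settled", , drop = FALSE]
  for (r in seq_len(nrow(st))) {
    C[st$source[r], st$settle_site[r]] <-
      C[st$source[r], st$settle_site[r]] + st$n[r]
  }
  C <- C / ifelse(released == 0, 1, released) # rows recycle released
  structure(C, released = released,
            class = c("connectivity_matrix", "matrix", "array"))
}

#' Element-wise mean of annual connectivity matrices
#'
#' Site-years with no spawning enter as zero rows and are counted in the
#' denominator: the average is over all supplied years.
#'
#' @param matrices non-empty list of equally shaped connectivity matrices.
#' @return the averaged `connectivity_matrix`.
#' @export
average_years <- function(matrices) {
  stop_if(length(matrices) == 0, "empty matrix list")
  d <- dim(matrices[[1]])
  for (m in matrices) stop_if(!all(dim(m) == d), "matrix shapes differ")
  out <- Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
  structure(out, class = c("connectivity_matrix", "matrix", "array"))
}

#' Multi-generation accumulation of dispersal
#'
#' Iterates the single-generation connectivity to the stepping-stone limit:
#' with `Chat` the row-normalized chain (rows scaled by their settling
#' total; empty rows stay zero), the accumulated matrix follows
#' `A[1] = C`, `A[g+1] = A[g] (+) A[g] %*% Chat` where `(+)` is the
#' element-wise saturating combine `a + b - a*b`. Entries are monotonically
#' non-decreasing in g and capped at 1; iteration stops when the largest
#' element change drops below `tol` or after `n_gen` generations.
#'
#' @param C square single-generation `connectivity_matrix` (values >= 0).
#' @param n_gen maximum generations (default 1000).
#' @param tol early-stopping tolerance on the max element change
#'   (default 1e-9).
#' @return list `matrix` (accumulated), `generations` (performed),
#'   `trace` (per-generation max element change).
#' @export
iterate_generations <- function(C, n_gen = 1000, tol = 1e-9) {
  C <- unclass(C)
  stop_if(nrow(C) != ncol(C), "connectivity matrix must be square")
  stop_if(any(C < 0), "negative connectivity entries")
  rs <- rowSums(C)
  Chat <- C / ifelse(rs == 0, 1, rs)
  A <- C
  trace <- numeric(0)
  g <- 1L
  while (g < n_gen) {
    step <- A %*% Chat
    Anew <- A + step - A * step
    Anew <- pmin(Anew, 1)
    delta <- max(abs(Anew - A))
    trace <- c(trace, delta)
    A <- Anew
    g <- g + 1L
    if (delta < tol) break
  }
  list(matrix = structure(A, class = c("connectivity_matrix", "matrix",
                                       "array")),
       generations = g, trace = trace)
}

#' Aggregate a site-level connectivity matrix to regions
#'
#' The region entry (a, b) is the mean over source sites in region a of the
#' summed probabilities into the sink sites of region b.
#'
#' @param C site-level `connectivity_matrix`.
#' @param region_map named character vector site -> region.
#' @return region x region matrix.
#' @export
aggregate_regions <- function(C, region_map) {
  sites <- rownames(C)
  miss <- setdiff(sites, names(region_map))
  stop_if(length(miss) > 0, "unmapped site(s): %s", paste(miss, collapse = ", "))
  regions <- unique(unname(region_map[sites]))
  R <- matrix(0, length(regions), length(regions),
              dimnames = list(regions, regions))
  for (a in regions) {
    src <- sites[region_map[sites] == a]
    for (b in regions) {
      snk <- sites[region_map[sites] == b]
      R[a, b] <- mean(rowSums(C[src, snk, drop = FALSE]))
    }
  }
  R
}
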