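#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centres the squared-distance (Gower) matrix and eigendecomposes it
#' (`stats::cmdscale`); axes are ordered by eigenvalue and the percentage of
#' variance per axis is the eigenvalue over the sum of positive eigenvalues.
#' Used to visualise cryptic-lineage separation from individual-level
#' allelic distances ([allelic_distance()]) or population-level matrices.
#'
#' @param distance symmetric distance matrix (or `dist`).
#' @param n_axes number of axes to return (default 2).
#' @return list `coords` (n x n_axes), `eig` (all eigenvalues),
#'   `pct_var` (percent variance per returned axis).
#' @export
pcoa <- function(distance, n_axes = 2) {
  if (inherits(distance, "dist")) distance <- as.matrix(distance)
  stop_if(nrow(distance) != ncol(distance), "distance matrix not square")
  stop_if(any(abs(distance - t(distance)) > 1e-8), "distance matrix not symmetric")
  n <- nrow(distance)
  n_axes <- min(n_axes, n - 1)
  # cmdscale warns when fewer than n_axes positive eigenvalues exist; the
  # degenerate case is handled below by zero-padding
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(distance), k = n_axes, eig = TRUE))
  pos <- sum(fit$eig[fit$eig > 1e-12])
  pct <- if (pos > 0) 100 * fit$eig[seq_len(n_axes)] / pos else
    rep(0, n_axes)
  coords <- fit$points
  if (is.null(coords) || ncol(coords) < n_axes) {
    # degenerate (e.g. all-zero distances): pad with zero coordinates
    coords <- cbind(coords, matrix(0, n, n_axes - ncol(coords)))
    rownames(coords) <- rownames(distance)
  }
  list(coords = coords, eig = fit$eig, pct_var = pct)
}
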