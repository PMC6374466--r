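`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) {
  if (cond) stop(sprintf(...), call. = FALSE)
}

#' Sample one draw from a Dirichlet distribution
#'
#' @param alpha positive concentration vector.
#' @return numeric vector summing to 1.
#' @keywords internal
rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) { # all shapes tiny: fall back to a single category
    x[sample.int(length(x), 1L)] <- 1
  }
  x / sum(x)
}

#' Harmonic mean
#' @keywords internal
harmonic_mean <- function(x) length(x) / sum(1 / x)

# canonical region-class labels used throughout the package
REGION_CLASSES <- c("recent_temperate", "pre_existing_temperate", "subtropical")
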