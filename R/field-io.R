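#' Write / read a gridded current field as plain-text CSV
#'
#' Long-format exchange for gridded surface fields using the usual variable
#' convention (`time`, `lon`, `lat`, `u`, `v`, `land`), one row per cell and
#' snapshot. Suited to the modest synthetic grids used here; externally
#' produced fields can be converted to this layout with any array tool.
#'
#' @param field a `current_field`.
#' @param path CSV path.
#' @export
write_current_field <- function(field, path) {
  G <- expand.grid(lon = field$lon, lat = field$lat)
  rows <- lapply(seq_along(field$time), function(it) {
    data.frame(time = format(field$time[it]), lon = G$lon, lat = G$lat,
               u = as.vector(field$u[, , it]), v = as.vector(field$v[, , it]),
               land = as.integer(as.vector(field$land)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_current_field
#' @return `read_current_field`: the reconstructed `current_field`.
#' @export
read_current_field <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if(!all(c("time", "lon", "lat", "u", "v", "land") %in% names(d)),
          "field file needs columns time, lon, lat, u, v, land")
  lon <- sort(unique(d$lon)); lat <- sort(unique(d$lat))
  times <- sort(unique(as.Date(d$time)))
  nx <- length(lon); ny <- length(lat); nt <- length(times)
  u <- array(NA_real_, c(nx, ny, nt)); v <- array(NA_real_, c(nx, ny, nt))
  land <- matrix(FALSE, nx, ny)
  ix <- match(d$lon, lon); iy <- match(d$lat, lat)
  it <- match(as.Date(d$time), times)
  u[cbind(ix, iy, it)] <- d$u
  v[cbind(ix, iy, it)] <- d$v
  land[cbind(ix, iy)] <- d$land == 1
  stop_if(anyNA(u), "incomplete grid in field file")
  make_current_field(lon, lat, times, u, v, land)
}
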