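#' Configuration for the synthetic ocean generator
#'
#' Describes a gridded coastal ocean with a western-boundary-current jet, an
#' optional eddy-noise field, a land mask built from polygons, and a
#' latitude-dependent seasonal sea-surface temperature (SST) climatology.
#' This is the stand-in for reanalysis current products when testing the
#' dispersal pipeline.
#'
#' @param lon_range,lat_range numeric length-2, domain extent in decimal
#'   degrees.
#' @param cell_deg grid cell size in degrees (default 1/12 degree, the
#'   resolution of the habitat cells used downstream).
#' @param start first day of the field (`Date` or string).
#' @param n_days length of the simulated span in days.
#' @param snapshot_days spacing of stored velocity snapshots in days
#'   (velocities are interpolated linearly in time between snapshots).
#' @param jet list: `path` (data.frame `lon`, `lat` polyline of the jet core),
#'   `width_deg` (Gaussian cross-jet e-folding width), `peak_ms` (core speed,
#'   m/s).
#' @param eddy_amp amplitude (m/s) of a smooth random-phase eddy field added
#'   to the jet; 0 disables it.
#' @param land_polys list of data.frames (`lon`, `lat`) whose interiors are
#'   land; velocities are zero on land cells.
#' @param sst list: `mean_coef` `c(a0, a1)` so the annual-mean SST at a site
#'   is `a0 + a1 * lat` (deg C), `amplitude` (seasonal half-range, deg C),
#'   `phase_day` (day offset of the seasonal sine).
#' @param seed integer seed for the eddy field.
#' @return a `sim_ocean_config` list.
#' @export
sim_ocean_config <- function(lon_range = c(127, 135), lat_range = c(24, 34),
                             cell_deg = 1 / 12,
                             start = "1993-01-01", n_days = 365,
                             snapshot_days = 5,
                             jet = list(path = data.frame(
                               lon = c(128.0, 128.3, 130.0, 133.0, 135.0),
                               lat = c(24.0, 28.5, 31.5, 32.8, 33.5)),
                               width_deg = 0.8, peak_ms = 1.2),
                             eddy_amp = 0.1, land_polys = list(),
                             sst = list(mean_coef = c(38, -0.55),
                                        amplitude = 5, phase_day = 122),
                             seed = 1L) {
  stop_if(cell_deg <= 0, "cell size must be > 0")
  stop_if(diff(lon_range) <= 0 || diff(lat_range) <= 0, "empty grid extent")
  stop_if(n_days < 1, "empty time span")
  stop_if(jet$peak_ms < 0, "peak speed must be >= 0")
  structure(list(lon_range = lon_range, lat_range = lat_range,
                 cell_deg = cell_deg, start = as.Date(start),
                 n_days = n_days, snapshot_days = snapshot_days,
                 jet = jet, eddy_amp = eddy_amp, land_polys = land_polys,
                 sst = sst, seed = as.integer(seed)),
            class = "sim_ocean_config")
}

# even-odd ray casting; pts: matrix [n,2] (lon,lat); poly: data.frame lon/lat
points_in_poly <- function(px, py, poly) {
  n <- length(px)
  inside <- logical(n)
  xs <- poly$lon; ys <- poly$lat
  m <- length(xs)
  j <- m
  for (i in seq_len(m)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# distance (deg) and unit tangent (metric-weighted) from points to a polyline
polyline_dist_tangent <- function(px, py, path) {
  n <- length(px)
  best <- rep(Inf, n); tx <- numeric(n); ty <- numeric(n)
  for (s in seq_len(nrow(path) - 1)) {
    x1 <- path$lon[s]; y1 <- path$lat[s]
    x2 <- path$lon[s + 1]; y2 <- path$lat[s + 1]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx^2 + dy^2
    t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
    qx <- x1 + t * dx; qy <- y1 + t * dy
    d <- sqrt((px - qx)^2 + (py - qy)^2)
    upd <- d < best
    best[upd] <- d[upd]
    # tangent as a unit vector in local metric coordinates (east, north)
    mx <- dx * cos(((y1 + y2) / 2) * pi / 180); my <- dy
    ml <- sqrt(mx^2 + my^2)
    tx[upd] <- mx / ml; ty[upd] <- my / ml
  }
  list(dist = best, tx = tx, ty = ty)
}

#' Generate a synthetic current field and per-site SST series
#'
#' Builds a gridded surface-velocity field consisting of a Gaussian-profile
#' jet flowing along a prescribed core path (speed = `peak_ms` on the core,
#' decaying with cross-jet distance), plus an optional smooth random-phase
#' eddy field, with zero velocity on land cells. SST at each requested site
#' follows `mean(lat) + amplitude * sin(2*pi*(day - phase)/365.25)` with
#' `day` counted from January 1 of the start year.
#'
#' @param config a [sim_ocean_config()].
#' @param sites optional data.frame (`site`, `lon`, `lat`) of sites at which
#'   daily SST series are produced.
#' @return list with elements `field` (a `current_field`: `lon`, `lat` cell
#'   centres, `time` (Dates of snapshots), `u`, `v` arrays
#'   `[lon, lat, time]` in m/s, `land` logical matrix) and `sst` (named list
#'   of data.frames `date`, `temp`, one per site; empty if no sites given).
#' @export
generate_ocean <- function(config, sites = NULL) {
  stopifnot(inherits(config, "sim_ocean_config"))
  set.seed(config$seed)
  h <- config$cell_deg
  lon <- seq(config$lon_range[1] + h / 2, config$lon_range[2] - h / 2, by = h)
  lat <- seq(config$lat_range[1] + h / 2, config$lat_range[2] - h / 2, by = h)
  stop_if(length(lon) == 0 || length(lat) == 0, "empty grid")
  times <- seq(0, config$n_days - 1, by = config$snapshot_days)
  nt <- length(times)

  G <- expand.grid(lon = lon, lat = lat) # lon varies fastest
  land <- rep(FALSE, nrow(G))
  for (poly in config$land_polys) {
    land <- land | points_in_poly(G$lon, G$lat, poly)
  }
  land_mat <- matrix(land, length(lon), length(lat))

  pj <- polyline_dist_tangent(G$lon, G$lat, config$jet$path)
  speed <- config$jet$peak_ms * exp(-(pj$dist / config$jet$width_deg)^2)
  u0 <- speed * pj$tx; v0 <- speed * pj$ty
  u0[land] <- 0; v0[land] <- 0

  u <- array(0, c(length(lon), length(lat), nt))
  v <- array(0, c(length(lon), length(lat), nt))
  n_modes <- 6L
  kx <- stats::runif(n_modes, 0.5, 3); ky <- stats::runif(n_modes, 0.5, 3)
  om <- stats::runif(n_modes, 2 * pi / 60, 2 * pi / 15)
  ph_u <- stats::runif(n_modes, 0, 2 * pi); ph_v <- stats::runif(n_modes, 0, 2 * pi)
  for (it in seq_len(nt)) {
    eu <- 0; ev <- 0
    if (config$eddy_amp > 0) {
      for (m in seq_len(n_modes)) {
        arg <- kx[m] * G$lon + ky[m] * G$lat + om[m] * times[it]
        eu <- eu + sin(arg + ph_u[m])
        ev <- ev + cos(arg + ph_v[m])
      }
      eu <- config$eddy_amp * eu / sqrt(n_modes)
      ev <- config$eddy_amp * ev / sqrt(n_modes)
      eu[land] <- 0; ev[land] <- 0
    }
    u[, , it] <- matrix(u0 + eu, length(lon), length(lat))
    v[, , it] <- matrix(v0 + ev, length(lon), length(lat))
  }

  field <- structure(list(lon = lon, lat = lat,
                          time = config$start + times,
                          u = u, v = v, land = land_mat,
                          cell_deg = h),
                     class = "current_field")

  sst <- list()
  if (!is.null(sites)) {
    origin <- as.Date(format(config$start, "%Y-01-01"))
    dates <- config$start + seq_len(config$n_days) - 1
    day <- as.numeric(dates - origin)
    for (i in seq_len(nrow(sites))) {
      mu <- config$sst$mean_coef[1] + config$sst$mean_coef[2] * sites$lat[i]
      temp <- mu + config$sst$amplitude *
        sin(2 * pi * (day - config$sst$phase_day) / 365.25)
      sst[[as.character(sites$site[i])]] <- data.frame(date = dates,
                                                       temp = temp)
    }
  }
  list(field = field, sst = sst)
}

#' Velocity at arbitrary points and time (bilinear in space, linear in time)
#'
#' @param field a `current_field`.
#' @param lon,lat numeric vectors of positions (decimal degrees).
#' @param when `Date` (or numeric days from the field start) of the query.
#' @return list `u`, `v` (m/s); 0 on land cells. Queries beyond the
#'   cell-centre hull use the nearest cell (constant extrapolation).
#' @export
field_velocity <- function(field, lon, lat, when) {
  t_num <- as.numeric(as.Date(when) - field$time[1])
  tt <- as.numeric(field$time - field$time[1])
  nt <- length(tt)
  t_num <- min(max(t_num, tt[1]), tt[nt])
  it <- min(max(findInterval(t_num, tt), 1L), nt)
  w <- if (it >= nt) 0 else (t_num - tt[it]) / (tt[it + 1] - tt[it])
  interp2 <- function(arr) {
    a <- bilinear_slice(field, arr[, , it], lon, lat)
    if (w == 0) return(a)
    b <- bilinear_slice(field, arr[, , it + 1], lon, lat)
    (1 - w) * a + w * b
  }
  u <- interp2(field$u); v <- interp2(field$v)
  # land cells are zero-velocity by construction of the snapshots; out of
  # grid is NA from the interpolator
  list(u = u, v = v)
}

# bilinear interpolation of one snapshot at vectors of points; queries are
# clamped to the cell-centre hull (constant extrapolation at the margins,
# so particles keep a finite velocity until they cross the outer cell edge)
bilinear_slice <- function(field, slice, lon, lat) {
  nx <- length(field$lon); ny <- length(field$lat)
  x1 <- field$lon[1]; y1 <- field$lat[1]; h <- field$cell_deg
  fx <- pmin(pmax((lon - x1) / h, 0), nx - 1)
  fy <- pmin(pmax((lat - y1) / h, 0), ny - 1)
  ix <- pmin(pmax(floor(fx), 0), nx - 2)
  iy <- pmin(pmax(floor(fy), 0), ny - 2)
  wx <- fx - ix; wy <- fy - iy
  i <- ix + 1L; j <- iy + 1L
  v11 <- slice[cbind(i, j)]; v21 <- slice[cbind(i + 1L, j)]
  v12 <- slice[cbind(i, j + 1L)]; v22 <- slice[cbind(i + 1L, j + 1L)]
  (1 - wx) * (1 - wy) * v11 + wx * (1 - wy) * v21 +
    (1 - wx) * wy * v12 + wx * wy * v22
}

#' Grid cell index of points in a current field
#' @param field a `current_field`.
#' @param lon,lat positions.
#' @return integer matrix with columns `ix`, `iy` (NA outside the grid).
#' @export
field_cell <- function(field, lon, lat) {
  h <- field$cell_deg
  ix <- floor((lon - (field$lon[1] - h / 2)) / h) + 1L
  iy <- floor((lat - (field$lat[1] - h / 2)) / h) + 1L
  ix[ix < 1L | ix > length(field$lon)] <- NA_integer_
  iy[iy < 1L | iy > length(field$lat)] <- NA_integer_
  bad <- is.na(ix) | is.na(iy)
  ix[bad] <- NA_integer_; iy[bad] <- NA_integer_
  cbind(ix = ix, iy = iy)
}

# mean synodic month, days
SYNODIC_DAYS <- 29.530588

#' Full-moon dates as a synodic-period arithmetic progression
#'
#' A deterministic lunar calendar: full moons at
#' `reference + k * 29.530588` days, truncated to `[start, end]` and rounded
#' to whole days. No ephemeris; sufficient for spawning-window scheduling.
#'
#' @param start,end span (Date or string), `start < end`.
#' @param reference_full_moon a known full-moon date anchoring the
#'   progression (default 2000-01-21).
#' @return strictly increasing vector of `Date`s.
#' @export
generate_moon_table <- function(start, end,
                                reference_full_moon = "2000-01-21") {
  start <- as.Date(start); end <- as.Date(end)
  stop_if(start >= end, "start must precede end")
  ref <- as.numeric(as.Date(reference_full_moon))
  lo <- ceiling((as.numeric(start) - ref) / SYNODIC_DAYS)
  hi <- floor((as.numeric(end) - ref) / SYNODIC_DAYS)
  if (hi < lo) return(as.Date(character()))
  d <- as.Date(round(ref + (lo:hi) * SYNODIC_DAYS),
               origin = "1970-01-01")
  d[d >= start & d <= end]
}
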