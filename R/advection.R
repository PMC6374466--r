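#' Assemble a current field from raw arrays
#'
#' Constructor used both by the synthetic generator and when loading gridded
#' fields from file; also the convenient way to build analytic fields
#' (uniform flow, solid-body rotation) for verification.
#'
#' @param lon,lat cell-centre coordinate vectors (regular spacing).
#' @param time vector of snapshot `Date`s.
#' @param u,v arrays `[lon, lat, time]`, m/s.
#' @param land logical matrix `[lon, lat]`, `TRUE` on land.
#' @return a `current_field`.
#' @export
make_current_field <- function(lon, lat, time, u, v, land = NULL) {
  stop_if(length(lon) < 2 || length(lat) < 2, "grid too small")
  land <- land %||% matrix(FALSE, length(lon), length(lat))
  stop_if(!all(dim(land) == c(length(lon), length(lat))),
          "land mask shape does not match grid")
  if (length(dim(u)) == 2) u <- array(u, c(dim(u), length(time)))
  if (length(dim(v)) == 2) v <- array(v, c(dim(v), length(time)))
  stop_if(!all(dim(u) == c(length(lon), length(lat), length(time))),
          "u array shape does not match grid/time")
  u[is.na(u)] <- 0; v[is.na(v)] <- 0
  for (it in seq_along(time)) {
    ui <- u[, , it]; vi <- v[, , it]
    ui[land] <- 0; vi[land] <- 0
    u[, , it] <- ui; v[, , it] <- vi
  }
  structure(list(lon = lon, lat = lat, time = as.Date(time), u = u, v = v,
                 land = land, cell_deg = lon[2] - lon[1]),
            class = "current_field")
}

#' Habitat-cell grid
#'
#' Snaps site release points to grid cells of the field and validates that
#' they are sea cells. Habitat cells are single grid-resolution rectangles;
#' a particle occupying one (after competency) settles there.
#'
#' @param field a `current_field`.
#' @param sites data.frame `site`, `lon`, `lat`, and optionally `region`.
#' @return a `habitat_grid` data.frame with cell indices `ix`, `iy`.
#' @export
make_habitat_grid <- function(field, sites) {
  stop_if(anyDuplicated(sites$site) > 0, "duplicate site identifiers")
  cells <- field_cell(field, sites$lon, sites$lat)
  stop_if(anyNA(cells), "site(s) outside the grid: %s",
          paste(sites$site[is.na(cells[, 1])], collapse = ", "))
  on_land <- field$land[cells]
  stop_if(any(on_land), "site(s) on land cells: %s",
          paste(sites$site[on_land], collapse = ", "))
  out <- data.frame(site = as.character(sites$site), lon = sites$lon,
                    lat = sites$lat, ix = cells[, "ix"], iy = cells[, "iy"],
                    region = if ("region" %in% names(sites))
                      as.character(sites$region) else NA_character_)
  class(out) <- c("habitat_grid", "data.frame")
  out
}

METRES_PER_DEG <- 111320

#' Lagrangian particle tracking with settlement
#'
#' Integrates passive surface particles through the field with a 4th-order
#' Runge-Kutta step on velocities interpolated bilinearly in space and
#' linearly in time; degree/metre conversion uses the local
#' `cos(latitude)`. Particles are released at each site's point on every day
#' of its spawning window. A particle settles in the first habitat cell it
#' occupies at age >= `competency_min` days (its natal cell included, so
#' self-recruitment is possible); a particle still unsettled at `pld_max`
#' days expires; a particle carried off the grid exits the domain. Particles
#' attempting to enter a land cell are held at their previous position
#' (no-flux); they do not die.
#'
#' Without diffusion the trajectory is deterministic, so the particles of
#' one site-day cohort are identical: each cohort is integrated once and its
#' fate carries the cohort size `n`.
#'
#' @param field a `current_field`.
#' @param schedule a `spawning_schedule` ([build_spawning_schedule()]).
#' @param habitat a `habitat_grid` ([make_habitat_grid()]); release points.
#' @param pld_max maximum pelagic larval duration, days (default 42).
#' @param competency_min earliest settleable age, days (default 3).
#' @param dt_days integration step in days (default 2 hours); must be in
#'   `(0, 1]`.
#' @param diffusion optional random-walk diffusivity (m^2/s, default 0:
#'   purely passive advection). With diffusion each particle is integrated
#'   individually.
#' @param seed integer seed (only used when `diffusion > 0`).
#' @param record_trajectory keep each cohort's positions at every step
#'   (attribute `trajectories`: list of matrices `t`, `lon`, `lat`); off by
#'   default.
#' @return a `particle_fates` data.frame: `source`, `release_date`,
#'   `outcome` (`settled`/`expired`/`exited`), `settle_site`, `age_days`,
#'   `n` (particles sharing this fate).
#' @export
advect <- function(field, schedule, habitat, pld_max = 42,
                   competency_min = 3, dt_days = 2 / 24, diffusion = 0,
                   seed = NULL, record_trajectory = FALSE) {
  stop_if(dt_days <= 0 || dt_days > 1, "dt_days must be in (0, 1]")
  sched <- schedule[schedule$spawned, , drop = FALSE]
  if (nrow(sched) == 0) {
    return(empty_fates())
  }
  stop_if(!all(sched$site %in% habitat$site),
          "schedule site(s) missing from habitat grid")
  if (!is.null(seed)) set.seed(seed)

  # habitat lookup: cell -> site index
  hab_key <- paste(habitat$ix, habitat$iy)

  # expand releases: one cohort per site-day (or per particle with diffusion)
  rel <- list()
  for (r in seq_len(nrow(sched))) {
    days <- seq(sched$window_start[r], sched$window_end[r], by = 1)
    hrow <- match(sched$site[r], habitat$site)
    for (d in days) {
      n_cohort <- sched$particles_per_day[r]
      reps <- if (diffusion > 0) n_cohort else 1L
      w <- if (diffusion > 0) 1L else n_cohort
      for (q in seq_len(reps)) {
        rel[[length(rel) + 1L]] <- list(site = sched$site[r],
                                        lon = habitat$lon[hrow],
                                        lat = habitat$lat[hrow],
                                        date = as.Date(d, origin = "1970-01-01"),
                                        n = w)
      }
    }
  }
  np <- length(rel)
  lon <- vapply(rel, `[[`, 1, "lon"); lat <- vapply(rel, `[[`, 1, "lat")
  rdate <- as.Date(vapply(rel, function(x) as.numeric(x$date), 1),
                   origin = "1970-01-01")
  src <- vapply(rel, `[[`, "", "site")
  wgt <- as.integer(vapply(rel, function(x) as.numeric(x$n), 1))

  status <- rep("drifting", np)
  settle_site <- rep(NA_character_, np)
  out_age <- rep(NA_real_, np)

  t0 <- min(rdate)
  t_end <- max(rdate) + pld_max
  n_steps <- ceiling(as.numeric(t_end - t0) / dt_days)
  rel_t <- as.numeric(rdate - t0)

  # velocity in degrees/day at positions p (cols lon,lat) and time t (days)
  vel_deg <- function(plon, plat, t) {
    vv <- field_velocity(field, plon, plat, t0 + t)
    u <- vv$u; v <- vv$v
    u[is.na(u)] <- 0; v[is.na(v)] <- 0
    list(dlon = u * 86400 / (METRES_PER_DEG * cos(plat * pi / 180)),
         dlat = v * 86400 / METRES_PER_DEG)
  }

  check_settle <- function(active_idx, age) {
    can <- active_idx[age[active_idx] >= competency_min - 1e-9]
    if (length(can) == 0) return(invisible())
    cells <- field_cell(field, lon[can], lat[can])
    key <- paste(cells[, 1], cells[, 2])
    hit <- match(key, hab_key)
    found <- which(!is.na(hit))
    if (length(found) > 0) {
      idx <- can[found]
      status[idx] <<- "settled"
      settle_site[idx] <<- habitat$site[hit[found]]
      out_age[idx] <<- age[idx]
    }
    invisible()
  }

  age_of <- function(t) t - rel_t
  traj <- if (record_trajectory)
    lapply(seq_len(np), function(i)
      list(t = 0, lon = lon[i], lat = lat[i])) else NULL
  t <- 0
  # settlement check at activation not needed before competency_min > 0
  for (step in seq_len(n_steps)) {
    active <- which(status == "drifting" & rel_t <= t + 1e-9)
    if (length(active) == 0) { t <- t + dt_days; next }

    # expire first: particles at the end of their pelagic duration
    expire <- active[age_of(t)[active] >= pld_max - 1e-9]
    if (length(expire) > 0) {
      status[expire] <- "expired"
      out_age[expire] <- pld_max
      active <- setdiff(active, expire)
    }
    if (length(active) == 0) { t <- t + dt_days; next }

    px <- lon[active]; py <- lat[active]
    k1 <- vel_deg(px, py, t)
    k2 <- vel_deg(px + dt_days / 2 * k1$dlon, py + dt_days / 2 * k1$dlat,
                  t + dt_days / 2)
    k3 <- vel_deg(px + dt_days / 2 * k2$dlon, py + dt_days / 2 * k2$dlat,
                  t + dt_days / 2)
    k4 <- vel_deg(px + dt_days * k3$dlon, py + dt_days * k3$dlat, t + dt_days)
    nx <- px + dt_days / 6 * (k1$dlon + 2 * k2$dlon + 2 * k3$dlon + k4$dlon)
    ny <- py + dt_days / 6 * (k1$dlat + 2 * k2$dlat + 2 * k3$dlat + k4$dlat)
    if (diffusion > 0) {
      sd_m <- sqrt(2 * diffusion * dt_days * 86400)
      nx <- nx + stats::rnorm(length(nx), 0, sd_m) /
        (METRES_PER_DEG * cos(py * pi / 180))
      ny <- ny + stats::rnorm(length(ny), 0, sd_m) / METRES_PER_DEG
    }
    cells <- field_cell(field, nx, ny)
    off <- is.na(cells[, 1])
    if (any(off)) { # left the domain during this step
      idx <- active[off]
      status[idx] <- "exited"
      out_age[idx] <- age_of(t + dt_days)[idx]
    }
    moved <- logical(length(active))
    idx_ok <- which(!off)
    if (length(idx_ok) > 0) {
      landhit <- field$land[cells[idx_ok, , drop = FALSE]]
      moved[idx_ok[!landhit]] <- TRUE # no-flux: land-bound steps are held
    }
    lon[active[moved]] <- nx[moved]
    lat[active[moved]] <- ny[moved]

    t <- t + dt_days
    if (record_trajectory) {
      for (ii in active) {
        traj[[ii]]$t <- c(traj[[ii]]$t, t - rel_t[ii])
        traj[[ii]]$lon <- c(traj[[ii]]$lon, lon[ii])
        traj[[ii]]$lat <- c(traj[[ii]]$lat, lat[ii])
      }
    }
    check_settle(active[status[active] == "drifting"], age_of(t))
  }
  # anything still drifting at the horizon has reached full duration
  left <- which(status == "drifting" & rel_t <= t)
  if (length(left) > 0) { status[left] <- "expired"; out_age[left] <- pld_max }

  out <- data.frame(source = src, release_date = rdate, outcome = status,
                    settle_site = settle_site, age_days = out_age, n = wgt)
  class(out) <- c("particle_fates", "data.frame")
  if (record_trajectory) attr(out, "trajectories") <- traj
  out
}

empty_fates <- function() {
  out <- data.frame(source = character(), release_date = as.Date(character()),
                    outcome = character(), settle_site = character(),
                    age_days = numeric(), n = integer())
  class(out) <- c("particle_fates", "data.frame")
  out
}
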