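one_day_schedule <- function(site, day, ppd = 1L) {
  data.frame(site = site, year = as.integer(format(day, "%Y")),
             spawned = TRUE, exceedance = day, full_moon = day + 3,
             window_start = day, window_end = day, particles_per_day = ppd)
}

flat_field <- function(u_ms, v_ms, lon = seq(128, 134, by = 0.1),
                       lat = seq(28, 33, by = 0.1), days = c(0, 60)) {
  nx <- length(lon); ny <- length(lat)
  make_current_field(lon, lat, as.Date("1993-01-01") + days,
                     array(u_ms, c(nx, ny, length(days))),
                     array(v_ms, c(nx, ny, length(days))))
}

test_that("still water means natal settlement at competency age", {
  f <- flat_field(0, 0)
  sites <- data.frame(site = c("A", "B"), lon = c(129, 132), lat = c(29, 31))
  hab <- make_habitat_grid(f, sites)
  sched <- rbind(one_day_schedule("A", as.Date("1993-02-01"), 50L),
                 one_day_schedule("B", as.Date("1993-02-01"), 50L))
  fates <- advect(f, sched, hab)
  expect_true(all(fates$outcome == "settled"))
  expect_equal(fates$settle_site, fates$source)
  expect_equal(fates$age_days, rep(3, 2), tolerance = 1e-9)
  C <- build_connectivity(fates, sched)
  expect_equal(unclass(C), diag(2), ignore_attr = TRUE)
})

test_that("uniform advection matches the closed-form displacement", {
  u <- 0.25
  f <- flat_field(u, 0)
  sites <- data.frame(site = "A", lon = 129, lat = 30)
  hab <- make_habitat_grid(f, sites)
  sched <- one_day_schedule("A", as.Date("1993-01-02"))
  fates <- advect(f, sched, hab, pld_max = 10, competency_min = 11,
                  dt_days = 2 / 24, record_trajectory = TRUE)
  tr <- attr(fates, "trajectories")[[1]]
  tdays <- 8
  i <- which.min(abs(tr$t - tdays))
  got <- tr$lon[i] - 129
  # longitude advances at u * t / (111320 cos(lat)); latitude is constant
  expected <- u * tdays * 86400 / (111320 * cos(30 * pi / 180))
  expect_lt(abs(got - expected) / expected, 0.001)
  expect_lt(max(abs(tr$lat - 30)), 1e-9)
})

test_that("solid-body rotation returns the particle to its start", {
  # angular velocity chosen for a 10-day period; near-equator grid keeps
  # the metric factor cos(lat) within 0.02% of 1
  lon <- seq(-1, 1, by = 0.05); lat <- seq(-1, 1, by = 0.05)
  period <- 10
  om <- 2 * pi / period # per day, in degree space
  G <- expand.grid(lon = lon, lat = lat)
  u_deg <- -om * G$lat; v_deg <- om * G$lon
  to_ms_u <- u_deg * 111320 * cos(G$lat * pi / 180) / 86400
  to_ms_v <- v_deg * 111320 / 86400
  nx <- length(lon); ny <- length(lat)
  f <- make_current_field(lon, lat, as.Date("1993-01-01") + c(0, 60),
                          array(rep(to_ms_u, 2), c(nx, ny, 2)),
                          array(rep(to_ms_v, 2), c(nx, ny, 2)))
  sites <- data.frame(site = "A", lon = 0.5, lat = 0)
  hab <- make_habitat_grid(f, sites)
  sched <- one_day_schedule("A", as.Date("1993-01-02"))
  fates <- advect(f, sched, hab, pld_max = 12, competency_min = 13,
                  dt_days = 1 / 24, record_trajectory = TRUE)
  tr <- attr(fates, "trajectories")[[1]]
  i <- which.min(abs(tr$t - period))
  # back within one grid cell of the start after one revolution
  expect_lt(sqrt((tr$lon[i] - 0.5)^2 + tr$lat[i]^2), 0.05)
})

test_that("every released particle is accounted for", {
  cfg <- sim_ocean_config(lon_range = c(128, 134), lat_range = c(28, 33),
                          cell_deg = 1 / 12, n_days = 120, eddy_amp = 0.3,
                          seed = 91)
  sites <- sites_along_path(cfg$jet$path, 5)
  sites <- sites[sites$lat < 33 & sites$lat > 28 &
                   sites$lon > 128 & sites$lon < 134, ]
  oc <- generate_ocean(cfg, sites = sites)
  hab <- make_habitat_grid(oc$field, sites)
  sched <- do.call(rbind, lapply(sites$site, function(s)
    one_day_schedule(s, as.Date("1993-01-10"), 20L)))
  fates <- advect(oc$field, sched, hab, pld_max = 20)
  expect_equal(sum(fates$n), nrow(sched) * 20)
  expect_true(all(fates$outcome %in% c("settled", "expired", "exited")))
  settled <- fates$outcome == "settled"
  expect_true(all(fates$age_days[settled] >= 3 - 1e-9))
  expect_true(all(fates$age_days[settled] <= 20 + 1e-9))
  expect_true(all(fates$age_days[fates$outcome == "expired"] == 20))
})

test_that("advection is deterministic and validates its step", {
  f <- flat_field(0.1, 0.05)
  sites <- data.frame(site = "A", lon = 129, lat = 30)
  hab <- make_habitat_grid(f, sites)
  sched <- one_day_schedule("A", as.Date("1993-01-02"), 10L)
  f1 <- advect(f, sched, hab, pld_max = 5)
  f2 <- advect(f, sched, hab, pld_max = 5)
  expect_identical(f1, f2)
  expect_error(advect(f, sched, hab, dt_days = 0), "dt_days")
  expect_error(advect(f, sched, hab, dt_days = 2), "dt_days")
})

test_that("land cells block but do not kill particles", {
  lon <- seq(130, 131, by = 0.1); lat <- seq(30, 31, by = 0.1)
  land <- matrix(FALSE, 11, 11); land[8:11, ] <- TRUE # wall to the east
  f <- make_current_field(lon, lat, as.Date("1993-01-01") + c(0, 30),
                          array(0.5, c(11, 11, 2)), array(0, c(11, 11, 2)),
                          land)
  sites <- data.frame(site = "A", lon = 130.2, lat = 30.5)
  hab <- make_habitat_grid(f, sites)
  sched <- one_day_schedule("A", as.Date("1993-01-02"), 5L)
  fates <- advect(f, sched, hab, pld_max = 6, competency_min = 7)
  # pushed against the wall, never entering land: expires in place
  expect_equal(fates$outcome, "expired")
})
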