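#' Degree-day spawning schedule for one site and year
#'
#' Spawning timing follows the degree-day rule: daily temperature excess over
#' the base (`max(T - t_base, 0)`) is accumulated from the season start
#' (February 1 by default); the exceedance date is the first day on which the
#' cumulative sum reaches `threshold` degree-days. Release is keyed to the
#' lunar calendar: the spawning full moon is the latest full moon on or
#' before the exceedance date, and particles are released daily over a
#' 10-day window opening 3 days before that full moon.
#'
#' @param sst data.frame `date`, `temp` (daily, deg C) covering the season.
#' @param moons vector of full-moon `Date`s ([generate_moon_table()]).
#' @param year calendar year to schedule.
#' @param t_base base temperature, deg C (default 13).
#' @param start_month_day season start as `"MM-DD"` (default `"02-01"`).
#' @param threshold cumulative degree-day threshold (default 1000).
#' @param window_days length of the release window in days (default 10).
#' @param offset_days release starts this many days before the full moon
#'   (default 3).
#' @param particles_per_day particles released per day (default 50).
#' @return one-row data.frame: `year`, `spawned`, `exceedance`, `full_moon`,
#'   `window_start`, `window_end`, `particles_per_day` (dates `NA` when the
#'   threshold is never reached that year).
#' @export
estimate_spawning <- function(sst, moons, year,
                              t_base = 13, start_month_day = "02-01",
                              threshold = 1000, window_days = 10,
                              offset_days = 3, particles_per_day = 50) {
  start <- as.Date(sprintf("%d-%s", year, start_month_day))
  end_of_year <- as.Date(sprintf("%d-12-31", year))
  s <- sst[sst$date >= start & sst$date <= end_of_year, ]
  stop_if(nrow(s) == 0, "SST series does not cover %d from %s", year,
          format(start))
  s <- s[order(s$date), ]
  cum <- cumsum(pmax(s$temp - t_base, 0))
  hit <- which(cum >= threshold)[1]
  no_spawn <- data.frame(year = year, spawned = FALSE,
                         exceedance = as.Date(NA), full_moon = as.Date(NA),
                         window_start = as.Date(NA), window_end = as.Date(NA),
                         particles_per_day = 0L)
  if (is.na(hit)) return(no_spawn)
  # each day's degree-days accrue by the end of that day: with constant
  # 10 degC excess the 1000 degC day integral completes 100 days after start
  exceed <- s$date[hit] + 1L
  cand <- moons[moons <= exceed & moons >= as.Date(sprintf("%d-01-01", year))]
  stop_if(length(cand) == 0,
          "no full moon in %d on or before exceedance (%s)", year,
          format(exceed))
  fm <- max(cand)
  ws <- fm - offset_days
  data.frame(year = year, spawned = TRUE, exceedance = exceed,
             full_moon = fm, window_start = ws,
             window_end = ws + window_days - 1,
             particles_per_day = as.integer(particles_per_day))
}

#' Spawning schedule for many sites and years
#'
#' @param ssts named list of SST data.frames, one per site
#'   (see [generate_ocean()]).
#' @param moons full-moon dates covering all years.
#' @param years integer vector of years to schedule.
#' @param ... passed to [estimate_spawning()].
#' @return a `spawning_schedule` data.frame with a `site` column; site-years
#'   whose threshold is never reached appear with `spawned = FALSE`.
#' @export
build_spawning_schedule <- function(ssts, moons, years, ...) {
  out <- list()
  for (site in names(ssts)) {
    for (y in years) {
      row <- estimate_spawning(ssts[[site]], moons, y, ...)
      out[[length(out) + 1L]] <- cbind(site = site, row)
    }
  }
  sched <- do.call(rbind, out)
  class(sched) <- c("spawning_schedule", "data.frame")
  sched
}
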