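#' Default end-to-end run configuration
#'
#' All tunable parameters of the pipeline in one structure, with the study
#' defaults embedded: lineage-membership threshold 0.70, minimum 9 MLGs per
#' population, probability-of-identity cutoff 0.001, assignment threshold
#' 0.70, alpha 0.05; degree-day spawning (base 13 deg C from February 1,
#' 1000 deg C day), 10-day release window opening 3 days before the full
#' moon, 50 particles/day, 42-day maximum pelagic duration, 3-day
#' pre-competency, 2-hour integration step. Permutation counts are the desk
#' defaults and every stochastic stage derives its seed from `seed`.
#'
#' @param seed master integer seed.
#' @return a nested configuration list (can be serialised to YAML).
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(
      genotypes = list(n_pops = 13, n_per_pop = 20, n_loci = 8,
                       alleles_per_locus = 8, fst_target = 0.05,
                       layout = "linear", missing_rate = 0.02,
                       clone_spec = list(P12 = c(6, 4, 3), P13 = c(4)),
                       lineage = list(prop = 0.25, q1 = 0.1)),
      ocean = list(lon_range = c(127, 135), lat_range = c(24, 34),
                   cell_deg = 1 / 12, n_days = 365, snapshot_days = 5,
                   eddy_amp = 0.1),
      years = c(1993L, 1994L),
      n_sites = 13),
    thresholds = list(lineage = 0.70, min_mlg = 9, pid = 0.001,
                      assignment = 0.70, alpha = 0.05),
    loci_excluded = character(),
    spawning = list(t_base = 13, threshold = 1000, start_month_day = "02-01",
                    window_days = 10, offset_days = 3, particles_per_day = 50),
    dispersal = list(pld_max = 42, competency_min = 3, dt_days = 2 / 24),
    permutations = list(fst = 199L, amova = 499L, exact = 2000L,
                        mantel = 9999L),
    generations = 1000L)
}

#' Evenly spaced sites along a polyline path
#'
#' Places `n` site points along the jet-core path (interpolated by arc
#' length in degree space), used to lay habitat sites along the synthetic
#' boundary current.
#'
#' @param path data.frame `lon`, `lat` polyline.
#' @param n number of sites.
#' @param labels site identifiers (default S01..Sn).
#' @return data.frame `site`, `lon`, `lat`.
#' @export
sites_along_path <- function(path, n, labels = NULL) {
  seg <- sqrt(diff(path$lon)^2 + diff(path$lat)^2)
  s <- c(0, cumsum(seg))
  at <- seq(0.02, 0.98, length.out = n) * s[length(s)]
  lon <- stats::approx(s, path$lon, xout = at)$y
  lat <- stats::approx(s, path$lat, xout = at)$y
  data.frame(site = labels %||% sprintf("S%02d", seq_len(n)),
             lon = lon, lat = lat)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> filter -> popgen -> dispersal -> ibd on synthetic
#' fixtures, writing every stage's tables under `outdir` plus a manifest
#' (parameters, seeds, input checksums). Stages are pure functions of their
#' written inputs; re-running with the same config and seed reproduces every
#' output byte-for-byte.
#'
#' @param config configuration list ([default_config()]) or path to a YAML
#'   file with the same structure.
#' @param outdir output directory (created).
#' @return invisibly, a list with the main stage results.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("run")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  seed <- config$seed

  ## ---- simulate fixtures ----
  gcfg <- config$simulate$genotypes
  sim_cfg <- sim_genotype_config(
    n_pops = gcfg$n_pops, n_per_pop = gcfg$n_per_pop, n_loci = gcfg$n_loci,
    alleles_per_locus = gcfg$alleles_per_locus, fst_target = gcfg$fst_target,
    layout = gcfg$layout, clone_spec = gcfg$clone_spec,
    lineage_spec = gcfg$lineage, missing_rate = gcfg$missing_rate,
    seed = seed)
  geno <- generate_genotypes(sim_cfg)

  ocfg <- config$simulate$ocean
  ocean_cfg <- sim_ocean_config(
    lon_range = ocfg$lon_range, lat_range = ocfg$lat_range,
    cell_deg = ocfg$cell_deg, n_days = ocfg$n_days,
    snapshot_days = ocfg$snapshot_days, eddy_amp = ocfg$eddy_amp,
    start = sprintf("%d-01-01", config$simulate$years[1]),
    seed = seed + 1L)
  n_days_total <- as.integer(
    as.Date(sprintf("%d-12-31", max(config$simulate$years))) -
      as.Date(sprintf("%d-01-01", config$simulate$years[1]))) + 1L
  ocean_cfg$n_days <- n_days_total

  sites <- sites_along_path(ocean_cfg$jet$path, config$simulate$n_sites,
                            labels = pop_levels(geno))
  # share geography between the genetic and dispersal stages
  geno$coords <- data.frame(pop = sites$site, lat = sites$lat,
                            lon = sites$lon)
  ocean <- generate_ocean(ocean_cfg, sites = sites)
  moons <- generate_moon_table(
    sprintf("%d-01-01", config$simulate$years[1]),
    sprintf("%d-12-31", max(config$simulate$years)))

  fx <- file.path(outdir, "fixtures")
  dir.create(fx, showWarnings = FALSE)
  write_genepop(geno, file.path(fx, "genotypes.gen"))
  write_metadata(geno, file.path(fx, "metadata.csv"))
  q2 <- true_qmatrix(geno, K = 2); q3 <- true_qmatrix(geno, K = 3)
  utils::write.table(q2, file.path(fx, "qmatrix_K2.txt"), col.names = FALSE,
                     quote = FALSE)
  utils::write.table(q3, file.path(fx, "qmatrix_K3.txt"), col.names = FALSE,
                     quote = FALSE)
  utils::write.csv(data.frame(date = format(moons)),
                   file.path(fx, "full_moons.csv"), row.names = FALSE)
  utils::write.csv(sites, file.path(fx, "sites.csv"), row.names = FALSE)

  ## ---- filter ----
  raw <- read_genepop(file.path(fx, "genotypes.gen"))
  raw <- read_metadata(raw, file.path(fx, "metadata.csv"))
  qs <- list(read_qmatrix(file.path(fx, "qmatrix_K2.txt")),
             read_qmatrix(file.path(fx, "qmatrix_K3.txt")))
  lf <- filter_lineage(raw, qs, target_cluster = 1,
                       threshold = config$thresholds$lineage)
  tab <- exclude_loci(lf$table, config$loci_excluded)
  clones <- detect_clones(tab, pid_threshold = config$thresholds$pid)
  tab <- clone_correct(tab, clones)
  pf <- filter_populations(tab, min_mlg = config$thresholds$min_mlg)
  tab <- pf$table
  utils::write.csv(data.frame(pop = names(clones$clonal_fraction),
                              n = clones$n_per_pop, mlg = clones$mlg_per_pop,
                              clonal_fraction = clones$clonal_fraction),
                   file.path(outdir, "clonality.csv"), row.names = FALSE)

  ## ---- popgen ----
  div <- diversity(tab)
  utils::write.csv(div$per_pop, file.path(outdir, "diversity.csv"),
                   row.names = FALSE)
  set.seed(seed + 2L)
  gf <- global_fst(tab, n_perm = config$permutations$fst)
  pw <- pairwise_fst(tab, n_perm = config$permutations$fst)
  dest <- jost_dest(tab)
  utils::write.csv(as.matrix(pw$fst), file.path(outdir, "pairwise_fst.csv"))
  utils::write.csv(as.matrix(dest), file.path(outdir, "pairwise_dest.csv"))
  grouping <- stats::setNames(
    vapply(pop_levels(tab), function(p) tab$region[match(p, tab$pop)], ""),
    pop_levels(tab))
  am <- amova(tab, grouping, n_perm = config$permutations$amova,
              seed = seed + 3L)
  amo <- cbind(am$components,
               index = c(names(am$indices), rep("", nrow(am$components) -
                                                  length(am$indices))))
  utils::write.csv(amo, file.path(outdir, "amova.csv"), row.names = FALSE)
  asg <- assign_individuals(tab, threshold = config$thresholds$assignment)
  utils::write.csv(asg, file.path(outdir, "assignment.csv"),
                   row.names = FALSE)

  ## ---- dispersal ----
  habitat <- make_habitat_grid(ocean$field, sites)
  sp <- config$spawning
  annual <- list()
  for (y in config$simulate$years) {
    sched <- build_spawning_schedule(
      ocean$sst, moons, y, t_base = sp$t_base, threshold = sp$threshold,
      start_month_day = sp$start_month_day, window_days = sp$window_days,
      offset_days = sp$offset_days, particles_per_day = sp$particles_per_day)
    fates <- advect(ocean$field, sched, habitat,
                    pld_max = config$dispersal$pld_max,
                    competency_min = config$dispersal$competency_min,
                    dt_days = config$dispersal$dt_days)
    annual[[as.character(y)]] <- build_connectivity(fates, sched,
                                                    sites = sites$site)
    utils::write.csv(as.matrix(annual[[as.character(y)]]),
                     file.path(outdir, sprintf("connectivity_%d.csv", y)))
  }
  cavg <- average_years(annual)
  iter <- iterate_generations(cavg, n_gen = config$generations)
  utils::write.csv(as.matrix(cavg), file.path(outdir, "connectivity_mean.csv"))
  utils::write.csv(as.matrix(iter$matrix),
                   file.path(outdir, "connectivity_iterated.csv"))

  ## ---- isolation by distance ----
  keep <- intersect(sites$site, pop_levels(tab))
  coords <- geno$coords[match(keep, geno$coords$pop), ]
  geo <- great_circle_matrix(coords)
  sea <- sea_path_matrix(coords, ocean$field)
  cd <- connectivity_distance(iter$matrix[keep, keep])
  fstm <- as.matrix(pw$fst)[keep, keep]
  set.seed(seed + 4L)
  ibd <- list(
    euclidean = mantel(fstm, geo, n_perm = config$permutations$mantel),
    sea_path = mantel(fstm, sea, n_perm = config$permutations$mantel),
    connectivity = mantel(fstm, cd, n_perm = config$permutations$mantel))
  utils::write.csv(data.frame(
    predictor = names(ibd),
    r = vapply(ibd, `[[`, 1, "r"),
    p = vapply(ibd, `[[`, 1, "p")),
    file.path(outdir, "ibd_mantel.csv"), row.names = FALSE)

  ## ---- manifest ----
  fixture_files <- list.files(fx, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("reefconnect")),
    seed = seed,
    config = rapply(config, function(z)
      if (inherits(z, "Date")) format(z) else z, how = "replace"),
    checksums = as.list(tools::md5sum(fixture_files)),
    elapsed_sec = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))

  invisible(list(genotypes = tab, clones = clones, diversity = div,
                 global_fst = gf, pairwise_fst = pw, dest = dest, amova = am,
                 assignment = asg, connectivity = annual, mean = cavg,
                 iterated = iter, ibd = ibd, outdir = outdir))
}
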