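#!/usr/bin/env Rscript

# Stage 5 — isolation by distance.
#
# Correlates pairwise FST with three distance predictors: great-circle
# distance, shortest sea-path distance on the land-masked grid, and the
# -log accumulated larval flow from the 1000-generation connectivity
# matrix. Significance by one-tailed Mantel permutation tests.

library(reefconnect)

outdir <- "results"
fx <- file.path(outdir, "fixtures")
cfg <- yaml::read_yaml(file.path(outdir, "config.yaml"))
seed <- cfg$seed

tab <- read_genepop(file.path(outdir, "filtered.gen"))
tab <- read_metadata(tab, file.path(outdir, "filtered_metadata.csv"))
fstm <- as.matrix(read.csv(file.path(outdir, "pairwise_fst.csv"),
                           row.names = 1, check.names = FALSE))
iter <- as.matrix(read.csv(file.path(outdir, "connectivity_iterated.csv"),
                           row.names = 1, check.names = FALSE))
sites <- read.csv(file.path(fx, "sites.csv"))

keep <- intersect(rownames(fstm), sites$site)
coords <- data.frame(pop = keep,
                     lat = sites$lat[match(keep, sites$site)],
                     lon = sites$lon[match(keep, sites$site)])

ocfg <- cfg$simulate$ocean
field <- generate_ocean(sim_ocean_config(
  lon_range = unlist(ocfg$lon_range), lat_range = unlist(ocfg$lat_range),
  cell_deg = ocfg$cell_deg, snapshot_days = ocfg$snapshot_days,
  eddy_amp = ocfg$eddy_amp, start = "1993-01-01", n_days = 5,
  seed = seed + 1L))$field

geo <- great_circle_matrix(coords)
sea <- sea_path_matrix(coords, field)
con <- connectivity_distance(iter[keep, keep])

set.seed(seed + 6L)
res <- list(
  euclidean = mantel(fstm, geo, n_perm = cfg$permutations$mantel),
  sea_path = mantel(fstm, sea, n_perm = cfg$permutations$mantel),
  connectivity = mantel(fstm, con, n_perm = cfg$permutations$mantel))
for (nm in names(res)) {
  cat(sprintf("%-13s r = %+.3f, one-tailed P = %.4g\n", nm, res[[nm]]$r,
              res[[nm]]$p))
}
write.csv(data.frame(predictor = names(res),
                     r = vapply(res, `[[`, 1, "r"),
                     p = vapply(res, `[[`, 1, "p"),
                     n_perm = cfg$permutations$mantel),
          file.path(outdir, "ibd_mantel.csv"), row.names = FALSE)

# scatter data for a distance-vs-FST figure
ut <- upper.tri(fstm[keep, keep])
write.csv(data.frame(
  pop1 = rownames(fstm[keep, keep])[row(fstm[keep, keep])[ut]],
  pop2 = colnames(fstm[keep, keep])[col(fstm[keep, keep])[ut]],
  fst = fstm[keep, keep][ut],
  great_circle_km = as.matrix(geo)[ut],
  sea_path_km = as.matrix(sea)[ut],
  neg_log_flow = as.matrix(con)[ut]),
  file.path(outdir, "ibd_scatter.csv"), row.names = FALSE)
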