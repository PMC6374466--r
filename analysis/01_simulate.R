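#!/usr/bin/env Rscript

# Stage 1 — build the synthetic study system.
#
# Generates every fixture the downstream stages consume: a 13-population
# microsatellite dataset laid out as a linear stepping-stone chain along a
# poleward coastline (with clonal replication in the two range-edge
# populations and a cryptic second lineage mixed into every site), a
# synthetic western-boundary-current ocean with seasonal SST, a lunar
# calendar, and the habitat sites shared by the genetic and dispersal
# stages. Everything is written under results/fixtures/.

library(reefconnect)

seed <- 1L
outdir <- "results"
dir.create(file.path(outdir, "fixtures"), recursive = TRUE,
           showWarnings = FALSE)

cfg <- default_config(seed = seed)
yaml::write_yaml(cfg, file.path(outdir, "config.yaml"))

gcfg <- cfg$simulate$genotypes
sim_cfg <- sim_genotype_config(
  n_pops = gcfg$n_pops, n_per_pop = gcfg$n_per_pop, n_loci = gcfg$n_loci,
  alleles_per_locus = gcfg$alleles_per_locus, fst_target = gcfg$fst_target,
  layout = gcfg$layout, clone_spec = gcfg$clone_spec,
  lineage_spec = gcfg$lineage, missing_rate = gcfg$missing_rate, seed = seed)
geno <- generate_genotypes(sim_cfg)

ocfg <- cfg$simulate$ocean
ocean_cfg <- sim_ocean_config(
  lon_range = ocfg$lon_range, lat_range = ocfg$lat_range,
  cell_deg = ocfg$cell_deg, snapshot_days = ocfg$snapshot_days,
  eddy_amp = ocfg$eddy_amp, start = "1993-01-01",
  n_days = 730, seed = seed + 1L)
sites <- sites_along_path(ocean_cfg$jet$path, gcfg$n_pops,
                          labels = pop_levels(geno))
geno$coords <- data.frame(pop = sites$site, lat = sites$lat,
                          lon = sites$lon)
ocean <- generate_ocean(ocean_cfg, sites = sites)
moons <- generate_moon_table("1993-01-01", "1994-12-31")

fx <- file.path(outdir, "fixtures")
write_genepop(geno, file.path(fx, "genotypes.gen"))
write_metadata(geno, file.path(fx, "metadata.csv"))
write.table(true_qmatrix(geno, 2), file.path(fx, "qmatrix_K2.txt"),
            col.names = FALSE, quote = FALSE)
write.table(true_qmatrix(geno, 3), file.path(fx, "qmatrix_K3.txt"),
            col.names = FALSE, quote = FALSE)
write.csv(sites, file.path(fx, "sites.csv"), row.names = FALSE)
write.csv(data.frame(date = format(moons)), file.path(fx, "full_moons.csv"),
          row.names = FALSE)
for (s in names(ocean$sst)) {
  write.csv(ocean$sst[[s]], file.path(fx, sprintf("sst_%s.csv", s)),
            row.names = FALSE)
}
# the velocity field itself is regenerated from config.yaml by stage 04
# rather than stored (it is large and fully determined by the seed)

cat(sprintf("simulated %d individuals x %d loci in %d populations\n",
            n_ind(geno), n_loci(geno), length(pop_levels(geno))))
cat(sprintf("ocean grid: %d x %d cells, %d snapshots; %d full moons\n",
            length(ocean$field$lon), length(ocean$field$lat),
            length(ocean$field$time), length(moons)))
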