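#!/usr/bin/env Rscript

# Stage 2 — sample and population filters.
#
# Reads the GenePop + metadata + Q-matrix fixtures from stage 1 and applies
# the study's filter cascade: keep individuals assigned to the focal
# lineage with membership >= 0.70 in both the K = 2 and K = 3 clustering
# solutions; drop loci on the exclusion list; collapse clonal groups
# (probability of identity < 0.001) to one ramet; drop populations with
# fewer than 9 multilocus genotypes. Writes the clonality table and the
# filtered dataset for the downstream statistics.

library(reefconnect)

outdir <- "results"
fx <- file.path(outdir, "fixtures")
cfg <- yaml::read_yaml(file.path(outdir, "config.yaml"))

geno <- read_genepop(file.path(fx, "genotypes.gen"))
geno <- read_metadata(geno, file.path(fx, "metadata.csv"))
qs <- list(read_qmatrix(file.path(fx, "qmatrix_K2.txt")),
           read_qmatrix(file.path(fx, "qmatrix_K3.txt")))

lf <- filter_lineage(geno, qs, target_cluster = 1,
                     threshold = cfg$thresholds$lineage)
cat(sprintf("lineage filter: %d -> %d individuals\n",
            lf$report$n_input, lf$report$n_retained))

tab <- exclude_loci(lf$table, unlist(cfg$loci_excluded))
clones <- detect_clones(tab, pid_threshold = cfg$thresholds$pid)
write.csv(data.frame(pop = names(clones$clonal_fraction),
                     n = clones$n_per_pop, mlg = clones$mlg_per_pop,
                     clonal_fraction = round(clones$clonal_fraction, 4)),
          file.path(outdir, "clonality.csv"), row.names = FALSE)
cat(sprintf("clone detection: %d genets over %d colonies; fractions:\n",
            length(clones$groups), sum(clones$n_per_pop)))
print(round(clones$clonal_fraction[clones$clonal_fraction > 0], 3))

tab <- clone_correct(tab, clones)
pf <- filter_populations(tab, min_mlg = cfg$thresholds$min_mlg)
if (nrow(pf$report$populations_removed) > 0) {
  cat("populations dropped (MLG below minimum):",
      paste(pf$report$populations_removed$pop, collapse = ", "), "\n")
}

write_genepop(pf$table, file.path(outdir, "filtered.gen"))
write_metadata(pf$table, file.path(outdir, "filtered_metadata.csv"))
cat(sprintf("final dataset: %d individuals, %d loci, %d populations\n",
            n_ind(pf$table), n_loci(pf$table),
            length(pop_levels(pf$table))))
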