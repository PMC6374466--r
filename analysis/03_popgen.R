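#!/usr/bin/env Rscript

# Stage 3 — population-genetic statistics on the filtered dataset.
#
# Diversity per population (Na, Ho, He, rarefied allelic richness, FIS,
# fixed loci, private alleles), global and pairwise Weir-Cockerham FST with
# permutation tests, pairwise Jost's DEST, exact differentiation tests with
# sequential Bonferroni flags, hierarchical AMOVA by region class, a
# Nei-distance neighbour-joining tree, PCoA, and Bayesian assignment.

library(reefconnect)

outdir <- "results"
cfg <- yaml::read_yaml(file.path(outdir, "config.yaml"))
seed <- cfg$seed

tab <- read_genepop(file.path(outdir, "filtered.gen"))
tab <- read_metadata(tab, file.path(outdir, "filtered_metadata.csv"))

div <- diversity(tab)
write.csv(div$per_pop, file.path(outdir, "diversity.csv"), row.names = FALSE)
write.csv(div$private, file.path(outdir, "private_alleles.csv"),
          row.names = FALSE)
cat(sprintf("diversity: mean He %.3f, mean A %.2f (rarefied to g = %d)\n",
            mean(div$per_pop$He), mean(div$per_pop$A), div$rarefaction_g))

set.seed(seed + 2L)
gf <- global_fst(tab, n_perm = cfg$permutations$fst)
cat(sprintf("global FST (WC theta) = %.3f, P = %.3g\n", gf$theta,
            gf$p_value))
pw <- pairwise_fst(tab, n_perm = cfg$permutations$fst)
dest <- jost_dest(tab)
write.csv(as.matrix(pw$fst), file.path(outdir, "pairwise_fst.csv"))
write.csv(as.matrix(pw$p), file.path(outdir, "pairwise_fst_p.csv"))
write.csv(as.matrix(dest), file.path(outdir, "pairwise_dest.csv"))

# exact differentiation tests over all pairs, Holm-corrected
pops <- pop_levels(tab)
pairs <- t(combn(pops, 2))
set.seed(seed + 3L)
pvals <- apply(pairs, 1, function(pr)
  exact_differentiation_test(tab, pr,
                             n_resample = cfg$permutations$exact)$p_combined)
flags <- sequential_bonferroni(pvals, alpha = cfg$thresholds$alpha)
write.csv(data.frame(pop1 = pairs[, 1], pop2 = pairs[, 2], p = pvals,
                     holm_adjusted = attr(flags, "adjusted"),
                     significant = as.logical(flags)),
          file.path(outdir, "exact_tests.csv"), row.names = FALSE)
cat(sprintf("exact tests: %d of %d pairs significant after Holm\n",
            sum(flags), length(flags)))

# AMOVA: regions as groups
grouping <- setNames(vapply(pops, function(p)
  tab$region[match(p, tab$pop)], ""), pops)
am <- amova(tab, grouping, n_perm = cfg$permutations$amova,
            seed = seed + 4L)
print(am)
write.csv(cbind(am$components,
                index = c(names(am$indices),
                          rep("", nrow(am$components) -
                                length(am$indices))),
                p = c(unlist(am$p_values),
                      rep(NA, nrow(am$components) -
                            length(am$p_values)))),
          file.path(outdir, "amova.csv"), row.names = FALSE)

# ordination and tree
pc <- pcoa(allelic_distance(tab), n_axes = 2)
write.csv(data.frame(id = rownames(pc$coords), pop = tab$pop,
                     axis1 = pc$coords[, 1], axis2 = pc$coords[, 2]),
          file.path(outdir, "pcoa_individuals.csv"), row.names = FALSE)
cat(sprintf("PCoA: first two axes explain %.1f%% + %.1f%%\n",
            pc$pct_var[1], pc$pct_var[2]))
tree <- nei_nj_tree(tab, n_bootstrap = 200, seed = seed + 5L)
ape::write.tree(tree, file.path(outdir, "nei_nj.nwk"))

# assignment and immigrant detection
asg <- assign_individuals(tab, threshold = cfg$thresholds$assignment)
write.csv(asg, file.path(outdir, "assignment.csv"), row.names = FALSE)
cat(sprintf("assignment: %d of %d assigned (>%.0f%%), %d putative immigrants\n",
            sum(asg$assigned != "unassigned"), nrow(asg),
            100 * cfg$thresholds$assignment,
            sum(asg$immigrant, na.rm = TRUE)))
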