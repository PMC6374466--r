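test_that("minimal GenePop files parse, including the missing convention", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy", "loc1", "pop", "A1 , 120120"), f)
  g <- read_genepop(f)
  expect_equal(n_ind(g), 1)
  expect_equal(unname(g$a1[1, 1]), 120L)
  expect_equal(unname(g$a2[1, 1]), 120L)

  writeLines(c("toy", "loc1", "loc2", "pop", "A1 , 000000 120122"), f)
  g <- read_genepop(f)
  expect_true(is.na(g$a1[1, 1]))
  expect_equal(unname(g$a1[1, 2]), 120L)

  # 2-digit dialect
  writeLines(c("toy", "loc1", "pop", "A1 , 0507"), f)
  g <- read_genepop(f)
  expect_equal(unname(g$a1[1, 1]), 5L)
  expect_equal(unname(g$a2[1, 1]), 7L)
})

test_that("malformed GenePop rows fail naming the line", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy", "loc1", "loc2", "pop", "A1 , 120120"), f)
  expect_error(read_genepop(f), "line 5.*ragged")
  writeLines(c("toy", "loc1", "pop", "A1 , 12012"), f)
  expect_error(read_genepop(f), "line 4")
})

test_that("write -> read round-trips calls, order and blocks", {
  g <- generate_genotypes(sim_genotype_config(n_pops = 13, n_per_pop = 6,
                                              n_loci = 5,
                                              missing_rate = 0.05, seed = 21))
  f <- withr::local_tempfile(fileext = ".gen")
  write_genepop(g, f)
  g2 <- read_genepop(f, pop_names = pop_levels(g))
  expect_identical(g$a1, g2$a1)
  expect_identical(g$a2, g2$a2)
  expect_identical(g$id, g2$id)
  expect_identical(g$pop, g2$pop)

  # metadata survives its own round trip
  fm <- withr::local_tempfile(fileext = ".csv")
  write_metadata(g, fm)
  g3 <- read_metadata(g2, fm)
  expect_identical(g3$region, g$region)
  expect_equal(g3$coords$lat, g$coords$lat)
})

test_that("lineage filter applies the inclusive threshold in every K block", {
  g <- generate_genotypes(sim_genotype_config(n_pops = 1, n_per_pop = 4,
                                              seed = 4))
  q2 <- matrix(c(0.71, 0.90, 0.70, 0.60,
                 0.29, 0.10, 0.30, 0.40), ncol = 2)
  rownames(q2) <- g$id
  q3 <- matrix(c(0.70, 0.65, 0.95, 0.80,
                 0.15, 0.20, 0.03, 0.10,
                 0.15, 0.15, 0.02, 0.10), ncol = 3)
  rownames(q3) <- g$id
  res <- filter_lineage(g, list(q2, q3), target_cluster = 1, threshold = 0.70)
  # i1: (0.71, 0.70) retained (boundary inclusive); i2: (0.90, 0.65) fails
  # one block; i3 passes both; i4 fails both
  expect_setequal(res$table$id, g$id[c(1, 3)])
  expect_setequal(res$report$individuals_removed$id, g$id[c(2, 4)])
  expect_equal(res$report$n_input - nrow(res$report$individuals_removed),
               res$report$n_retained)

  # vacuous filter retains everything
  res0 <- filter_lineage(g, list(q2, q3), threshold = 0)
  expect_equal(n_ind(res0$table), 4)

  # unknown individual is reported by identifier
  expect_error(filter_lineage(gt_subset(g, ind = 1:4), q2[1:2, ]),
               "missing from Q")
})

test_that("population filter drops below-minimum-MLG populations inclusively", {
  g <- generate_genotypes(sim_genotype_config(
    n_pops = 3, n_per_pop = 10,
    clone_spec = list(P01 = c(3), P02 = c(2)), seed = 6))
  # MLG counts: P01 = 8, P02 = 9, P03 = 10
  res <- filter_populations(g, min_mlg = 9)
  expect_setequal(unique(res$table$pop), c("P02", "P03"))
  expect_equal(res$report$populations_removed$pop, "P01")
  res1 <- filter_populations(g, min_mlg = 1)
  expect_equal(n_ind(res1$table), 30)
})

test_that("locus exclusion is exact and guarded", {
  g <- generate_genotypes(sim_genotype_config(n_pops = 2, n_loci = 8, seed = 7))
  g2 <- exclude_loci(g, "L03")
  expect_equal(n_loci(g2), 7)
  expect_false("L03" %in% g2$loci)
  expect_identical(exclude_loci(g, character()), g)
  expect_error(exclude_loci(g, "nope"), "unknown locus")
  expect_error(exclude_loci(g, g$loci), "every locus")
})

test_that("lineage filtering and locus exclusion commute", {
  g <- generate_genotypes(sim_genotype_config(
    n_pops = 2, n_per_pop = 8, lineage_spec = list(prop = 0.4, q1 = 0.1),
    seed = 10))
  q <- true_qmatrix(g, 2)
  a <- exclude_loci(filter_lineage(g, q, threshold = 0.7)$table, "L01")
  b <- filter_lineage(exclude_loci(g, "L01"), q, threshold = 0.7)$table
  expect_identical(a$a1, b$a1)
  expect_identical(a$id, b$id)
})

test_that("Q matrices read from disk and validate row sums", {
  g <- generate_genotypes(sim_genotype_config(n_pops = 1, n_per_pop = 3,
                                              seed = 1))
  q <- true_qmatrix(g, 3)
  f <- withr::local_tempfile(fileext = ".txt")
  write.table(q, f, col.names = FALSE, quote = FALSE)
  q2 <- read_qmatrix(f)
  expect_equal(unname(q2), unname(q), tolerance = 1e-6)
  writeLines("A1 0.5 0.2", f)
  expect_error(read_qmatrix(f), "summing to 1")
})

test_that("gridded fields round-trip through the CSV exchange format", {
  ocfg <- sim_ocean_config(lon_range = c(130, 131), lat_range = c(30, 31),
                           cell_deg = 0.25, n_days = 6, snapshot_days = 2,
                           seed = 9)
  f1 <- generate_ocean(ocfg)$field
  path <- withr::local_tempfile(fileext = ".csv")
  write_current_field(f1, path)
  f2 <- read_current_field(path)
  expect_equal(f2$u, f1$u, tolerance = 1e-9)
  expect_equal(f2$v, f1$v, tolerance = 1e-9)
  expect_identical(f2$land, f1$land)
})
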