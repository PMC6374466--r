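test_that("generators are deterministic given a seed", {
  cfg <- sim_genotype_config(n_pops = 4, n_per_pop = 8, n_loci = 3,
                             missing_rate = 0.05, seed = 11)
  g1 <- generate_genotypes(cfg)
  g2 <- generate_genotypes(cfg)
  expect_identical(g1$a1, g2$a1)
  expect_identical(g1$a2, g2$a2)
  ocfg <- sim_ocean_config(lon_range = c(130, 131), lat_range = c(30, 31),
                           cell_deg = 0.25, n_days = 10, seed = 5)
  o1 <- generate_ocean(ocfg); o2 <- generate_ocean(ocfg)
  expect_identical(o1$field$u, o2$field$u)
})

test_that("planted allele frequencies are proper distributions", {
  g <- generate_genotypes(sim_genotype_config(n_pops = 5, seed = 2))
  truth <- attr(g, "truth")
  for (f in truth$freqs) {
    expect_equal(unname(rowSums(f)), rep(1, nrow(f)), tolerance = 1e-12)
  }
})

test_that("no divergence planted means theta centred on zero", {
  th <- vapply(1:30, function(s) {
    g <- generate_genotypes(sim_genotype_config(n_pops = 4, n_per_pop = 30,
                                                n_loci = 6, fst_target = 0,
                                                seed = 1000 + s))
    global_fst(g)$theta
  }, 1)
  expect_lt(abs(mean(th)), 0.01)
})

test_that("clone specification produces the constructed duplication", {
  g <- generate_genotypes(sim_genotype_config(
    n_pops = 1, n_per_pop = 10, clone_spec = list(P01 = 5), seed = 3))
  part <- detect_clones(g)
  expect_equal(unname(part$mlg_per_pop[["P01"]]), 6)
  expect_equal(unname(part$clonal_fraction[["P01"]]), 0.4)
})

test_that("invalid generator configurations are refused", {
  expect_error(sim_genotype_config(fst_target = 1), "fst_target")
  expect_error(sim_genotype_config(clone_spec = list(P01 = c(8, 8)),
                                   n_per_pop = 10), "ramets")
  expect_error(sim_genotype_config(missing_rate = 1), "missing_rate")
  expect_error(sim_ocean_config(n_days = 0), "time span")
})

test_that("jet field obeys its construction contracts", {
  land <- list(data.frame(lon = c(130, 130.5, 130.5, 130),
                          lat = c(30.6, 30.6, 31, 31)))
  cfg <- sim_ocean_config(lon_range = c(130, 131), lat_range = c(30, 31),
                          cell_deg = 0.1, n_days = 5, eddy_amp = 0,
                          jet = list(path = data.frame(lon = c(130, 131),
                                                       lat = c(30.35, 30.35)),
                                     width_deg = 0.2, peak_ms = 0.8),
                          land_polys = land, seed = 1)
  oc <- generate_ocean(cfg)
  spd <- sqrt(oc$field$u^2 + oc$field$v^2)
  # on-core speed equals the configured peak, and nothing exceeds it
  expect_equal(max(spd), 0.8, tolerance = 1e-9)
  # land cells carry zero velocity
  expect_true(any(oc$field$land))
  for (it in seq_along(oc$field$time)) {
    expect_true(all(oc$field$u[, , it][oc$field$land] == 0))
    expect_true(all(oc$field$v[, , it][oc$field$land] == 0))
  }
})

test_that("SST follows its closed form", {
  cfg <- sim_ocean_config(lon_range = c(130, 131), lat_range = c(30, 31),
                          cell_deg = 0.25, n_days = 400,
                          sst = list(mean_coef = c(20, 0), amplitude = 3,
                                     phase_day = 0), seed = 1)
  oc <- generate_ocean(cfg, sites = data.frame(site = "A", lon = 130.5,
                                               lat = 30.5))
  s <- oc$sst$A
  # at the phase day (day 0 is Jan 1 here) the sine is zero: SST = mean
  jan1 <- s$temp[s$date == as.Date("1993-01-01")]
  expect_equal(jan1, 20 + 3 * sin(2 * pi * 0 / 365.25), tolerance = 1e-9)
  expect_equal(max(s$temp), 23, tolerance = 0.01)
  expect_equal(min(s$temp), 17, tolerance = 0.01)
})

test_that("moon table is an exact synodic progression", {
  ref <- as.Date("2000-01-21")
  m <- generate_moon_table("2000-01-01", "2000-12-31", ref)
  expect_true(ref %in% m)
  expect_true(all(diff(m) > 0))
  expect_true(all(round(diff(as.numeric(m))) %in% c(29, 30)))
  # a 59.2-day span holds two or three full moons depending on alignment
  lens <- vapply(0:29, function(off) {
    length(generate_moon_table(ref + off, ref + off + 59.2, ref))
  }, 1L)
  expect_true(all(lens %in% c(2L, 3L)))
  expect_true(any(lens == 2L) && any(lens == 3L))
  expect_error(generate_moon_table("2000-02-01", "2000-01-01"), "precede")
})

test_that("lineage admixture truth is exposed as a Q matrix", {
  g <- generate_genotypes(sim_genotype_config(
    n_pops = 2, n_per_pop = 10,
    lineage_spec = list(prop = 0.3, q1 = 0.2), seed = 8))
  q <- true_qmatrix(g, K = 2)
  expect_equal(unname(rowSums(q)), rep(1, 20))
  expect_equal(sum(q[, 1] == 0.2), 6) # 30% of each population admixed
})
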