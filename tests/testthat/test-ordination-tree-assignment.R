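test_that("PCoA reproduces planted planar configurations", {
  set.seed(61)
  pts <- cbind(runif(7), runif(7))
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(letters[1:7], letters[1:7])
  fit <- pcoa(D, 2)
  # distances reconstructed from the two recovered axes match exactly
  expect_lt(max(abs(as.matrix(dist(fit$coords)) - D)), 1e-8)
  expect_equal(sum(fit$pct_var), 100, tolerance = 1e-6)

  # three equidistant points: two equal positive eigenvalues
  D3 <- matrix(1, 3, 3) - diag(3)
  dimnames(D3) <- list(c("a", "b", "c"), c("a", "b", "c"))
  f3 <- pcoa(D3, 2)
  pos <- f3$eig[f3$eig > 1e-9]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)

  # zero matrix: all eigenvalues vanish
  Z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_true(all(abs(pcoa(Z, 2)$eig) < 1e-12))

  # non-symmetric input refused
  Dbad <- D; Dbad[1, 2] <- Dbad[1, 2] + 1
  expect_error(pcoa(Dbad), "symmetric")
})

test_that("Nei distance is zero for identical frequencies and NJ recovers structure", {
  calls <- replicate(6, matrix(c(1L, 2L), 2), simplify = FALSE)
  g0 <- tiny_table(c(calls, calls), rep(c("A", "B"), each = 6))
  expect_equal(as.matrix(nei_distance(g0))[1, 2], 0, tolerance = 1e-12)

  # two diverged population pairs: NJ must pair (P01,P02) and (P03,P04)
  set.seed(62)
  pool1 <- generate_genotypes(sim_genotype_config(n_pops = 2, n_per_pop = 25,
                                                  n_loci = 8,
                                                  fst_target = 0.03,
                                                  seed = 63))
  pool2 <- generate_genotypes(sim_genotype_config(n_pops = 2, n_per_pop = 25,
                                                  n_loci = 8,
                                                  fst_target = 0.03,
                                                  seed = 64))
  g <- genotype_table(rbind(pool1$a1, pool2$a1), rbind(pool1$a2, pool2$a2),
                      pool1$loci,
                      c(paste0("x", pool1$id), paste0("y", pool2$id)),
                      c(pool1$pop, sub("P0([12])", "P0\\+2", pool2$pop)))
  g$pop <- c(pool1$pop, c(P01 = "P03", P02 = "P04")[pool2$pop])
  tree <- nei_nj_tree(g, n_bootstrap = 50, seed = 65)
  split <- ape::prop.part(tree)
  # the unrooted tree has exactly one internal split: {P01,P02}|{P03,P04}
  pairs <- lapply(split, function(s) sort(attr(split, "labels")[s]))
  expect_true(list(c("P01", "P02")) %in% pairs ||
                list(c("P03", "P04")) %in% pairs)
  # supports on a strongly diverged pair of clades are high
  expect_true(any(as.numeric(tree$node.label) >= 90, na.rm = TRUE))
  expect_error(nei_nj_tree(g0), ">= 3")
})

test_that("assignment follows the Dirichlet-multinomial closed form", {
  # two pops, one locus; candidate counts chosen so the posterior is easy
  calls_a <- c(replicate(4, matrix(c(1L, 1L), 2), simplify = FALSE),
               list(matrix(c(1L, 2L), 2)))
  calls_b <- c(replicate(4, matrix(c(2L, 2L), 2), simplify = FALSE),
               list(matrix(c(1L, 2L), 2)))
  g <- tiny_table(c(calls_a, calls_b), rep(c("A", "B"), each = 5))
  res <- assign_individuals(g, threshold = 0.7)
  prob <- attr(res, "prob")
  # hand computation for individual i01 = (1,1), home pop A (leave-one-out):
  # pop A counts without i01: allele1 7, allele2 1; k = 2, prior = 1/2
  # P_A = (7.5 * 8.5) / (9 * 10); pop B counts: allele1 1, allele2 9
  # P_B = (1.5 * 2.5) / (11 * 12)
  pA <- (7.5 * 8.5) / (9 * 10); pB <- (1.5 * 2.5) / (11 * 12)
  expect_equal(unname(prob["i01", ]), c(pA, pB) / (pA + pB),
               tolerance = 1e-10)
  expect_equal(res$assigned[1], "A")

  # symmetric individual (1,2) in symmetric populations: ~(0.5, 0.5),
  # unassigned at 0.7
  expect_lt(abs(prob["i05", "A"] - prob["i10", "B"]), 1e-10)
  expect_equal(res$assigned[5], "unassigned")
})

test_that("private diagnostic alleles drive assignment and immigrant flags", {
  set.seed(66)
  g <- generate_genotypes(sim_genotype_config(n_pops = 3, n_per_pop = 20,
                                              n_loci = 8, fst_target = 0.2,
                                              seed = 67))
  res <- assign_individuals(g, threshold = 0.7)
  prob <- attr(res, "prob")
  expect_equal(unname(rowSums(prob)), rep(1, n_ind(g)), tolerance = 1e-9)
  # strong differentiation: most individuals go home
  home <- mean(res$best_pop == res$pop)
  expect_gt(home, 0.8)
  # an allele absent from every reference population never breaks scoring
  g$a1[1, 1] <- g$a2[1, 1] <- 999L
  expect_silent(res2 <- assign_individuals(g, threshold = 0.7))
  expect_true(all(is.finite(attr(res2, "prob"))))
})
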