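test_that("great-circle distances match the haversine closed form", {
  co <- data.frame(pop = c("a", "b", "c"),
                   lat = c(0, 0, 10), lon = c(0, 1, 1))
  D <- great_circle_matrix(co)
  # one degree of longitude on the equator with R = 6371 km
  expect_equal(D["a", "b"], 6371 * pi / 180, tolerance = 0.1 / 111)
  expect_equal(D["a", "b"], 111.19, tolerance = 0.001)
  expect_equal(unclass(D), t(unclass(D)))
  expect_equal(D["a", "a"], 0)
  expect_error(great_circle_matrix(data.frame(pop = "x", lat = 91, lon = 0)),
               "latitude")
})

test_that("sea paths equal great circles on open water and detour around land", {
  lon <- seq(130, 132, by = 0.05); lat <- seq(30, 32, by = 0.05)
  nx <- length(lon); ny <- length(lat)
  open <- make_current_field(lon, lat, as.Date("1993-01-01"),
                             array(0, c(nx, ny, 1)), array(0, c(nx, ny, 1)))
  co <- data.frame(pop = c("a", "b"), lat = c(30.3, 31.7),
                   lon = c(130.3, 131.7))
  gc <- great_circle_matrix(co)
  sp <- sea_path_matrix(co, open)
  # within one cell diagonal of discretization error
  cell_diag <- 111.32 * 0.05 * sqrt(2)
  expect_lt(abs(sp["a", "b"] - gc["a", "b"]), cell_diag)
  expect_gte(sp["a", "b"], gc["a", "b"] - 1e-6)

  # wall with a single gap away from the straight line: path must detour,
  # never shorten, and must equal an independently coded Dijkstra
  land <- matrix(FALSE, nx, ny)
  land[, 21] <- TRUE # horizontal wall at lat = 31
  land[4, 21] <- FALSE # gap near the western edge
  walled <- make_current_field(lon, lat, as.Date("1993-01-01"),
                               array(0, c(nx, ny, 1)),
                               array(0, c(nx, ny, 1)), land)
  sp2 <- sea_path_matrix(co, walled)
  expect_gt(sp2["a", "b"], sp["a", "b"])

  cells <- which(!land, arr.ind = TRUE)
  cells <- data.frame(ix = cells[, 1], iy = cells[, 2],
                      lon = lon[cells[, 1]], lat = lat[cells[, 2]])
  from <- which.min((cells$lon - co$lon[1])^2 + (cells$lat - co$lat[1])^2)
  to <- which.min((cells$lon - co$lon[2])^2 + (cells$lat - co$lat[2])^2)
  expect_equal(sp2["a", "b"], oracle_sea_dijkstra(cells, from, to),
               tolerance = 1e-6)

  # fully enclosed site is an error naming the pair
  land2 <- land; land2[, 21] <- TRUE
  closed <- make_current_field(lon, lat, as.Date("1993-01-01"),
                               array(0, c(nx, ny, 1)),
                               array(0, c(nx, ny, 1)), land2)
  expect_error(sea_path_matrix(co, closed), "no sea path between")
})

test_that("connectivity distance is monotone in symmetrized flow", {
  C <- matrix(c(0, 0.4, 0.01,
                0.2, 0, 0,
                0.05, 0, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  d <- connectivity_distance(C)
  s <- (C + t(C)) / 2
  eps <- min(s[s > 0]) / 2
  expect_equal(d["x", "y"], -log(0.3 + eps))
  expect_equal(d["x", "z"], -log(0.03 + eps))
  # zero-flow pair sits strictly farthest
  expect_gt(d["y", "z"], max(d["x", "y"], d["x", "z"]))
  # equal flows mean equal distances
  E <- matrix(0.2, 2, 2, dimnames = list(c("p", "q"), c("p", "q")))
  diag(E) <- 0
  de <- connectivity_distance(E)
  expect_equal(de["p", "q"], de["q", "p"])
  expect_error(connectivity_distance(matrix(0, 2, 2)), "all-zero")
})

test_that("Mantel statistic and tail behave as a permutation test", {
  set.seed(111)
  co <- data.frame(pop = letters[1:7], lat = runif(7, 28, 33),
                   lon = runif(7, 128, 134))
  D <- as.matrix(great_circle_matrix(co))
  # identity comparison: r = 1, p at the resolution floor (up to ties)
  m <- mantel(D, D, n_perm = 999, seed = 1)
  expect_equal(m$r, 1)
  expect_lte(m$p, 0.01)

  # r agrees with the definition and with an independent implementation
  G <- D + matrix(rnorm(49, 0, 50), 7, 7)
  G <- (G + t(G)) / 2; diag(G) <- 0
  dimnames(G) <- dimnames(D)
  m2 <- mantel(G, D, n_perm = 99, seed = 2)
  expect_equal(m2$r, oracle_mantel_r(G, D), tolerance = 1e-12)
  if (requireNamespace("vegan", quietly = TRUE)) {
    v <- vegan::mantel(as.dist(G), as.dist(D), permutations = 99)
    expect_equal(m2$r, unname(v$statistic), tolerance = 1e-10)
  }

  # invariance under a joint relabeling of both matrices
  o <- sample(7)
  m3 <- mantel(G[o, o], D[o, o], n_perm = 99, seed = 3)
  expect_equal(m3$r, m2$r, tolerance = 1e-12)

  # exclusions and the degenerate-size guard
  m4 <- mantel(G, D, n_perm = 99, exclude = "a", seed = 4)
  expect_equal(m4$n, 6)
  expect_error(mantel(G[1:3, 1:3], D[1:3, 1:3], n_perm = 99), ">= 4")
})

test_that("stepping-stone structure shows isolation by distance", {
  # linear drift chain along the coast: FST grows with separation, so the
  # Mantel correlation with great-circle distance is positive and usually
  # significant (majority criterion over replicates)
  hits <- 0L; rs <- numeric(10)
  for (i in 1:10) {
    g <- generate_genotypes(sim_genotype_config(
      n_pops = 8, n_per_pop = 20, n_loci = 8, fst_target = 0.04,
      layout = "linear", seed = 8100 + i))
    fst <- as.matrix(pairwise_fst(g)$fst)
    geo <- great_circle_matrix(g$coords)
    m <- mantel(fst, geo, n_perm = 199, seed = i)
    rs[i] <- m$r
    if (m$r > 0 && m$p < 0.05) hits <- hits + 1L
  }
  expect_gt(mean(rs), 0)
  expect_gte(hits, 6)
})
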