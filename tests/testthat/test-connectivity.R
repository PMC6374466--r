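fates_row <- function(source, outcome, settle = NA_character_, n = 1L) {
  data.frame(source = source, release_date = as.Date("1993-06-01"),
             outcome = outcome, settle_site = settle, age_days = 10, n = n)
}

two_site_schedule <- function() {
  data.frame(site = c("A", "B"), year = 1993, spawned = TRUE,
             exceedance = as.Date("1993-06-01"),
             full_moon = as.Date("1993-06-04"),
             window_start = as.Date("1993-06-01"),
             window_end = as.Date("1993-06-10"), particles_per_day = 50L)
}

test_that("connectivity entries are settled over released", {
  sched <- two_site_schedule()
  fates <- rbind(fates_row("A", "settled", "B", 250L),
                 fates_row("A", "expired", n = 250L),
                 fates_row("B", "exited", n = 500L))
  C <- build_connectivity(fates, sched)
  expect_equal(C["A", "B"], 0.5)
  expect_equal(sum(C["B", ]), 0)
  expect_equal(unname(attr(C, "released")), c(500, 500))

  # all expired: zero matrix
  C0 <- build_connectivity(rbind(fates_row("A", "expired", n = 500L),
                                 fates_row("B", "expired", n = 500L)), sched)
  expect_true(all(C0 == 0))

  # a never-spawning site warns and yields a zero row
  sched2 <- two_site_schedule(); sched2$spawned[2] <- FALSE
  expect_warning(C2 <- build_connectivity(fates_row("A", "settled", "A", 100L),
                                          sched2), "no particles released")
  expect_equal(sum(C2["B", ]), 0)
})

test_that("year averaging is the element-wise mean", {
  M <- matrix(runif(16), 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  Z <- matrix(0, 4, 4, dimnames = dimnames(M))
  expect_equal(unclass(average_years(list(M))), M, ignore_attr = TRUE)
  expect_equal(unclass(average_years(list(M, Z))), M / 2, ignore_attr = TRUE)
  set.seed(101)
  ms <- replicate(24, matrix(runif(9), 3, 3), simplify = FALSE)
  avg <- average_years(ms)
  direct <- matrix(0, 3, 3)
  for (m in ms) direct <- direct + m / 24
  expect_equal(unclass(avg), direct, ignore_attr = TRUE)
  expect_error(average_years(list()), "empty")
  expect_error(average_years(list(M, matrix(0, 2, 2))), "shapes")
})

# run the exported iteration for exactly g generations
iterate_generations_partial <- function(C, g) {
  unclass(iterate_generations(C, n_gen = g, tol = 0)$matrix)
}

test_that("generation iteration is monotone, capped and correct on chains", {
  # identity: fixed point immediately
  I3 <- diag(3); dimnames(I3) <- list(letters[1:3], letters[1:3])
  it <- iterate_generations(I3, 50)
  expect_equal(unclass(it$matrix), I3, ignore_attr = TRUE)
  expect_lte(it$generations, 2)

  # deterministic one-way chain a->b->c: (a,c) reaches 1 by generation 2
  C <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  C["a", "b"] <- 1; C["b", "c"] <- 1
  it2 <- iterate_generations(C, 1000)
  expect_equal(it2$matrix["a", "c"], 1)
  expect_equal(it2$matrix["c", "a"], 0)

  # monotone non-decreasing trajectory, entries within [0, 1]
  set.seed(102)
  R <- matrix(runif(25, 0, 0.3), 5, 5)
  dimnames(R) <- list(letters[1:5], letters[1:5])
  A_prev <- R
  for (g in 2:12) {
    A_g <- iterate_generations_partial(R, g)
    expect_true(all(A_g >= A_prev - 1e-12))
    expect_true(all(A_g <= 1 + 1e-12))
    A_prev <- A_g
  }

  expect_error(iterate_generations(matrix(0, 2, 3)), "square")
})

test_that("iteration fixed point matches the scalar-loop oracle", {
  set.seed(103)
  for (k in c(3, 5)) {
    C <- matrix(runif(k * k, 0, 0.4), k, k)
    C[sample(k * k, k)] <- 0
    dimnames(C) <- list(paste0("s", 1:k), paste0("s", 1:k))
    mine <- iterate_generations(C, 200)$matrix
    theirs <- oracle_iterate(C, 200)
    expect_equal(unclass(mine), theirs, ignore_attr = TRUE,
                 tolerance = 1e-8)
    # support of the limit = reachability in >= 1 step on the chain graph
    P <- (C > 0) * 1
    R <- P; Pk <- P
    for (s in 2:k) { Pk <- (Pk %*% P > 0) * 1; R <- ((R + Pk) > 0) * 1 }
    expect_equal(unname(unclass(mine) > 1e-12), unname(R == 1))
  }
})

test_that("region aggregation means rows and sums sinks", {
  C <- matrix(c(0.1, 0.2, 0.0, 0.3,
                0.0, 0.1, 0.4, 0.0,
                0.2, 0.0, 0.1, 0.1,
                0.0, 0.3, 0.0, 0.2), 4, 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  map <- c(s1 = "N", s2 = "N", s3 = "S", s4 = "S")
  R <- aggregate_regions(C, map)
  expect_equal(R["N", "S"], mean(c(0.0 + 0.3, 0.4 + 0.0)))
  expect_equal(R["S", "N"], mean(c(0.2 + 0.0, 0.0 + 0.3)))
  # one site per region: identity aggregation
  map1 <- setNames(paste0("r", 1:4), paste0("s", 1:4))
  expect_equal(unname(aggregate_regions(C, map1)), unname(C))
  # all sites one region: mean row sum
  mapall <- setNames(rep("all", 4), paste0("s", 1:4))
  expect_equal(aggregate_regions(C, mapall)[1, 1], mean(rowSums(C)))
  expect_error(aggregate_regions(C, map[1:3]), "unmapped")
})
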