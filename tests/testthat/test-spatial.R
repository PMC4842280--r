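test_that("great-circle distance has the right scale, symmetry and errors", {
  expect_equal(great_circle(c(10, 20), c(10, 20)), 0)
  expect_equal(great_circle(c(0, 0), c(0, 90)), pi * 6371 / 2, tolerance = 1e-3)
  set.seed(51)
  for (rep in 1:20) {
    a <- c(runif(1, -80, 80), runif(1, -170, 170))
    b <- c(runif(1, -80, 80), runif(1, -170, 170))
    expect_equal(great_circle(a, b), great_circle(b, a))
  }
  expect_error(great_circle(c(95, 0), c(0, 0)), "domain error")
})

test_that("Mantel test detects identity and scales with noise", {
  set.seed(53)
  xy <- cbind(runif(12), runif(12))
  dx <- as.matrix(dist(xy))
  dimnames(dx) <- list(letters[1:12], letters[1:12])
  mt <- mantel(dx, dx, perms = 200, seed = 1)
  expect_equal(mt$r, 1)
  expect_lt(mt$p, 0.05)
  expect_equal(mt$n_pairs, choose(12, 2))

  rs <- sapply(c(0.01, 0.3, 3), function(s) {
    noise <- matrix(rnorm(144, 0, s), 12, 12)
    dy <- 2 * dx + (noise + t(noise)) / 2
    diag(dy) <- 0
    dimnames(dy) <- dimnames(dx)
    mantel(dx, dy, perms = 100, seed = 1)$r
  })
  expect_true(all(diff(rs) < 0))
  expect_gt(rs[1], 0.99)

  cst <- dx * 0
  expect_true(is.na(mantel(dx, cst, perms = 100)$r))
})

test_that("Mantel correlation agrees with the vegan implementation", {
  set.seed(59)
  for (rep in 1:10) {
    a <- as.matrix(dist(cbind(runif(9), runif(9))))
    b <- as.matrix(dist(cbind(runif(9), runif(9))))
    labs <- paste0("p", 1:9)
    dimnames(a) <- dimnames(b) <- list(labs, labs)
    ours <- mantel(a, b, perms = 100, seed = 1)
    ref <- vegan::mantel(as.dist(a), as.dist(b), permutations = 99)
    expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-10)
  }
})

test_that("IBD inputs linearise F_ST and carry coordinates through", {
  set.seed(55)
  sim <- simulate_dataset(sim_config(n_demes = 3, samples_per_deme = 8,
                                     migration = 0.3, seed = 4))
  ibd <- ibd_inputs(sim$aln, sim$pops, perms = 100, seed = 1)
  expect_identical(rownames(ibd$geo), rownames(ibd$gen))
  f <- 0.5
  expect_equal(f / (1 - f), 1)         # the linearisation at F_ST = 0.5
  expect_true(all(ibd$gen[upper.tri(ibd$gen)] > -1))
})

test_that("SAMOVA finds the planted bipartition and matches exhaustive search", {
  # two pairs of populations fixed for different haplotypes
  a <- alignment(paste0("s", 1:16),
                 c(rep("AAAAA", 4), rep("AAAAT", 4),
                   rep("TTTTA", 4), rep("TTTTT", 4)))
  pm <- population_set(setNames(rep(c("P1", "P2", "P3", "P4"), each = 4),
                                a$ids))
  ex <- samova_exhaustive(a, pm, K = 2)
  g <- ex$best_grouping
  expect_equal(g[["P1"]], g[["P2"]])
  expect_equal(g[["P3"]], g[["P4"]])
  expect_true(g[["P1"]] != g[["P3"]])

  sam <- samova(a, pm, K_range = 2, runs = 4, iters = 300, seed = 9)
  expect_equal(unname(sam$fct_trace["2"]), unname(ex$phi["F_CT"]),
               tolerance = 1e-12)

  # K = number of populations: the within-group population level vanishes
  sam4 <- samova(a, pm, K_range = 4, runs = 2, iters = 100, seed = 9)
  expect_true(is.na(sam4$per_k[["4"]]$phi["F_SC"]))
  expect_error(samova(a, pm, K_range = 5), "domain error")
})

test_that("landscape surface is flat for constant distances and bounded by inputs", {
  pm <- population_set(
    setNames(paste0("P", 1:4), paste0("x", 1:4)),
    data.frame(population = paste0("P", 1:4),
               latitude = c(20, 20, 24, 24), longitude = c(100, 104, 100, 104)))
  labs <- paste0("P", 1:4)
  gen <- matrix(0.37, 4, 4, dimnames = list(labs, labs)); diag(gen) <- 0
  surf <- landscape_surface(pm, gen, grid = c(12, 12), alpha = 1)
  expect_lt(max(abs(surf$grid - 0.37)), 1e-9)
  expect_equal(dim(surf$grid), c(12L, 12L))

  set.seed(57)
  gen2 <- matrix(runif(16, 0.1, 0.9), 4, 4); gen2 <- (gen2 + t(gen2)) / 2
  diag(gen2) <- 0; dimnames(gen2) <- list(labs, labs)
  s2 <- landscape_surface(pm, gen2, grid = c(10, 10), alpha = 1)
  vals <- s2$midpoints[, "value"]
  expect_true(all(s2$grid >= min(vals) - 1e-9 & s2$grid <= max(vals) + 1e-9))
})

test_that("a single high-distance edge raises a ridge between two clusters", {
  pm <- population_set(
    setNames(paste0("P", 1:4), paste0("x", 1:4)),
    data.frame(population = paste0("P", 1:4),
               latitude = c(20, 20.4, 20, 20.4),
               longitude = c(100, 100, 106, 106)))
  labs <- paste0("P", 1:4)
  gen <- matrix(0.05, 4, 4, dimnames = list(labs, labs)); diag(gen) <- 0
  gen[c("P1", "P2"), c("P3", "P4")] <- 0.9
  gen[c("P3", "P4"), c("P1", "P2")] <- 0.9
  surf <- landscape_surface(pm, gen, grid = c(21, 5), alpha = 1)
  centre <- surf$grid[, 11]
  edges <- c(surf$grid[, 1], surf$grid[, 21])
  expect_gt(min(centre), max(edges))
})

test_that("large alpha approaches the nearest-midpoint surface", {
  pm <- population_set(
    setNames(paste0("P", 1:3), paste0("x", 1:3)),
    data.frame(population = paste0("P", 1:3),
               latitude = c(20, 20, 23), longitude = c(100, 104, 102)))
  labs <- paste0("P", 1:3)
  gen <- matrix(c(0, 0.2, 0.8, 0.2, 0, 0.5, 0.8, 0.5, 0), 3, 3,
                dimnames = list(labs, labs))
  surf <- landscape_surface(pm, gen, grid = c(25, 25), alpha = 20)
  mids <- surf$midpoints
  # at the grid node nearest each midpoint, that midpoint dominates
  for (k in seq_len(nrow(mids))) {
    ix <- which.min(abs(surf$x_coords - mids[k, 1]))
    iy <- which.min(abs(surf$y_coords - mids[k, 2]))
    expect_equal(unname(surf$grid[iy, ix]), unname(mids[k, "value"]),
                 tolerance = 0.02)
  }
})
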