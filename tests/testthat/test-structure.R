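make_pops <- function(aln, pop) {
  population_set(setNames(pop, aln$ids))
}

test_that("two populations fixed for different haplotypes give F_ST = 1", {
  a <- alignment(paste0("s", 1:8),
                 c(rep("AAAA", 4), rep("AATT", 4)))
  pm <- make_pops(a, rep(c("P1", "P2"), each = 4))
  pw <- pairwise_differentiation(a, pm, mode = "fst_freq", perms = 200,
                                 seed = 1)
  expect_equal(unname(pw$d["P1", "P2"]), 1)
  expect_lt(pw$p["P1", "P2"], 0.05)

  # identical composition: F_ST near 0, clearly not significant
  b <- alignment(paste0("t", 1:8),
                 rep(c("AAAA", "AAAA", "AATT", "AATT"), 2))
  pm2 <- make_pops(b, rep(c("P1", "P2"), 4))
  pw2 <- pairwise_differentiation(b, pm2, mode = "fst_freq", perms = 200,
                                  seed = 1)
  expect_lt(abs(pw2$d["P1", "P2"]), 0.35)
  expect_gt(pw2$p["P1", "P2"], 0.2)
})

test_that("4-sequence toy AMOVA reproduces the hand variance components", {
  # one fixed difference between populations, none within
  a <- alignment(paste0("s", 1:4), c("AAA", "AAA", "AAT", "AAT"))
  pm <- make_pops(a, c("P1", "P1", "P2", "P2"))
  am <- amova(a, pm, mode = "phist", perms = 0)
  expect_equal(unname(am$phi["F_ST"]), 1)
  expect_equal(unname(am$variance_components["within_populations"]), 0)
})

test_that("AMOVA components equal the direct-summation oracle", {
  set.seed(41)
  for (rep in 1:200) {
    n_per <- sample(2:5, 3, replace = TRUE)
    pop <- rep(c("A", "B", "C"), n_per)
    a <- random_alignment(sum(n_per), sample(4:10, 1), c("A", "T"))
    pm <- make_pops(a, pop)
    grouping <- c(A = "g1", B = "g1", C = "g2")
    am <- amova(a, pm, grouping = grouping, mode = "phist", perms = 0)
    d2 <- kdrscape:::pairwise_diff_matrix(a)
    or <- oracle_amova(d2, pop, unname(grouping[pop]))
    expect_equal(unname(am$phi["F_CT"]), unname(or["fct"]), tolerance = 1e-10)
    expect_equal(unname(am$phi["F_SC"]), unname(or["fsc"]), tolerance = 1e-10)
    expect_equal(unname(am$phi["F_ST"]), unname(or["fst"]), tolerance = 1e-10)
    expect_equal(sum(am$percentages), 100, tolerance = 1e-6)
  }
})

test_that("degenerate groupings behave as expected", {
  a <- alignment(paste0("s", 1:6),
                 c("AAA", "AAA", "TTA", "TTA", "TTT", "TTT"))
  pm <- make_pops(a, rep(c("P1", "P2", "P3"), each = 2))
  # one population per group, no within-population variation: all among groups
  am <- amova(a, pm, grouping = c(P1 = "g1", P2 = "g2", P3 = "g3"),
              mode = "phist", perms = 0)
  expect_equal(unname(am$percentages["among_groups"]), 100, tolerance = 1e-6)
  # single group falls back to the one-level analysis
  am2 <- amova(a, pm, grouping = c(P1 = "g", P2 = "g", P3 = "g"), perms = 0)
  expect_false("F_CT" %in% names(am2$phi))
  # all populations identical in composition: within dominates
  b <- alignment(paste0("t", 1:6), rep(c("AAA", "TTT"), 3))
  pm3 <- make_pops(b, rep(c("P1", "P2", "P3"), 2))
  am3 <- amova(b, pm3, perms = 0)
  expect_gt(unname(am3$percentages["within_populations"]), 99)
})

test_that("pairwise matrices are symmetric with correct p-value range", {
  set.seed(43)
  a <- random_alignment(18, 8, c("A", "T"))
  pm <- make_pops(a, rep(c("X", "Y", "Z"), each = 6))
  pw <- pairwise_differentiation(a, pm, perms = 100, seed = 2)
  expect_identical(pw$d, t(pw$d))
  expect_true(all(diag(pw$d) == 0))
  offp <- pw$p[upper.tri(pw$p)]
  expect_true(all(offp >= 1 / 101 & offp <= 1))
})

test_that("significant-pair counting applies FDR and Bonferroni", {
  p <- matrix(c(0, 0.001, 0.2, 0.001, 0, 0.04, 0.2, 0.04, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  fdr <- count_significant_pairs(p, "fdr")
  bon <- count_significant_pairs(p, "bonferroni")
  expect_gte(fdr$n_significant, bon$n_significant)
  expect_equal(fdr$n_pairs, 3L)
})

test_that("Nei's unbiased distance matches the closed-form toy case", {
  # two populations sharing one of two equifrequent haplotypes
  counts <- matrix(c(5, 5, 0, 5, 0, 5), ncol = 2,
                   dimnames = list(NULL, c("X", "Y")))
  d <- nei_distance(list(counts = counts))
  nX <- 10
  Jx <- (nX * 0.5 - 1) / (nX - 1)          # sum x^2 = 0.5
  Jxy <- 0.25
  expect_equal(unname(d["X", "Y"]), -log(Jxy / Jx))

  # identical frequency vectors, large n: distance ~ 0
  big <- matrix(c(500, 500, 500, 500), ncol = 2,
                dimnames = list(NULL, c("X", "Y")))
  expect_lt(unname(nei_distance(list(counts = big))["X", "Y"]), 0.01)

  # disjoint haplotype sets: capped infinite distance
  dis <- matrix(c(5, 0, 0, 5), ncol = 2, dimnames = list(NULL, c("X", "Y")))
  dd <- nei_distance(list(counts = dis), cap = 10)
  expect_equal(unname(dd["X", "Y"]), 10)
  expect_true(attr(dd, "capped")["X", "Y"])
})

test_that("UPGMA reproduces hand agglomeration and the two-taxon case", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- ape::read.tree(text = upgma(d))
  ref <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  labs <- c("A", "B", "C")
  expect_equal(ape::cophenetic.phylo(tr)[labs, labs],
               ape::cophenetic.phylo(ref)[labs, labs])

  two <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(upgma(two), "(A:1,B:1);")
  expect_error(upgma(matrix(c(0, NA, NA, 0), 2, 2,
                            dimnames = list(c("A", "B"), c("A", "B")))),
               "input error")
})

test_that("UPGMA recovers ultrametric hierarchies exactly and matches hclust", {
  set.seed(47)
  for (rep in 1:25) {
    # random ultrametric matrix via a random hierarchy
    n <- sample(4:8, 1)
    labs <- paste0("t", 1:n)
    hc <- stats::hclust(stats::as.dist(
      matrix(runif(n * n), n, n, dimnames = list(labs, labs))), "average")
    ultra <- stats::cophenetic(hc)
    d <- as.matrix(ultra)
    tr <- ape::read.tree(text = upgma(d))
    coph <- ape::cophenetic.phylo(tr)[labs, labs]
    expect_equal(coph, d[labs, labs], tolerance = 1e-8)
  }
})
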