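test_that("simulation is byte-identical under a fixed seed and varies across seeds", {
  cfg <- sim_config(n_demes = 2, samples_per_deme = 6, migration = 1,
                    theta_per_site = 0.003, seed = 77)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$aln$mat, b$aln$mat)
  cfg2 <- cfg; cfg2$seed <- 78
  c2 <- simulate_dataset(cfg2)
  expect_false(identical(a$aln$mat, c2$aln$mat))
})

test_that("pairwise coalescence time has the neutral expectation", {
  set.seed(71)
  tm <- replicate(4000, coalescent_tree(2)$tmrca)
  expect_lt(abs(mean(tm) - 1), 0.05)
})

test_that("segregating sites follow Watterson's expectation", {
  set.seed(73)
  theta <- 4
  S <- replicate(3000, {
    tr <- coalescent_tree(10)
    sum(rpois(length(tr$lengths), theta / 2 * tr$lengths))
  })
  expect_lt(abs(mean(S) / (theta * sum(1 / (1:9))) - 1), 0.05)
})

test_that("high migration approaches panmixia (F_ST near 0)", {
  set.seed(79)
  fst <- replicate(25, {
    sim <- simulate_dataset(sim_config(n_demes = 2, samples_per_deme = 10,
                                       migration = 100, theta_per_site = 0.01,
                                       seed = sample.int(1e6, 1)))
    am <- amova(sim$aln, sim$pops, perms = 0)
    unname(am$phi["F_ST"])
  })
  expect_lt(abs(mean(fst)), 0.05)
})

test_that("theta = 0 yields identical sequences and mutations respect the mask", {
  sim <- simulate_dataset(sim_config(n_demes = 1, samples_per_deme = 8,
                                     theta_per_site = 0, seed = 5))
  expect_equal(length(unique(apply(sim$aln$mat, 1, paste, collapse = ""))), 1L)

  sim2 <- simulate_dataset(sim_config(n_demes = 1, samples_per_deme = 10,
                                      theta_per_site = 0.01, seed = 6))
  exon_cols <- layout_columns(sim2$layout, "exon")
  for (j in exon_cols) {
    expect_equal(length(unique(sim2$aln$mat[, j])), 1L)
  }
  # wild codon everywhere without a sweep
  expect_true(all(classify_kdr_codon(sim2$aln, sim2$layout)$allele_class ==
                  "wild_L"))
})

test_that("the sweep overlay is the identity at frequency zero", {
  sim <- simulate_dataset(sim_config(n_demes = 2, samples_per_deme = 8,
                                     migration = 1, seed = 8))
  out <- implant_sweep(sim$aln, sim$pops,
                       list(demes = "D1", allele = "F",
                            final_frequency = 0, background_count = 1),
                       sim$layout)
  expect_identical(out$mat, sim$aln$mat)
})

test_that("the sweep reduces intron haplotype diversity in target demes", {
  set.seed(83)
  hits <- replicate(30, {
    cfg <- sim_config(n_demes = 2, samples_per_deme = 20, migration = 1,
                      theta_per_site = 0.008,
                      sweep = list(demes = "D1", allele = "F",
                                   final_frequency = 0.95,
                                   background_count = 1),
                      seed = sample.int(1e6, 1))
    sim <- simulate_dataset(cfg)
    introns <- extract_region(sim$aln, sim$layout, "intron")$aln
    hd <- diversity_by_population(introns, sim$pops)
    hd$Hd[hd$population == "D1"] < hd$Hd[hd$population == "D2"]
  })
  expect_gte(mean(hits), 0.95)
})

test_that("two sweep backgrounds produce at least two recoverable origins", {
  set.seed(87)
  ok <- replicate(10, {
    cfg <- sim_config(n_demes = 2, samples_per_deme = 30, migration = 1,
                      theta_per_site = 0.01,
                      sweep = list(demes = "D1", allele = c("F", "C"),
                                   final_frequency = 0.9,
                                   background_count = 2),
                      seed = sample.int(1e6, 1))
    sim <- simulate_dataset(cfg)
    info <- informative_sites(sim$aln, sim$layout, maf = 0.05)
    states <- select_sites(sim$aln, info$sites, sim$pops)
    net <- build_network(states, 2L, layout = sim$layout)
    if (any(net$nodes$allele_class == "unresolved")) return(NA)
    count_origin_events(net)$n_events >= 2
  })
  expect_gte(mean(ok, na.rm = TRUE), 0.7)
})

test_that("single-deme and degenerate configurations behave", {
  sim <- simulate_dataset(sim_config(n_demes = 1, samples_per_deme = 4, seed = 3))
  expect_equal(length(populations(sim$pops)), 1L)
  expect_error(sim_config(n_demes = 1, samples_per_deme = 0), "domain error")
  expect_error(structured_coalescent(c(3, 3), 0), "divergence_time")
})
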