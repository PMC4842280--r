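test_that("codon classification agrees with an independent translation oracle", {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  lay <- fragment_layout(data.frame(label = "exon", start = 1, end = 3),
                         c(1, 3))
  a <- alignment(paste0("s", seq_along(codons)), codons)
  got <- classify_kdr_codon(a, lay)
  oracle_aa <- toupper(vapply(strsplit(codons, ""), function(x) {
    seqinr::translate(tolower(x))
  }, character(1)))
  oracle_aa[oracle_aa == "*"] <- "*"
  expect_equal(got$amino_acid, oracle_aa)
  cls <- function(aa) switch(aa, L = "wild_L", F = "F", C = "C", S = "S",
                             W = "W", "other")
  expect_equal(got$allele_class, vapply(oracle_aa, cls, character(1)),
               ignore_attr = TRUE)
})

test_that("the kdr alleles of the survey translate to their classes", {
  lay <- fragment_layout(data.frame(label = "exon", start = 1, end = 3),
                         c(1, 3))
  a <- alignment(paste0("s", 1:5), c("TTG", "TTT", "TGT", "TCG", "NTG"))
  got <- classify_kdr_codon(a, lay)
  expect_equal(got$allele_class,
               c("wild_L", "F", "C", "S", "unresolved"))
})

test_that("allele frequency rows sum to one and match arithmetic", {
  lay <- fragment_layout(data.frame(label = "exon", start = 1, end = 3),
                         c(1, 3))
  a <- alignment(paste0("s", 1:10), c(rep("TTT", 8), rep("TTG", 2)))
  pm <- population_set(setNames(rep("D", 10), a$ids))
  fr <- allele_frequencies(classify_kdr_codon(a, lay), pm)
  expect_equal(fr$F, 0.8)
  expect_equal(fr$wild_L, 0.2)
  num <- fr[, !(names(fr) %in% c("population", "n")), drop = FALSE]
  expect_equal(rowSums(num), 1, ignore_attr = TRUE)

  b <- alignment(paste0("t", 1:6), rep("TTG", 6))
  pm2 <- population_set(setNames(rep(c("D1", "D2"), 3), b$ids))
  fr2 <- allele_frequencies(classify_kdr_codon(b, lay), pm2)
  expect_true(all(fr2$wild_L == 1))
})

test_that("informative sites respect the frequency threshold", {
  lay <- fragment_layout(data.frame(label = c("intron", "exon"),
                                    start = c(1, 3), end = c(2, 5)),
                         c(3, 5))
  # column 1: minor count 1/100; column 2: 50/50
  seqs <- c(paste0("CA", "TTG"), rep(paste0("AA", "TTG"), 49),
            rep(paste0("AT", "TTG"), 50))
  a <- alignment(paste0("s", 1:100), seqs)
  info <- informative_sites(a, lay, maf = 0.10)
  expect_equal(info$intron_sites, 2L)
  expect_equal(info$codon_sites, integer(0))   # codon is monomorphic
  expect_error(informative_sites(a, lay, maf = 0.6), "maf")
})

test_that("network construction matches the hand-built chain with root weights", {
  lay <- fragment_layout(data.frame(label = c("intron", "exon"),
                                    start = c(1, 2), end = c(1, 4)),
                         c(2, 4))
  seqs <- c(rep("AA", 5), rep("AT", 3), rep("TT", 1))
  # states over two selected sites, built directly
  st <- collapse_haplotypes(alignment(paste0("s", 1:9), seqs))
  attr(st, "sites") <- c(1L, 2L)
  net <- build_network(st, connection_limit = 2L, codon_sites = integer(0),
                       layout = lay)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 2L)          # AA-AT and AT-TT, not AA-TT
  expect_equal(net$edges$steps, c(1L, 1L))
  expect_equal(which.max(net$nodes$root_prob), 1L)  # AA most frequent
  expect_equal(sum(net$nodes$root_prob), 1)

  single <- collapse_haplotypes(alignment("s1", "AC"))
  attr(single, "sites") <- c(1L, 2L)
  n1 <- build_network(single, codon_sites = integer(0), layout = lay)
  expect_equal(nrow(n1$nodes), 1L)
  expect_equal(nrow(n1$edges), 0L)

  # two haplotypes three steps apart with limit 2: two components
  far <- collapse_haplotypes(alignment(c("a", "b"), c("AAA", "TTT")))
  attr(far, "sites") <- 1:3
  lay3 <- fragment_layout(data.frame(label = c("intron", "exon"),
                                     start = c(1, 4), end = c(3, 6)),
                          c(4, 6))
  n2 <- build_network(far, connection_limit = 2L, codon_sites = integer(0),
                      layout = lay3)
  expect_equal(nrow(n2$edges), 0L)
  expect_equal(max(n2$nodes$component), 2L)
})

test_that("network equals the brute-force minimum-spanning construction", {
  set.seed(61)
  lay <- fragment_layout(data.frame(label = c("intron", "exon"),
                                    start = c(1, 5), end = c(4, 7)),
                         c(5, 7))
  for (rep in 1:200) {
    k <- sample(2:6, 1)
    states <- unique(replicate(k, paste(sample(c("A", "T"), 4, replace = TRUE),
                                        collapse = "")))
    a <- alignment(paste0("s", seq_along(states)), states)
    st <- collapse_haplotypes(a)
    attr(st, "sites") <- 1:4
    net <- build_network(st, connection_limit = 2L,
                         codon_sites = integer(0), layout = lay)
    got <- as.matrix(net$edges[order(net$edges$from, net$edges$to),
                               c("from", "to", "steps")])
    storage.mode(got) <- "double"
    want <- oracle_msn(states, 2L)
    storage.mode(want) <- "double"
    expect_equal(dim(got), dim(want))
    if (nrow(want) > 0) expect_equal(unname(got), unname(want))
  }
})

test_that("origin events are counted per codon-changing edge", {
  lay <- kdr_layout()
  mk_states <- function(seqs, counts) {
    a <- alignment(paste0("s", seq_len(sum(counts))), rep(seqs, counts))
    st <- collapse_haplotypes(a)
    attr(st, "sites") <- c(100L, 1161L, 1162L)   # one intron + the codon pair
    st
  }
  # chain wild(A) -> F(A): one event on background A
  st <- mk_states(c("ATG", "ATT"), c(5, 3))
  net <- build_network(st, 2L, layout = lay)
  rep1 <- count_origin_events(net)
  expect_equal(rep1$n_events, 1L)
  expect_equal(rep1$events$allele, "F")
  expect_equal(rep1$events$background, "A")

  # star: wild centre, two F neighbours on different backgrounds
  st2 <- mk_states(c("ATG", "ATT", "TTG", "TTT"), c(6, 3, 4, 2))
  net2 <- build_network(st2, 2L, layout = lay)
  rep2 <- count_origin_events(net2)
  expect_equal(sum(rep2$events$allele == "F"), 2L)
  expect_equal(rep2$n_backgrounds, 2L)

  # two-step path wild -> F -> C counts C as a further event derived from F
  st3 <- mk_states(c("ATG", "ATT", "AGT"), c(6, 5, 2))
  net3 <- build_network(st3, 2L, layout = lay)
  rep3 <- count_origin_events(net3)
  expect_setequal(rep3$events$allele, c("F", "C"))
  expect_equal(rep3$n_events, 2L)

  # invariance under node relabeling (input order shuffled)
  st4 <- mk_states(c("AGT", "ATG", "ATT"), c(2, 6, 5))
  rep4 <- count_origin_events(build_network(st4, 2L, layout = lay))
  expect_equal(rep4$n_events, rep3$n_events)
  expect_setequal(rep4$events$allele, rep3$events$allele)
})
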