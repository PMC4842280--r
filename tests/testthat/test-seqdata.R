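test_that("FASTA round trip preserves ids and sequences exactly", {
  a <- alignment(c("x1", "x2"), c("ACGT", "ACGA"))
  expect_equal(a$length, 4L)
  expect_equal(n_seq(a), 2L)
  f <- tempfile(fileext = ".fasta")
  write_alignment(a, f)
  b <- read_alignment(f)
  expect_identical(b$ids, a$ids)
  expect_identical(b$mat, a$mat)
})

test_that("malformed alignments are rejected with informative errors", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGTA"), f)
  expect_error(read_alignment(f), "alignment-shape.*'b'")
  expect_error(alignment(c("a", "b"), c("ACGT", "ACXT")), "illegal character 'X'")
  expect_error(alignment(c("a", "a"), c("AC", "AC")), "unique")
  # lower case is normalised, gaps and N are legal states
  a <- alignment("s", "acg-n")
  expect_identical(a$mat[1, ], c("A", "C", "G", "-", "N"))
})

test_that("popmap parsing handles coordinates, regions and bad input", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tpopulation\tlatitude\tlongitude\tregion",
               "s1\tP1\t24.5\t98.2\twest",
               "s2\tP1\t24.5\t98.2\twest",
               "s3\tP2\t30.1\t104.0\teast"), f)
  pm <- read_popmap(f)
  expect_equal(length(populations(pm)), 2L)
  expect_equal(nrow(pm$pop_coords), 2L)
  expect_equal(unname(pm$pop_region["P2"]), "east")

  writeLines(c("sample\tpopulation", "s1\tP1", "s1\tP2"), f)
  expect_error(read_popmap(f), "duplicate sample")
  writeLines(c("sample\tpopulation\tcolour", "s1\tP1\tred"), f)
  expect_error(read_popmap(f), "unknown column")
  expect_error(population_set(c(s1 = "P"),
                              data.frame(population = "P", latitude = 95,
                                         longitude = 0)),
               "latitude")
})

test_that("degree-minute coordinate strings convert to decimal degrees", {
  expect_equal(parse_dms("24°51'"), 24 + 51 / 60)
  expect_equal(parse_dms(c("98°18'", "30.25")), c(98.3, 30.25))
  # the packaged 15-site table parses to one coordinate pair per site
  f <- system.file("extdata", "sites.tsv", package = "kdrscape")
  pm <- read_popmap(f)
  expect_equal(length(populations(pm)), 15L)
  expect_equal(nrow(pm$pop_coords), 15L)
  expect_true(all(pm$pop_coords$latitude > 18 & pm$pop_coords$latitude < 35))
})

test_that("fragment layout validates tiling and codon placement", {
  expect_error(fragment_layout(data.frame(label = c("exon", "intron"),
                                          start = c(1, 4), end = c(2, 6)),
                               c(1, 3)),
               "tile")
  expect_error(fragment_layout(data.frame(label = "exon", start = 1, end = 9),
                               c(1, 4)), "3 bases")
  expect_error(fragment_layout(data.frame(label = c("exon", "intron"),
                                          start = c(1, 5), end = c(4, 10)),
                               c(4, 6)), "inside one exon")
  lay <- kdr_layout()
  expect_equal(lay$length, 1285L)
  expect_equal(sum(lay$segments$end - lay$segments$start + 1), 1285)
  f <- tempfile(fileext = ".json")
  write_layout(lay, f)
  lay2 <- read_layout(f)
  expect_equal(lay2$segments$start, lay$segments$start)
  expect_equal(lay2$codon, lay$codon)
})

test_that("extract_region selects intron columns, identity and errors", {
  lay <- fragment_layout(data.frame(label = c("exon", "intron", "exon"),
                                    start = c(1, 3, 5), end = c(2, 4, 7)),
                         c(5, 7))
  a <- alignment(c("s1", "s2"), c("ACGTAAA", "ACTTAAA"))
  ex <- extract_region(a, lay, "intron")
  expect_equal(ex$aln$mat[1, ], c("G", "T"))
  expect_equal(ex$col_map, 3:4)
  idc <- extract_region(a, lay, c("exon", "intron"))
  expect_identical(idc$aln$mat, a$mat)
  expect_error(extract_region(a, lay, character(0)), "empty-region")

  # kdr layout: intron restriction of a 1285-column alignment keeps 969
  lay2 <- kdr_layout()
  b <- alignment("s", strrep("A", 1285))
  expect_equal(extract_region(b, lay2, "intron")$aln$length, 969L)
  # disjoint label sets partition the columns
  n_int <- extract_region(b, lay2, "intron")$aln$length
  n_ex <- extract_region(b, lay2, "exon")$aln$length
  expect_equal(n_int + n_ex, 1285L)
})

test_that("haplotype collapsing counts by population deterministically", {
  a <- alignment(c("s1", "s2", "s3"), c("AA", "AA", "AT"))
  pm <- population_set(c(s1 = "P", s2 = "P", s3 = "P"))
  ht <- collapse_haplotypes(a, pm)
  expect_equal(length(ht$haplotypes), 2L)
  expect_equal(unname(rowSums(ht$counts)), c(2L, 1L))
  expect_equal(ht$haplotypes[1], "AA")   # first-occurrence order

  same <- alignment(paste0("s", 1:4), rep("GGG", 4))
  expect_equal(length(collapse_haplotypes(same)$haplotypes), 1L)
  expect_error(collapse_haplotypes(a, population_set(c(s1 = "P", s2 = "P"))),
               "mapping error")
})

test_that("collapse counts sum to n for random inputs", {
  set.seed(1)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    a <- random_alignment(n, sample(3:8, 1), alphabet = c("A", "T"))
    pm <- population_set(setNames(sample(c("X", "Y"), n, replace = TRUE),
                                  a$ids))
    ht <- collapse_haplotypes(a, pm)
    expect_equal(sum(ht$counts), n)
    expect_equal(anyDuplicated(ht$haplotypes), 0L)
    sizes <- table(pm$sample_to_pop)
    expect_equal(colSums(ht$counts)[names(sizes)], unclass(sizes)[names(sizes)],
                 ignore_attr = TRUE)
  }
})
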