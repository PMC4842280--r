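Package: kdrscape
Title: Landscape Genetics of Knockdown-Resistance Mutations in Anopheles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genetic analysis of the evolutionary origins of
    knockdown-resistance (kdr) mutations at codon L1014 of the para-type
    sodium channel gene in Anopheles sinensis. Implements per-population
    sequence diversity and neutrality statistics (Tajima's D, Fu and Li's
    D* and F*, Fu's Fs, Ramos-Onsins and Rozas's R2) with coalescent null
    distributions, mismatch-distribution fitting under the sudden-expansion
    model (tau, theta0, theta1, SSD, raggedness), hierarchical AMOVA with
    permutation tests, SAMOVA group search by simulated annealing, Mantel
    isolation-by-distance, inverse-distance-weighted genetic landscape
    surfaces, and a statistical-parsimony haplotype network that counts
    independent mutational origins of resistance alleles. A structured
    coalescent simulator with infinite-sites mutation and a phenomenological
    selective-sweep overlay generates synthetic datasets with the
    statistical structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    seqinr,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
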