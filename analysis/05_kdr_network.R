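#!/usr/bin/env Rscript
# kdr codon classification, per-population allele frequencies,
# informative-site selection, the statistical-parsimony network, and the
# count of independent resistance origins.

suppressPackageStartupMessages(library(kdrscape))

aln <- read_alignment("results/survey.fasta")
pops <- read_popmap("results/survey_popmap.tsv")
layout <- read_layout("results/survey_layout.json")

alleles <- classify_kdr_codon(aln, layout)
freqs <- allele_frequencies(alleles, pops)
write.table(freqs, "results/kdr_allele_frequencies.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
res <- setNames(1 - freqs$wild_L, freqs$population)
cat(sprintf("resistant-codon frequency: central %.2f, south %.2f, southwest %.2f\n",
            mean(res[11:15]), mean(res[4:10]), mean(res[1:3])))

info <- informative_sites(aln, layout, maf = 0.10)
cat(sprintf("informative intron sites (>10%% minor allele): %s\n",
            paste(info$intron_sites, collapse = ", ")))
cat(sprintf("variable codon positions: %s\n",
            paste(info$codon_sites, collapse = ", ")))

states <- select_sites(aln, info$sites, pops)
net <- build_network(states, connection_limit = 2L, layout = layout)
write_network(net, "results/network_edges.tsv")
origins <- count_origin_events(net)
jsonlite::write_json(list(n_events = origins$n_events,
                          n_backgrounds = origins$n_backgrounds,
                          n_resistant_haplotypes = origins$n_resistant_haplotypes,
                          alleles = origins$events$allele),
                     "results/origins.json", auto_unbox = TRUE, digits = NA)
cat(sprintf("network: %d nodes, %d edges, %d component(s)\n",
            nrow(net$nodes), nrow(net$edges), max(net$nodes$component)))
cat(sprintf("at least %d independent origin event(s) on %d intron background(s); %d resistant haplotype(s)\n",
            origins$n_events, origins$n_backgrounds,
            origins$n_resistant_haplotypes))
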