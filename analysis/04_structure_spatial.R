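#!/usr/bin/env Rscript
# Hierarchical AMOVA, pairwise differentiation, UPGMA on Nei distances,
# Mantel isolation-by-distance, SAMOVA group search, and the genetic
# landscape surface.

suppressPackageStartupMessages(library(kdrscape))
seed <- as.integer(Sys.getenv("KDRSCAPE_SEED", "11"))

aln <- read_alignment("results/survey.fasta")
pops <- read_popmap("results/survey_popmap.tsv")
layout <- read_layout("results/survey_layout.json")
introns <- extract_region(aln, layout, "intron")$aln

am <- amova(introns, pops, grouping = pops$pop_region, mode = "phist",
            perms = 199, seed = seed)
write.table(data.frame(statistic = names(am$phi), value = unname(am$phi),
                       p = unname(am$pvals)),
            "results/amova.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("AMOVA: F_CT=%.3f (p=%.3f), F_SC=%.3f, F_ST=%.3f\n",
            am$phi["F_CT"], am$pvals["F_CT"], am$phi["F_SC"], am$phi["F_ST"]))

pw <- pairwise_differentiation(introns, pops, mode = "fst_freq",
                               perms = 200, seed = seed)
write.table(round(pw$d, 5), "results/pairwise_fst.tsv", sep = "\t",
            quote = FALSE, col.names = NA)
sig <- count_significant_pairs(pw$p, method = "fdr")
cat(sprintf("%d of %d population pairs significantly differentiated (FDR)\n",
            sig$n_significant, sig$n_pairs))

ht <- collapse_haplotypes(introns, pops)
tree <- upgma(nei_distance(list(counts = ht$counts)))
writeLines(tree, "results/upgma_nei.nwk")

ibd <- ibd_inputs(introns, pops, perms = 100, seed = seed)
mt <- mantel(ibd$geo, ibd$gen, perms = 999, seed = seed)
jsonlite::write_json(mt, "results/mantel.json", auto_unbox = TRUE, digits = NA)
cat(sprintf("Mantel isolation-by-distance: r=%.3f, R2=%.3f, p=%.3f (n=%d pairs)\n",
            mt$r, mt$R2, mt$p, mt$n_pairs))

sam <- samova(introns, pops, K_range = 2:5, runs = 10, iters = 2000,
              seed = seed)
samtab <- do.call(rbind, lapply(sam$per_k, function(x) {
  data.frame(K = x$K, F_CT = x$phi["F_CT"], F_SC = x$phi["F_SC"],
             F_ST = x$phi["F_ST"],
             grouping = paste(x$best_grouping, collapse = ","))
}))
write.table(samtab, "results/samova.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("SAMOVA best F_CT by K: %s\n",
            paste(sprintf("K=%s:%.3f", names(sam$fct_trace), sam$fct_trace),
                  collapse = "  ")))

surf <- landscape_surface(pops, ibd$gen, grid = c(80, 80), alpha = 1)
write.table(surf$grid, "results/landscape_grid.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
cat(sprintf("landscape surface: %dx%d grid, height range [%.3f, %.3f]\n",
            nrow(surf$grid), ncol(surf$grid), min(surf$grid), max(surf$grid)))
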