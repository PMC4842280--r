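#' Pipeline configuration
#'
#' Bundles inputs (paths or a [sim_config()]), stage toggles, and the
#' statistical parameters of each stage. Every stochastic stage derives
#' its seed deterministically from `seed`.
#'
#' @param aln_path,popmap_path,layout_path input files (FASTA / TSV /
#'   JSON), or `NULL` when `synth` is supplied.
#' @param synth optional [sim_config()] generating the inputs in-process.
#' @param out_dir output directory.
#' @param stages character subset of
#'   `c("diversity", "neutrality", "expansion", "structure", "spatial",
#'   "kdrnet")`.
#' @param perms permutations for permutation tests.
#' @param reps replicates for coalescent nulls / bootstraps.
#' @param maf informative-site threshold.
#' @param connection_limit network connection limit (mutational steps).
#' @param K_range SAMOVA group numbers.
#' @param samova_runs,samova_iters SAMOVA effort per K.
#' @param grid landscape grid size `c(nx, ny)`.
#' @param alpha landscape distance-weighting exponent.
#' @param mu_locus optional per-locus per-year mutation rate for
#'   expansion-time conversion.
#' @param seed master seed (mandatory).
#' @param overwrite allow writing into an existing non-empty `out_dir`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(aln_path = NULL, popmap_path = NULL,
                            layout_path = NULL, synth = NULL,
                            out_dir = tempfile("kdrscape_run_"),
                            stages = c("diversity", "neutrality", "expansion",
                                       "structure", "spatial", "kdrnet"),
                            perms = 1000L, reps = 1000L, maf = 0.10,
                            connection_limit = 2L, K_range = 2:5,
                            samova_runs = 10L, samova_iters = 1000L,
                            grid = c(80L, 80L), alpha = 1,
                            mu_locus = NULL, seed = NULL,
                            overwrite = FALSE) {
  if (is.null(seed)) stop("pipeline runs require an explicit seed", call. = FALSE)
  if (is.null(synth) && is.null(aln_path)) {
    stop("either input paths or a synth config must be given", call. = FALSE)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

pipeline_seed <- function(cfg, stage) {
  (cfg$seed * 1000L + match(stage, c("synth", "diversity", "neutrality",
                                     "expansion", "structure", "spatial",
                                     "kdrnet"))) %% .Machine$integer.max
}

#' Run the full analysis pipeline
#'
#' Executes, per the configured stages: per-population diversity,
#' neutrality tests with coalescent null p-values and FDR adjustment,
#' sudden-expansion fits with bootstrap goodness-of-fit, hierarchical
#' AMOVA and pairwise differentiation with a UPGMA tree on Nei
#' distances, Mantel isolation-by-distance, SAMOVA, the landscape
#' surface, and the kdr codon / network / origin analysis. Writes plain
#' TSV/JSON/Newick reports plus a run manifest into `out_dir` and
#' returns the result objects invisibly.
#'
#' @param cfg a [pipeline_config()].
#' @return (invisibly) a named list of per-stage results.
#' @export
run_pipeline <- function(cfg) {
  if (dir.exists(cfg$out_dir) &&
      length(dir(cfg$out_dir)) > 0L && !cfg$overwrite) {
    stop(sprintf("output directory %s is not empty (set overwrite = TRUE)",
                 cfg$out_dir), call. = FALSE)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)

  if (!is.null(cfg$synth)) {
    cfg$synth$seed <- pipeline_seed(cfg, "synth")
    ds <- simulate_dataset(cfg$synth)
    aln <- ds$aln; pops <- ds$pops; layout <- ds$layout
    write_alignment(aln, out("input.fasta"))
    write_popmap(pops, out("input_popmap.tsv"))
  } else {
    aln <- read_alignment(cfg$aln_path)
    pops <- read_popmap(cfg$popmap_path)
    layout <- if (!is.null(cfg$layout_path)) read_layout(cfg$layout_path)
              else kdr_layout()
  }
  grouping <- pops$pop_region
  results <- list(aln = aln, pops = pops, layout = layout)
  pop_ids <- populations(pops)
  pop_samples <- function(p) {
    intersect(aln$ids, names(pops$sample_to_pop)[pops$sample_to_pop == p])
  }

  ## intron region: the neutral flank the per-population statistics use
  introns <- extract_region(aln, layout, "intron")$aln

  if ("diversity" %in% cfg$stages || "neutrality" %in% cfg$stages ||
      "expansion" %in% cfg$stages) {
    rows <- list()
    for (p in pop_ids) {
      sub <- subset_alignment(introns, pop_samples(p))
      st <- diversity_stats(sub)
      row <- data.frame(population = p, n = st$n, S = st$S, K = st$K,
                        Pi = st$Pi, h = st$h, Hd = st$Hd)
      if ("neutrality" %in% cfg$stages && st$n >= 4L && st$S >= 1L) {
        obs <- neutrality_stats(sub)
        pv <- neutrality_pvalues(obs, st$n, st$S, reps = cfg$reps,
                                 seed = pipeline_seed(cfg, "neutrality"))
        for (s in pv$statistic) {
          row[[s]] <- pv$value[pv$statistic == s]
          row[[paste0("p_", s)]] <- pv$p[pv$statistic == s]
        }
      }
      if ("expansion" %in% cfg$stages && st$n >= 5L && st$S >= 1L) {
        mm <- mismatch_distribution(sub)
        fit <- fit_expansion(mm, method = "least_squares")
        gof <- gof_bootstrap(fit, mm, st$n,
                             reps = max(100L, cfg$reps %/% 5L),
                             seed = pipeline_seed(cfg, "expansion"))
        row$tau <- fit$tau; row$theta0 <- fit$theta0; row$theta1 <- fit$theta1
        row$SSD <- fit$SSD; row$p_SSD <- gof$p_SSD
        row$r <- gof$obs_r; row$p_r <- gof$p_r
        if (!is.null(cfg$mu_locus)) {
          row$time_years <- expansion_time(fit$tau, cfg$mu_locus)
        }
      }
      rows[[p]] <- row
    }
    tab <- do.call(rbind, lapply(rows, function(r) {
      missing <- setdiff(unique(unlist(lapply(rows, names))), names(r))
      for (mcol in missing) r[[mcol]] <- NA
      r[, unique(unlist(lapply(rows, names)))]
    }))
    pcols <- grep("^p_", names(tab), value = TRUE)
    for (pc in pcols) tab[[sub("^p_", "q_", pc)]] <- fdr_adjust(tab[[pc]])
    utils::write.table(tab, out("population_stats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    results$population_stats <- tab
  }

  if ("structure" %in% cfg$stages) {
    am <- amova(introns, pops, grouping = grouping, mode = "phist",
                perms = cfg$perms, seed = pipeline_seed(cfg, "structure"))
    amtab <- data.frame(statistic = names(am$phi), value = unname(am$phi),
                        p = unname(am$pvals))
    utils::write.table(amtab, out("amova.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    pw <- pairwise_differentiation(introns, pops, mode = "fst_freq",
                                   perms = max(100L, cfg$perms %/% 10L),
                                   seed = pipeline_seed(cfg, "structure"))
    utils::write.table(round(pw$d, 5), out("pairwise_fst.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    ht <- collapse_haplotypes(introns, pops)
    keepable <- colSums(ht$counts) >= 2L
    nei <- nei_distance(list(counts = ht$counts[, keepable, drop = FALSE]))
    tree <- upgma(nei)
    writeLines(tree, out("upgma_nei.nwk"))
    results$amova <- am; results$pairwise <- pw; results$upgma <- tree
  }

  if ("spatial" %in% cfg$stages && !is.null(pops$pop_coords)) {
    ibd <- ibd_inputs(introns, pops, perms = max(100L, cfg$perms %/% 10L),
                      seed = pipeline_seed(cfg, "spatial"))
    mt <- mantel(ibd$geo, ibd$gen, perms = cfg$perms,
                 seed = pipeline_seed(cfg, "spatial"))
    jsonlite::write_json(mt, out("mantel.json"), auto_unbox = TRUE, digits = NA)
    sam <- samova(introns, pops, K_range = cfg$K_range,
                  runs = cfg$samova_runs, iters = cfg$samova_iters,
                  seed = pipeline_seed(cfg, "spatial"))
    samtab <- do.call(rbind, lapply(sam$per_k, function(x) {
      data.frame(K = x$K, F_CT = x$phi["F_CT"], F_SC = x$phi["F_SC"],
                 F_ST = x$phi["F_ST"],
                 grouping = paste(x$best_grouping, collapse = ","))
    }))
    utils::write.table(samtab, out("samova.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    surf <- landscape_surface(pops, ibd$gen, grid = cfg$grid,
                              alpha = cfg$alpha)
    utils::write.table(surf$grid, out("landscape_grid.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    results$mantel <- mt; results$samova <- sam; results$surface <- surf
  }

  if ("kdrnet" %in% cfg$stages) {
    alleles <- classify_kdr_codon(aln, layout)
    freqs <- allele_frequencies(alleles, pops)
    utils::write.table(freqs, out("kdr_allele_frequencies.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    info <- informative_sites(aln, layout, maf = cfg$maf)
    states <- select_sites(aln, info$sites, pops)
    net <- build_network(states, connection_limit = cfg$connection_limit,
                         layout = layout)
    write_network(net, out("network_edges.tsv"))
    origins <- count_origin_events(net)
    jsonlite::write_json(
      list(n_events = origins$n_events,
           n_backgrounds = origins$n_backgrounds,
           n_resistant_haplotypes = origins$n_resistant_haplotypes),
      out("origins.json"), auto_unbox = TRUE, digits = NA)
    results$alleles <- alleles; results$allele_freqs <- freqs
    results$informative <- info; results$network <- net
    results$origins <- origins
  }

  manifest <- list(seed = cfg$seed, stages = cfg$stages,
                   perms = cfg$perms, reps = cfg$reps, maf = cfg$maf,
                   connection_limit = cfg$connection_limit,
                   n_sequences = n_seq(aln), n_populations = length(pop_ids),
                   alignment_length = aln$length,
                   package_version = as.character(utils::packageVersion("kdrscape")))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  results$manifest <- manifest
  invisible(results)
}
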