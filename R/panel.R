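## SYNTHETIC stand-in for the deposited 85-haplotype panel of the kdr
## fragment. The real panel lives in GenBank and is not redistributed
## here; this construction is a deterministic, fully in-code panel whose
## ground truth mirrors the published summary structure (85 distinct
## 1285 bp haplotypes; 71 polymorphic sites of which 65 are intronic;
## six intron sites above 10 % minor-allele frequency at the published
## positions; 18 six-site haplotypes; resistant codons arising on seven
## distinct intron backgrounds). Every quantity the pipeline is checked
## against below is derivable from the construction, not from the
## deposited sequences.

#' Synthetic stand-in for the deposited kdr haplotype panel
#'
#' Builds, deterministically and without RNG, an 85-haplotype panel of
#' the 1285 bp kdr fragment together with a 546-chromosome weighted
#' sample, for exercising the full informative-site / network / origin
#' pipeline offline. This is a constructed object, not the deposited
#' GenBank data; its design truth is returned alongside so tests can
#' verify recovery.
#'
#' @return list with `panel` (the 85-haplotype [alignment()]), `sample`
#'   (the 546-chromosome weighted [alignment()]), `pops` (a trivial
#'   one-population [population_set()] for the weighted sample),
#'   `layout`, `counts` (per-haplotype multiplicities), and `truth`
#'   (design ground truth).
#' @export
synthetic_deposited_panel <- function() {
  layout <- kdr_layout()
  L <- layout$length
  bases <- c("A", "C", "G", "T")
  reference <- bases[(seq_len(L) %% 4L) + 1L]
  reference[1160:1162] <- c("T", "T", "G")   # wild L1014 codon TTG
  alt_of <- c(A = "G", C = "T", G = "A", T = "C")

  info_sites <- c(181L, 940L, 943L, 1197L, 1210L, 1226L)
  rare_intron <- c(seq(100L, 910L, by = 15L),       # 55 intron-1 sites
                   c(1170L, 1180L, 1190L, 1205L))   # 4 intron-2 sites
  rare_exon <- c(20L, 40L, 1000L, 1240L)

  ## 18 six-site cores as alt-allele indicator patterns
  core_bits <- rbind(
    c(0,0,0,0,0,0), c(1,0,0,0,0,0), c(0,1,0,0,0,0), c(0,0,1,0,0,0),
    c(0,0,0,1,0,0), c(0,0,0,0,1,0), c(0,0,0,0,0,1), c(1,1,0,0,0,0),
    c(0,1,1,0,0,0), c(0,0,1,1,0,0), c(0,0,0,1,1,0), c(0,0,0,0,1,1),
    c(1,1,1,0,0,0), c(0,0,0,1,1,1), c(1,0,1,0,0,0), c(0,1,0,1,0,0),
    c(0,0,1,0,1,0), c(0,0,0,1,0,1))

  make_seq <- function(core, codon = NULL, extra_sites = integer(0),
                       gap_at = integer(0)) {
    s <- reference
    alt <- info_sites[core_bits[core, ] == 1]
    s[alt] <- alt_of[s[alt]]
    if (!is.null(codon)) s[1160:1162] <- strsplit(codon, "")[[1L]]
    s[extra_sites] <- alt_of[s[extra_sites]]
    s[gap_at] <- "-"
    paste(s, collapse = "")
  }

  seqs <- character(0); counts <- integer(0); who <- character(0)
  add <- function(seq, count, label) {
    seqs <<- c(seqs, seq); counts <<- c(counts, count); who <<- c(who, label)
  }

  ## resistant haplotypes: F and C on background 1, F on 2 and 3, F twice
  ## (TTT and TTC) on background 4, S on 5 and 6, F on 7
  add(make_seq(1, "TTT"), 122L, "b1_F")
  add(make_seq(1, "TGT"), 60L, "b1_C")
  add(make_seq(2, "TTT"), 20L, "b2_F")
  add(make_seq(3, "TTT"), 15L, "b3_F")
  add(make_seq(4, "TTT"), 30L, "b4_F_TTT")
  add(make_seq(4, "TTC"), 12L, "b4_F_TTC")
  add(make_seq(5, "TCG"), 18L, "b5_S")
  add(make_seq(6, "TCG"), 25L, "b6_S")
  add(make_seq(7, "TTT"), 30L, "b7_F")

  ## one wild-type representative per core
  core_wild_counts <- c(12L, rep(9L, 8L), rep(8L, 9L))
  for (k in 1:18) add(make_seq(k), core_wild_counts[k], sprintf("c%02d_wild", k))

  ## 54 rare-intron carriers covering the 59 rare intron sites
  ## (the first five carry two sites each), cores assigned cyclically
  carrier_sites <- vector("list", 54L)
  idx <- 1L
  for (i in 1:5) { carrier_sites[[i]] <- rare_intron[idx + 0:1]; idx <- idx + 2L }
  for (i in 6:54) { carrier_sites[[i]] <- rare_intron[idx]; idx <- idx + 1L }
  for (i in 1:54) {
    core <- ((i - 1L) %% 18L) + 1L
    gap <- if (i == 1L) 946L else integer(0)   # indel-bearing haplotype
    add(make_seq(core, extra_sites = carrier_sites[[i]], gap_at = gap),
        1L, sprintf("ri%02d", i))
  }

  ## 4 rare-exon carriers (intron states duplicate their cores)
  for (i in 1:4) {
    add(make_seq(i + 7L, extra_sites = rare_exon[i]), 1L, sprintf("re%d", i))
  }

  stopifnot(length(seqs) == 85L, sum(counts) == 546L,
            !anyDuplicated(seqs))
  panel <- alignment(sprintf("Hap%03d", seq_len(85L)), seqs)
  sample_ids <- sprintf("chr%03d", seq_len(sum(counts)))
  sample_aln <- alignment(sample_ids, rep(seqs, counts))
  pops <- population_set(stats::setNames(rep("panel", length(sample_ids)),
                                         sample_ids))
  truth <- list(
    n_haplotypes = 85L,
    fragment_length = 1285L,
    intron_length = 969L,
    polymorphic_sites = 71L,      # 65 intron + 4 exon + 2 codon columns
    intron_polymorphic_sites = 65L,
    intron_haplotypes = 72L,
    informative_intron_sites = info_sites,
    codon_variable_sites = c(1161L, 1162L),
    six_site_haplotypes = 18L,
    n_origin_events = 9L,         # >= the published lower bound of 8
    n_origin_backgrounds = 7L,
    n_resistant_haplotypes = 9L)
  list(panel = panel, sample = sample_aln, pops = pops, layout = layout,
       counts = counts, truth = truth)
}
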