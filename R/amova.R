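## Excoffier-style analysis of molecular variance for haploid sequences.
## All sums of squares come from a per-individual squared-distance matrix:
## haplotype identity (0/1) for frequency-based F-statistics, pairwise
## nucleotide differences for the Phi-statistics (the difference count is
## the squared Euclidean distance between sequences).

## squared-distance matrix between individuals of an alignment
individual_distance2 <- function(aln, mode = c("phist", "fst_freq")) {
  mode <- match.arg(mode)
  if (mode == "phist") {
    pairwise_diff_matrix(aln)
  } else {
    seqs <- aln_strings(aln)
    d <- outer(seqs, seqs, FUN = "!=") * 1
    dimnames(d) <- list(aln$ids, aln$ids)
    d
  }
}

## SS of one set of individuals: (1 / size) * sum of pairwise delta^2
ss_of <- function(D2, idx) {
  if (length(idx) < 2L) return(0)
  sum(D2[idx, idx]) / (2 * length(idx))
}

## variance components for a pop (and optional group) partition
amova_components <- function(D2, pop, group = NULL) {
  N <- length(pop)
  pops <- unique(pop)
  P <- length(pops)
  ss_total <- ss_of(D2, seq_len(N))
  ss_wp <- sum(vapply(pops, function(p) ss_of(D2, which(pop == p)), numeric(1)))
  n_p <- vapply(pops, function(p) sum(pop == p), numeric(1))

  if (is.null(group)) {
    df_ap <- P - 1L; df_wp <- N - P
    ms_ap <- (ss_total - ss_wp) / df_ap
    ms_wp <- ss_wp / df_wp
    nprime <- (N - sum(n_p^2) / N) / (P - 1)
    sig_w <- ms_wp
    sig_a <- (ms_ap - ms_wp) / nprime
    tot <- sig_a + sig_w
    return(list(
      variance_components = c(among_populations = sig_a, within_populations = sig_w),
      percentages = 100 * c(among_populations = sig_a, within_populations = sig_w) / tot,
      phi = c(F_ST = sig_a / tot),
      df = c(among_populations = df_ap, within_populations = df_wp),
      ss = c(among_populations = ss_total - ss_wp, within_populations = ss_wp)))
  }

  grp_of_pop <- stats::setNames(group[match(pops, pop)], pops)
  groups <- unique(grp_of_pop)
  G <- length(groups)
  N_g <- vapply(groups, function(g) sum(group == g), numeric(1))
  ss_g <- vapply(groups, function(g) ss_of(D2, which(group == g)), numeric(1))
  ss_ap_wg <- sum(ss_g) - ss_wp
  ss_ag <- ss_total - sum(ss_g)
  df_ag <- G - 1L; df_ap <- P - G; df_wp <- N - P

  sum_np2_by_g <- vapply(groups, function(g) {
    sum(n_p[grp_of_pop == g]^2) / N_g[groups == g]
  }, numeric(1))
  n1 <- (N - sum(sum_np2_by_g)) / df_ap
  n2 <- (sum(sum_np2_by_g) - sum(n_p^2) / N) / df_ag
  n3 <- (N - sum(N_g^2) / N) / df_ag

  ms_wp <- ss_wp / df_wp
  ms_ag <- ss_ag / df_ag
  sig_c <- ms_wp
  ## P = G leaves no populations-within-groups level: sig_b drops out
  sig_b <- if (df_ap > 0L) (ss_ap_wg / df_ap - sig_c) / n1 else 0
  sig_a <- (ms_ag - sig_c - n2 * sig_b) / n3
  tot <- sig_a + sig_b + sig_c
  list(
    variance_components = c(among_groups = sig_a,
                            among_populations_within_groups = sig_b,
                            within_populations = sig_c),
    percentages = 100 * c(among_groups = sig_a,
                          among_populations_within_groups = sig_b,
                          within_populations = sig_c) / tot,
    phi = c(F_CT = sig_a / tot,
            F_SC = if (df_ap > 0L) sig_b / (sig_b + sig_c) else NA_real_,
            F_ST = (sig_a + sig_b) / tot),
    df = c(among_groups = df_ag,
           among_populations_within_groups = df_ap,
           within_populations = df_wp),
    ss = c(among_groups = ss_ag,
           among_populations_within_groups = ss_ap_wg,
           within_populations = ss_wp))
}

#' Hierarchical analysis of molecular variance
#'
#' Partitions molecular variance among groups (`F_CT`), among populations
#' within groups (`F_SC`) and within populations (`F_ST` overall), with
#' one permutation scheme per statistic: individuals among populations
#' within groups (`F_SC`), whole populations among groups (`F_CT`), and
#' individuals among all populations (`F_ST`). With no grouping (or one
#' group) a one-level AMOVA is returned and `F_CT`/`F_SC` are `NA`.
#'
#' @param aln a [alignment()].
#' @param pops a [population_set()].
#' @param grouping optional named vector population -> group label.
#' @param mode `"phist"` (nucleotide distances) or `"fst_freq"`
#'   (haplotype identity).
#' @param perms permutations for the p-values (0 to skip).
#' @param seed RNG seed for the permutations.
#' @return list of class `amova_result` with `variance_components`,
#'   `percentages`, `phi`, `pvals`, `df`, `ss`, `mode`.
#' @export
amova <- function(aln, pops, grouping = NULL,
                  mode = c("phist", "fst_freq"), perms = 1000L, seed = NULL) {
  mode <- match.arg(mode)
  D2 <- individual_distance2(aln, mode)
  pop <- unname(pops$sample_to_pop[aln$ids])
  if (anyNA(pop)) stop("mapping error: samples missing from population map", call. = FALSE)
  group <- NULL
  if (!is.null(grouping) && length(unique(grouping[pop])) > 1L) {
    group <- unname(grouping[pop])
    if (anyNA(group)) stop("mapping error: populations missing from grouping", call. = FALSE)
  }
  obs <- amova_components(D2, pop, group)

  pvals <- rep(NA_real_, length(obs$phi))
  names(pvals) <- names(obs$phi)
  if (perms > 0L) {
    if (!is.null(seed)) set.seed(seed)
    N <- length(pop)
    count <- stats::setNames(numeric(length(obs$phi)), names(obs$phi))
    grp_of_pop <- if (is.null(group)) NULL else
      stats::setNames(group[match(unique(pop), pop)], unique(pop))
    for (b in seq_len(perms)) {
      ## F_ST: individuals among all populations (group follows the
      ## permuted population so nesting stays intact)
      perm_pop <- sample(pop)
      phi_st <- if (is.null(group)) {
        amova_components(D2, perm_pop)$phi["F_ST"]
      } else {
        amova_components(D2, perm_pop, unname(grp_of_pop[perm_pop]))$phi["F_ST"]
      }
      count["F_ST"] <- count["F_ST"] + (phi_st >= obs$phi["F_ST"])
      if (!is.null(group)) {
        ## F_SC: individuals among populations within their group
        perm_pop2 <- pop
        for (g in unique(group)) {
          idx <- which(group == g)
          perm_pop2[idx] <- sample(pop[idx])
        }
        phi_sc <- amova_components(D2, perm_pop2, group)$phi["F_SC"]
        count["F_SC"] <- count["F_SC"] + (phi_sc >= obs$phi["F_SC"])
        ## F_CT: whole populations among groups
        pops_u <- unique(pop)
        gsizes <- table(stats::setNames(group, pop)[pops_u])
        perm_g_of_pop <- stats::setNames(
          sample(rep(names(gsizes), gsizes)), sample(pops_u))
        phi_ct <- amova_components(D2, pop, unname(perm_g_of_pop[pop]))$phi["F_CT"]
        count["F_CT"] <- count["F_CT"] + (phi_ct >= obs$phi["F_CT"])
      }
    }
    pvals <- (count[names(obs$phi)] + 1) / (perms + 1)
  }
  structure(c(obs, list(pvals = pvals, mode = mode)), class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("<amova_result:%s>\n", x$mode))
  for (s in names(x$phi)) {
    cat(sprintf("  %s = %.4f (p = %s)\n", s, x$phi[s],
                if (is.na(x$pvals[s])) "-" else format(x$pvals[s])))
  }
  cat("  variance:", paste(sprintf("%s=%.2f%%", names(x$percentages),
                                   x$percentages), collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise population differentiation with permutation tests
#'
#' For every population pair, a two-population one-level AMOVA F-statistic
#' -- `fst_freq` from haplotype identity, `phist` from nucleotide
#' distances -- with a p-value from permuting individuals between the two
#' populations. Negative estimates are reported as computed unless
#' `clamp_negative`.
#'
#' @param aln a [alignment()].
#' @param pops a [population_set()].
#' @param mode `"fst_freq"` or `"phist"`.
#' @param perms permutations per pair.
#' @param seed RNG seed.
#' @param clamp_negative clamp negative estimates to 0.
#' @return list with `d` (symmetric F-statistic matrix), `p` (p-value
#'   matrix), and `excluded` (populations with < 2 samples).
#' @export
pairwise_differentiation <- function(aln, pops, mode = c("fst_freq", "phist"),
                                     perms = 1000L, seed = NULL,
                                     clamp_negative = FALSE) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  D2 <- individual_distance2(aln, mode)
  pop <- unname(pops$sample_to_pop[aln$ids])
  sizes <- table(pop)
  excluded <- names(sizes)[sizes < 2L]
  if (length(excluded)) {
    warning(sprintf("excluding population(s) with < 2 samples: %s",
                    paste(excluded, collapse = ", ")))
  }
  keep <- setdiff(populations(pops), excluded)
  keep <- keep[keep %in% pop]
  P <- length(keep)
  if (P < 2L) stop("need at least 2 populations with >= 2 samples", call. = FALSE)
  fst <- matrix(0, P, P, dimnames = list(keep, keep))
  pmat <- matrix(NA_real_, P, P, dimnames = list(keep, keep))
  for (i in seq_len(P - 1L)) {
    for (j in (i + 1L):P) {
      idx <- which(pop %in% c(keep[i], keep[j]))
      sub_pop <- pop[idx]
      subD <- D2[idx, idx]
      obs <- amova_components(subD, sub_pop)$phi["F_ST"]
      cnt <- 0L
      for (b in seq_len(perms)) {
        phi_b <- amova_components(subD, sample(sub_pop))$phi["F_ST"]
        if (!is.na(phi_b) && phi_b >= obs) cnt <- cnt + 1L
      }
      est <- if (clamp_negative) max(obs, 0) else obs
      fst[i, j] <- fst[j, i] <- est
      pmat[i, j] <- pmat[j, i] <- (cnt + 1) / (perms + 1)
    }
  }
  list(d = fst, p = pmat, excluded = excluded, mode = mode)
}

#' Count significant pairwise comparisons after multiple-testing
#' correction
#'
#' @param p symmetric p-value matrix from [pairwise_differentiation()].
#' @param method `"fdr"` (Benjamini-Hochberg, default) or
#'   `"bonferroni"`.
#' @param alpha significance level.
#' @return list with `n_significant`, `n_pairs` and the adjusted p matrix.
#' @export
count_significant_pairs <- function(p, method = c("fdr", "bonferroni"),
                                    alpha = 0.05) {
  method <- match.arg(method)
  ut <- upper.tri(p)
  raw <- p[ut]
  adj <- if (method == "fdr") fdr_adjust(raw) else
    stats::p.adjust(raw, method = "bonferroni")
  padj <- p
  padj[ut] <- adj
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  list(n_significant = sum(adj < alpha, na.rm = TRUE),
       n_pairs = sum(!is.na(raw)), p_adjusted = padj)
}

#' Permutation test for F_CT (whole populations among groups)
#'
#' The F_CT permutation scheme only relabels whole populations, so it
#' runs on population-level sufficient statistics; useful when the
#' individual-level matrix is large and only the among-group test is
#' needed.
#'
#' @param aln a [alignment()].
#' @param pops a [population_set()].
#' @param grouping named vector population -> group label.
#' @param mode distance mode, as in [amova()].
#' @param perms permutations.
#' @param seed RNG seed.
#' @return list with `F_CT`, `p`, and the permuted values.
#' @export
fct_permutation_test <- function(aln, pops, grouping,
                                 mode = c("phist", "fst_freq"),
                                 perms = 999L, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  D2 <- individual_distance2(aln, mode)
  pop <- unname(pops$sample_to_pop[aln$ids])
  pre <- samova_precompute(D2, pop)
  g <- as.integer(factor(unname(grouping[pre$pops])))
  obs <- samova_phi(pre, g)["F_CT"]
  sim <- numeric(perms)
  for (b in seq_len(perms)) sim[b] <- samova_phi(pre, sample(g))["F_CT"]
  list(F_CT = unname(obs), p = (sum(sim >= obs) + 1) / (perms + 1),
       permuted = sim)
}
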