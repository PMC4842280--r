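#' Collapse an alignment to a haplotype frequency table
#'
#' Distinct sequences (exact string identity after upper-casing; gaps and
#' `N` are ordinary states for identity purposes) with per-population
#' counts. Haplotype order is first-occurrence order, so the collapse is
#' deterministic.
#'
#' @param aln a [alignment()].
#' @param pops a [population_set()] covering every sample; may be omitted
#'   for a single pooled population.
#' @return An object of class `haplotype_table`: list with `haplotypes`
#'   (character vector of distinct sequences), `counts` (integer matrix,
#'   haplotype x population), `total_n`, and `members` (list of sample ids
#'   per haplotype).
#' @export
collapse_haplotypes <- function(aln, pops = NULL) {
  seqs <- aln_strings(aln)
  if (is.null(pops)) {
    popv <- stats::setNames(rep("all", length(seqs)), aln$ids)
  } else {
    popv <- pops$sample_to_pop
    miss <- setdiff(aln$ids, names(popv))
    if (length(miss)) {
      stop(sprintf("mapping error: sample(s) missing from population map: %s",
                   paste(utils::head(miss, 5L), collapse = ", ")), call. = FALSE)
    }
    popv <- popv[aln$ids]
  }
  haps <- unique(unname(seqs))
  hap_idx <- match(seqs, haps)
  pop_levels <- unique(unname(popv))
  counts <- table(factor(hap_idx, levels = seq_along(haps)),
                  factor(popv, levels = pop_levels))
  counts <- matrix(as.integer(counts), nrow = length(haps),
                   dimnames = list(paste0("H", seq_along(haps)), pop_levels))
  members <- split(aln$ids, hap_idx)
  names(members) <- rownames(counts)[as.integer(names(members))]
  structure(list(haplotypes = haps, counts = counts,
                 total_n = length(seqs), members = members),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("<haplotype_table> %d haplotypes, %d sequences, %d population(s)\n",
              length(x$haplotypes), x$total_n, ncol(x$counts)))
  invisible(x)
}

#' Per-population haplotype frequencies
#' @param table a [collapse_haplotypes()] result.
#' @return numeric matrix of relative frequencies (columns sum to 1).
#' @export
haplotype_frequencies <- function(table) {
  sweep(table$counts, 2L, pmax(colSums(table$counts), 1L), "/")
}
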