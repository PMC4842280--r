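## Site handling convention: columns containing '-' or 'N' are excluded
## from site-based statistics (complete deletion), while pairwise
## difference counts skip only the positions missing in that pair
## (pairwise deletion). `deletion = "complete"` switches K to the
## complete-deletion column set for strict DnaSP-style parity.

analysed_columns <- function(aln) {
  ok <- apply(aln$mat, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  which(ok)
}

## pairwise difference counts; returns n x n symmetric integer matrix
pairwise_diff_matrix <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- aln$mat
  if (deletion == "complete") m <- m[, analysed_columns(aln), drop = FALSE]
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(aln$ids, aln$ids))
  if (n < 2L || ncol(m) == 0L) return(d)
  valid <- m %in% c("A", "C", "G", "T")
  dim(valid) <- dim(m)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      use <- valid[i, ] & valid[j, ]
      d[i, j] <- d[j, i] <- sum(m[i, use] != m[j, use])
    }
  }
  d
}

#' Per-population sequence diversity summaries
#'
#' Computes the standard per-sample diversity panel: segregating sites `S`,
#' mean pairwise differences `K`, nucleotide diversity `Pi = K/L`, number
#' of haplotypes `h`, haplotype diversity `Hd`, total mutations `eta` and
#' singleton mutations `eta_s`. Site-based quantities (`S`, `eta`,
#' `eta_s`, `L`) use complete deletion (columns with `-`/`N` dropped);
#' `K` uses pairwise deletion by default.
#'
#' A multi-allelic column contributes 1 to `S` but (number of bases - 1)
#' to `eta`, the infinite-sites mutation count used by the Fu & Li tests;
#' `eta_s` counts mutations whose derived state occurs in exactly one
#' sequence.
#'
#' @param aln a [alignment()] with `n >= 1` sequences.
#' @param deletion `"pairwise"` (default) or `"complete"`; governs `K`.
#' @return list of class `diversity_stats` with fields `n`, `S`, `K`,
#'   `Pi`, `h`, `Hd`, `eta`, `eta_s`, `L`, and `singletons_per_seq`
#'   (named vector `U_i`: per sequence, the number of singleton sites at
#'   which it carries the unique base). `Hd` is `NA` when `n = 1`.
#' @export
diversity_stats <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  n <- n_seq(aln)
  if (n < 1L) stop("empty-input error: no sequences", call. = FALSE)
  cols <- analysed_columns(aln)
  m <- aln$mat[, cols, drop = FALSE]
  L <- length(cols)

  S <- 0L; eta <- 0L; eta_s <- 0L
  U <- stats::setNames(numeric(n), aln$ids)
  if (L > 0L && n > 1L) {
    for (j in seq_len(L)) {
      tab <- sort(table(m[, j]), decreasing = TRUE)
      k <- length(tab)
      if (k > 1L) {
        S <- S + 1L
        eta <- eta + (k - 1L)
        ## most frequent base is the ancestral proxy; derived bases carried
        ## by exactly one sequence are singleton mutations
        derived <- names(tab)[-1L]
        sing <- derived[tab[derived] == 1L]
        eta_s <- eta_s + length(sing)
        for (b in sing) U[m[, j] == b] <- U[m[, j] == b] + 1
      }
    }
  }

  dmat <- pairwise_diff_matrix(aln, deletion)
  K <- if (n > 1L) mean(dmat[upper.tri(dmat)]) else 0
  Pi <- if (L > 0L) K / L else 0

  ht <- collapse_haplotypes(aln)
  h <- length(ht$haplotypes)
  p <- rowSums(ht$counts) / n
  Hd <- if (n > 1L) (n / (n - 1)) * (1 - sum(p^2)) else NA_real_

  structure(list(n = n, S = S, K = K, Pi = Pi, h = h, Hd = Hd,
                 eta = eta, eta_s = eta_s, L = L,
                 singletons_per_seq = U),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf("<diversity_stats> n=%d S=%d K=%.4f Pi=%.5f h=%d Hd=%s\n",
              x$n, x$S, x$K, x$Pi, x$h,
              if (is.na(x$Hd)) "NA" else sprintf("%.4f", x$Hd)))
  invisible(x)
}

#' Mismatch distribution of an alignment
#'
#' Histogram of pairwise difference counts over all unordered sequence
#' pairs; the raw material of the sudden-expansion fit.
#'
#' @param aln a [alignment()] with `n >= 2`.
#' @param deletion passed to the pairwise difference computation.
#' @return list of class `mismatch_distribution` with `counts` (named
#'   integer vector over `0..max` observed differences) and `n_pairs`.
#' @export
mismatch_distribution <- function(aln, deletion = c("pairwise", "complete")) {
  n <- n_seq(aln)
  if (n < 2L) stop("insufficient-sample error: need at least 2 sequences", call. = FALSE)
  d <- pairwise_diff_matrix(aln, match.arg(deletion))
  pair_d <- d[upper.tri(d)]
  mismatch_from_pairs(pair_d)
}

## build a mismatch_distribution from a vector of pairwise difference counts
mismatch_from_pairs <- function(pair_d) {
  mx <- max(pair_d)
  counts <- tabulate(pair_d + 1L, nbins = mx + 1L)
  names(counts) <- 0:mx
  structure(list(counts = counts, n_pairs = length(pair_d)),
            class = "mismatch_distribution")
}

#' Mean of a mismatch distribution
#' @param mm a [mismatch_distribution()].
#' @return mean pairwise difference count.
#' @export
mismatch_mean <- function(mm) {
  i <- as.numeric(names(mm$counts))
  sum(i * mm$counts) / mm$n_pairs
}

mismatch_var <- function(mm) {
  i <- as.numeric(names(mm$counts))
  m <- mismatch_mean(mm)
  sum(mm$counts * (i - m)^2) / mm$n_pairs
}

#' Per-population diversity table
#'
#' Applies [diversity_stats()] population by population and returns one
#' row per population, matching the usual per-site summary-table shape.
#'
#' @param aln a [alignment()].
#' @param pops a [population_set()].
#' @return data.frame with columns `population, n, S, K, Pi, h, Hd`.
#' @export
diversity_by_population <- function(aln, pops) {
  pop_ids <- populations(pops)
  rows <- lapply(pop_ids, function(p) {
    ids <- names(pops$sample_to_pop)[pops$sample_to_pop == p]
    ids <- intersect(aln$ids, ids)
    st <- diversity_stats(subset_alignment(aln, ids))
    data.frame(population = p, n = st$n, S = st$S, K = st$K, Pi = st$Pi,
               h = st$h, Hd = st$Hd, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
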