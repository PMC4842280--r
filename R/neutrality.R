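#' Tajima's D
#'
#' Contrasts the mean pairwise difference `K` with the Watterson estimate
#' `S/a1`; positive values indicate an excess of intermediate-frequency
#' variants, negative values an excess of rare variants.
#'
#' @param stats a [diversity_stats()] result (or any list with `n`, `S`,
#'   `K`).
#' @return numeric D, or `NA` (undefined) when `S = 0`.
#' @export
tajima_d <- function(stats) {
  n <- stats$n; S <- stats$S; K <- stats$K
  if (n < 4L) stop("sample-size error: Tajima's D needs n >= 4", call. = FALSE)
  if (S == 0L) return(NA_real_)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (K - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Fu and Li's D* and F* (no outgroup)
#'
#' Outgroup-free versions contrasting total mutations `eta` and singleton
#' mutations `eta_s` (D*), and mean pairwise differences and singletons
#' (F*), with the corrected variance coefficients of Simonsen, Churchill &
#' Aquadro (1995).
#'
#' @param stats a [diversity_stats()] result (needs `n`, `K`, `eta`,
#'   `eta_s`).
#' @return named numeric vector `c(Dstar = , Fstar = )`; `NA`s when
#'   `eta = 0`.
#' @export
fu_li_star <- function(stats) {
  n <- stats$n; eta <- stats$eta; eta_s <- stats$eta_s; pi_ <- stats$K
  if (n < 4L) stop("sample-size error: Fu & Li tests need n >= 4", call. = FALSE)
  if (eta == 0L) return(c(Dstar = NA_real_, Fstar = NA_real_))
  i <- seq_len(n - 1L)
  a <- sum(1 / i); b <- sum(1 / i^2)
  a1 <- a + 1 / n                        # sum_{i=1}^{n} 1/i
  cn <- 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * a1 - 3) / (n - 2) - 1 / n)
  nn <- n / (n - 1)
  vD <- (nn^2 * b + a^2 * dn - 2 * (n * a * (a + 1)) / (n - 1)^2) / (a^2 + b)
  uD <- nn * (a - nn) - vD
  Dstar <- (nn * eta - a * eta_s) / sqrt(uD * eta + vD * eta^2)
  vF <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           (2 / (n - 1)) * (4 * b - 6 + 8 / n)) / (a^2 + b)
  uF <- (nn + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
           2 * (n + 1) / (n - 1)^2 * (a1 - 2 * n / (n + 1))) / a - vF
  Fstar <- (pi_ - ((n - 1) / n) * eta_s) / sqrt(uF * eta + vF * eta^2)
  c(Dstar = Dstar, Fstar = Fstar)
}

## log unsigned Stirling numbers of the first kind, row n: log|s(n, k)|
## for k = 1..n; recurrence |s(n,k)| = |s(n-1,k-1)| + (n-1)|s(n-1,k)| in
## log space, stable up to n in the many hundreds. Memoised per n.
.stirling_cache <- new.env(parent = emptyenv())

log_stirling_row <- function(n) {
  key <- as.character(n)
  if (!is.null(.stirling_cache[[key]])) return(.stirling_cache[[key]])
  row <- 0                               # n = 1: |s(1,1)| = 1
  if (n > 1L) {
    for (m in 2:n) {
      prev <- row
      row <- numeric(m)
      row[1L] <- log(m - 1) + prev[1L]
      row[m] <- 0
      if (m > 2L) {
        k <- 2:(m - 1L)
        x <- prev[k - 1L]
        y <- log(m - 1) + prev[k]
        mx <- pmax(x, y)
        row[k] <- mx + log1p(exp(pmin(x, y) - mx))
      }
    }
  }
  .stirling_cache[[key]] <- row
  row
}

## log Ewens sampling probabilities of the number of alleles:
## Pr(k alleles | n, theta) = |s(n,k)| theta^k / theta_(n)
log_ewens_allele_probs <- function(n, theta) {
  ls <- log_stirling_row(n)
  k <- seq_len(n)
  lp <- ls + k * log(theta) - sum(log(theta + 0:(n - 1L)))
  lp - log_sum_exp(lp)                   # guard rounding; sums to 1 exactly
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Fu's Fs
#'
#' `S' = Pr(number of alleles >= h_obs | theta = K)` under the Ewens
#' sampling distribution; `Fs = ln(S'/(1 - S'))`. Strongly negative values
#' indicate an excess of haplotypes relative to the pairwise diversity, as
#' expected after a demographic expansion (or a hitchhiking sweep).
#'
#' @param stats a [diversity_stats()] result (needs `n`, `K`, `h`).
#' @return numeric Fs; `NA` when `K = 0`; `Inf`/`-Inf` at the numerical
#'   boundaries `S' = 1` / `S' = 0`.
#' @export
fu_fs <- function(stats) {
  n <- stats$n; theta <- stats$K; h <- stats$h
  if (n < 2L) stop("sample-size error: Fs needs n >= 2", call. = FALSE)
  if (theta <= 0) return(NA_real_)
  lp <- log_ewens_allele_probs(n, theta)
  if (h <= 1L) return(Inf)               # S' = 1
  lS <- log_sum_exp(lp[h:n])
  lC <- log_sum_exp(lp[seq_len(h - 1L)]) # log(1 - S') without cancellation
  lS - lC
}

#' Ramos-Onsins and Rozas's R2
#'
#' `R2 = sqrt(mean((U_i - K/2)^2)) / S`, where `U_i` is the number of
#' singleton sites at which sequence `i` carries the unique base. Small
#' values indicate the star-like genealogies of recent expansions.
#'
#' @param aln a [alignment()] with `n >= 2`, or a [diversity_stats()]
#'   result carrying `singletons_per_seq`.
#' @return numeric R2; `NA` when `S = 0`.
#' @export
r2_stat <- function(aln) {
  stats <- if (inherits(aln, "diversity_stats")) aln else diversity_stats(aln)
  if (stats$n < 2L) stop("sample-size error: R2 needs n >= 2", call. = FALSE)
  if (stats$S == 0L) return(NA_real_)
  sqrt(mean((stats$singletons_per_seq - stats$K / 2)^2)) / stats$S
}

#' All five neutrality statistics of an alignment
#'
#' @param aln a [alignment()].
#' @return named numeric vector `D, Dstar, Fstar, Fs, R2`.
#' @export
neutrality_stats <- function(aln) {
  st <- diversity_stats(aln)
  fl <- fu_li_star(st)
  c(D = tajima_d(st), Dstar = unname(fl["Dstar"]), Fstar = unname(fl["Fstar"]),
    Fs = fu_fs(st), R2 = r2_stat(st))
}

## -- fixed-S null distribution -----------------------------------------

## the five statistics computed from a binary derived-allele matrix
## (infinite sites, so eta = S); folded singleton convention matching
## diversity_stats()
stats_from_binary <- function(M) {
  n <- nrow(M); S <- ncol(M)
  cs <- colSums(M)
  K <- sum(cs * (n - cs)) / choose(n, 2)
  cmin <- pmin(cs, n - cs)
  eta_s <- sum(cmin == 1L)
  U <- numeric(n)
  for (j in which(cmin == 1L)) {
    carrier <- if (cs[j] == 1L) which(M[, j] == 1L) else which(M[, j] == 0L)
    U[carrier] <- U[carrier] + 1
  }
  h <- length(unique(apply(M, 1L, paste, collapse = "")))
  base <- list(n = n, S = S, K = K, eta = S, eta_s = eta_s, h = h,
               singletons_per_seq = U)
  fl <- fu_li_star(base)
  c(D = tajima_d(base), Dstar = unname(fl["Dstar"]),
    Fstar = unname(fl["Fstar"]), Fs = fu_fs(base),
    R2 = if (S > 0) sqrt(mean((U - K / 2)^2)) / S else NA_real_)
}

## one neutral constant-size sample with exactly S mutations placed
## multinomially on the genealogy's branches (the fixed-S convention)
simulate_fixed_s <- function(n, S) {
  tr <- coalescent_tree(n)
  e <- stats::rmultinom(1L, S, tr$lengths)[, 1L]
  M <- matrix(0L, n, S)
  col <- 1L
  for (b in which(e > 0L)) {
    for (r in seq_len(e[b])) {
      M[tr$tipsets[[b]], col] <- 1L
      col <- col + 1L
    }
  }
  M
}

#' Null distribution of the neutrality statistics conditioned on S
#'
#' Simulates neutral constant-size coalescent samples with exactly `S`
#' mutations and recomputes the five statistics on each; the empirical
#' reference distribution for [neutrality_pvalues()].
#'
#' @param n sample size.
#' @param S conditioning number of segregating sites.
#' @param reps number of simulated samples.
#' @return numeric matrix `reps x 5` (columns `D, Dstar, Fstar, Fs, R2`).
#' @export
neutrality_null <- function(n, S, reps = 1000L) {
  out <- matrix(NA_real_, reps, 5L,
                dimnames = list(NULL, c("D", "Dstar", "Fstar", "Fs", "R2")))
  for (r in seq_len(reps)) out[r, ] <- stats_from_binary(simulate_fixed_s(n, S))
  out
}

## empirical p with mid-p tie handling: some statistics (notably Fu &
## Li's D*, a function of the discrete pair (eta, eta_s)) put large
## probability lumps on single values; counting ties at half weight keeps
## the tests calibrated at their nominal level instead of conservative
empirical_p <- function(obs, null, tail = c("two", "lower", "upper")) {
  tail <- match.arg(tail)
  null <- null[is.finite(null)]
  B <- length(null)
  if (!is.finite(obs) || B == 0L) return(NA_real_)
  ties <- sum(null == obs)
  lo <- (sum(null < obs) + 0.5 * ties + 1) / (B + 1)
  hi <- (sum(null > obs) + 0.5 * ties + 1) / (B + 1)
  switch(tail,
         lower = lo,
         upper = hi,
         two = min(1, 2 * min(lo, hi)))
}

#' Empirical p-values for the neutrality statistics
#'
#' Compares observed statistics with a fixed-S coalescent null: two-tailed
#' for `D`, `D*`, `F*`; lower-tailed for `Fs` and `R2` (the expansion /
#' sweep direction). Upper-tail p-values for `Fs` are also reported so
#' either tail convention can be applied.
#'
#' @param obs named vector as returned by [neutrality_stats()].
#' @param n sample size of the observed data.
#' @param S observed number of segregating sites (the conditioning value).
#' @param reps null simulations (>= 100).
#' @param seed RNG seed.
#' @param null optional precomputed [neutrality_null()] matrix for
#'   `(n, S)`; when supplied, no simulation is run.
#' @return data.frame with columns `statistic`, `value`, `p` (and
#'   `p_upper` for Fs).
#' @export
neutrality_pvalues <- function(obs, n, S, reps = 1000L, seed = NULL,
                               null = NULL) {
  if (is.null(null)) {
    if (reps < 100L) stop("reps must be >= 100", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    null <- neutrality_null(n, S, reps)
  }
  tails <- c(D = "two", Dstar = "two", Fstar = "two",
             Fs = "lower", R2 = "lower")
  p <- vapply(names(tails), function(s) {
    empirical_p(obs[[s]], null[, s], tails[[s]])
  }, numeric(1))
  out <- data.frame(statistic = names(tails),
                    value = unname(obs[names(tails)]),
                    p = unname(p),
                    stringsAsFactors = FALSE)
  out$p_upper <- NA_real_
  out$p_upper[out$statistic == "Fs"] <- empirical_p(obs[["Fs"]], null[, "Fs"], "upper")
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up q-values for a vector of p-values; a thin, named wrapper over
#' `stats::p.adjust(method = "BH")` so reports carry one canonical
#' multiple-testing column.
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (`NA`s allowed).
#' @return numeric vector of q-values.
#' @export
fdr_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}
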