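## Sudden (stepwise) expansion model of the mismatch distribution.
## A population at equilibrium theta0 grows instantaneously to theta1 at
## mutational time tau before the present; the distribution of pairwise
## differences is the equilibrium geometric law convolved with the
## Poisson(tau) mutations accumulated since the expansion.

geom_equilibrium <- function(i, theta) {
  if (!is.finite(theta)) return(rep(0, length(i)))
  if (theta == 0) return(as.numeric(i == 0L))
  exp(i * log(theta) - (i + 1) * log1p(theta))
}

#' Expected mismatch distribution under sudden expansion
#'
#' Probability of observing `i = 0..max_i` pairwise differences for a
#' population that jumped from scaled mutation rate `theta0` to `theta1`
#' at mutational time `tau`; `tau = 0` collapses to the equilibrium
#' geometric law, `theta0 = 0, theta1 = Inf` to Poisson(`tau`). The
#' returned vector is renormalised after truncation at `max_i`.
#'
#' @param tau expansion age in mutational units (>= 0).
#' @param theta0 pre-expansion scaled mutation rate (>= 0).
#' @param theta1 post-expansion scaled mutation rate (>= `theta0`;
#'   `Inf` allowed).
#' @param max_i largest difference class.
#' @return numeric probability vector of length `max_i + 1`, summing to 1.
#' @export
expected_mismatch <- function(tau, theta0, theta1, max_i) {
  if (tau < 0 || theta0 < 0 || theta1 < 0) {
    stop("domain error: parameters must be non-negative", call. = FALSE)
  }
  i <- 0:max_i
  base <- geom_equilibrium(i, theta1)
  decay <- if (is.finite(theta1) && theta1 > 0) {
    exp(-tau * (theta1 + 1) / theta1)
  } else if (!is.finite(theta1)) {
    exp(-tau)
  } else {
    0   # theta1 = 0: no post-expansion diversity beyond the initial state
  }
  lpois <- if (tau > 0) i * log(tau) - lgamma(i + 1) else c(0, rep(-Inf, max_i))
  g0 <- geom_equilibrium(i, theta0)
  g1 <- base
  conv <- vapply(i, function(ii) {
    j <- 0:ii
    sum(exp(lpois[j + 1L]) * (g0[ii - j + 1L] - g1[ii - j + 1L]))
  }, numeric(1))
  p <- base + decay * conv
  p[p < 0] <- 0                      # truncation / rounding guard
  s <- sum(p)
  if (s <= 0) return(as.numeric(i == 0L))
  p / s
}

#' Harpending's raggedness index
#'
#' `r = sum((x_i - x_(i-1))^2)` over the relative mismatch frequencies
#' `x_0..x_d` with `x_(d+1) = 0`; small for the smooth unimodal
#' distributions of expanded populations, large for the ragged multimodal
#' distributions of stationary ones.
#'
#' @param mm a [mismatch_distribution()].
#' @return numeric raggedness.
#' @export
raggedness <- function(mm) {
  if (mm$n_pairs < 1L) stop("empty mismatch distribution", call. = FALSE)
  x <- c(mm$counts / mm$n_pairs, 0)
  sum(diff(x)^2)
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' `method = "moments"` uses Rogers' estimators from the mean `m` and
#' variance `v` of pairwise differences: `theta0 = sqrt(max(v - m, 0))`,
#' `tau = m - theta0`, with `theta1` at its moment-method limit
#' (infinity). `method = "least_squares"` minimises the sum of squared
#' deviations (SSD) between observed and expected relative frequencies
#' over `(tau, theta0, theta1)` -- coarse grid, then local refinement --
#' with `theta1 >= theta0` and `theta1` capped at 10x the largest
#' mismatch class to tame the flat ridge. Both are deterministic.
#'
#' @param mm a [mismatch_distribution()] with `n_pairs >= 10`.
#' @param method `"moments"` or `"least_squares"`.
#' @return list of class `expansion_fit`: `tau`, `theta0`, `theta1`,
#'   `SSD`, `method`, `obs` (observed relative frequencies),
#'   `degenerate` (TRUE when all pairs are identical).
#' @export
fit_expansion <- function(mm, method = c("least_squares", "moments")) {
  method <- match.arg(method)
  if (mm$n_pairs < 10L) stop("need at least 10 sequence pairs", call. = FALSE)
  obs <- mm$counts / mm$n_pairs
  d <- length(obs) - 1L
  if (d == 0L) {   # all pairs identical
    fit <- list(tau = 0, theta0 = 0, theta1 = 0, SSD = 0,
                method = method, obs = obs, degenerate = TRUE)
    class(fit) <- "expansion_fit"
    return(fit)
  }
  m <- mismatch_mean(mm)
  ssd_of <- function(tau, th0, th1) {
    sum((obs - expected_mismatch(tau, th0, th1, d))^2)
  }
  if (method == "moments") {
    v <- mismatch_var(mm)
    th0 <- sqrt(max(v - m, 0))
    tau <- max(m - th0, 0)
    fit <- list(tau = tau, theta0 = th0, theta1 = Inf,
                SSD = ssd_of(tau, th0, Inf),
                method = method, obs = obs, degenerate = FALSE)
  } else {
    cap <- 10 * d
    grid <- expand.grid(tau = seq(0, 2 * d, length.out = 12L),
                        th0 = seq(0, max(m, 0.5), length.out = 6L),
                        th1 = c(1, 5, 10, 25, cap))
    grid <- grid[grid$th1 >= grid$th0, , drop = FALSE]
    ssd <- mapply(ssd_of, grid$tau, grid$th0, grid$th1)
    best <- grid[which.min(ssd), ]
    ## refine with theta1 = theta0 + delta to keep the order constraint;
    ## multi-start from the best grid point and the moment estimate (the
    ## capped theta1 approximates the infinite-growth limit to O(1/theta1))
    v <- mismatch_var(mm)
    th0_m <- sqrt(max(v - m, 0))
    starts <- list(c(best$tau, best$th0, max(best$th1 - best$th0, 0)),
                   c(max(m - th0_m, 0), min(th0_m, cap), cap))
    obj <- function(p) {
      p <- pmax(p, 0)   # finite-difference probes can graze the bounds
      ssd_of(p[1L], p[2L], min(p[2L] + p[3L], cap))
    }
    opt <- NULL
    for (st in starts) {
      o <- stats::optim(pmin(st, c(4 * d, cap, cap)), obj,
                        method = "L-BFGS-B",
                        lower = c(0, 0, 0), upper = c(4 * d, cap, cap))
      if (is.null(opt) || o$value < opt$value) opt <- o
    }
    fit <- list(tau = opt$par[1L], theta0 = opt$par[2L],
                theta1 = min(opt$par[2L] + opt$par[3L], cap),
                SSD = opt$value, method = method, obs = obs,
                degenerate = FALSE)
  }
  class(fit) <- "expansion_fit"
  fit
}

#' @export
print.expansion_fit <- function(x, ...) {
  cat(sprintf("<expansion_fit:%s> tau=%.3f theta0=%.3f theta1=%s SSD=%.5f%s\n",
              x$method, x$tau, x$theta0,
              if (is.finite(x$theta1)) sprintf("%.3f", x$theta1) else "Inf",
              x$SSD, if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

## simulate one sample of size n under the fitted expansion and return its
## mismatch distribution (pairwise differences via the genealogy)
simulate_expansion_mismatch <- function(n, tau, theta0, theta1) {
  th1 <- if (is.finite(theta1) && theta1 > 0) theta1 else max(100, 10 * tau)
  factor <- th1 / max(theta0, th1 * 1e-4)   # rate jump at the expansion
  tree <- coalescent_tree(n, rate_step = list(time = tau / th1, factor = factor))
  nm <- stats::rpois(length(tree$lengths), th1 / 2 * tree$lengths)
  M <- matrix(0L, n, sum(nm))
  col <- 0L
  for (b in which(nm > 0L)) {
    for (r in seq_len(nm[b])) {
      col <- col + 1L
      M[tree$tipsets[[b]], col] <- 1L
    }
  }
  d <- if (ncol(M) > 0L) {
    X <- M
    D <- X %*% t(1 - X) ; D <- D + t(D)
    D[upper.tri(D)]
  } else {
    rep(0L, choose(n, 2))
  }
  mismatch_from_pairs(d)
}

#' Parametric bootstrap goodness-of-fit for an expansion fit
#'
#' Simulates `reps` coalescent samples of size `n` under the fitted
#' sudden-expansion demography, refits each with the same method, and
#' returns bootstrap p-values `p = (b + 1)/(reps + 1)` for the SSD and
#' the raggedness index (fraction of simulated values >= observed).
#'
#' @param fit an [fit_expansion()] result.
#' @param mm the observed [mismatch_distribution()] the fit came from.
#' @param n sample size (sequences) behind `mm`.
#' @param reps bootstrap replicates (>= 100).
#' @param seed RNG seed.
#' @return list with `p_SSD`, `p_r`, `obs_r`, and the simulated `SSD`
#'   and `r` vectors.
#' @export
gof_bootstrap <- function(fit, mm, n, reps = 1000L, seed = NULL) {
  if (reps < 100L) stop("reps must be >= 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  obs_r <- raggedness(mm)
  ssd_sim <- numeric(reps)
  r_sim <- numeric(reps)
  for (b in seq_len(reps)) {
    mm_b <- simulate_expansion_mismatch(n, fit$tau, fit$theta0, fit$theta1)
    fit_b <- fit_expansion(mm_b, method = fit$method)
    ssd_sim[b] <- fit_b$SSD
    r_sim[b] <- raggedness(mm_b)
  }
  list(p_SSD = (sum(ssd_sim >= fit$SSD) + 1) / (reps + 1),
       p_r = (sum(r_sim >= obs_r) + 1) / (reps + 1),
       obs_r = obs_r, SSD_sim = ssd_sim, r_sim = r_sim)
}

#' Convert an expansion age to years
#'
#' `tau = 2 t mu` for a per-locus per-year mutation rate `mu`, so
#' `t = tau / (2 mu)`.
#'
#' @param tau expansion parameter (mutational units).
#' @param mu_locus mutation rate per locus per year (> 0).
#' @return time in years.
#' @export
expansion_time <- function(tau, mu_locus) {
  if (mu_locus <= 0) stop("domain error: mu must be > 0", call. = FALSE)
  tau / (2 * mu_locus)
}
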