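#' Great-circle distance between two points
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param a,b numeric `(latitude, longitude)` pairs in decimal degrees.
#' @return distance in kilometres.
#' @export
great_circle <- function(a, b) {
  if (abs(a[1L]) > 90 || abs(b[1L]) > 90 || abs(a[2L]) > 180 || abs(b[2L]) > 180) {
    stop("domain error: coordinates out of range", call. = FALSE)
  }
  ## geosphere expects (lon, lat); radius in km gives km out
  geosphere::distHaversine(c(a[2L], a[1L]), c(b[2L], b[1L]), r = 6371)
}

#' Great-circle distance matrix of a population set
#'
#' @param pops a [population_set()] with coordinates for every population.
#' @return symmetric km matrix with population labels.
#' @export
geo_distance_matrix <- function(pops) {
  cc <- pops$pop_coords
  if (is.null(cc)) stop("mapping error: population set has no coordinates", call. = FALSE)
  labs <- cc$population
  P <- length(labs)
  d <- matrix(0, P, P, dimnames = list(labs, labs))
  for (i in seq_len(P - 1L)) {
    for (j in (i + 1L):P) {
      d[i, j] <- d[j, i] <- great_circle(
        c(cc$latitude[i], cc$longitude[i]),
        c(cc$latitude[j], cc$longitude[j]))
    }
  }
  d
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the upper-triangle entries, with a one-tailed
#' permutation test (rows/columns of `dy` permuted jointly; p = fraction
#' of permuted correlations >= observed, add-one corrected).
#'
#' @param dx,dy symmetric matrices with matching labels.
#' @param perms permutations (>= 100).
#' @param seed RNG seed.
#' @return list with `r`, `R2`, `p`, `n_pairs`.
#' @export
mantel <- function(dx, dy, perms = 1000L, seed = NULL) {
  if (!identical(dim(dx), dim(dy))) stop("matrix dimensions differ", call. = FALSE)
  if (!is.null(rownames(dx)) && !is.null(rownames(dy)) &&
      !identical(rownames(dx), rownames(dy))) {
    dy <- dy[rownames(dx), rownames(dx)]
  }
  if (perms < 100L) stop("perms must be >= 100", call. = FALSE)
  ut <- upper.tri(dx)
  x <- dx[ut]; y <- dy[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, R2 = NA_real_, p = NA_real_, n_pairs = sum(ut)))
  }
  r <- stats::cor(x, y)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(dx)
  cnt <- 0L
  for (b in seq_len(perms)) {
    o <- sample.int(n)
    if (stats::cor(x, dy[o, o][ut]) >= r) cnt <- cnt + 1L
  }
  list(r = r, R2 = r^2, p = (cnt + 1) / (perms + 1), n_pairs = sum(ut))
}

#' Geographic and linearised-genetic distance matrices for
#' isolation-by-distance
#'
#' Genetic distances are `F_ST / (1 - F_ST)` elementwise on the pairwise
#' F-statistics; `F_ST = 1` is clamped to `cap` (recorded in the
#' `capped` attribute).
#'
#' @param aln a [alignment()].
#' @param pops a [population_set()] with coordinates.
#' @param mode passed to [pairwise_differentiation()].
#' @param perms permutations for the pairwise tests.
#' @param seed RNG seed.
#' @param cap finite stand-in for `F_ST = 1`.
#' @return list with `geo` (km matrix) and `gen` (linearised F_ST
#'   matrix).
#' @export
ibd_inputs <- function(aln, pops, mode = "fst_freq", perms = 100L,
                       seed = NULL, cap = 1e6) {
  geo <- geo_distance_matrix(pops)
  pw <- pairwise_differentiation(aln, pops, mode = mode, perms = perms,
                                 seed = seed)
  f <- pw$d
  lin <- ifelse(f >= 1, cap, f / (1 - f))
  diag(lin) <- 0
  attr(lin, "capped") <- f >= 1
  common <- intersect(rownames(geo), rownames(lin))
  list(geo = geo[common, common], gen = lin[common, common])
}

## -- SAMOVA -------------------------------------------------------------

## population-level sufficient statistics for fast F_CT evaluation:
## s_p = within-population pair sums, W[p, q] = cross-population pair
## sums, so any grouping's sums of squares follow without touching the
## individual-level matrix again.
samova_precompute <- function(D2, pop) {
  pops <- unique(pop)
  P <- length(pops)
  idx <- lapply(pops, function(p) which(pop == p))
  n_p <- lengths(idx)
  s_p <- vapply(seq_len(P), function(p) sum(D2[idx[[p]], idx[[p]]]) / 2, numeric(1))
  W <- matrix(0, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1L)) {
    for (j in (i + 1L):P) {
      W[i, j] <- W[j, i] <- sum(D2[idx[[i]], idx[[j]]])
    }
  }
  list(pops = pops, n_p = stats::setNames(n_p, pops),
       s_p = stats::setNames(s_p, pops), W = W,
       N = length(pop), ss_total = sum(D2) / (2 * length(pop)),
       ss_wp = sum(s_p / n_p))
}

## three-level variance components for a group assignment (integer vector
## over populations); returns phi triple
samova_phi <- function(pre, g) {
  P <- length(pre$pops)
  G <- length(unique(g))
  N <- pre$N
  N_g <- vapply(unique(g), function(gg) sum(pre$n_p[g == gg]), numeric(1))
  ss_g <- vapply(unique(g), function(gg) {
    members <- which(g == gg)
    tot <- sum(pre$s_p[members])
    if (length(members) > 1L) {
      tot <- tot + sum(pre$W[members, members]) / 2
    }
    tot / sum(pre$n_p[members])
  }, numeric(1))
  ss_wp <- pre$ss_wp
  ss_ap_wg <- sum(ss_g) - ss_wp
  ss_ag <- pre$ss_total - sum(ss_g)
  df_ag <- G - 1L; df_ap <- P - G; df_wp <- N - P
  sum_np2_by_g <- vapply(seq_along(unique(g)), function(k) {
    gg <- unique(g)[k]
    sum(pre$n_p[g == gg]^2) / N_g[k]
  }, numeric(1))
  sig_c <- ss_wp / df_wp
  sig_b <- if (df_ap > 0L) {
    n1 <- (N - sum(sum_np2_by_g)) / df_ap
    (ss_ap_wg / df_ap - sig_c) / n1
  } else {
    NA_real_  # K = P: no populations within groups level
  }
  n2 <- (sum(sum_np2_by_g) - sum(pre$n_p^2) / N) / df_ag
  n3 <- (N - sum(N_g^2) / N) / df_ag
  sig_b_eff <- if (is.na(sig_b)) 0 else sig_b
  sig_a <- (ss_ag / df_ag - sig_c - n2 * sig_b_eff) / n3
  tot <- sig_a + sig_b_eff + sig_c
  c(F_CT = sig_a / tot,
    F_SC = if (is.na(sig_b)) NA_real_ else sig_b / (sig_b + sig_c),
    F_ST = (sig_a + sig_b_eff) / tot)
}

#' Spatial analysis of molecular variance (simulated-annealing group
#' search)
#'
#' For each K in `K_range`, runs `runs` simulated-annealing chains: a
#' random valid grouping of populations into K non-empty groups, a
#' proposal that moves one population to another group (never emptying a
#' group), the AMOVA `F_CT` as the objective, Metropolis acceptance with
#' geometric cooling, and the best grouping over all chains retained.
#' Group composition is not geographically constrained.
#'
#' @param aln a [alignment()].
#' @param pops a [population_set()].
#' @param K_range integer vector of group numbers to scan.
#' @param runs annealing chains per K.
#' @param iters iterations per chain.
#' @param seed RNG seed.
#' @param mode distance mode, as in [amova()].
#' @param t0 initial temperature (objective scale).
#' @param cooling geometric cooling factor per iteration.
#' @return list of class `samova_result`: per K, `best_grouping` (named
#'   vector population -> group index), `phi` (`F_CT`, `F_SC`, `F_ST`),
#'   plus `fct_trace` (best F_CT per K) and `rng_seed`.
#' @export
samova <- function(aln, pops, K_range = 2:5, runs = 10L, iters = 1000L,
                   seed = NULL, mode = c("phist", "fst_freq"),
                   t0 = 0.1, cooling = 0.999) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  D2 <- individual_distance2(aln, mode)
  pop <- unname(pops$sample_to_pop[aln$ids])
  pre <- samova_precompute(D2, pop)
  P <- length(pre$pops)
  if (any(K_range > P)) stop("domain error: K exceeds number of populations", call. = FALSE)
  per_k <- list()
  for (K in K_range) {
    best <- NULL
    for (run in seq_len(runs)) {
      ## random valid start: each group seeded, leftovers placed uniformly
      g <- integer(P)
      g[sample.int(P, K)] <- seq_len(K)
      g[g == 0L] <- sample.int(K, sum(g == 0L), replace = TRUE)
      f <- samova_phi(pre, g)["F_CT"]
      cur_g <- g; cur_f <- f
      temp <- t0
      for (it in seq_len(iters)) {
        p <- sample.int(P, 1L)
        if (sum(cur_g == cur_g[p]) == 1L) { temp <- temp * cooling; next }
        newgrp <- sample(setdiff(seq_len(K), cur_g[p]), 1L)
        prop <- cur_g; prop[p] <- newgrp
        pf <- samova_phi(pre, prop)["F_CT"]
        if (pf >= cur_f || stats::runif(1L) < exp((pf - cur_f) / temp)) {
          cur_g <- prop; cur_f <- pf
        }
        if (is.null(best) || cur_f > best$f) best <- list(g = cur_g, f = cur_f)
        temp <- temp * cooling
      }
      if (is.null(best) || cur_f > best$f) best <- list(g = cur_g, f = cur_f)
    }
    phi <- samova_phi(pre, best$g)
    per_k[[as.character(K)]] <- list(
      K = K,
      best_grouping = stats::setNames(best$g, pre$pops),
      phi = phi)
  }
  structure(list(per_k = per_k,
                 fct_trace = vapply(per_k, function(x) unname(x$phi["F_CT"]),
                                    numeric(1)),
                 rng_seed = seed, mode = mode),
            class = "samova_result")
}

#' Exhaustive SAMOVA search (oracle for small problems)
#'
#' Enumerates every partition of the populations into exactly K non-empty
#' groups and returns the one maximising `F_CT`. Exponential in the
#' number of populations; intended for <= 10 populations.
#'
#' @inheritParams samova
#' @param K number of groups.
#' @return list with `best_grouping` and `phi`.
#' @export
samova_exhaustive <- function(aln, pops, K, mode = c("phist", "fst_freq")) {
  mode <- match.arg(mode)
  D2 <- individual_distance2(aln, mode)
  pop <- unname(pops$sample_to_pop[aln$ids])
  pre <- samova_precompute(D2, pop)
  P <- length(pre$pops)
  best <- NULL
  ## restricted growth strings enumerate set partitions; keep those with K blocks
  g <- integer(P)
  rec <- function(i, maxg) {
    if (i > P) {
      if (maxg == K) {
        f <- samova_phi(pre, g)["F_CT"]
        if (is.null(best) || f > best$f) best <<- list(g = g, f = f)
      }
      return(invisible())
    }
    for (v in seq_len(min(maxg + 1L, K))) {
      g[i] <<- v
      rec(i + 1L, max(maxg, v))
    }
  }
  rec(1L, 0L)
  list(best_grouping = stats::setNames(best$g, pre$pops),
       phi = samova_phi(pre, best$g))
}

## -- genetic landscape surface ------------------------------------------

## equirectangular planar projection about the mean latitude (km)
project_planar <- function(lat, lon) {
  R <- 6371
  lat0 <- mean(lat) * pi / 180
  cbind(x = R * cos(lat0) * lon * pi / 180, y = R * lat * pi / 180)
}

## brute-force Delaunay edges: a triangle belongs to the triangulation iff
## its circumcircle contains no other point (general position assumed)
delaunay_edges <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(t(utils::combn(n, 2L)))
  edges <- matrix(integer(0), 0L, 2L)
  found_triangle <- FALSE
  for (tri in utils::combn(n, 3L, simplify = FALSE)) {
    p <- xy[tri, , drop = FALSE]
    ax <- p[1L, 1L]; ay <- p[1L, 2L]
    bx <- p[2L, 1L]; by <- p[2L, 2L]
    cx <- p[3L, 1L]; cy <- p[3L, 2L]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-9) next            # collinear triple
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    others <- setdiff(seq_len(n), tri)
    inside <- (xy[others, 1L] - ux)^2 + (xy[others, 2L] - uy)^2 < r2 * (1 - 1e-12)
    if (!any(inside)) {
      found_triangle <- TRUE
      edges <- rbind(edges, tri[c(1L, 2L)], tri[c(1L, 3L)], tri[c(2L, 3L)])
    }
  }
  if (!found_triangle) {
    warning("collinear sites: falling back to the complete graph")
    return(t(utils::combn(n, 2L)))
  }
  unique(t(apply(edges, 1L, sort)))
}

#' Genetic landscape shape surface (inverse-distance-weighted)
#'
#' Builds a Delaunay connectivity network over the population locations,
#' places each pairwise genetic distance at the corresponding edge
#' midpoint, and interpolates surface heights over a uniform grid by
#' inverse-distance weighting with exponent `alpha`: high ridges mark
#' zones of strong differentiation (gene-flow barriers).
#'
#' @param pops a [population_set()] with coordinates (>= 3 populations).
#' @param gen symmetric genetic distance matrix (population labels).
#' @param grid `c(nx, ny)` grid resolution.
#' @param alpha distance-weighting exponent.
#' @return list of class `landscape_surface` with `grid` (ny x nx height
#'   matrix), `x_coords`, `y_coords` (planar km axes), `midpoints`, and
#'   `alpha`.
#' @export
landscape_surface <- function(pops, gen, grid = c(80L, 80L), alpha = 1) {
  cc <- pops$pop_coords
  if (is.null(cc) || nrow(cc) < 3L) {
    stop("need >= 3 populations with coordinates", call. = FALSE)
  }
  labs <- intersect(cc$population, rownames(gen))
  cc <- cc[match(labs, cc$population), ]
  gen <- gen[labs, labs]
  xy <- project_planar(cc$latitude, cc$longitude)
  ed <- delaunay_edges(xy)
  mid <- cbind((xy[ed[, 1L], 1L] + xy[ed[, 2L], 1L]) / 2,
               (xy[ed[, 1L], 2L] + xy[ed[, 2L], 2L]) / 2)
  g <- gen[cbind(ed[, 1L], ed[, 2L])]
  xs <- seq(min(xy[, 1L]), max(xy[, 1L]), length.out = grid[1L])
  ys <- seq(min(xy[, 2L]), max(xy[, 2L]), length.out = grid[2L])
  z <- matrix(NA_real_, length(ys), length(xs))
  for (iy in seq_along(ys)) {
    for (ix in seq_along(xs)) {
      dd <- sqrt((mid[, 1L] - xs[ix])^2 + (mid[, 2L] - ys[iy])^2)
      if (any(dd == 0)) {
        z[iy, ix] <- mean(g[dd == 0])
      } else {
        w <- (1 / dd)^alpha
        z[iy, ix] <- sum(w * g) / sum(w)
      }
    }
  }
  structure(list(grid = z, x_coords = xs, y_coords = ys,
                 midpoints = cbind(mid, value = g), alpha = alpha,
                 edges = matrix(labs[ed], ncol = 2L)),
            class = "landscape_surface")
}
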