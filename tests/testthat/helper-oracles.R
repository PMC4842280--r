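# Brute-force oracles, written independently of the package internals:
# plain double loops and first-principles formulas only.

# diversity panel by direct enumeration over pairs and columns
oracle_diversity <- function(seqs) {
  n <- length(seqs)
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  good <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  mg <- m[, good, drop = FALSE]
  S <- 0L
  for (j in seq_len(ncol(mg))) if (length(unique(mg[, j])) > 1L) S <- S + 1L
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] %in% c("A","C","G","T") & m[j, ] %in% c("A","C","G","T")
      tot <- tot + sum(m[i, ok] != m[j, ok])
      np <- np + 1
    }
  }
  K <- tot / np
  h <- length(unique(seqs))
  p <- as.numeric(table(seqs)) / n
  Hd <- (n / (n - 1)) * (1 - sum(p^2))
  list(S = S, K = K, Pi = K / ncol(mg), h = h, Hd = Hd, L = ncol(mg))
}

# AMOVA variance components straight from the sums-of-squares definitions
oracle_amova <- function(d2, pop, group = NULL) {
  N <- length(pop)
  ss <- function(idx) {
    if (length(idx) < 2) return(0)
    tot <- 0
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      tot <- tot + d2[idx[a], idx[b]]
    }
    tot / (2 * length(idx))
  }
  pops <- unique(pop)
  P <- length(pops)
  sstot <- ss(1:N)
  sswp <- sum(sapply(pops, function(p) ss(which(pop == p))))
  np <- sapply(pops, function(p) sum(pop == p))
  if (is.null(group)) {
    msap <- (sstot - sswp) / (P - 1)
    mswp <- sswp / (N - P)
    nprime <- (N - sum(np^2) / N) / (P - 1)
    sa <- (msap - mswp) / nprime
    return(c(among = sa, within = mswp, fst = sa / (sa + mswp)))
  }
  gof <- sapply(pops, function(p) group[which(pop == p)[1]])
  grps <- unique(gof)
  G <- length(grps)
  Ng <- sapply(grps, function(g) sum(pop %in% pops[gof == g]))
  ssg <- sapply(grps, function(g) ss(which(pop %in% pops[gof == g])))
  ssapwg <- sum(ssg) - sswp
  ssag <- sstot - sum(ssg)
  s2 <- sapply(grps, function(g) sum(np[gof == g]^2) / Ng[grps == g])
  n1 <- (N - sum(s2)) / (P - G)
  n2 <- (sum(s2) - sum(np^2) / N) / (G - 1)
  n3 <- (N - sum(Ng^2) / N) / (G - 1)
  sc <- sswp / (N - P)
  sb <- (ssapwg / (P - G) - sc) / n1
  sa <- (ssag / (G - 1) - sc - n2 * sb) / n3
  tot <- sa + sb + sc
  c(sa = sa, sb = sb, sc = sc,
    fct = sa / tot, fsc = sb / (sb + sc), fst = (sa + sb) / tot)
}

# exact Fu's Fs for small n: integer Stirling numbers and direct summation
oracle_fs_exact <- function(n, theta, h_obs) {
  st <- matrix(0, n + 1, n + 1)   # |s(i, k)| exact in double for n <= 8
  st[1, 1] <- 1                   # row i+1 = n = i
  for (i in 1:n) {
    for (k in 1:i) {
      st[i + 1, k + 1] <- st[i, k] + (i - 1) * st[i, k + 1]
    }
  }
  rising <- prod(theta + 0:(n - 1))
  pk <- sapply(1:n, function(k) st[n + 1, k + 1] * theta^k / rising)
  Sp <- sum(pk[h_obs:n])
  log(Sp / (1 - Sp))
}

# minimum-spanning network by literal level-wise construction with
# Dijkstra-checked redundancy
oracle_msn <- function(states, limit) {
  H <- length(states)
  m <- do.call(rbind, strsplit(states, ""))
  dist <- matrix(0, H, H)
  for (i in seq_len(H)) for (j in seq_len(H)) dist[i, j] <- sum(m[i, ] != m[j, ])
  W <- matrix(Inf, H, H); diag(W) <- 0
  shortest <- function(W, s, t) {   # Dijkstra
    distv <- rep(Inf, H); distv[s] <- 0; done <- rep(FALSE, H)
    for (it in 1:H) {
      u <- which(!done & distv == min(distv[!done]))[1]
      if (!is.finite(distv[u])) break
      done[u] <- TRUE
      for (v in 1:H) if (is.finite(W[u, v])) {
        distv[v] <- min(distv[v], distv[u] + W[u, v])
      }
    }
    distv[t]
  }
  edges <- NULL
  for (d in seq_len(limit)) {
    level <- NULL
    for (i in seq_len(H - 1)) for (j in (i + 1):H) {
      if (dist[i, j] == d && shortest(W, i, j) > d) level <- rbind(level, c(i, j))
    }
    if (!is.null(level)) {
      for (r in seq_len(nrow(level))) {
        W[level[r, 1], level[r, 2]] <- W[level[r, 2], level[r, 1]] <- d
      }
      edges <- rbind(edges, cbind(level, d))
    }
  }
  if (is.null(edges)) edges <- matrix(numeric(0), 0, 3)
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

# random small alignment for property tests
random_alignment <- function(n, L, alphabet = c("A", "C", "G", "T")) {
  seqs <- replicate(n, paste(sample(alphabet, L, replace = TRUE), collapse = ""))
  alignment(paste0("s", seq_len(n)), seqs)
}
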