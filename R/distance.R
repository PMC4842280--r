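#' Nei's (1978) unbiased genetic distance between populations
#'
#' Treats the sequenced fragment as one locus with haplotypes as alleles.
#' With unbiased within-population identities
#' `J_X = (n_X * sum(x_i^2) - 1) / (n_X - 1)` and between-population
#' identity `J_XY = sum(x_i * y_i)`, the distance is
#' `D = -ln(J_XY / sqrt(J_X * J_Y))`. Populations sharing no haplotype
#' have identity 0; their distance is capped at `cap` (and recorded).
#'
#' @param table a [collapse_haplotypes()] result with per-population
#'   counts (each population `n >= 2`).
#' @param cap finite stand-in for infinite distances.
#' @return symmetric distance matrix (population labels as dimnames);
#'   attribute `capped` marks pairs that hit the cap.
#' @export
nei_distance <- function(table, cap = 10) {
  counts <- table$counts
  n <- colSums(counts)
  if (any(n < 2L)) stop("each population needs n >= 2", call. = FALSE)
  freq <- sweep(counts, 2L, n, "/")
  P <- ncol(counts)
  labels <- colnames(counts)
  d <- matrix(0, P, P, dimnames = list(labels, labels))
  capped <- matrix(FALSE, P, P, dimnames = list(labels, labels))
  J <- vapply(seq_len(P), function(p) {
    (n[p] * sum(freq[, p]^2) - 1) / (n[p] - 1)
  }, numeric(1))
  for (i in seq_len(P - 1L)) {
    for (j in (i + 1L):P) {
      Jxy <- sum(freq[, i] * freq[, j])
      if (Jxy <= 0 || J[i] <= 0 || J[j] <= 0) {
        d[i, j] <- d[j, i] <- cap
        capped[i, j] <- capped[j, i] <- TRUE
      } else {
        d[i, j] <- d[j, i] <- max(-log(Jxy / sqrt(J[i] * J[j])), 0)
      }
    }
  }
  attr(d, "capped") <- capped
  d
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration with a deterministic tie-break (the
#' lexicographically smallest label pair joins first); node height is
#' half the join distance, so tip-to-node path lengths are ultrametric.
#'
#' @param d symmetric numeric matrix with zero diagonal and labels as
#'   dimnames.
#' @return Newick string (with branch lengths, terminated by `;`).
#' @export
upgma <- function(d) {
  if (is.null(dimnames(d)) || is.null(rownames(d))) {
    stop("distance matrix needs labels as dimnames", call. = FALSE)
  }
  if (anyNA(d)) stop("input error: NaN/NA in distance matrix", call. = FALSE)
  if (nrow(d) < 2L) stop("need at least 2 labels", call. = FALSE)
  labels <- rownames(d)
  newick <- labels          # growing subtree strings
  height <- numeric(length(labels))
  size <- rep(1L, length(labels))
  repr <- labels            # lexicographic representative per cluster
  dm <- d
  while (length(newick) > 1L) {
    m <- length(newick)
    best <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        pr <- sort(c(repr[i], repr[j]))
        cand <- list(val = dm[i, j], pair = c(i, j), key = pr)
        if (is.null(best) || cand$val < best$val ||
            (cand$val == best$val &&
             (cand$key[1L] < best$key[1L] ||
              (cand$key[1L] == best$key[1L] && cand$key[2L] < best$key[2L])))) {
          best <- cand
        }
      }
    }
    i <- best$pair[1L]; j <- best$pair[2L]
    h <- best$val / 2
    node <- sprintf("(%s:%s,%s:%s)",
                    newick[i], format(h - height[i], digits = 10),
                    newick[j], format(h - height[j], digits = 10))
    ## average-linkage update
    newd <- (dm[i, ] * size[i] + dm[j, ] * size[j]) / (size[i] + size[j])
    keep <- setdiff(seq_len(m), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    newick <- c(newick[keep], node)
    height <- c(height[keep], h)
    size <- c(size[keep], size[i] + size[j])
    repr <- c(repr[keep], min(repr[c(i, j)]))
  }
  paste0(newick, ";")
}
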