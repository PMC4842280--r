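## Coalescent scaling used throughout: time is measured in units of 2N
## generations of one (current-size) deme; a pair of lineages in the same
## deme coalesces at rate 1; mutations accrue at rate theta_locus/2 per
## lineage, so an equilibrium pair differs at Poisson(theta * t) sites for
## separation time t. A sudden expansion of magnitude tau (mutational
## units) is a coalescence-rate step at scaled time tau/theta_locus, which
## puts the mode of the mismatch distribution near tau.

#' Single-population coalescent genealogy
#'
#' Simulates a Kingman coalescent for `n` tips, optionally with a
#' piecewise-constant size change: for times older than `rate_step$time`,
#' the pairwise coalescence rate is multiplied by `rate_step$factor`
#' (a factor > 1 encodes a smaller, pre-expansion population).
#'
#' @param n number of tips (>= 2).
#' @param rate_step optional `list(time =, factor =)`.
#' @return list with `lengths` (branch lengths of the 2n-2 edges),
#'   `tipsets` (tip index vector subtended by each edge), and `tmrca`.
#' @export
coalescent_tree <- function(n, rate_step = NULL) {
  if (n < 2L) stop("domain error: need at least 2 tips", call. = FALSE)
  sets <- as.list(seq_len(n))
  start <- numeric(n)
  lengths <- numeric(2L * (n - 1L))
  tipsets <- vector("list", 2L * (n - 1L))
  e <- 0L
  t <- 0
  k <- n
  while (k > 1L) {
    rate <- k * (k - 1) / 2
    if (is.null(rate_step) || t >= rate_step$time) {
      f <- if (is.null(rate_step)) 1 else rate_step$factor
      t <- t + stats::rexp(1L, rate * f)
    } else {
      dt <- stats::rexp(1L, rate)
      t <- if (t + dt <= rate_step$time) t + dt else
        rate_step$time + stats::rexp(1L, rate * rate_step$factor)
    }
    pair <- sample.int(k, 2L)
    for (ch in pair) {
      e <- e + 1L
      lengths[e] <- t - start[ch]
      tipsets[[e]] <- sets[[ch]]
    }
    merged <- c(sets[[pair[1L]]], sets[[pair[2L]]])
    keep <- setdiff(seq_len(k), pair)
    sets <- c(sets[keep], list(merged))
    start <- c(start[keep], t)
    k <- k - 1L
  }
  list(lengths = lengths, tipsets = tipsets, tmrca = t)
}

#' Structured n-island coalescent genealogy
#'
#' Lineages live in demes; within-deme pairs coalesce at rate
#' `factor_d(t)`, lineages migrate (backwards in time) at the rates of
#' `mig`, and older than `divergence_time` all demes merge into one
#' panmictic ancestral population (which makes zero-migration models
#' well-defined).
#'
#' @param sizes integer vector: sampled chromosomes per deme.
#' @param mig square migration-rate matrix (`mig[d, e]` = backwards rate
#'   per lineage from deme `d` into deme `e`; diagonal ignored), or a
#'   single number for a symmetric island model.
#' @param demography list (per deme) of `NULL` (constant size) or
#'   `list(time =, factor =)` rate steps.
#' @param divergence_time scaled time at which all demes join one
#'   ancestral population (default `Inf`).
#' @return as [coalescent_tree()], plus `tip_deme` (deme index per tip).
#' @export
structured_coalescent <- function(sizes, mig, demography = NULL,
                                  divergence_time = Inf) {
  D <- length(sizes)
  n <- sum(sizes)
  if (n < 2L) stop("domain error: need at least 2 tips", call. = FALSE)
  if (is.matrix(mig)) {
    stopifnot(nrow(mig) == D, ncol(mig) == D)
  } else {
    mig <- matrix(mig / max(1L, D - 1L), D, D)
  }
  diag(mig) <- 0
  if (D > 1L && all(mig == 0) && !is.finite(divergence_time)) {
    stop("domain error: zero migration requires a finite divergence_time",
         call. = FALSE)
  }
  if (is.null(demography)) demography <- vector("list", D)

  tip_deme <- rep(seq_len(D), sizes)
  sets <- as.list(seq_len(n))
  start <- numeric(n)
  deme <- tip_deme
  lengths <- numeric(2L * (n - 1L))
  tipsets <- vector("list", 2L * (n - 1L))
  e <- 0L
  t <- 0
  k <- n

  rate_factor <- function(d, t) {
    st <- demography[[d]]
    if (is.null(st) || t < st$time) 1 else st$factor
  }
  breakpoints <- sort(unique(c(
    vapply(demography, function(s) if (is.null(s)) Inf else s$time, numeric(1)),
    divergence_time)))

  while (k > 1L) {
    if (t >= divergence_time) deme <- rep(1L, k)
    kd <- tabulate(deme, nbins = D)
    coal_rates <- vapply(seq_len(D), function(d) {
      f <- if (t >= divergence_time) 1 else rate_factor(d, t)
      kd[d] * (kd[d] - 1) / 2 * f
    }, numeric(1))
    mig_out <- if (t >= divergence_time) numeric(k) else rowSums(mig)[deme]
    total <- sum(coal_rates) + sum(mig_out)
    if (total <= 0) stop("internal: zero event rate in structured coalescent")
    dt <- stats::rexp(1L, total)
    nxt <- breakpoints[breakpoints > t]
    if (length(nxt) && t + dt > nxt[1L]) {
      t <- nxt[1L]
      next
    }
    t <- t + dt
    u <- stats::runif(1L, 0, total)
    if (u <= sum(coal_rates)) {
      d <- which(cumsum(coal_rates) >= u)[1L]
      idx <- which(deme == d)
      pair <- idx[sample.int(length(idx), 2L)]
      for (ch in pair) {
        e <- e + 1L
        lengths[e] <- t - start[ch]
        tipsets[[e]] <- sets[[ch]]
      }
      merged <- c(sets[[pair[1L]]], sets[[pair[2L]]])
      keep <- setdiff(seq_len(k), pair)
      sets <- c(sets[keep], list(merged))
      start <- c(start[keep], t)
      deme <- c(deme[keep], d)
      k <- k - 1L
    } else {
      u <- u - sum(coal_rates)
      i <- which(cumsum(mig_out) >= u)[1L]
      dest_rates <- mig[deme[i], ]
      deme[i] <- sample.int(D, 1L, prob = dest_rates)
    }
  }
  list(lengths = lengths, tipsets = tipsets, tmrca = t, tip_deme = tip_deme)
}

#' Drop infinite-sites mutations onto a genealogy
#'
#' Poisson mutations (rate `theta_locus/2` per lineage per unit time) are
#' placed on branches; each mutation occupies a fresh column drawn
#' uniformly from `columns` (without replacement). If more mutations occur
#' than eligible columns, positions are re-drawn with replacement and the
#' result is flagged (`finite_sites_fallback`).
#'
#' @param tree a [coalescent_tree()] / [structured_coalescent()] result.
#' @param theta_locus scaled mutation rate for the whole eligible region.
#' @param L total alignment length.
#' @param columns eligible column indices (default: all).
#' @param ids sample identifiers (default `s1..sn`).
#' @param reference optional reference sequence (character vector length
#'   `L`); random bases otherwise.
#' @return a [alignment()]; attribute `finite_sites_fallback` is TRUE if
#'   column saturation forced reuse of positions.
#' @export
drop_mutations <- function(tree, theta_locus, L, columns = seq_len(L),
                           ids = NULL, reference = NULL) {
  if (theta_locus < 0) stop("domain error: theta must be >= 0", call. = FALSE)
  n <- length(unique(unlist(tree$tipsets)))
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  if (is.null(reference)) {
    reference <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  }
  mat <- matrix(rep(reference, each = n), nrow = n)
  nmut <- stats::rpois(length(tree$lengths), theta_locus / 2 * tree$lengths)
  total <- sum(nmut)
  fallback <- FALSE
  if (total > 0L) {
    if (total <= length(columns)) {
      pos <- sample(columns, total, replace = FALSE)
    } else {
      pos <- sample(columns, total, replace = TRUE)
      fallback <- TRUE
    }
    m <- 0L
    bases <- c("A", "C", "G", "T")
    for (b in which(nmut > 0L)) {
      for (r in seq_len(nmut[b])) {
        m <- m + 1L
        j <- pos[m]
        anc <- reference[j]
        derived <- sample(setdiff(bases, anc), 1L)
        mat[tree$tipsets[[b]], j] <- derived
      }
    }
  }
  out <- alignment(ids, apply(mat, 1L, paste, collapse = ""))
  attr(out, "finite_sites_fallback") <- fallback
  out
}

#' Simulation configuration
#'
#' Bundles everything [simulate_dataset()] needs: deme structure,
#' migration, mutation rate, fragment layout, per-deme demography, and an
#' optional selective-sweep overlay.
#'
#' @param n_demes number of demes.
#' @param samples_per_deme integer (scalar or per-deme vector) of sampled
#'   chromosomes.
#' @param migration scalar symmetric island-model rate, or a full
#'   `n_demes x n_demes` backwards migration-rate matrix.
#' @param theta_per_site scaled mutation rate per eligible site.
#' @param layout a [fragment_layout()]; mutations fall on its intron
#'   columns (the codon and exons stay clean unless the sweep writes
#'   them).
#' @param demography per-deme list: `NULL` (constant) or
#'   `list(tau =, ratio =)` for a sudden expansion of mutational age
#'   `tau` with pre/post size ratio `ratio = theta0/theta1 < 1`.
#' @param sweep optional `list(demes =, allele =, final_frequency =,
#'   background_count =)`; see [implant_sweep()].
#' @param coords optional data.frame `population, latitude, longitude,
#'   region` per deme; a regular grid is generated when absent.
#' @param divergence_time scaled time of the ancestral merge (default 20).
#' @param seed RNG seed (mandatory for pipeline runs).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_demes = 1L,
                       samples_per_deme = 20L,
                       migration = 1,
                       theta_per_site = 0.005,
                       layout = kdr_layout(),
                       demography = NULL,
                       sweep = NULL,
                       coords = NULL,
                       divergence_time = 20,
                       seed = NULL) {
  samples_per_deme <- rep_len(as.integer(samples_per_deme), n_demes)
  if (any(samples_per_deme < 1L)) stop("domain error: zero samples", call. = FALSE)
  if (theta_per_site < 0) stop("domain error: negative theta", call. = FALSE)
  if (any(unlist(migration) < 0)) stop("domain error: negative migration", call. = FALSE)
  if (!is.null(sweep)) {
    stopifnot(sweep$final_frequency >= 0, sweep$final_frequency <= 1,
              sweep$background_count >= 1)
  }
  if (is.null(coords)) {
    side <- ceiling(sqrt(n_demes))
    coords <- data.frame(
      population = paste0("D", seq_len(n_demes)),
      latitude = 20 + 2 * ((seq_len(n_demes) - 1L) %/% side),
      longitude = 100 + 2 * ((seq_len(n_demes) - 1L) %% side),
      region = "all",
      stringsAsFactors = FALSE)
  }
  structure(list(n_demes = n_demes, samples_per_deme = samples_per_deme,
                 migration = migration, theta_per_site = theta_per_site,
                 layout = layout, demography = demography, sweep = sweep,
                 coords = coords, divergence_time = divergence_time,
                 seed = seed),
            class = "sim_config")
}

## resistant codon per allele class (wild TTG, Leu)
kdr_codon_for_class <- function(class) {
  switch(class,
         F = "TTT",  # G->T at the third codon base
         C = "TGT",  # T->G at the second codon base
         S = "TCG",  # T->C at the second codon base
         W = "TGG",
         stop(sprintf("unknown resistant allele class '%s'", class), call. = FALSE))
}

#' Overlay a selective sweep on simulated data
#'
#' Phenomenological sweep: in each target deme, the `background_count`
#' most frequent haplotype backgrounds receive the resistant codon, and
#' deme chromosomes are resampled so the resistant classes reach
#' `final_frequency`. Swept demes end up with near-fixed resistant codons
#' riding few intron backgrounds, hence reduced intron diversity --
#' the hitchhiking signature the analyses look for.
#'
#' @param aln a [alignment()] over the full fragment.
#' @param pops a [population_set()] for `aln`.
#' @param sweep `list(demes, allele, final_frequency, background_count)`;
#'   `allele` is a class in `F, C, S, W` (recycled across backgrounds).
#' @param layout the [fragment_layout()] locating the codon.
#' @return the modified [alignment()].
#' @export
implant_sweep <- function(aln, pops, sweep, layout = kdr_layout()) {
  if (sweep$final_frequency == 0) return(aln)
  mat <- aln$mat
  cod <- layout$codon[1L]:layout$codon[2L]
  classes <- rep_len(sweep$allele, sweep$background_count)
  for (d in sweep$demes) {
    idx <- which(aln$ids %in% names(pops$sample_to_pop)[pops$sample_to_pop == d])
    if (length(idx) == 0L) {
      stop(sprintf("domain error: sweep target deme '%s' has no samples", d),
           call. = FALSE)
    }
    seqs <- apply(mat[idx, , drop = FALSE], 1L, paste, collapse = "")
    tab <- table(factor(seqs, levels = unique(seqs)))  # first-occurrence ties
    nb <- min(sweep$background_count, length(tab))
    backgrounds <- names(sort(tab, decreasing = TRUE))[seq_len(nb)]
    n_res <- round(sweep$final_frequency * length(idx))
    if (n_res == 0L) next
    carriers <- sample(idx, n_res)
    assign_bg <- sample.int(nb, n_res, replace = TRUE)
    for (r in seq_len(n_res)) {
      bg <- strsplit(backgrounds[assign_bg[r]], "")[[1L]]
      bg[cod] <- strsplit(kdr_codon_for_class(classes[assign_bg[r]]), "")[[1L]]
      mat[carriers[r], ] <- bg
    }
  }
  alignment(aln$ids, apply(mat, 1L, paste, collapse = ""))
}

#' Simulate a full analysis-ready dataset
#'
#' Runs the structured coalescent over the configured demes, drops
#' infinite-sites mutations on the intron columns, writes the wild-type
#' codon (TTG) at the focal codon, applies the sweep overlay if
#' configured, and returns the alignment together with its population
#' set. Deterministic under `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `aln` ([alignment()]), `pops` ([population_set()]),
#'   and `layout`.
#' @export
simulate_dataset <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  L <- cfg$layout$length
  intron_cols <- layout_columns(cfg$layout, "intron")
  theta_locus <- cfg$theta_per_site * length(intron_cols)

  demog <- NULL
  if (!is.null(cfg$demography)) {
    demog <- lapply(cfg$demography, function(d) {
      if (is.null(d)) return(NULL)
      list(time = d$tau / max(theta_locus, 1e-12), factor = 1 / d$ratio)
    })
  }

  pop_ids <- cfg$coords$population
  ids <- unlist(lapply(seq_len(cfg$n_demes), function(d) {
    paste0(pop_ids[d], "_", seq_len(cfg$samples_per_deme[d]))
  }))
  s2p <- stats::setNames(rep(pop_ids, cfg$samples_per_deme), ids)
  pops <- population_set(
    s2p,
    cfg$coords[, c("population", "latitude", "longitude")],
    stats::setNames(cfg$coords$region, cfg$coords$population))

  reference <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  reference[cfg$layout$codon[1L]:cfg$layout$codon[2L]] <- c("T", "T", "G")

  if (cfg$n_demes == 1L && sum(cfg$samples_per_deme) >= 2L) {
    tree <- coalescent_tree(cfg$samples_per_deme[1L],
                            rate_step = if (is.null(demog)) NULL else demog[[1L]])
  } else {
    tree <- structured_coalescent(cfg$samples_per_deme, cfg$migration,
                                  demography = demog,
                                  divergence_time = cfg$divergence_time)
  }
  aln <- drop_mutations(tree, theta_locus, L, columns = intron_cols,
                        ids = ids, reference = reference)
  if (!is.null(cfg$sweep)) {
    aln <- implant_sweep(aln, pops, cfg$sweep, cfg$layout)
  }
  list(aln = aln, pops = pops, layout = cfg$layout)
}
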