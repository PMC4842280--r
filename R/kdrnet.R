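## kdr-specific analysis: the focal codon (L1014 of the para sodium
## channel) is classified by the amino acid it encodes; leucine is the
## susceptible wild type, phenylalanine/cysteine/serine/tryptophan are
## the knockdown-resistance classes.

kdr_class_for_aa <- function(aa) {
  switch(aa, L = "wild_L", F = "F", C = "C", S = "S", W = "W", "other")
}

#' Classify the resistance codon of every sequence
#'
#' Extracts the focal 3-base codon, translates it with the standard
#' genetic code, and assigns the allele class (`wild_L` for leucine,
#' `F`/`C`/`S`/`W` for the resistance replacements, `other` otherwise).
#' Codons containing `-`/`N` are flagged `unresolved`.
#'
#' @param aln a [alignment()].
#' @param layout a [fragment_layout()] locating the codon.
#' @return data.frame with one row per sequence: `sample`, `codon`,
#'   `amino_acid`, `allele_class`.
#' @export
classify_kdr_codon <- function(aln, layout = kdr_layout()) {
  cod <- layout$codon[1L]:layout$codon[2L]
  if (max(cod) > aln$length) stop("codon span outside alignment", call. = FALSE)
  codons <- apply(aln$mat[, cod, drop = FALSE], 1L, paste, collapse = "")
  gc <- Biostrings::GENETIC_CODE
  aa <- ifelse(grepl("^[ACGT]{3}$", codons), unname(gc[codons]), NA_character_)
  cls <- ifelse(is.na(aa), "unresolved",
                vapply(aa, function(a) if (is.na(a)) "unresolved"
                       else kdr_class_for_aa(a), character(1)))
  data.frame(sample = aln$ids, codon = codons, amino_acid = aa,
             allele_class = unname(cls), stringsAsFactors = FALSE)
}

#' Per-population resistance allele frequencies
#'
#' @param alleles a [classify_kdr_codon()] result.
#' @param pops a [population_set()] covering every sample.
#' @return data.frame, one row per population (rows sum to 1 across the
#'   allele-class columns), plus an `n` column.
#' @export
allele_frequencies <- function(alleles, pops) {
  pop <- pops$sample_to_pop[alleles$sample]
  if (anyNA(pop)) stop("mapping error: samples missing from population map", call. = FALSE)
  classes <- c("wild_L", "F", "C", "S", "W", "other", "unresolved")
  tab <- table(factor(unname(pop), levels = unique(unname(pop))),
               factor(alleles$allele_class, levels = classes))
  freq <- sweep(tab, 1L, pmax(rowSums(tab), 1L), "/")
  keep <- classes[colSums(tab) > 0 | classes == "wild_L"]
  out <- data.frame(population = rownames(tab), n = as.integer(rowSums(tab)),
                    as.data.frame.matrix(freq[, keep, drop = FALSE]),
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Highly polymorphic (informative) sites of the intron regions
#'
#' Intron columns whose minor-allele frequency across all chromosomes
#' exceeds `maf` (columns with alignment gaps or `N` are skipped), in
#' original-fragment coordinates, followed by the focal codon's variable
#' positions as designated sites.
#'
#' @param aln a [alignment()] over the full fragment.
#' @param layout a [fragment_layout()].
#' @param maf minor-allele-frequency threshold in `(0, 0.5)`.
#' @return list with `intron_sites`, `codon_sites`, and `sites` (their
#'   concatenation, sorted).
#' @export
informative_sites <- function(aln, layout = kdr_layout(), maf = 0.10) {
  if (maf <= 0 || maf >= 0.5) stop("maf must be in (0, 0.5)", call. = FALSE)
  intron_cols <- layout_columns(layout, "intron")
  keep <- logical(0)
  sel <- integer(0)
  for (j in intron_cols) {
    col <- aln$mat[, j]
    if (!all(col %in% c("A", "C", "G", "T"))) next
    tab <- table(col)
    if (length(tab) < 2L) next
    if ((1 - max(tab) / length(col)) > maf) sel <- c(sel, j)
  }
  cod <- layout$codon[1L]:layout$codon[2L]
  codon_var <- cod[vapply(cod, function(j) {
    length(unique(aln$mat[, j][aln$mat[, j] %in% c("A", "C", "G", "T")])) > 1L
  }, logical(1))]
  list(intron_sites = sel, codon_sites = codon_var,
       sites = sort(c(sel, codon_var)))
}

#' Restrict an alignment to selected sites and collapse to states
#'
#' @param aln a [alignment()].
#' @param sites original-fragment column indices.
#' @param pops optional [population_set()] for per-population counts.
#' @return a [collapse_haplotypes()] table over the selected-site states,
#'   with attribute `sites`.
#' @export
select_sites <- function(aln, sites, pops = NULL) {
  m <- aln$mat[, sites, drop = FALSE]
  sub <- alignment(aln$ids, apply(m, 1L, paste, collapse = ""))
  tab <- collapse_haplotypes(sub, pops)
  attr(tab, "sites") <- sites
  tab
}

#' Statistical-parsimony (minimum-spanning) haplotype network
#'
#' Nodes are the distinct selected-site states; candidate edges are node
#' pairs at Hamming distance `<= connection_limit`. Edges are added in
#' increasing step order, skipping any pair already connected at equal or
#' smaller total path cost, so all co-minimal alternative connections are
#' retained and the network may stay disconnected (components are
#' reported). Root probability within each component is proportional to
#' haplotype frequency, the usual frequency-age surrogate.
#'
#' @param states a [select_sites()] table (attribute `sites` gives the
#'   original coordinates of the selected columns).
#' @param connection_limit maximum mutational steps per edge.
#' @param codon_sites original coordinates of the codon columns among the
#'   selected sites (used to split codon state from intron background).
#' @param layout optional [fragment_layout()]; default supplies
#'   `codon_sites` when absent.
#' @param prob_threshold parsimony connection probability carried as
#'   metadata.
#' @return list of class `haplo_network`: `nodes` data.frame (`id`,
#'   `state`, `freq`, `codon_state`, `background`, `allele_class`,
#'   `root_prob`, `component`), `edges` data.frame (`from`, `to`,
#'   `steps`, `changes` in `from-siteindex-to` notation), plus the
#'   parameters and the per-population count matrix.
#' @export
build_network <- function(states, connection_limit = 2L, codon_sites = NULL,
                          layout = kdr_layout(), prob_threshold = 0.95) {
  sites <- attr(states, "sites")
  if (is.null(codon_sites)) {
    cod <- layout$codon[1L]:layout$codon[2L]
    codon_sites <- intersect(sites, cod)
  }
  codon_idx <- match(codon_sites, sites)
  H <- length(states$haplotypes)
  sm <- do.call(rbind, strsplit(states$haplotypes, ""))
  freq <- rowSums(states$counts)

  ## pairwise Hamming distances over the selected sites
  dist <- matrix(0L, H, H)
  if (H > 1L) {
    for (i in seq_len(H - 1L)) {
      for (j in (i + 1L):H) {
        dist[i, j] <- dist[j, i] <- sum(sm[i, ] != sm[j, ])
      }
    }
  }

  ## add edges level by level; an edge is redundant if its endpoints are
  ## already connected by a path of total cost <= its step count
  edges <- data.frame(from = integer(0), to = integer(0), steps = integer(0),
                      changes = character(0), stringsAsFactors = FALSE)
  adj <- matrix(Inf, H, H); diag(adj) <- 0
  path_cost <- adj
  for (d in seq_len(max(1L, connection_limit))) {
    if (d > connection_limit) break
    cand <- which(dist == d & upper.tri(dist), arr.ind = TRUE)
    if (nrow(cand) == 0L) next
    keep <- path_cost[cand] > d      # connectivity before this level
    for (r in which(keep)) {
      i <- cand[r, 1L]; j <- cand[r, 2L]
      diffs <- which(sm[i, ] != sm[j, ])
      lab <- paste(sprintf("%s-%d-%s", sm[i, diffs], diffs, sm[j, diffs]),
                   collapse = ",")
      edges <- rbind(edges, data.frame(from = i, to = j, steps = d,
                                       changes = lab, stringsAsFactors = FALSE))
      adj[i, j] <- adj[j, i] <- d
    }
    ## refresh shortest path costs (Floyd-Warshall; H is small)
    path_cost <- adj
    for (k in seq_len(H)) {
      path_cost <- pmin(path_cost, outer(path_cost[, k], path_cost[k, ], "+"))
    }
  }

  ## connected components
  comp <- integer(H)
  cid <- 0L
  for (v in seq_len(H)) {
    if (comp[v] == 0L) {
      cid <- cid + 1L
      queue <- v
      while (length(queue)) {
        u <- queue[1L]; queue <- queue[-1L]
        if (comp[u] != 0L) next
        comp[u] <- cid
        nb <- unique(c(edges$to[edges$from == u], edges$from[edges$to == u]))
        queue <- c(queue, nb[comp[nb] == 0L])
      }
    }
  }
  root_prob <- numeric(H)
  for (cc in seq_len(cid)) {
    m <- comp == cc
    root_prob[m] <- freq[m] / sum(freq[m])
  }

  codon_state <- apply(sm[, codon_idx, drop = FALSE], 1L, paste, collapse = "")
  background <- apply(sm[, setdiff(seq_along(sites), codon_idx), drop = FALSE],
                      1L, paste, collapse = "")
  gc <- Biostrings::GENETIC_CODE
  full_codon <- vapply(seq_len(H), function(i) {
    cod <- layout$codon[1L]:layout$codon[2L]
    tmpl <- c("T", "T", "G")             # wild codon backbone
    tmpl[match(codon_sites, cod)] <- sm[i, codon_idx]
    paste(tmpl, collapse = "")
  }, character(1))
  allele_class <- vapply(full_codon, function(cd) {
    if (!grepl("^[ACGT]{3}$", cd)) return("unresolved")
    kdr_class_for_aa(unname(gc[cd]))
  }, character(1))

  nodes <- data.frame(id = seq_len(H),
                      state = states$haplotypes,
                      freq = freq,
                      codon_state = codon_state,
                      background = background,
                      allele_class = unname(allele_class),
                      root_prob = root_prob,
                      component = comp,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 connection_limit = connection_limit,
                 prob_threshold = prob_threshold,
                 sites = sites, codon_sites = codon_sites,
                 counts = states$counts),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("<haplo_network> %d nodes, %d edges, %d component(s), limit %d steps\n",
              nrow(x$nodes), nrow(x$edges), max(x$nodes$component),
              x$connection_limit))
  invisible(x)
}

#' Count independent origins of resistance mutations in a network
#'
#' An origin event is a network edge whose endpoints differ at a codon
#' position such that the allele class changes from wild type to a
#' resistant class, or between two resistant classes along the inferred
#' direction of descent (away from the higher-root-probability node).
#' Resistant nodes in components containing no wild-type member
#' contribute one event per component founder, so the totals are lower
#' bounds ("at least N origins").
#'
#' @param net a [build_network()] result.
#' @return list of class `origin_report`: `n_events`, `events`
#'   (data.frame: derived allele class, intron background, edge), plus
#'   `n_backgrounds` (distinct intron backgrounds carrying an origin) and
#'   `n_resistant_haplotypes`.
#' @export
count_origin_events <- function(net) {
  nodes <- net$nodes
  if (any(nodes$allele_class == "unresolved")) {
    stop("input error: node with unresolved codon state", call. = FALSE)
  }
  resistant <- setdiff(unique(nodes$allele_class), "wild_L")
  ev <- list()
  for (r in seq_len(nrow(net$edges))) {
    i <- net$edges$from[r]; j <- net$edges$to[r]
    ci <- nodes$allele_class[i]; cj <- nodes$allele_class[j]
    if (ci == cj) next
    if (ci == "wild_L" || cj == "wild_L") {
      derived <- if (ci == "wild_L") j else i
    } else {
      ## resistant -> resistant: ancestral side has the larger root probability
      derived <- if (nodes$root_prob[i] >= nodes$root_prob[j]) j else i
    }
    ev[[length(ev) + 1L]] <- data.frame(
      allele = nodes$allele_class[derived],
      background = nodes$background[derived],
      node = derived, edge = r, stringsAsFactors = FALSE)
  }
  ## components with resistant members but no wild type: founder = the
  ## highest-root-probability node of each resistant class present
  for (cc in unique(nodes$component)) {
    m <- nodes$component == cc
    if (any(nodes$allele_class[m] == "wild_L")) next
    for (cls in intersect(unique(nodes$allele_class[m]), resistant)) {
      sel <- which(m & nodes$allele_class == cls)
      founder <- sel[which.max(nodes$root_prob[sel])]
      already <- length(ev) > 0L &&
        any(vapply(ev, function(e) e$node == founder, logical(1)))
      if (!already) {
        ev[[length(ev) + 1L]] <- data.frame(
          allele = cls, background = nodes$background[founder],
          node = founder, edge = NA_integer_, stringsAsFactors = FALSE)
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(allele = character(0), background = character(0),
               node = integer(0), edge = integer(0))
  structure(list(
    n_events = nrow(events),
    events = events,
    n_backgrounds = length(unique(events$background)),
    n_resistant_haplotypes = sum(nodes$allele_class %in% resistant)),
    class = "origin_report")
}

#' @export
print.origin_report <- function(x, ...) {
  cat(sprintf("<origin_report> %d origin event(s) on %d background(s); %d resistant haplotype(s)\n",
              x$n_events, x$n_backgrounds, x$n_resistant_haplotypes))
  invisible(x)
}

#' Write a network as an edge-list TSV
#'
#' @param net a [build_network()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  e <- net$edges
  out <- data.frame(
    from_state = net$nodes$state[e$from],
    to_state = net$nodes$state[e$to],
    from_class = net$nodes$allele_class[e$from],
    to_class = net$nodes$allele_class[e$to],
    steps = e$steps, changes = e$changes,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
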