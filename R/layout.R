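#' Exon/intron layout of the sequenced fragment
#'
#' Describes how the amplified fragment tiles into exon and intron segments
#' (1-based inclusive coordinates) and where the focal resistance codon
#' sits. All reported site positions use these original-fragment
#' coordinates, even after a region has been extracted.
#'
#' @param segments data.frame with columns `label` (`"exon"`/`"intron"`),
#'   `start`, `end`; segments must tile `[1, total length]` without overlap.
#' @param codon integer vector of length 2, `(start, end)` of the focal
#'   codon; must span exactly 3 bases inside one exon segment.
#' @return An object of class `fragment_layout`.
#' @export
fragment_layout <- function(segments, codon) {
  segments <- as.data.frame(segments)
  if (!all(c("label", "start", "end") %in% names(segments))) {
    stop("fragment_layout: segments need columns label, start, end", call. = FALSE)
  }
  if (!all(segments$label %in% c("exon", "intron"))) {
    stop("fragment_layout: segment labels must be 'exon' or 'intron'", call. = FALSE)
  }
  segments <- segments[order(segments$start), , drop = FALSE]
  if (segments$start[1L] != 1L) stop("fragment_layout: segments must start at 1", call. = FALSE)
  if (nrow(segments) > 1L &&
      any(segments$start[-1L] != segments$end[-nrow(segments)] + 1L)) {
    stop("fragment_layout: segments must tile without gaps or overlap", call. = FALSE)
  }
  codon <- as.integer(codon)
  if (length(codon) != 2L || codon[2L] - codon[1L] != 2L) {
    stop("fragment_layout: codon span must cover exactly 3 bases", call. = FALSE)
  }
  host <- segments$label[segments$start <= codon[1L] & segments$end >= codon[2L]]
  if (length(host) != 1L || host != "exon") {
    stop("fragment_layout: codon must lie inside one exon segment", call. = FALSE)
  }
  structure(list(segments = segments, codon = codon,
                 length = max(segments$end)),
            class = "fragment_layout")
}

#' @export
print.fragment_layout <- function(x, ...) {
  cat(sprintf("<fragment_layout> %d bp, %d segments, codon %d-%d\n",
              x$length, nrow(x$segments), x$codon[1L], x$codon[2L]))
  invisible(x)
}

#' Layout of the 1285 bp kdr fragment
#'
#' The default layout of the sequenced para sodium-channel fragment:
#' exon 1-74, intron-1 75-979 (905 bp), exon 980-1166 (187 bp, carrying the
#' L1014 codon at 1160-1162), intron-2 1167-1230 (64 bp), exon 1231-1285
#' (55 bp). This is the unique exon/intron arrangement consistent with the
#' stated segment lengths and with the known polymorphic-site positions
#' (181, 940, 943 in intron-1; 1197, 1210, 1226 in intron-2; codon bases at
#' 1161 and 1162).
#'
#' @return a [fragment_layout()] for the 1285 bp fragment.
#' @export
kdr_layout <- function() {
  fragment_layout(
    data.frame(label = c("exon", "intron", "exon", "intron", "exon"),
               start = c(1L, 75L, 980L, 1167L, 1231L),
               end   = c(74L, 979L, 1166L, 1230L, 1285L)),
    codon = c(1160L, 1162L)
  )
}

#' Read a fragment layout from JSON
#'
#' Schema: `{"segments": [{"label": ..., "start": ..., "end": ...}, ...],
#' "codon": [start, end]}`.
#'
#' @param path JSON path.
#' @return a [fragment_layout()].
#' @export
read_layout <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fragment_layout(as.data.frame(x$segments), as.integer(x$codon))
}

#' Write a fragment layout to JSON
#' @param layout a [fragment_layout()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  jsonlite::write_json(list(segments = layout$segments,
                            codon = layout$codon),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Columns of a layout belonging to given segment labels
#' @param layout a [fragment_layout()].
#' @param labels subset of `c("exon", "intron")`.
#' @return integer vector of original-fragment column indices.
#' @export
layout_columns <- function(layout, labels) {
  seg <- layout$segments[layout$segments$label %in% labels, , drop = FALSE]
  if (nrow(seg) == 0L) return(integer(0))
  unlist(Map(seq.int, seg$start, seg$end), use.names = FALSE)
}

#' Extract the columns of selected segment types
#'
#' Restricts an alignment to the columns of the segments whose label is in
#' `labels` (e.g. the two introns flanking the resistance codon), keeping
#' column order. The returned `col_map` translates columns of the extracted
#' alignment back to original-fragment coordinates so that site positions
#' can always be reported on the full fragment.
#'
#' @param aln a [alignment()] whose length matches the layout.
#' @param layout a [fragment_layout()].
#' @param labels segment labels to keep.
#' @return list with `aln` (the restricted [alignment()]) and `col_map`
#'   (integer vector: extracted column -> original column).
#' @export
extract_region <- function(aln, layout, labels) {
  if (layout$length != aln$length) {
    stop(sprintf("layout length %d does not match alignment length %d",
                 layout$length, aln$length), call. = FALSE)
  }
  cols <- layout_columns(layout, labels)
  if (length(cols) == 0L) {
    stop("empty-region error: no columns match the requested labels", call. = FALSE)
  }
  m <- aln$mat[, cols, drop = FALSE]
  out <- alignment(aln$ids, apply(m, 1L, paste, collapse = ""))
  list(aln = out, col_map = cols)
}
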