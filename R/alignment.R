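#' Aligned haploid DNA sequences
#'
#' An `kdr_alignment` is the universal input of the package: a matrix of
#' equal-length haploid DNA sequences over the alphabet `A,C,G,T,-,N`
#' (case-insensitive input is normalised to upper case), with unique,
#' non-empty sample identifiers.
#'
#' @param ids character vector of unique sample identifiers.
#' @param seqs character vector of DNA strings, all of identical length.
#' @return An object of class `kdr_alignment`: a list with elements `ids`
#'   (character), `mat` (character matrix, samples x columns), and `length`
#'   (number of alignment columns).
#' @export
alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) {
    stop("alignment: ids and seqs must have equal length", call. = FALSE)
  }
  if (length(ids) == 0L) stop("alignment: empty input", call. = FALSE)
  if (anyDuplicated(ids) || any(!nzchar(ids))) {
    stop("alignment: sample ids must be unique and non-empty", call. = FALSE)
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- ids[which(lens != lens[1L])[1L]]
    stop(sprintf("alignment: ragged sequence lengths (record '%s' has %d columns, expected %d)",
                 bad, nchar(seqs[ids == bad][1L]), lens[1L]), call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- ids
  ok <- mat %in% c("A", "C", "G", "T", "-", "N")
  if (!all(ok)) {
    idx <- which(!ok)[1L]
    pos <- arrayInd(idx, dim(mat))
    stop(sprintf("alignment: illegal character '%s' in record '%s' at column %d",
                 mat[idx], ids[pos[1L]], pos[2L]), call. = FALSE)
  }
  structure(list(ids = ids, mat = mat, length = ncol(mat)),
            class = "kdr_alignment")
}

#' @export
print.kdr_alignment <- function(x, ...) {
  cat(sprintf("<kdr_alignment> %d sequences x %d columns\n",
              length(x$ids), x$length))
  invisible(x)
}

#' Number of sequences in an alignment
#' @param aln a [alignment()] object.
#' @return integer sample count.
#' @export
n_seq <- function(aln) length(aln$ids)

## sequences as strings (internal convenience)
aln_strings <- function(aln) {
  stats::setNames(apply(aln$mat, 1L, paste, collapse = ""), aln$ids)
}

#' Read an alignment from FASTA
#'
#' @param path path to a FASTA file of pre-aligned sequences.
#' @param format only `"fasta"` is supported.
#' @return A [alignment()] object; record order is preserved.
#' @export
read_alignment <- function(path, format = "fasta") {
  format <- match.arg(tolower(format), "fasta")
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: no records", call. = FALSE)
  w <- Biostrings::width(ss)
  if (length(unique(w)) != 1L) {
    bad <- names(ss)[which(w != w[1L])[1L]]
    stop(sprintf("alignment-shape error: record '%s' has length %d, expected %d",
                 bad, w[names(ss) == bad][1L], w[1L]), call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(ss))
  alignment(ids, as.character(ss))
}

#' Write an alignment to FASTA
#'
#' @param aln a [alignment()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- aln_strings(aln)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", aln$ids, "\n", seqs), con)
  invisible(path)
}

#' Subset an alignment by sample ids
#' @param aln a [alignment()] object.
#' @param ids sample identifiers to keep (order respected).
#' @return a [alignment()] restricted to `ids`.
#' @export
subset_alignment <- function(aln, ids) {
  miss <- setdiff(ids, aln$ids)
  if (length(miss)) {
    stop(sprintf("unknown sample ids: %s", paste(miss, collapse = ", ")), call. = FALSE)
  }
  m <- aln$mat[ids, , drop = FALSE]
  alignment(ids, apply(m, 1L, paste, collapse = ""))
}
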