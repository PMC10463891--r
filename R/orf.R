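#' Enumerate complete open reading frames in a spliced sequence
#'
#' Every ATG is paired with the first in-frame stop codon downstream of it;
#' only complete ORFs (stop present within the sequence) are returned.
#' Coordinates are 0-based half-open in spliced space and include the stop
#' codon.
#'
#' @param spliced_seq character scalar (5'->3').
#' @return data.frame `start`, `end`, `length_nt`, sorted by start.
#' @export
find_orfs <- function(spliced_seq) {
  s <- toupper(spliced_seq)
  n <- nchar(s)
  out <- list()
  if (n >= 6L) {
    codons_at <- function(pos) substring(s, pos, pos + 2L)
    for (frame in 0:2) {
      pos <- seq(frame + 1L, n - 2L, by = 3L)
      if (!length(pos)) next
      cods <- codons_at(pos)
      is_start <- cods == "ATG"
      is_stop <- cods %in% c("TAA", "TAG", "TGA")
      stop_idx <- which(is_stop)
      for (i in which(is_start)) {
        nxt <- stop_idx[stop_idx >= i]
        if (!length(nxt)) next
        a <- pos[i] - 1L
        b <- pos[nxt[1]] + 2L
        out[[length(out) + 1L]] <- c(a, b)
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      length_nt = integer()))
  m <- do.call(rbind, out)
  df <- data.frame(start = m[, 1], end = m[, 2])
  df$length_nt <- df$end - df$start
  df[order(df$start, df$end), , drop = FALSE]
}

#' Select the optimal ORF of a spliced transcript
#'
#' Two selection modes reflecting curation practice: `"longest"` picks the
#' maximal-length complete ORF; `"max_exon_span"` prefers the ORF whose
#' coding sequence touches the most exons (breaking ties by length), the
#' manual override used when a shorter ORF distributes coding sequence across
#' more exons than the longest one. Residual ties go to the most-5' start.
#'
#' @param spliced_seq exon-concatenated transcript sequence (5'->3').
#' @param exon_offsets data.frame with `offset` (0-based start of each exon in
#'   spliced coordinates, 5'->3' order) and `length`; a single pseudo-exon
#'   covering the sequence is assumed when omitted.
#' @param mode `"longest"` or `"max_exon_span"`.
#' @return object of class `"orf_choice"`: list with `start`, `end` (0-based
#'   half-open, stop codon included), `length_nt`, `n_exons_spanned`, `mode`;
#'   or `NULL` when no complete ORF exists.
#' @export
select_orf <- function(spliced_seq, exon_offsets = NULL,
                       mode = c("longest", "max_exon_span")) {
  mode <- match.arg(mode)
  if (is.null(exon_offsets))
    exon_offsets <- data.frame(offset = 0L, length = nchar(spliced_seq))
  orfs <- find_orfs(spliced_seq)
  if (!nrow(orfs)) return(NULL)
  orfs$n_exons <- vapply(seq_len(nrow(orfs)), function(i) {
    sum(exon_offsets$offset < orfs$end[i] &
          exon_offsets$offset + exon_offsets$length > orfs$start[i])
  }, integer(1))
  key <- if (mode == "longest") {
    order(-orfs$length_nt, orfs$start)
  } else {
    order(-orfs$n_exons, -orfs$length_nt, orfs$start)
  }
  best <- orfs[key[1], ]
  structure(list(start = best$start, end = best$end,
                 length_nt = best$length_nt,
                 n_exons_spanned = best$n_exons, mode = mode),
            class = "orf_choice")
}

#' @export
print.orf_choice <- function(x, ...) {
  cat(sprintf("<orf_choice> [%d,%d) %d nt over %d exon(s), mode=%s\n",
              x$start, x$end, x$length_nt, x$n_exons_spanned, x$mode))
  invisible(x)
}

#' Re-derive the CDS of a transcript from its optimal ORF
#'
#' Replaces the transcript's CDS segments with those of the selected ORF in
#' genomic coordinates. Returns `NULL` when no complete ORF exists.
#'
#' @param tx a [transcript()].
#' @param genome named contig sequences.
#' @param mode passed to [select_orf()].
#' @return a transcript with updated `cds`, or `NULL`.
#' @export
reorf_transcript <- function(tx, genome, mode = "longest") {
  s <- spliced_sequence(tx, genome)
  off <- spliced_offsets(tx)
  choice <- select_orf(s, off, mode = mode)
  if (is.null(choice)) return(NULL)
  tx$cds <- spliced_to_genomic(tx, choice$start, choice$end)
  tx
}
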