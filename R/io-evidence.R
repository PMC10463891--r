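#' Read a genome FASTA
#' @param path FASTA file.
#' @return named character vector of contig sequences (upper case).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a genome FASTA
#' @param genome named character vector (or DNAStringSet).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  if (is.character(genome))
    genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path, width = 80L)
  invisible(path)
}

#' Read a bedGraph coverage file into dense per-base tracks
#'
#' bedGraph intervals are 0-based half-open; the returned tracks are dense
#' 1-based per-base depth vectors with uncovered positions at 0. Overlapping
#' records follow last-writer-wins with a warning.
#'
#' @param path bedGraph file.
#' @param contig_lengths named integer vector of contig lengths.
#' @return named list of numeric depth vectors (a coverage track).
#' @export
read_coverage_bedgraph <- function(path, contig_lengths) {
  track <- lapply(contig_lengths, function(n) numeric(n))
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(track)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!length(gr)) return(track)
  seqid <- as.character(GenomicRanges::seqnames(gr))
  bad <- setdiff(unique(seqid), names(contig_lengths))
  if (length(bad)) stop("bedGraph contig not in genome: ",
                        paste(bad, collapse = ", "))
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  if (any(en > contig_lengths[seqid]))
    stop("bedGraph interval beyond contig length")
  touched <- lapply(contig_lengths, function(n) logical(n))
  overlap <- FALSE
  for (i in seq_along(gr)) {
    idx <- st[i]:en[i]
    if (any(touched[[seqid[i]]][idx])) overlap <- TRUE
    touched[[seqid[i]]][idx] <- TRUE
    track[[seqid[i]]][idx] <- gr$score[i]
  }
  if (overlap)
    warning("overlapping bedGraph records: last record wins")
  track
}

#' Write a coverage track as bedGraph
#' @param track named list of per-base depth vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_coverage_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (seqid in names(track)) {
    v <- track[[seqid]]
    if (!length(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%g", seqid, starts[keep] - 1L,
                       ends[keep], r$values[keep]), con)
  }
  invisible(path)
}

#' Read spliced junctions from a BED6 file
#'
#' Each record is one intron: BED coordinates are converted so that `start`
#' and `end` are the first and last intronic base (1-based inclusive). The
#' BED score column carries the supporting read count; the name column is
#' ignored. Strandless records (`.`) are kept with strand `"*"`, optionally
#' resolved by GT-AG inference against a genome.
#'
#' @param path BED6 file.
#' @param genome optional named character vector; when given, strandless
#'   junctions flanked by GT..AG (or CT..AC) are assigned a strand.
#' @param source label recorded in the `source` column (default `"short"`).
#' @return junction data.frame (see [evidence_bundle()]).
#' @export
read_junctions_bed <- function(path, genome = NULL, source = "short") {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(empty_junctions())
  gr <- rtracklayer::import(path, format = "BED")
  if (!length(gr)) return(empty_junctions())
  j <- data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr),
                  end = GenomicRanges::end(gr),
                  strand = as.character(GenomicRanges::strand(gr)),
                  read_count = as.integer(gr$score),
                  source = source)
  if (any(j$read_count < 1L)) stop("junction with read_count < 1")
  if (!is.null(genome)) {
    amb <- which(j$strand == "*")
    for (i in amb) {
      contig <- genome_contig(genome, j$seqid[i])
      don <- substr(contig, j$start[i], j$start[i] + 1L)
      acc <- substr(contig, j$end[i] - 1L, j$end[i])
      if (don == "GT" && acc == "AG") j$strand[i] <- "+"
      else if (don == "CT" && acc == "AC") j$strand[i] <- "-"
    }
  }
  j[order(j$seqid, j$start, j$end), , drop = FALSE]
}

#' Write junctions as BED6
#' @param junctions junction data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_junctions_bed <- function(junctions, path) {
  j <- junctions
  strand <- ifelse(j$strand == "*", ".", j$strand)
  lines <- sprintf("%s\t%d\t%d\tjunc%d\t%d\t%s",
                   j$seqid, j$start - 1L, j$end, seq_len(nrow(j)),
                   j$read_count, strand)
  writeLines(lines, path)
  invisible(path)
}
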