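#' Construct a transcript
#'
#' A transcript is an ordered set of exons on one contig and strand, with an
#' optional set of CDS segments nested inside the exons. Coordinates are
#' 1-based inclusive throughout the package (GFF3 convention).
#'
#' @param transcript_id character scalar.
#' @param seqid contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with integer columns `start`, `end`; stored sorted
#'   by `start`. Exons must be non-overlapping and separated by at least 1 bp.
#' @param cds data.frame with columns `start`, `end` (may have zero rows);
#'   every CDS segment must lie within an exon.
#' @param gene_id parent gene id (filled in by [gene_model()] if missing).
#' @return An object of class `"transcript"`.
#' @export
transcript <- function(transcript_id, seqid, strand, exons,
                       cds = exons[0, , drop = FALSE], gene_id = NA_character_) {
  exons <- normalize_intervals(exons)
  cds <- normalize_intervals(cds)
  obj <- structure(
    list(transcript_id = as.character(transcript_id),
         gene_id = as.character(gene_id),
         seqid = as.character(seqid),
         strand = as.character(strand),
         exons = exons, cds = cds),
    class = "transcript")
  validate_transcript(obj)
  obj
}

normalize_intervals <- function(df) {
  df <- as.data.frame(df)[, c("start", "end"), drop = FALSE]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

validate_transcript <- function(tx) {
  stopifnot(is.character(tx$seqid), nzchar(tx$seqid))
  if (!tx$strand %in% c("+", "-"))
    stop("transcript ", tx$transcript_id, ": strand must be '+' or '-'")
  ex <- tx$exons
  if (nrow(ex) == 0L)
    stop("transcript ", tx$transcript_id, ": needs at least one exon")
  if (any(ex$start < 1L) || any(ex$end < ex$start))
    stop("transcript ", tx$transcript_id, ": invalid exon coordinates")
  if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)] + 1L))
    stop("transcript ", tx$transcript_id,
         ": exons must be non-overlapping and intron-separated")
  cds <- tx$cds
  if (nrow(cds)) {
    if (any(cds$end < cds$start))
      stop("transcript ", tx$transcript_id, ": invalid CDS coordinates")
    inside <- vapply(seq_len(nrow(cds)), function(i) {
      any(ex$start <= cds$start[i] & cds$end[i] <= ex$end)
    }, logical(1))
    if (!all(inside))
      stop("transcript ", tx$transcript_id,
           ": CDS segment outside exon boundaries")
  }
  invisible(tx)
}

#' Construct a gene model
#'
#' @param gene_id character scalar.
#' @param transcripts non-empty list of [transcript()] objects sharing `seqid`
#'   and `strand`.
#' @return An object of class `"gene_model"` with a derived `span`.
#' @export
gene_model <- function(gene_id, transcripts) {
  stopifnot(length(transcripts) >= 1L)
  transcripts <- lapply(transcripts, function(tx) {
    tx$gene_id <- as.character(gene_id); tx
  })
  seqids <- unique(vapply(transcripts, `[[`, "", "seqid"))
  strands <- unique(vapply(transcripts, `[[`, "", "strand"))
  if (length(seqids) != 1L || length(strands) != 1L)
    stop("gene ", gene_id, ": transcripts must share seqid and strand")
  ids <- vapply(transcripts, `[[`, "", "transcript_id")
  transcripts <- transcripts[order(ids)]
  names(transcripts) <- sort(ids)
  structure(
    list(gene_id = as.character(gene_id), seqid = seqids, strand = strands,
         transcripts = transcripts),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  sp <- gene_span(x)
  cat(sprintf("<gene_model> %s %s:%d-%d(%s), %d transcript(s)\n",
              x$gene_id, x$seqid, sp[1], sp[2], x$strand,
              length(x$transcripts)))
  invisible(x)
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript> %s (%s) %s:%s, %d exon(s), %d CDS segment(s)\n",
              x$transcript_id, x$gene_id, x$seqid, x$strand,
              nrow(x$exons), nrow(x$cds)))
  invisible(x)
}

#' Genomic span of a gene model or transcript
#' @param x a `gene_model` or `transcript`.
#' @return integer vector `c(start, end)`.
#' @export
gene_span <- function(x) {
  if (inherits(x, "transcript"))
    return(c(min(x$exons$start), max(x$exons$end)))
  exs <- lapply(x$transcripts, `[[`, "exons")
  c(min(vapply(exs, function(e) min(e$start), 1L)),
    max(vapply(exs, function(e) max(e$end), 1L)))
}

cds_span <- function(x) {
  if (inherits(x, "transcript")) {
    if (!nrow(x$cds)) return(NULL)
    return(c(min(x$cds$start), max(x$cds$end)))
  }
  cds <- do.call(rbind, lapply(x$transcripts, `[[`, "cds"))
  if (is.null(cds) || !nrow(cds)) return(NULL)
  c(min(cds$start), max(cds$end))
}

#' Introns of a transcript
#' @param tx a `transcript`.
#' @return data.frame `start`, `end` of each intron (first and last intronic
#'   base), ordered by genomic position; zero rows for single-exon transcripts.
#' @export
tx_introns <- function(tx) {
  ex <- tx$exons
  if (nrow(ex) < 2L) return(data.frame(start = integer(), end = integer()))
  data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1L] - 1L)
}

#' Ordered exons in transcript (5' to 3') orientation
#' @noRd
exons_5to3 <- function(tx) {
  ex <- tx$exons
  if (tx$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  rownames(ex) <- NULL
  ex
}

#' Spliced (exon-concatenated) sequence of a transcript
#'
#' @param tx a `transcript`.
#' @param genome named [Biostrings::DNAStringSet] (or named character vector)
#'   of contig sequences.
#' @return character scalar, 5' to 3' in transcript orientation.
#' @export
spliced_sequence <- function(tx, genome) {
  contig <- genome_contig(genome, tx$seqid)
  parts <- substring(contig, tx$exons$start, tx$exons$end)
  s <- paste(parts, collapse = "")
  if (tx$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

genome_contig <- function(genome, seqid) {
  if (is.character(genome)) {
    if (!seqid %in% names(genome)) stop("contig not in genome: ", seqid)
    return(genome[[seqid]])
  }
  if (!seqid %in% names(genome)) stop("contig not in genome: ", seqid)
  as.character(genome[[seqid]])
}

#' Exon offsets in spliced coordinates
#'
#' 0-based start offset of each exon (in 5'->3' transcript order) within the
#' spliced sequence, plus exon lengths.
#' @noRd
spliced_offsets <- function(tx) {
  ex <- exons_5to3(tx)
  len <- ex$end - ex$start + 1L
  data.frame(offset = cumsum(c(0L, len[-length(len)])), length = len)
}

#' Map a half-open spliced interval to genomic CDS segments
#'
#' @param tx a `transcript`.
#' @param from,to 0-based half-open interval in spliced coordinates
#'   (transcript orientation).
#' @return data.frame `start`, `end` of genomic segments, sorted by start.
#' @export
spliced_to_genomic <- function(tx, from, to) {
  ex <- exons_5to3(tx)
  off <- spliced_offsets(tx)
  segs <- list()
  for (i in seq_len(nrow(ex))) {
    a <- max(from, off$offset[i]); b <- min(to, off$offset[i] + off$length[i])
    if (a >= b) next
    ra <- a - off$offset[i]; rb <- b - off$offset[i]  # within-exon, half-open
    if (tx$strand == "+") {
      segs[[length(segs) + 1L]] <- c(ex$start[i] + ra, ex$start[i] + rb - 1L)
    } else {
      segs[[length(segs) + 1L]] <- c(ex$end[i] - rb + 1L, ex$end[i] - ra)
    }
  }
  out <- as.data.frame(do.call(rbind, segs))
  names(out) <- c("start", "end")
  normalize_intervals(out)
}

#' Translated protein of a transcript's CDS
#'
#' @inheritParams spliced_sequence
#' @param strip_stop drop the trailing `*` if present.
#' @return character scalar amino-acid sequence, or `NA` if the transcript has
#'   no CDS.
#' @export
tx_protein <- function(tx, genome, strip_stop = TRUE) {
  if (!nrow(tx$cds)) return(NA_character_)
  cds_tx <- tx
  cds_tx$exons <- tx$cds
  s <- spliced_sequence(cds_tx, genome)
  n <- 3L * (nchar(s) %/% 3L)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(substr(s, 1L, n)),
                                           if.fuzzy.codon = "X"))
  if (strip_stop) aa <- sub("\\*$", "", aa)
  aa
}

#' Flatten gene models to a per-gene summary table
#' @param models list of `gene_model`.
#' @return data.frame with gene_id, seqid, strand, start, end, n_transcripts.
#' @export
models_table <- function(models) {
  do.call(rbind, c(list(data.frame(gene_id = character(), seqid = character(),
                                   strand = character(), start = integer(),
                                   end = integer(), n_transcripts = integer())),
    lapply(models, function(g) {
      sp <- gene_span(g)
      data.frame(gene_id = g$gene_id, seqid = g$seqid, strand = g$strand,
                 start = sp[1], end = sp[2],
                 n_transcripts = length(g$transcripts))
    })))
}

#' Canonically sort a list of gene models (seqid, start, gene_id)
#' @param models list of `gene_model`.
#' @return the sorted list, named by gene_id.
#' @export
sort_models <- function(models) {
  if (!length(models)) return(models)
  tab <- models_table(models)
  o <- order(tab$seqid, tab$start, tab$gene_id)
  models <- models[o]
  names(models) <- tab$gene_id[o]
  models
}

#' Union of exon intervals across all transcripts of a gene
#' @noRd
gene_exon_union <- function(g) {
  ex <- do.call(rbind, lapply(g$transcripts, `[[`, "exons"))
  ir <- IRanges::reduce(IRanges::IRanges(ex$start, ex$end))
  data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
}

#' Evidence bundle
#'
#' Bundles the RNA evidence consulted by the curation rules: a short-read
#' coverage track, an optional long-read coverage track, a weighted junction
#' table and a list of long-read transcript models.
#'
#' @param coverage_short named list of per-contig numeric depth vectors.
#' @param junctions data.frame with columns `seqid`, `start`, `end` (first and
#'   last intronic base), `strand` (`"+"`, `"-"` or `"*"`), `read_count`,
#'   `source` (`"short"` or `"long"`).
#' @param coverage_long optional named list like `coverage_short`.
#' @param long_chains list of [transcript()] objects (full-length long-read
#'   models).
#' @return object of class `"evidence_bundle"`.
#' @export
evidence_bundle <- function(coverage_short,
                            junctions = empty_junctions(),
                            coverage_long = NULL,
                            long_chains = list()) {
  junctions <- as.data.frame(junctions)
  if (nrow(junctions) && any(junctions$read_count < 1L))
    stop("junction read_count must be >= 1")
  if (nrow(junctions) && any(junctions$end <= junctions$start))
    stop("junction end must exceed start")
  structure(list(coverage_short = coverage_short,
                 coverage_long = coverage_long,
                 junctions = junctions,
                 long_chains = long_chains),
            class = "evidence_bundle")
}

#' @export
print.evidence_bundle <- function(x, ...) {
  cat(sprintf("<evidence_bundle> %d contig(s), %d junction(s), %d long chain(s)\n",
              length(x$coverage_short), nrow(x$junctions),
              length(x$long_chains)))
  invisible(x)
}

empty_junctions <- function() {
  data.frame(seqid = character(), start = integer(), end = integer(),
             strand = character(), read_count = integer(),
             source = character())
}

#' Curation configuration
#'
#' Central container for the thresholds used by the curation rules.
#'
#' @param min_edit_coverage mean exonic short-read depth below which a gene
#'   model is preserved untouched (default 2, i.e. "2x" coverage).
#' @param min_junction_reads short-read support needed to trust a junction
#'   (default 3).
#' @param coverage_gap_min_len bp of sub-threshold depth counting as a
#'   coverage gap (default 20).
#' @param intergenic_cov_fraction fraction of intergenic bases that must be
#'   covered for "uninterrupted" coverage (default 1.0).
#' @param intergenic_min_depth per-base depth for an intergenic base to count
#'   as covered (default 1).
#' @param max_isoform_clusters cap on alternative-junction clusters
#'   enumerated per gene (default 8).
#' @param dup_min_reciprocal_overlap reciprocal-overlap fraction for grouping
#'   collinear segments (default 0.5).
#' @param coords_merge_gap maximum gap (bp) when pre-merging collinear
#'   alignment records (default 500).
#' @param rng_seed integer seed recorded with the run.
#' @return object of class `"curation_config"`.
#' @export
curation_config <- function(min_edit_coverage = 2,
                            min_junction_reads = 3,
                            coverage_gap_min_len = 20,
                            intergenic_cov_fraction = 1.0,
                            intergenic_min_depth = 1,
                            max_isoform_clusters = 8,
                            dup_min_reciprocal_overlap = 0.5,
                            coords_merge_gap = 500,
                            rng_seed = 1L) {
  cfg <- list(min_edit_coverage = min_edit_coverage,
              min_junction_reads = min_junction_reads,
              coverage_gap_min_len = coverage_gap_min_len,
              intergenic_cov_fraction = intergenic_cov_fraction,
              intergenic_min_depth = intergenic_min_depth,
              max_isoform_clusters = max_isoform_clusters,
              dup_min_reciprocal_overlap = dup_min_reciprocal_overlap,
              coords_merge_gap = coords_merge_gap,
              rng_seed = as.integer(rng_seed))
  stopifnot(min_edit_coverage > 0, min_junction_reads > 0,
            coverage_gap_min_len > 0, max_isoform_clusters > 0,
            coords_merge_gap > 0,
            intergenic_cov_fraction > 0, intergenic_cov_fraction <= 1,
            dup_min_reciprocal_overlap > 0, dup_min_reciprocal_overlap <= 1)
  structure(cfg, class = "curation_config")
}

#' Read a curation configuration from a YAML file
#'
#' Keys present in the file override [curation_config()] defaults.
#' @param path YAML file.
#' @return `"curation_config"` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(curation_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(curation_config, vals)
}
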