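#' Read gene models from a GFF3 file
#'
#' Reconstructs the gene -> mRNA -> exon/CDS hierarchy from a GFF3 file with
#' `Parent` attributes. Coordinates are preserved exactly (1-based inclusive).
#' Features with unknown parents, or CDS segments extending outside their
#' transcript's exons, raise errors naming the offending feature.
#'
#' @param path GFF3 file.
#' @return Named list of [gene_model()] objects, sorted by seqid then start.
#' @export
read_gff3 <- function(path) {
  gff <- rtracklayer::readGFF(path,
                              columns = c("seqid", "start", "end", "strand", "type"),
                              tags = c("ID", "Parent"))
  gff <- as.data.frame(gff)
  if (!nrow(gff)) return(list())
  gff$Parent <- vapply(gff$Parent, function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, "")
  gff$seqid <- as.character(gff$seqid)
  gff$strand <- as.character(gff$strand)
  gff$type <- as.character(gff$type)

  genes <- gff[gff$type == "gene", , drop = FALSE]
  mrnas <- gff[gff$type %in% c("mRNA", "transcript"), , drop = FALSE]
  parts <- gff[gff$type %in% c("exon", "CDS"), , drop = FALSE]

  orphan <- setdiff(mrnas$Parent, genes$ID)
  if (length(orphan[!is.na(orphan)]))
    stop("mRNA with unknown Parent: ", paste(orphan, collapse = ", "))
  orphan <- setdiff(parts$Parent, mrnas$ID)
  if (length(orphan[!is.na(orphan)]))
    stop("exon/CDS with unknown Parent: ", paste(orphan, collapse = ", "))

  models <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$ID[i]
    tx_rows <- mrnas[mrnas$Parent == gid, , drop = FALSE]
    if (!nrow(tx_rows)) stop("gene without mRNA children: ", gid)
    txs <- lapply(seq_len(nrow(tx_rows)), function(j) {
      tid <- tx_rows$ID[j]
      ex <- parts[parts$Parent == tid & parts$type == "exon", , drop = FALSE]
      cd <- parts[parts$Parent == tid & parts$type == "CDS", , drop = FALSE]
      tryCatch(
        transcript(tid, tx_rows$seqid[j], tx_rows$strand[j],
                   ex[, c("start", "end")],
                   cd[, c("start", "end")], gene_id = gid),
        error = function(e) stop("invalid feature ", tid, ": ",
                                 conditionMessage(e), call. = FALSE))
    })
    gene_model(gid, txs)
  })
  sort_models(models)
}

#' Write gene models to a GFF3 file
#'
#' Output is valid GFF3 sorted by seqid then start, with deterministic
#' attribute layout, so that `read_gff3(write_gff3(x))` reproduces `x` and a
#' second write is byte-identical.
#'
#' @param models list of [gene_model()] objects (validated before writing).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  for (g in models) lapply(g$transcripts, validate_transcript)
  models <- sort_models(models)
  lines <- c("##gff-version 3")
  for (g in models) {
    sp <- gene_span(g)
    lines <- c(lines, gff_line(g$seqid, "gene", sp[1], sp[2], g$strand, ".",
                               sprintf("ID=%s", g$gene_id)))
    for (tx in g$transcripts) {
      tsp <- gene_span(tx)
      lines <- c(lines, gff_line(g$seqid, "mRNA", tsp[1], tsp[2], g$strand, ".",
                                 sprintf("ID=%s;Parent=%s", tx$transcript_id,
                                         g$gene_id)))
      ex <- tx$exons
      for (i in seq_len(nrow(ex)))
        lines <- c(lines, gff_line(g$seqid, "exon", ex$start[i], ex$end[i],
                                   g$strand, ".",
                                   sprintf("Parent=%s", tx$transcript_id)))
      cd <- tx$cds
      if (nrow(cd)) {
        phase <- cds_phases(cd, tx$strand)
        for (i in seq_len(nrow(cd)))
          lines <- c(lines, gff_line(g$seqid, "CDS", cd$start[i], cd$end[i],
                                     g$strand, phase[i],
                                     sprintf("Parent=%s", tx$transcript_id)))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

gff_line <- function(seqid, type, start, end, strand, phase, attrs) {
  paste(seqid, "annocurate", type, start, end, ".", strand, phase, attrs,
        sep = "\t")
}

cds_phases <- function(cd, strand) {
  len <- cd$end - cd$start + 1L
  ord <- if (strand == "-") rev(seq_len(nrow(cd))) else seq_len(nrow(cd))
  ph <- integer(nrow(cd))
  acc <- 0L
  for (i in ord) {
    ph[i] <- (3L - acc %% 3L) %% 3L
    acc <- acc + len[i]
  }
  ph
}
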