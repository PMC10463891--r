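#' Match and classify changes between two annotation sets
#'
#' Links genes of set A and set B on the same genome through a same-strand
#' CDS-overlap graph (at least 1 bp of CDS overlap) and classifies each
#' connected component: two-or-more A genes against one B gene is a SPLIT
#' (of A, repaired in B), one A against two-or-more B a FUSION, a 1-1 pair
#' with identical translated protein UNCHANGED and otherwise INTRON_CHAIN;
#' anything more complex (including genes private to one set) is
#' UNCLASSIFIED.
#'
#' @param setA,setB named lists of gene models on the same genome.
#' @param genome named contig sequences (for protein comparison).
#' @return data.frame with `genes_a`, `genes_b` (comma-joined ids),
#'   `change_class`, `protein_identical`.
#' @export
match_and_classify <- function(setA, setB, genome) {
  for (g in c(setA, setB))
    if (!g$seqid %in% names(genome))
      stop("gene ", g$gene_id, " on contig absent from genome: ", g$seqid)
  cds_gr <- function(models, tag) {
    rows <- lapply(models, function(g) {
      cds <- do.call(rbind, lapply(g$transcripts, `[[`, "cds"))
      if (is.null(cds) || !nrow(cds)) {
        cds <- do.call(rbind, lapply(g$transcripts, `[[`, "exons"))
      }
      data.frame(seqid = g$seqid, start = cds$start, end = cds$end,
                 strand = g$strand, gene = g$gene_id)
    })
    df <- do.call(rbind, rows)
    GenomicRanges::GRanges(df$seqid, IRanges::IRanges(df$start, df$end),
                           strand = df$strand, gene = df$gene, set = tag)
  }
  grA <- cds_gr(setA, "A"); grB <- cds_gr(setB, "B")
  hits <- GenomicRanges::findOverlaps(grA, grB, ignore.strand = FALSE)
  edges <- unique(data.frame(
    a = paste0("A:", grA$gene[S4Vectors::queryHits(hits)]),
    b = paste0("B:", grB$gene[S4Vectors::subjectHits(hits)])))
  verts <- unique(c(paste0("A:", names(setA)), paste0("B:", names(setB)),
                    edges$a, edges$b))
  gr <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                      vertices = verts)
  comp <- igraph::components(gr)$membership
  recs <- lapply(split(names(comp), comp), function(members) {
    a <- sub("^A:", "", members[startsWith(members, "A:")])
    b <- sub("^B:", "", members[startsWith(members, "B:")])
    cls <- if (length(a) == 1L && length(b) == 1L) {
      pa <- tx_protein(longest_isoform(setA[[a]], genome), genome)
      pb <- tx_protein(longest_isoform(setB[[b]], genome), genome)
      if (identical(pa, pb)) "UNCHANGED" else "INTRON_CHAIN"
    } else if (length(a) >= 2L && length(b) == 1L) "SPLIT"
    else if (length(a) == 1L && length(b) >= 2L) "FUSION"
    else "UNCLASSIFIED"
    data.frame(genes_a = paste(sort(a), collapse = ","),
               genes_b = paste(sort(b), collapse = ","),
               change_class = cls,
               protein_identical = cls == "UNCHANGED")
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out[order(out$genes_a, out$genes_b), , drop = FALSE]
}

longest_isoform <- function(g, genome) {
  lens <- vapply(g$transcripts, function(tx)
    if (nrow(tx$cds)) sum(tx$cds$end - tx$cds$start + 1L) else
      sum(tx$exons$end - tx$exons$start + 1L), 1L)
  g$transcripts[[which.max(lens)]]
}

#' Summarize change classifications
#'
#' Counts per change class and the percentage each class represents among
#' modified (non-UNCHANGED) genes, rounded to one decimal.
#'
#' @param records data.frame from [match_and_classify()], or a named integer
#'   vector/list of per-class counts (names among SPLIT, FUSION,
#'   INTRON_CHAIN, UNCLASSIFIED, UNCHANGED).
#' @return data.frame with `change_class`, `n`, `pct_of_modified`.
#' @export
summarize_changes <- function(records) {
  classes <- c("UNCHANGED", "SPLIT", "FUSION", "INTRON_CHAIN", "UNCLASSIFIED")
  if (is.data.frame(records)) {
    counts <- table(factor(records$change_class, levels = classes))
    counts <- setNames(as.integer(counts), classes)
  } else {
    counts <- setNames(integer(length(classes)), classes)
    counts[names(records)] <- as.integer(unlist(records))
  }
  modified <- sum(counts[setdiff(classes, "UNCHANGED")])
  pct <- if (modified == 0) {
    message("no modified genes; percentages reported as 0")
    setNames(numeric(length(classes)), classes)
  } else {
    round(100 * counts / modified, 1)
  }
  pct["UNCHANGED"] <- NA_real_
  data.frame(change_class = classes, n = unname(counts),
             pct_of_modified = unname(pct))
}

#' Transcripts-per-gene ratio of an annotation set
#'
#' @param models named list of gene models, or a length-2 numeric vector
#'   `c(n_transcripts, n_genes)`.
#' @return ratio rounded to two decimals.
#' @export
transcripts_per_gene <- function(models) {
  if (is.numeric(models) && length(models) == 2L)
    return(round(models[1] / models[2], 2))
  n_tx <- sum(vapply(models, function(g) length(g$transcripts), 1L))
  round(n_tx / length(models), 2)
}
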