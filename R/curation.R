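#' Curation flag
#'
#' One detected candidate error: its type, the gene models involved, a
#' numeric evidence summary and (where derivable) a proposed replacement.
#'
#' @param flag_type one of `SPLIT_CANDIDATE`, `FUSION_CANDIDATE`,
#'   `INTRON_CHAIN_MISMATCH`, `LOW_COVERAGE_PRESERVED`, `DE_NOVO_CANDIDATE`,
#'   `ISOFORM_CANDIDATE`, `UTR_EXTENSION`.
#' @param gene_ids character vector of involved gene ids (empty for de novo).
#' @param seqid,start,end locus of the flag.
#' @param subtype optional qualifier (e.g. `JUNCTION_SHIFT`).
#' @param evidence named list of numeric/character evidence summaries.
#' @param proposed_fix list of proposed `gene_model`/`transcript` objects
#'   (may be empty).
#' @return object of class `"curation_flag"`.
#' @export
curation_flag <- function(flag_type, gene_ids, seqid, start, end,
                          subtype = NA_character_, evidence = list(),
                          proposed_fix = list()) {
  types <- c("SPLIT_CANDIDATE", "FUSION_CANDIDATE", "INTRON_CHAIN_MISMATCH",
             "LOW_COVERAGE_PRESERVED", "DE_NOVO_CANDIDATE",
             "ISOFORM_CANDIDATE", "UTR_EXTENSION")
  stopifnot(flag_type %in% types)
  structure(list(flag_type = flag_type, gene_ids = as.character(gene_ids),
                 seqid = seqid, start = as.integer(start),
                 end = as.integer(end), subtype = subtype,
                 evidence = evidence, proposed_fix = proposed_fix),
            class = "curation_flag")
}

#' @export
print.curation_flag <- function(x, ...) {
  cat(sprintf("<curation_flag> %s%s %s:%d-%d [%s]\n", x$flag_type,
              if (is.na(x$subtype)) "" else paste0("/", x$subtype),
              x$seqid, x$start, x$end, paste(x$gene_ids, collapse = ",")))
  invisible(x)
}

#' Tabulate curation flags
#' @param flags list of [curation_flag()] objects.
#' @return data.frame, one row per flag.
#' @export
flags_table <- function(flags) {
  if (!length(flags))
    return(data.frame(flag_type = character(), subtype = character(),
                      gene_ids = character(), seqid = character(),
                      start = integer(), end = integer(),
                      evidence = character(), n_proposals = integer()))
  do.call(rbind, lapply(flags, function(f) {
    data.frame(flag_type = f$flag_type, subtype = f$subtype,
               gene_ids = paste(f$gene_ids, collapse = ","),
               seqid = f$seqid, start = f$start, end = f$end,
               evidence = paste(names(f$evidence),
                                vapply(f$evidence, format, ""),
                                sep = "=", collapse = ";"),
               n_proposals = length(f$proposed_fix))
  }))
}

sort_flags <- function(flags) {
  if (length(flags) < 2L) return(flags)
  tab <- flags_table(flags)
  flags[order(tab$seqid, tab$start, tab$flag_type, tab$gene_ids)]
}

primary_tx <- function(g) g$transcripts[[1]]

short_depth <- function(evidence, seqid, from, to) {
  if (from > to) return(numeric())
  evidence$coverage_short[[seqid]][from:to]
}

#' Junctions trusted by the curation rules
#'
#' Short-read junctions with at least `min_junction_reads` supporting reads,
#' plus all long-read junctions.
#' @param evidence an [evidence_bundle()].
#' @param config a [curation_config()].
#' @return junction data.frame.
#' @export
supported_junctions <- function(evidence, config) {
  j <- evidence$junctions
  j[(j$source == "short" & j$read_count >= config$min_junction_reads) |
      j$source == "long", , drop = FALSE]
}

strand_ok <- function(junction_strand, strand) {
  junction_strand == "*" | junction_strand == strand
}

# base-wise coverage test: short depth, junction bridging (spliced reads
# span the gap) and long-read coverage all count
covered_mask <- function(evidence, config, seqid, from, to, strand) {
  if (from > to) return(logical())
  ok <- short_depth(evidence, seqid, from, to) >= config$intergenic_min_depth
  if (!is.null(evidence$coverage_long) &&
      !is.null(evidence$coverage_long[[seqid]]))
    ok <- ok | evidence$coverage_long[[seqid]][from:to] >= 1
  sj <- supported_junctions(evidence, config)
  sj <- sj[sj$seqid == seqid & strand_ok(sj$strand, strand) &
             sj$start <= to & sj$end >= from, , drop = FALSE]
  for (i in seq_len(nrow(sj))) {
    a <- max(from, sj$start[i]); b <- min(to, sj$end[i])
    ok[(a - from + 1L):(b - from + 1L)] <- TRUE
  }
  ok
}

#' Mean exonic short-read depth of a gene
#' @param g a `gene_model`.
#' @param evidence an [evidence_bundle()].
#' @return numeric scalar.
#' @export
mean_exonic_depth <- function(g, evidence) {
  ex <- gene_exon_union(g)
  v <- unlist(lapply(seq_len(nrow(ex)), function(i)
    short_depth(evidence, g$seqid, ex$start[i], ex$end[i])))
  mean(v)
}

#' Preserve gene models below the coverage threshold
#'
#' Genes whose mean exonic short-read depth is strictly below
#' `min_edit_coverage` are flagged `LOW_COVERAGE_PRESERVED`; the other
#' detectors skip these genes so the models pass through untouched.
#'
#' @param models list of gene models.
#' @param evidence an [evidence_bundle()].
#' @param config a [curation_config()].
#' @return list of [curation_flag()] objects.
#' @export
preserve_low_coverage <- function(models, evidence, config = curation_config()) {
  flags <- list()
  for (g in models) {
    d <- mean_exonic_depth(g, evidence)
    if (d < config$min_edit_coverage) {
      sp <- gene_span(g)
      flags[[length(flags) + 1L]] <- curation_flag(
        "LOW_COVERAGE_PRESERVED", g$gene_id, g$seqid, sp[1], sp[2],
        evidence = list(mean_exonic_depth = round(d, 3)))
    }
  }
  sort_flags(flags)
}

#' Detect gene-split candidates
#'
#' For each same-strand adjacent pair of models whose intergenic region has
#' uninterrupted RNA coverage (per-base depth, spliced-read bridging or
#' long-read coverage; fraction of covered bases at least
#' `intergenic_cov_fraction`), the two models are merged (bridging the gap as
#' an intron when a supported junction spans it, as an exon otherwise), the
#' coding sequence is re-predicted, and the pair is flagged only when the
#' merged ORF spans both original coding regions; otherwise the merger is
#' discarded, mirroring the reverted-merger rule.
#'
#' @inheritParams preserve_low_coverage
#' @param genome named contig sequences.
#' @param exclude gene ids skipped (e.g. low-coverage preserved genes).
#' @return list of [curation_flag()] objects.
#' @export
detect_split_candidates <- function(models, evidence, genome,
                                    config = curation_config(),
                                    exclude = character()) {
  tab <- models_table(models)
  flags <- list()
  for (sq in unique(tab$seqid)) {
    for (st in c("+", "-")) {
      sub <- tab[tab$seqid == sq & tab$strand == st, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      if (nrow(sub) < 2L) next
      for (i in seq_len(nrow(sub) - 1L)) {
        a <- models[[sub$gene_id[i]]]; b <- models[[sub$gene_id[i + 1L]]]
        if (a$gene_id %in% exclude || b$gene_id %in% exclude) next
        ga <- gene_span(a); gb <- gene_span(b)
        if (gb[1] <= ga[2]) next  # overlapping models are not a split pair
        from <- ga[2] + 1L; to <- gb[1] - 1L
        frac <- if (from > to) 1 else
          mean(covered_mask(evidence, config, sq, from, to, st))
        if (frac < config$intergenic_cov_fraction) next
        merged <- merge_pair(a, b, evidence, config, genome)
        if (is.null(merged)) next
        sp <- gene_span(merged)
        flags[[length(flags) + 1L]] <- curation_flag(
          "SPLIT_CANDIDATE", c(a$gene_id, b$gene_id), sq, sp[1], sp[2],
          evidence = list(intergenic_covered_fraction = round(frac, 3),
                          intergenic_len = max(0L, to - from + 1L)),
          proposed_fix = list(merged))
      }
    }
  }
  sort_flags(flags)
}

# merge two adjacent same-strand models; NULL when the merged ORF does not
# span both original coding regions (merger "reverted")
merge_pair <- function(a, b, evidence, config, genome) {
  ta <- primary_tx(a); tb <- primary_tx(b)
  exA <- ta$exons; exB <- tb$exons
  gap_from <- max(exA$end) + 1L; gap_to <- min(exB$start) - 1L
  sj <- supported_junctions(evidence, config)
  sj <- sj[sj$seqid == a$seqid & strand_ok(sj$strand, a$strand) &
             sj$start > exA$start[nrow(exA)] & sj$end < exB$end[1] &
             sj$end >= gap_from - 1L & sj$start <= gap_to + 1L, , drop = FALSE]
  if (nrow(sj)) {
    j <- sj[order(-sj$read_count, sj$start), ][1, ]
    exA$end[nrow(exA)] <- j$start - 1L
    exB$start[1] <- j$end + 1L
    ex <- rbind(exA, exB)
  } else {
    ex <- rbind(exA[-nrow(exA), , drop = FALSE],
                data.frame(start = exA$start[nrow(exA)], end = exB$end[1]),
                exB[-1L, , drop = FALSE])
  }
  mid <- paste0(a$gene_id, "+", b$gene_id)
  tx <- tryCatch(transcript(paste0(mid, ".t1"), a$seqid, a$strand, ex),
                 error = function(e) NULL)
  if (is.null(tx)) return(NULL)
  tx <- reorf_transcript(tx, genome, mode = "longest")
  if (is.null(tx)) return(NULL)
  orf_span <- c(min(tx$cds$start), max(tx$cds$end))
  for (side in list(cds_span(ta), cds_span(tb))) {
    if (is.null(side)) next
    if (orf_span[1] > side[2] || orf_span[2] < side[1]) return(NULL)
  }
  gene_model(mid, list(tx))
}

#' Detect gene-fusion candidates
#'
#' Flags an annotated intron when (a) its interior contains a run of
#' sub-threshold short-read depth of at least `coverage_gap_min_len` bp and
#' (b) an in-frame stop codon (continuing the upstream coding frame) occurs
#' at a covered position inside the intron — the signature of a spurious
#' intron bypassing the true stop of an upstream gene. The proposal cuts the
#' model in two at the coverage gap and re-predicts each coding sequence.
#'
#' @inheritParams detect_split_candidates
#' @return list of [curation_flag()] objects.
#' @export
detect_fusion_candidates <- function(models, evidence, genome,
                                     config = curation_config(),
                                     exclude = character()) {
  flags <- list()
  for (g in models) {
    if (g$gene_id %in% exclude) next
    tx <- primary_tx(g)
    if (nrow(tx$exons) < 2L) next
    intr <- tx_introns(tx)
    ord <- if (g$strand == "-") rev(seq_len(nrow(intr))) else
      seq_len(nrow(intr))
    ex53 <- exons_5to3(tx)
    cum_len <- cumsum(ex53$end - ex53$start + 1L)
    for (k in seq_along(ord)) {
      i <- ord[k]
      d <- short_depth(evidence, g$seqid, intr$start[i], intr$end[i])
      runs <- rle(d < config$intergenic_min_depth)
      lens <- runs$lengths[runs$values]
      if (!length(lens) || max(lens) < config$coverage_gap_min_len) next
      stop_hit <- scan_inframe_stop(g, intr$start[i], intr$end[i],
                                    cum_len[k] %% 3L, genome, evidence)
      if (is.null(stop_hit)) next
      # largest sub-threshold run = the putative intergenic gap
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      big <- which(runs$values & runs$lengths == max(lens))[1]
      gap <- c(intr$start[i] + starts[big] - 1L,
               intr$start[i] + ends[big] - 1L)
      fix <- cut_fusion(g, i, gap, genome)
      flags[[length(flags) + 1L]] <- curation_flag(
        "FUSION_CANDIDATE", g$gene_id, g$seqid, intr$start[i], intr$end[i],
        evidence = list(gap_len = max(lens), stop_pos = stop_hit,
                        gap_start = gap[1], gap_end = gap[2]),
        proposed_fix = fix)
      break
    }
  }
  sort_flags(flags)
}

# in-frame covered stop codon inside an intron; `phase` = spliced CDS length
# upstream of the intron mod 3. Returns genomic position of the stop or NULL.
scan_inframe_stop <- function(g, int_start, int_end, phase, genome, evidence) {
  contig <- genome_contig(genome, g$seqid)
  lead <- (3L - phase) %% 3L  # bases completing the codon split by the donor
  if (g$strand == "+") {
    p <- int_start + lead
    while (p + 2L <= int_end) {
      cod <- substr(contig, p, p + 2L)
      if (cod %in% c("TAA", "TAG", "TGA") &&
          all(short_depth(evidence, g$seqid, p, p + 2L) >= 1))
        return(p)
      p <- p + 3L
    }
  } else {
    p <- int_end - lead
    while (p - 2L >= int_start) {
      cod <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(contig, p - 2L, p))))
      if (cod %in% c("TAA", "TAG", "TGA") &&
          all(short_depth(evidence, g$seqid, p - 2L, p) >= 1))
        return(p - 2L)
      p <- p - 3L
    }
  }
  NULL
}

# split a fused model in two at the coverage gap inside intron i (genomic
# index); covered intron flanks are treated as exonic tails
cut_fusion <- function(g, i, gap, genome) {
  tx <- primary_tx(g)
  ex <- tx$exons
  left <- ex[seq_len(i), , drop = FALSE]
  right <- ex[(i + 1L):nrow(ex), , drop = FALSE]
  if (gap[1] - 1L >= left$end[nrow(left)] + 1L)
    left$end[nrow(left)] <- gap[1] - 1L
  if (gap[2] + 1L <= right$start[1] - 1L)
    right$start[1] <- gap[2] + 1L
  out <- list()
  for (part in list(list(ex = left, tag = "a"), list(ex = right, tag = "b"))) {
    id <- paste0(g$gene_id, ".", part$tag)
    tx2 <- tryCatch(transcript(paste0(id, ".t1"), g$seqid, g$strand,
                               part$ex),
                    error = function(e) NULL)
    if (is.null(tx2)) next
    tx2 <- reorf_transcript(tx2, genome, mode = "longest")
    if (!is.null(tx2)) out[[length(out) + 1L]] <- gene_model(id, list(tx2))
  }
  out
}

#' Detect intron-chain mismatches
#'
#' Compares each model's intron chain to the evidence consensus. With a
#' long-read chain at the locus the chain is authoritative over the region it
#' covers; otherwise trusted short-read junctions drive an evidence-positive
#' comparison: a supported junction absent from the annotation is a missing
#' exon boundary, an unsupported annotated intron overlapping a supported
#' junction with different endpoints is a junction shift, and an unsupported
#' annotated intron whose interior is covered by reads is an extra intron
#' (retained in RNA). When the long-read chain contradicts a well-supported
#' short-read junction, both alternative transcripts are kept in the
#' proposal.
#'
#' @inheritParams preserve_low_coverage
#' @param exclude gene ids skipped (low-coverage genes, fusion candidates).
#' @param genome optional named contig sequences; when supplied, proposed
#'   transcripts get re-predicted coding sequences.
#' @return list of [curation_flag()] objects.
#' @export
detect_intron_chain_mismatch <- function(models, evidence,
                                         config = curation_config(),
                                         exclude = character(),
                                         genome = NULL) {
  sj_all <- supported_junctions(evidence, config)
  flags <- list()
  for (g in models) {
    if (g$gene_id %in% exclude) next
    tx <- primary_tx(g)
    sp <- gene_span(g)
    ann <- tx_introns(tx)
    sj <- sj_all[sj_all$seqid == g$seqid & strand_ok(sj_all$strand, g$strand) &
                   sj_all$start >= sp[1] & sj_all$end <= sp[2], , drop = FALSE]
    chain <- locus_long_chain(evidence, g)
    res <- if (!is.null(chain))
      compare_to_long_chain(g, ann, chain, evidence, config)
    else compare_to_short_junctions(g, ann, sj, evidence, config)
    if (is.null(res)) next
    prop <- build_corrected_transcript(g, res$new_introns, genome)
    fixes <- if (is.null(prop)) list() else list(prop)
    if (isTRUE(res$conflict) && !is.null(prop)) fixes <- c(fixes, list(tx))
    flags[[length(flags) + 1L]] <- curation_flag(
      "INTRON_CHAIN_MISMATCH", g$gene_id, g$seqid, sp[1], sp[2],
      subtype = res$subtype,
      evidence = c(res$evidence,
                   list(conflict = isTRUE(res$conflict))),
      proposed_fix = fixes)
  }
  sort_flags(flags)
}

locus_long_chain <- function(evidence, g) {
  sp <- gene_span(g)
  best <- NULL; best_ov <- 0
  for (ch in evidence$long_chains) {
    if (ch$seqid != g$seqid || ch$strand != g$strand) next
    cs <- gene_span(ch)
    ov <- min(sp[2], cs[2]) - max(sp[1], cs[1]) + 1L
    if (ov > best_ov) { best <- ch; best_ov <- ov }
  }
  best
}

intr_key <- function(df) if (!nrow(df)) character() else
  paste(df$start, df$end, sep = "-")

compare_to_long_chain <- function(g, ann, chain, evidence, config) {
  cs <- gene_span(chain); sp <- gene_span(g)
  lo <- max(cs[1], sp[1]); hi <- min(cs[2], sp[2])
  ann_c <- ann[ann$start >= lo & ann$end <= hi, , drop = FALSE]
  cons <- tx_introns(chain)
  cons <- cons[cons$start >= lo & cons$end <= hi, , drop = FALSE]
  if (setequal(intr_key(ann_c), intr_key(cons))) return(NULL)
  n_shift <- 0L; n_missing <- 0L; n_extra <- 0L
  conflict <- FALSE
  drop <- logical(nrow(ann))
  sj_short <- evidence$junctions
  sj_short <- sj_short[sj_short$source == "short" &
                         sj_short$read_count >= config$min_junction_reads &
                         sj_short$seqid == g$seqid, , drop = FALSE]
  for (i in which(ann$start >= lo & ann$end <= hi)) {
    key <- paste(ann$start[i], ann$end[i], sep = "-")
    if (key %in% intr_key(cons)) next
    # a trusted short-read junction contradicting the long-read chain:
    # correct toward the chain but keep the original as an alternative
    if (key %in% intr_key(sj_short)) conflict <- TRUE
    ov <- any(cons$start <= ann$end[i] & cons$end >= ann$start[i])
    if (ov) n_shift <- n_shift + 1L else n_extra <- n_extra + 1L
    drop[i] <- TRUE
  }
  add <- cons[!(intr_key(cons) %in% intr_key(ann)), , drop = FALSE]
  # an added consensus intron overlapping a kept annotated intron is the
  # other half of a shift, not a separate missing exon
  repl <- vapply(seq_len(nrow(add)), function(k)
    any(ann$start[drop] <= add$end[k] & ann$end[drop] >= add$start[k]),
    logical(1))
  n_missing <- sum(!repl)
  new_introns <- rbind(ann[!drop, , drop = FALSE], add)
  list(subtype = pick_subtype(n_shift, n_missing, n_extra),
       new_introns = new_introns, conflict = conflict,
       evidence = list(n_shift = n_shift, n_missing = n_missing,
                       n_extra = n_extra, source = "long"))
}

compare_to_short_junctions <- function(g, ann, sj, evidence, config) {
  keys_sj <- intr_key(sj)
  n_shift <- 0L; n_missing <- 0L; n_extra <- 0L
  drop <- logical(nrow(ann))
  add <- sj[0, c("start", "end"), drop = FALSE]
  for (i in seq_len(nrow(ann))) {
    key <- paste(ann$start[i], ann$end[i], sep = "-")
    if (key %in% keys_sj) next
    ov <- which(sj$start <= ann$end[i] & sj$end >= ann$start[i])
    if (length(ov)) {
      j <- ov[order(-sj$read_count[ov])][1]
      n_shift <- n_shift + 1L
      drop[i] <- TRUE
      add <- rbind(add, sj[j, c("start", "end"), drop = FALSE])
    } else {
      interior <- mean(short_depth(evidence, g$seqid, ann$start[i],
                                   ann$end[i]))
      if (interior >= 1) {
        n_extra <- n_extra + 1L
        drop[i] <- TRUE
      }
    }
  }
  kept <- ann[!drop, , drop = FALSE]
  for (k in seq_len(nrow(sj))) {
    key <- paste(sj$start[k], sj$end[k], sep = "-")
    if (key %in% intr_key(ann) || key %in% intr_key(add)) next
    if (any(kept$start <= sj$end[k] & kept$end >= sj$start[k])) next
    if (any(add$start <= sj$end[k] & add$end >= sj$start[k])) next
    n_missing <- n_missing + 1L
    add <- rbind(add, sj[k, c("start", "end"), drop = FALSE])
  }
  if (n_shift + n_missing + n_extra == 0L) return(NULL)
  list(subtype = pick_subtype(n_shift, n_missing, n_extra),
       new_introns = rbind(kept, add), conflict = FALSE,
       evidence = list(n_shift = n_shift, n_missing = n_missing,
                       n_extra = n_extra, source = "short"))
}

pick_subtype <- function(n_shift, n_missing, n_extra) {
  if (n_shift > 0) "JUNCTION_SHIFT"
  else if (n_missing > 0) "MISSING_EXON"
  else "EXTRA_EXON"
}

# rebuild exons of the primary transcript from a corrected intron set,
# preserving the annotated gene termini
build_corrected_transcript <- function(g, introns, genome = NULL) {
  sp <- gene_span(g)
  introns <- introns[order(introns$start), , drop = FALSE]
  if (nrow(introns) > 1L &&
      any(introns$start[-1L] <= introns$end[-nrow(introns)]))
    return(NULL)
  if (nrow(introns) &&
      (introns$start[1] <= sp[1] || introns$end[nrow(introns)] >= sp[2]))
    return(NULL)
  starts <- c(sp[1], introns$end + 1L)
  ends <- c(introns$start - 1L, sp[2])
  tx <- tryCatch(
    transcript(paste0(g$gene_id, ".t1c"), g$seqid, g$strand,
               data.frame(start = starts, end = ends), gene_id = g$gene_id),
    error = function(e) NULL)
  if (is.null(tx)) return(NULL)
  if (!is.null(genome)) {
    tx2 <- reorf_transcript(tx, genome, mode = "longest")
    if (!is.null(tx2)) tx <- tx2
  }
  tx
}
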