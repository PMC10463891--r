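#' Detect de novo gene candidates
#'
#' Assembles candidate transcripts from chains of trusted junctions linked by
#' covered exonic blocks in regions overlapping no existing model, and keeps
#' a candidate only when a complete ORF is found (on the junction strand, or
#' the better of both strands for strandless chains). Single-exon covered
#' blobs are never candidates (multi-exon requirement).
#'
#' @inheritParams detect_split_candidates
#' @return list of [curation_flag()] objects.
#' @export
detect_de_novo <- function(models, evidence, genome,
                           config = curation_config()) {
  tab <- models_table(models)
  sj <- supported_junctions(evidence, config)
  if (nrow(sj)) {
    inside <- vapply(seq_len(nrow(sj)), function(i) {
      any(tab$seqid == sj$seqid[i] & tab$start <= sj$end[i] &
            tab$end >= sj$start[i])
    }, logical(1))
    sj <- sj[!inside, , drop = FALSE]
  }
  flags <- list()
  for (sq in unique(sj$seqid)) {
    js <- sj[sj$seqid == sq, , drop = FALSE]
    js <- js[order(js$start), , drop = FALSE]
    js <- js[!duplicated(paste(js$start, js$end)), , drop = FALSE]
    used <- logical(nrow(js))
    for (i in seq_len(nrow(js))) {
      if (used[i]) next
      chain <- i
      repeat {
        last <- chain[length(chain)]
        nxt <- which(!used & js$start > js$end[last] &
                       seq_len(nrow(js)) > last)
        nxt <- nxt[vapply(nxt, function(k) {
          gap <- short_depth(evidence, sq, js$end[last] + 1L,
                             js$start[k] - 1L)
          length(gap) > 0 && all(gap >= config$intergenic_min_depth)
        }, logical(1))]
        if (!length(nxt)) break
        chain <- c(chain, nxt[1])
        used[nxt[1]] <- TRUE
      }
      used[chain] <- TRUE
      cand <- assemble_denovo(js[chain, , drop = FALSE], sq, evidence,
                              genome, config, tab)
      if (!is.null(cand)) flags[[length(flags) + 1L]] <- cand
    }
  }
  sort_flags(flags)
}

assemble_denovo <- function(js, sq, evidence, genome, config, tab) {
  left <- js$start[1] - 1L
  cov <- evidence$coverage_short[[sq]]
  while (left > 1L && cov[left - 1L] >= config$intergenic_min_depth &&
         js$start[1] - left < 5000L) left <- left - 1L
  right <- js$end[nrow(js)] + 1L
  while (right < length(cov) &&
         cov[right + 1L] >= config$intergenic_min_depth &&
         right - js$end[nrow(js)] < 5000L) right <- right + 1L
  if (left >= js$start[1] || right <= js$end[nrow(js)]) return(NULL)
  starts <- c(left, js$end + 1L)
  ends <- c(js$start - 1L, right)
  if (any(tab$seqid == sq & tab$start <= right & tab$end >= left))
    return(NULL)
  strands <- unique(js$strand[js$strand != "*"])
  try_strands <- if (length(strands) == 1L) strands else c("+", "-")
  best <- NULL
  for (st in try_strands) {
    tx <- tryCatch(transcript("denovo.t1", sq, st,
                              data.frame(start = starts, end = ends)),
                   error = function(e) NULL)
    if (is.null(tx)) next
    tx <- reorf_transcript(tx, genome, mode = "longest")
    if (is.null(tx)) next
    len <- sum(tx$cds$end - tx$cds$start + 1L)
    if (is.null(best) || len > best$len) best <- list(tx = tx, len = len)
  }
  if (is.null(best)) return(NULL)  # no ORF in any frame/strand: discarded
  gid <- sprintf("denovo_%s_%d", sq, left)
  tx <- best$tx
  tx$transcript_id <- paste0(gid, ".t1")
  g <- gene_model(gid, list(tx))
  curation_flag("DE_NOVO_CANDIDATE", character(), sq, left, right,
                evidence = list(n_junctions = nrow(js),
                                orf_nt = best$len),
                proposed_fix = list(g))
}

#' Enumerate evidence-supported isoform candidates for one gene
#'
#' Trusted junctions at the locus are clustered (junctions that overlap or
#' share an endpoint form alternative groups); one-choice-per-cluster
#' permutations are enumerated (capped at `max_isoform_clusters` clusters,
#' with a warning on truncation) and kept when the re-predicted ORF runs from
#' the first to the last exon. Structurally unique long-read chains become
#' candidates as well (kept even when their ORF is shorter), and annotated
#' isoforms with no junction or long-read support are reported for removal.
#'
#' @param model a single `gene_model`.
#' @inheritParams detect_split_candidates
#' @return list of [curation_flag()] objects.
#' @export
enumerate_isoforms <- function(model, evidence, genome,
                               config = curation_config()) {
  g <- model
  sp <- gene_span(g)
  sj <- supported_junctions(evidence, config)
  sj <- sj[sj$seqid == g$seqid & strand_ok(sj$strand, g$strand) &
             sj$start >= sp[1] & sj$end <= sp[2], , drop = FALSE]
  sj <- sj[!duplicated(paste(sj$start, sj$end)), , drop = FALSE]
  ann_chains <- lapply(g$transcripts, function(tx) intr_key(tx_introns(tx)))
  flags <- list()

  if (nrow(sj)) {
    adj <- outer(seq_len(nrow(sj)), seq_len(nrow(sj)), function(i, j)
      sj$start[i] <= sj$end[j] & sj$end[i] >= sj$start[j])
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))$membership
    clusters <- split(seq_len(nrow(sj)), comp)
    ord <- order(vapply(clusters, function(ix) min(sj$start[ix]), 1L))
    clusters <- clusters[ord]
    if (length(clusters) > config$max_isoform_clusters) {
      warning("gene ", g$gene_id, ": ", length(clusters),
              " junction clusters; truncating to ",
              config$max_isoform_clusters)
      clusters <- clusters[seq_len(config$max_isoform_clusters)]
    }
    combos <- expand.grid(lapply(clusters, identity),
                          KEEP.OUT.ATTRS = FALSE)
    if (nrow(combos) > 256L) {
      warning("gene ", g$gene_id, ": isoform permutations truncated to 256")
      combos <- combos[seq_len(256L), , drop = FALSE]
    }
    seen <- character()
    for (r in seq_len(nrow(combos))) {
      ix <- as.integer(combos[r, ])
      introns <- sj[ix, c("start", "end"), drop = FALSE]
      introns <- introns[order(introns$start), , drop = FALSE]
      if (nrow(introns) > 1L &&
          any(introns$start[-1L] <= introns$end[-nrow(introns)] + 1L)) next
      key <- paste(intr_key(introns), collapse = ";")
      if (key %in% seen) next
      seen <- c(seen, key)
      if (setequal(intr_key(introns), ann_chains[[1]]) ||
          key %in% vapply(ann_chains, paste, "", collapse = ";")) next
      tx <- build_corrected_transcript(g, introns, genome)
      if (is.null(tx) || !nrow(tx$cds)) next
      # continuous ORF from the first to the last exon
      first_ex <- if (g$strand == "+") tx$exons[1, ] else
        tx$exons[nrow(tx$exons), ]
      last_ex <- if (g$strand == "+") tx$exons[nrow(tx$exons), ] else
        tx$exons[1, ]
      if (!cds_touches(tx, first_ex) || !cds_touches(tx, last_ex)) next
      tx$transcript_id <- sprintf("%s.iso%d", g$gene_id, length(flags) + 1L)
      flags[[length(flags) + 1L]] <- curation_flag(
        "ISOFORM_CANDIDATE", g$gene_id, g$seqid, sp[1], sp[2],
        subtype = "PERMUTATION",
        evidence = list(n_introns = nrow(introns)),
        proposed_fix = list(tx))
    }
  }

  # structurally unique long-read chains
  for (ch in evidence$long_chains) {
    if (ch$seqid != g$seqid || ch$strand != g$strand) next
    cs <- gene_span(ch)
    if (cs[1] > sp[2] || cs[2] < sp[1]) next
    key <- intr_key(tx_introns(ch))
    known <- any(vapply(ann_chains, function(k) setequal(k, key), logical(1)))
    if (known) next
    tx <- ch
    tx$gene_id <- g$gene_id
    tx2 <- if (!is.null(genome)) reorf_transcript(tx, genome) else NULL
    if (!is.null(tx2)) tx <- tx2
    flags[[length(flags) + 1L]] <- curation_flag(
      "ISOFORM_CANDIDATE", g$gene_id, g$seqid, cs[1], cs[2],
      subtype = "LONG_READ",
      evidence = list(chain_id = ch$transcript_id),
      proposed_fix = list(tx))
  }

  # annotated isoforms with zero support
  all_j <- evidence$junctions
  all_j <- all_j[all_j$seqid == g$seqid &
                   strand_ok(all_j$strand, g$strand), , drop = FALSE]
  long_keys <- lapply(evidence$long_chains, function(ch)
    if (ch$seqid == g$seqid && ch$strand == g$strand)
      intr_key(tx_introns(ch)) else NULL)
  for (tx in g$transcripts) {
    keys <- intr_key(tx_introns(tx))
    if (!length(keys)) next
    short_support <- any(keys %in% intr_key(all_j))
    long_support <- any(vapply(long_keys, function(k)
      !is.null(k) && setequal(k, keys), logical(1)))
    if (!short_support && !long_support) {
      tsp <- gene_span(tx)
      flags[[length(flags) + 1L]] <- curation_flag(
        "ISOFORM_CANDIDATE", g$gene_id, g$seqid, tsp[1], tsp[2],
        subtype = "REMOVE_UNSUPPORTED",
        evidence = list(transcript_id = tx$transcript_id))
    }
  }
  sort_flags(flags)
}

cds_touches <- function(tx, exon_row) {
  any(tx$cds$start <= exon_row$end & tx$cds$end >= exon_row$start)
}

#' Propose untranslated-region extensions
#'
#' For each gene end, the proposed UTR terminus is the long-read transcript
#' terminus when a long chain covers the coding sequence, otherwise the end
#' of the contiguous covered block overlapping the terminal exon. Extensions
#' are suppressed toward a same-strand neighbor whose intergenic region has
#' continuous short-read coverage, and isoforms with identical terminal
#' exons receive identical proposed boundaries.
#'
#' @param model a single `gene_model`.
#' @param neighbors the full model list (used to find same-strand
#'   neighbors).
#' @inheritParams preserve_low_coverage
#' @return list of [curation_flag()] objects.
#' @export
extend_utrs <- function(model, evidence, neighbors,
                        config = curation_config()) {
  g <- model
  tab <- models_table(neighbors)
  tab <- tab[tab$seqid == g$seqid & tab$strand == g$strand &
               tab$gene_id != g$gene_id, , drop = FALSE]
  cov <- evidence$coverage_short[[g$seqid]]
  flags <- list()
  proposals <- list()
  for (tx in g$transcripts) {
    if (!nrow(tx$cds)) next
    sp <- gene_span(tx)
    for (side in c("left", "right")) {
      is_five <- (side == "left") == (g$strand == "+")
      label <- if (is_five) "5prime" else "3prime"
      if (side == "left") {
        nb <- tab[tab$end < sp[1], , drop = FALSE]
        nb_edge <- if (nrow(nb)) max(nb$end) else NA_integer_
      } else {
        nb <- tab[tab$start > sp[2], , drop = FALSE]
        nb_edge <- if (nrow(nb)) min(nb$start) else NA_integer_
      }
      if (!is.na(nb_edge)) {
        gap <- if (side == "left") c(nb_edge + 1L, sp[1] - 1L) else
          c(sp[2] + 1L, nb_edge - 1L)
        if (gap[1] > gap[2] ||
            all(cov[gap[1]:gap[2]] >= config$intergenic_min_depth))
          next  # close same-strand neighbor with continuous coverage
      }
      chain <- long_chain_covering_cds(evidence, tx, g)
      if (!is.null(chain)) {
        csp <- gene_span(chain)
        prop <- if (side == "left") csp[1] else csp[2]
      } else {
        prop <- if (side == "left") {
          p <- sp[1]
          while (p > 1L && cov[p - 1L] >= config$intergenic_min_depth &&
                 sp[1] - p < 5000L) p <- p - 1L
          p
        } else {
          p <- sp[2]
          while (p < length(cov) &&
                 cov[p + 1L] >= config$intergenic_min_depth &&
                 p - sp[2] < 5000L) p <- p + 1L
          p
        }
      }
      extended <- if (side == "left") prop < sp[1] else prop > sp[2]
      if (!extended) next
      term_ex <- if (side == "left") tx$exons[1, ] else
        tx$exons[nrow(tx$exons), ]
      proposals[[length(proposals) + 1L]] <- list(
        tx = tx$transcript_id, side = side, label = label,
        terminal_exon = paste(term_ex$start, term_ex$end, sep = "-"),
        proposed = prop, current = if (side == "left") sp[1] else sp[2])
    }
  }
  if (!length(proposals)) return(list())
  # equalize boundaries for isoforms sharing the identical terminal exon
  keys <- vapply(proposals, function(p) paste(p$side, p$terminal_exon), "")
  for (k in unique(keys)) {
    ix <- which(keys == k)
    side <- proposals[[ix[1]]]$side
    best <- if (side == "left") min(vapply(proposals[ix], `[[`, 1L, "proposed"))
    else max(vapply(proposals[ix], `[[`, 1L, "proposed"))
    for (i in ix) proposals[[i]]$proposed <- best
  }
  sp <- gene_span(g)
  for (p in proposals) {
    flags[[length(flags) + 1L]] <- curation_flag(
      "UTR_EXTENSION", g$gene_id, g$seqid,
      min(p$proposed, p$current), max(p$proposed, p$current),
      subtype = toupper(p$label),
      evidence = list(transcript_id = p$tx, proposed_terminus = p$proposed,
                      current_terminus = p$current))
  }
  sort_flags(flags)
}

long_chain_covering_cds <- function(evidence, tx, g) {
  cs <- cds_span(tx)
  if (is.null(cs)) return(NULL)
  for (ch in evidence$long_chains) {
    if (ch$seqid != g$seqid || ch$strand != g$strand) next
    csp <- gene_span(ch)
    if (csp[1] <= cs[1] && csp[2] >= cs[2]) return(ch)
  }
  NULL
}
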