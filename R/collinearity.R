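#' Detect duplication events from whole-genome alignment coordinates
#'
#' Finds truth-genome segments represented at two or more distinct locations
#' in the audited genome: alignment records are clustered by reciprocal
#' overlap of their truth-genome intervals (single linkage at
#' `dup_min_reciprocal_overlap`), and every cluster with two or more
#' distinct audited intervals becomes a duplication event. With
#' `merge = TRUE`, fragmented collinear records (same contigs and
#' orientation, gaps of at most `coords_merge_gap` bp on both genomes) are
#' merged first — useful for raw aligner output broken by small unaligned
#' gaps. Output is invariant to input record order.
#'
#' @param alignments data.frame from [read_coords()] (ref = truth genome,
#'   qry = audited genome).
#' @param config a [curation_config()].
#' @param merge pre-merge fragmented collinear records (default FALSE).
#' @return data.frame of events: `event_id`, `ref_seqid`, `ref_start`,
#'   `ref_end`, `n_segments`, `same_chromosome`, `any_inverted`, plus a
#'   `segments` list-column of the audited intervals.
#' @export
find_duplications <- function(alignments, config = curation_config(),
                              merge = FALSE) {
  al <- alignments
  if (!nrow(al))
    return(empty_events())
  al <- al[order(al$ref_seqid, al$ref_start, al$ref_end, al$qry_seqid,
                 al$qry_start), , drop = FALSE]
  rownames(al) <- NULL
  if (merge) al <- merge_collinear(al, config$coords_merge_gap)
  events <- list()
  for (sq in sort(unique(al$ref_seqid))) {
    sub <- al[al$ref_seqid == sq, , drop = FALSE]
    n <- nrow(sub)
    if (!n) next
    # single-linkage clustering by reciprocal overlap of ref intervals
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (reciprocal_overlap(sub$ref_start[i], sub$ref_end[i],
                             sub$ref_start[j], sub$ref_end[j]) >=
          config$dup_min_reciprocal_overlap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
    roots <- vapply(seq_len(n), find, 1L)
    for (cl in split(seq_len(n), roots)) {
      segs <- unique(sub[cl, c("qry_seqid", "qry_start", "qry_end",
                               "inverted"), drop = FALSE])
      if (nrow(segs) < 2L) next
      events[[length(events) + 1L]] <- data.frame(
        ref_seqid = sq,
        ref_start = min(sub$ref_start[cl]),
        ref_end = max(sub$ref_end[cl]),
        n_segments = nrow(segs),
        same_chromosome = length(unique(segs$qry_seqid)) == 1L,
        any_inverted = any(segs$inverted),
        segments = I(list(segs[order(segs$qry_seqid, segs$qry_start), ,
                               drop = FALSE])))
    }
  }
  if (!length(events)) return(empty_events())
  out <- do.call(rbind, events)
  out <- out[order(out$ref_seqid, out$ref_start, out$ref_end), , drop = FALSE]
  out$event_id <- sprintf("ev%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("event_id", "ref_seqid", "ref_start", "ref_end", "n_segments",
          "same_chromosome", "any_inverted", "segments")]
}

empty_events <- function() {
  data.frame(event_id = character(), ref_seqid = character(),
             ref_start = integer(), ref_end = integer(),
             n_segments = integer(), same_chromosome = logical(),
             any_inverted = logical(),
             segments = I(list()))
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2) + 1L
  if (ov <= 0) return(0)
  min(ov / (e1 - s1 + 1L), ov / (e2 - s2 + 1L))
}

# merge collinear adjacent records: same contigs and orientation, gaps on
# both genomes <= max_gap, consistent order
merge_collinear <- function(al, max_gap) {
  key <- paste(al$ref_seqid, al$qry_seqid, al$inverted)
  out <- list()
  for (k in unique(key)) {
    sub <- al[key == k, , drop = FALSE]
    sub <- sub[order(sub$ref_start), , drop = FALSE]
    cur <- sub[1, , drop = FALSE]
    for (i in seq_len(nrow(sub) - 1L) + 1L) {
      nxt <- sub[i, , drop = FALSE]
      rgap <- nxt$ref_start - cur$ref_end - 1L
      qgap <- if (cur$inverted) cur$qry_start - nxt$qry_end - 1L else
        nxt$qry_start - cur$qry_end - 1L
      if (rgap >= 0 && rgap <= max_gap && qgap >= 0 && qgap <= max_gap) {
        cur$ref_end <- nxt$ref_end
        cur$qry_start <- min(cur$qry_start, nxt$qry_start)
        cur$qry_end <- max(cur$qry_end, nxt$qry_end)
        cur$pct_identity <- (cur$pct_identity + nxt$pct_identity) / 2
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- nxt
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  res <- do.call(rbind, out)
  res[order(res$ref_seqid, res$ref_start, res$ref_end, res$qry_seqid,
            res$qry_start), , drop = FALSE]
}

#' Genes affected by duplication events
#'
#' A gene is affected when its CDS span overlaps any audited segment of any
#' event by at least 1 bp; the global count de-duplicates genes across
#' events.
#'
#' @param events data.frame from [find_duplications()].
#' @param models gene models on the audited genome.
#' @return list with `per_event` (event_id -> gene id vector) and
#'   `n_affected` (global deduplicated count) and `affected` (sorted ids).
#' @export
affected_genes <- function(events, models) {
  spans <- lapply(models, function(g) {
    cs <- cds_span(g)
    if (is.null(cs)) cs <- gene_span(g)
    data.frame(seqid = g$seqid, start = cs[1], end = cs[2],
               gene_id = g$gene_id)
  })
  spans <- do.call(rbind, spans)
  if (nrow(events)) {
    segs <- do.call(rbind, lapply(events$segments, identity))
    missing <- setdiff(unique(segs$qry_seqid), unique(spans$seqid))
    if (length(missing))
      stop("event contigs absent from annotation: ",
           paste(missing, collapse = ", "))
  }
  per_event <- list()
  for (i in seq_len(nrow(events))) {
    segs <- events$segments[[i]]
    hit <- unique(unlist(lapply(seq_len(nrow(segs)), function(k) {
      spans$gene_id[spans$seqid == segs$qry_seqid[k] &
                      spans$start <= segs$qry_end[k] &
                      spans$end >= segs$qry_start[k]]
    })))
    per_event[[events$event_id[i]]] <- sort(hit)
  }
  affected <- sort(unique(unlist(per_event)))
  list(per_event = per_event, affected = affected,
       n_affected = length(affected))
}

#' Tabular report of duplication events
#'
#' @param events data.frame from [find_duplications()].
#' @return list with `events` (one row per event, audited coordinates
#'   comma-joined) and `segments` (one row per audited segment, dot-plot
#'   ready, orientation `+`/`-`).
#' @export
event_report <- function(events) {
  if (!nrow(events)) {
    return(list(
      events = data.frame(event_id = character(), ref_seqid = character(),
                          ref_start = integer(), ref_end = integer(),
                          n_segments = integer(),
                          same_chromosome = logical(),
                          any_inverted = logical()),
      segments = data.frame(event_id = character(), ref_seqid = character(),
                            ref_start = integer(), ref_end = integer(),
                            qry_seqid = character(), qry_start = integer(),
                            qry_end = integer(), orientation = character())))
  }
  segs <- do.call(rbind, lapply(seq_len(nrow(events)), function(i) {
    s <- events$segments[[i]]
    data.frame(event_id = events$event_id[i],
               ref_seqid = events$ref_seqid[i],
               ref_start = events$ref_start[i],
               ref_end = events$ref_end[i],
               qry_seqid = s$qry_seqid, qry_start = s$qry_start,
               qry_end = s$qry_end,
               orientation = ifelse(s$inverted, "-", "+"))
  }))
  list(events = events[, setdiff(names(events), "segments")],
       segments = segs)
}
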