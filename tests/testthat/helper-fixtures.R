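# shared in-code fixtures for the test suite

# two-exon plus-strand gene on a hand-built contig
toy_gene <- function(gene_id = "gA", seqid = "chrT", start = 101L) {
  ex <- data.frame(start = c(start, start + 150L),
                   end = c(start + 89L, start + 239L))
  gene_model(gene_id, list(
    transcript(paste0(gene_id, ".t1"), seqid, "+", ex, ex)))
}

# deterministic noise-free simulated dataset shared across tests
fixture_dataset <- local({
  cache <- list()
  function(noise = "none", seed = 42L) {
    key <- paste(noise, seed)
    if (is.null(cache[[key]]))
      cache[[key]] <<- simulate_dataset(
        simulation_recipe(noise = noise, rng_seed = seed))
    cache[[key]]
  }
})

# independent brute-force ORF oracle: scan every ATG in every frame with
# plain substring arithmetic, pair with its first in-frame stop
oracle_orfs <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  res <- list()
  for (i in seq_len(max(0L, n - 5L))) {
    if (substr(s, i, i + 2L) != "ATG") next
    p <- i
    repeat {
      p <- p + 3L
      if (p + 2L > n) break
      cod <- substr(s, p, p + 2L)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        res[[length(res) + 1L]] <- c(start = i - 1L, end = p + 2L)
        break
      }
    }
  }
  if (!length(res))
    return(data.frame(start = integer(), end = integer(),
                      length_nt = integer()))
  df <- as.data.frame(do.call(rbind, res))
  df$length_nt <- df$end - df$start
  df[order(df$start, df$end), , drop = FALSE]
}

oracle_select <- function(s, exon_offsets, mode) {
  orfs <- oracle_orfs(s)
  if (!nrow(orfs)) return(NULL)
  orfs$n_exons <- vapply(seq_len(nrow(orfs)), function(i)
    sum(exon_offsets$offset < orfs$end[i] &
          exon_offsets$offset + exon_offsets$length > orfs$start[i]),
    integer(1))
  o <- if (mode == "longest") order(-orfs$length_nt, orfs$start) else
    order(-orfs$n_exons, -orfs$length_nt, orfs$start)
  orfs[o[1], c("start", "end", "length_nt")]
}

# quadratic brute-force duplication oracle: single-linkage closure over all
# record pairs by reciprocal ref-interval overlap, then clusters with >= 2
# distinct audited segments
oracle_duplications <- function(al, min_ro = 0.5) {
  if (!nrow(al)) return(list())
  al <- al[order(al$ref_seqid, al$ref_start, al$ref_end, al$qry_seqid,
                 al$qry_start), , drop = FALSE]
  n <- nrow(al)
  ro <- function(i, j) {
    if (al$ref_seqid[i] != al$ref_seqid[j]) return(0)
    ov <- min(al$ref_end[i], al$ref_end[j]) -
      max(al$ref_start[i], al$ref_start[j]) + 1L
    if (ov <= 0) return(0)
    min(ov / (al$ref_end[i] - al$ref_start[i] + 1L),
        ov / (al$ref_end[j] - al$ref_start[j] + 1L))
  }
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      if (ro(i, j) >= min_ro && grp[i] != grp[j]) {
        grp[grp == grp[j]] <- grp[i]
        changed <- TRUE
      }
    if (!changed) break
  }
  out <- list()
  for (g in sort(unique(grp))) {
    ix <- which(grp == g)
    segs <- unique(al[ix, c("qry_seqid", "qry_start", "qry_end", "inverted")])
    if (nrow(segs) < 2L) next
    out[[length(out) + 1L]] <- list(
      ref_seqid = al$ref_seqid[ix[1]],
      ref_start = min(al$ref_start[ix]), ref_end = max(al$ref_end[ix]),
      segs = segs[order(segs$qry_seqid, segs$qry_start), , drop = FALSE])
  }
  ord <- order(vapply(out, `[[`, "", "ref_seqid"),
               vapply(out, `[[`, 1L, "ref_start"))
  out[ord]
}

# exhaustive best-of-best RBH oracle
oracle_rbh <- function(forward, backward) {
  best <- function(h, q) {
    hh <- h[h$query == q, , drop = FALSE]
    if (!nrow(hh)) return(NA_character_)
    hh <- hh[order(hh$evalue, -hh$bitscore, hh$subject), , drop = FALSE]
    hh$subject[1]
  }
  pairs <- list()
  for (q in sort(unique(forward$query))) {
    s <- best(forward, q)
    if (is.na(s)) next
    if (identical(best(backward, s), q))
      pairs[[length(pairs) + 1L]] <- data.frame(query = q, subject = s)
  }
  if (!length(pairs)) return(data.frame(query = character(),
                                        subject = character()))
  out <- do.call(rbind, pairs)
  rownames(out) <- NULL
  out
}
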