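#' Simulate a misassembled genome copy with planted duplications
#'
#' Copies `n_duplications` gene-containing segments of the input genome back
#' into it (tandem or distant, optionally reverse-complemented), lifts the
#' gene models onto the new coordinates (duplicated genes gain a `.dup`
#' copy), and emits the exact by-construction alignment-coordinate table of
#' misassembled-vs-original genome. Identity alignments are broken at
#' duplication source boundaries and insertion points, the way an aligner
#' breaks collinear runs at structural discontinuities, so each duplicated
#' truth segment owns alignment records at two or more query locations.
#'
#' @param genome named contig sequences (the truth genome).
#' @param true_models true gene models.
#' @param recipe a [simulation_recipe()] (`n_duplications`,
#'   `inversion_probability`, `inter_contig_probability`, `rng_seed`).
#' @return list with `genome` (misassembled), `models` (lifted, incl. dup
#'   copies), `coords` (data.frame as from [read_coords()]; ref = truth,
#'   qry = misassembled) and `truth` (per-duplication table).
#' @export
simulate_misassembly <- function(genome, true_models, recipe) {
  rng_scope(recipe$rng_seed + 3L, {
    margin <- 50L
    tab <- models_table(true_models)
    n_dup <- recipe$n_duplications
    if (n_dup > nrow(tab)) stop("more duplications than genes")
    dup_rows <- if (n_dup > 0)
      sort(sample(seq_len(nrow(tab)), n_dup)) else integer()
    segs <- lapply(dup_rows, function(i) {
      list(seqid = tab$seqid[i],
           start = max(1L, tab$start[i] - margin),
           end = min(nchar(genome[[tab$seqid[i]]]), tab$end[i] + margin),
           gene_id = tab$gene_id[i],
           inverted = stats::runif(1) < recipe$inversion_probability)
    })
    # choose insertion points in intergenic space, away from segments
    occupied <- lapply(names(genome), function(sq) {
      rbind(do.call(rbind, lapply(segs[vapply(segs, `[[`, "", "seqid") == sq],
                                  function(s) c(s$start, s$end))),
            as.matrix(tab[tab$seqid == sq, c("start", "end")]))
    })
    names(occupied) <- names(genome)
    chosen_points <- list()
    free_point <- function(sq) {
      occ <- occupied[[sq]]
      prev <- chosen_points[[sq]]
      for (tries in 1:200) {
        p <- sample(100L:(nchar(genome[[sq]]) - 100L), 1)
        clash <- (!is.null(occ) && nrow(occ) &&
                    any(p >= occ[, 1] - 60L & p <= occ[, 2] + 60L)) ||
          (!is.null(prev) && any(abs(p - prev) < 60L))
        if (!clash) return(p)
      }
      stop("could not place duplication insertion point on ", sq)
    }
    inserts <- lapply(segs, function(s) {
      tandem <- stats::runif(1) < 0.5
      dest <- s$seqid
      if (stats::runif(1) < recipe$inter_contig_probability &&
          length(genome) > 1L)
        dest <- sample(setdiff(names(genome), s$seqid), 1)
      point <- if (tandem && dest == s$seqid) s$end else free_point(dest)
      chosen_points[[dest]] <<- c(chosen_points[[dest]], point)
      c(s, list(dest = dest, point = point))
    })
    # per destination contig: sorted insertion points -> block layout
    new_genome <- genome
    lift_tables <- list()  # per contig: data.frame(point, added)
    for (sq in names(genome)) {
      ins <- inserts[vapply(inserts, `[[`, "", "dest") == sq]
      if (!length(ins)) {
        lift_tables[[sq]] <- data.frame(point = integer(), added = integer())
        next
      }
      o <- order(vapply(ins, `[[`, 1L, "point"))
      ins <- ins[o]
      pieces <- character(); pos <- 1L
      added <- 0L; lift <- list()
      for (k in seq_along(ins)) {
        s <- ins[[k]]
        dup_seq <- substr(genome[[s$seqid]], s$start, s$end)
        if (s$inverted)
          dup_seq <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(dup_seq)))
        pieces <- c(pieces, substr(genome[[sq]], pos, s$point), dup_seq)
        pos <- s$point + 1L
        lift[[k]] <- data.frame(point = s$point,
                                added = nchar(dup_seq),
                                seg_seqid = s$seqid, seg_start = s$start,
                                seg_end = s$end, inverted = s$inverted,
                                gene_id = s$gene_id)
        added <- added + nchar(dup_seq)
      }
      pieces <- c(pieces, substr(genome[[sq]], pos, nchar(genome[[sq]])))
      new_genome[[sq]] <- paste(pieces, collapse = "")
      lift_tables[[sq]] <- do.call(rbind, lift)
    }
    lift_pos <- function(sq, x) {
      lt <- lift_tables[[sq]]
      x + if (nrow(lt)) sum(lt$added[lt$point < x]) else 0L
    }
    # lifted original models
    out_models <- lapply(true_models, function(g) {
      g$transcripts <- lapply(g$transcripts, function(tx) {
        tx$exons$start <- vapply(tx$exons$start, function(x)
          lift_pos(g$seqid, x), 1L)
        tx$exons$end <- vapply(tx$exons$end, function(x)
          lift_pos(g$seqid, x), 1L)
        if (nrow(tx$cds)) {
          tx$cds$start <- vapply(tx$cds$start, function(x)
            lift_pos(g$seqid, x), 1L)
          tx$cds$end <- vapply(tx$cds$end, function(x)
            lift_pos(g$seqid, x), 1L)
        }
        tx
      })
      g
    })
    # duplicate gene copies inside inserted blocks + coords + truth
    coords <- list(); dup_truth <- list()
    for (sq in names(genome)) {
      lt <- lift_tables[[sq]]
      # identity pieces: cut at insertion points and at source boundaries
      cuts <- sort(unique(c(0L,
        if (nrow(lt)) lt$point,
        unlist(lapply(inserts, function(s)
          if (s$seqid == sq) c(s$start - 1L, s$end) else integer())),
        nchar(genome[[sq]]))))
      cuts <- cuts[cuts >= 0L & cuts <= nchar(genome[[sq]])]
      for (k in seq_len(length(cuts) - 1L)) {
        a <- cuts[k] + 1L; b <- cuts[k + 1L]
        if (a > b) next
        coords[[length(coords) + 1L]] <- data.frame(
          ref_seqid = sq, ref_start = a, ref_end = b,
          qry_seqid = sq, qry_start = lift_pos(sq, a),
          qry_end = lift_pos(sq, a) + (b - a),
          inverted = FALSE, pct_identity = 100)
      }
    }
    for (k in seq_along(inserts)) {
      s <- inserts[[k]]
      lt <- lift_tables[[s$dest]]
      row <- which(lt$point == s$point & lt$seg_start == s$start &
                     lt$seg_seqid == s$seqid)[1]
      blk_start <- s$point + sum(lt$added[lt$point < s$point]) + 1L
      L <- s$end - s$start + 1L
      coords[[length(coords) + 1L]] <- data.frame(
        ref_seqid = s$seqid, ref_start = s$start, ref_end = s$end,
        qry_seqid = s$dest, qry_start = blk_start,
        qry_end = blk_start + L - 1L,
        inverted = s$inverted, pct_identity = 100)
      g <- true_models[[s$gene_id]]
      tx <- g$transcripts[[1]]
      ex <- tx$exons
      if (s$inverted) {
        new_ex <- data.frame(start = blk_start + (s$end - ex$end),
                             end = blk_start + (s$end - ex$start))
        strand <- if (g$strand == "+") "-" else "+"
      } else {
        new_ex <- data.frame(start = blk_start + (ex$start - s$start),
                             end = blk_start + (ex$end - s$start))
        strand <- g$strand
      }
      did <- paste0(s$gene_id, ".dup")
      out_models[[did]] <- gene_model(did, list(
        transcript(paste0(did, ".t1"), s$dest, strand, new_ex, new_ex)))
      dup_truth[[k]] <- data.frame(
        dup_id = sprintf("dup%02d", k), src_seqid = s$seqid,
        src_start = s$start, src_end = s$end, dest_seqid = s$dest,
        dest_start = blk_start, inverted = s$inverted,
        gene_id = s$gene_id)
    }
    coords <- do.call(rbind, coords)
    rownames(coords) <- NULL
    list(genome = new_genome, models = sort_models(out_models),
         coords = coords,
         truth = if (length(dup_truth)) do.call(rbind, dup_truth) else
           data.frame())
  })
}

#' Simulate three-strain ortholog protein-length tables with BLAST hits
#'
#' Builds protein length sets for two audited strains (default labels
#' `AF16`, `QX1410`) against a reference strain (`N2`), perturbs lengths per
#' strain, emits self-consistent forward/backward BLAST tabular hits (true
#' orthologs are reciprocal best by construction; each query also receives a
#' lower-scoring decoy hit) and the true orthogroup table. A configurable
#' subset of genes is duplicated in the first strain to create 2:1:1 copy
#' patterns.
#'
#' @param n_pairs number of ortholog trios.
#' @param multipliers named list/vector of per-strain length multipliers
#'   (scalar or length `n_pairs`), e.g. `list(AF16 = 1, QX1410 = 1.04)`.
#' @param n_duplicated genes present as two copies in the first strain.
#' @param seed integer seed.
#' @return list with `lengths` (named list of named integer vectors per
#'   strain incl. `N2`), `forward`/`backward` (QX1410 vs N2 BLAST tables),
#'   `orthogroups` (data.frame as from [read_orthogroups_tsv()]) and `truth`
#'   (per-trio table).
#' @export
simulate_ortholog_lengths <- function(n_pairs,
                                      multipliers = list(AF16 = 1,
                                                         QX1410 = 1),
                                      n_duplicated = 0L, seed = 1L) {
  rng_scope(seed, {
    strains <- names(multipliers)
    stopifnot(length(strains) == 2L, n_duplicated <= n_pairs)
    base <- pmax(50L, as.integer(round(stats::rlnorm(n_pairs, log(400), 0.4))))
    ids_n2 <- sprintf("n2_%04d", seq_len(n_pairs))
    lengths <- list(N2 = setNames(base, ids_n2))
    for (s in strains) {
      m <- multipliers[[s]]
      ids <- sprintf("%s_%04d", tolower(s), seq_len(n_pairs))
      lengths[[s]] <- setNames(as.integer(round(base * m)), ids)
    }
    qx <- strains[2]; af <- strains[1]
    qids <- names(lengths[[qx]])
    mk_hits <- function(query_ids, subject_ids, qlen) {
      true_hit <- data.frame(query = query_ids, subject = subject_ids,
                             pident = 95, length = qlen,
                             evalue = 1e-150, bitscore = round(1.9 * qlen, 1))
      decoy_sub <- subject_ids[(seq_along(subject_ids) %% length(subject_ids)) + 1L]
      decoy <- data.frame(query = query_ids, subject = decoy_sub,
                          pident = 40, length = pmax(30L, qlen %/% 3L),
                          evalue = 1e-30,
                          bitscore = round(0.5 * qlen, 1))
      rbind(true_hit, decoy)
    }
    forward <- mk_hits(qids, ids_n2, lengths[[qx]])
    backward <- mk_hits(ids_n2, qids, lengths$N2)
    dup_idx <- if (n_duplicated > 0) sort(sample(n_pairs, n_duplicated)) else
      integer()
    og <- data.frame(orthogroup = sprintf("OG%07d", seq_len(n_pairs)))
    af_members <- lapply(seq_len(n_pairs), function(i) {
      m <- names(lengths[[af]])[i]
      if (i %in% dup_idx) c(m, paste0(m, "b")) else m
    })
    og[[af]] <- I(af_members)
    og[[qx]] <- I(as.list(qids))
    og[["N2"]] <- I(as.list(ids_n2))
    for (s in c(af, qx, "N2")) og[[paste0("n_", s)]] <- lengths(og[[s]])
    truth <- data.frame(n2 = ids_n2, qx = qids,
                        af = names(lengths[[af]]),
                        len_n2 = base,
                        len_qx = unname(lengths[[qx]]),
                        duplicated_in_first = seq_len(n_pairs) %in% dup_idx)
    list(lengths = lengths, forward = forward, backward = backward,
         orthogroups = og, truth = truth)
  })
}
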