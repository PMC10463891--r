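#' Simulation recipe
#'
#' Parameters of the synthetic genome/annotation/evidence generator. All
#' outputs are byte-deterministic under `rng_seed`.
#'
#' The defaults emulate the data regime the curation rules target: compact
#' multi-exon genes with canonical GT-AG introns, intergenic spacing of at
#' least 200 bp, log-normal expression with a floor keeping simulated loci
#' above the editing threshold, Poisson read-depth noise with sparse
#' intergenic background, long-read models for the better-expressed half of
#' genes, and 5'-end underrepresentation applied to first-exon coverage.
#'
#' @param n_contigs number of contigs.
#' @param contig_length bp per contig.
#' @param n_genes total genes to place (split evenly across contigs).
#' @param exons_per_gene integer range `c(min, max)`.
#' @param exon_length bp range for exons.
#' @param intron_length bp range for introns.
#' @param intergenic_gap bp range between consecutive genes (min >= 200).
#' @param tpm_meanlog,tpm_sdlog log-normal expression parameters (TPM).
#' @param tpm_floor lower clamp on expression (TPM).
#' @param cov_per_tpm short-read depth per TPM unit.
#' @param noise `"poisson"` (per-base Poisson depth, sparse background) or
#'   `"none"` (exact expected depth, clean background).
#' @param noise_depth Poisson rate of background depth outside exons
#'   (only under `noise = "poisson"`).
#' @param error_rates named list of per-gene probabilities for planting
#'   `split`, `fusion` and `intron_chain` prediction errors.
#' @param drop_rate fraction of genes deleted from the predicted set
#'   (planted de-novo cases).
#' @param fiveprime_dropout fraction of 5'-most exon coverage (and of the
#'   first junction's support) suppressed.
#' @param long_read_fraction fraction of genes (by expression rank) that get
#'   a long-read transcript model.
#' @param long_read_depth depth contributed by long reads over their exons.
#' @param n_duplications segments re-inserted by [simulate_misassembly()].
#' @param inversion_probability probability a planted duplication is
#'   reverse-complemented.
#' @param inter_contig_probability probability a planted duplication is
#'   inserted on a different contig.
#' @param rng_seed integer seed.
#' @return object of class `"simulation_recipe"`.
#' @export
simulation_recipe <- function(n_contigs = 2L,
                              contig_length = 60000L,
                              n_genes = 60L,
                              exons_per_gene = c(2L, 6L),
                              exon_length = c(60L, 240L),
                              intron_length = c(60L, 200L),
                              intergenic_gap = c(200L, 500L),
                              tpm_meanlog = log(40),
                              tpm_sdlog = 0.8,
                              tpm_floor = 8,
                              cov_per_tpm = 1,
                              noise = c("poisson", "none"),
                              noise_depth = 0.02,
                              error_rates = list(split = 0.1, fusion = 0.1,
                                                 intron_chain = 0.2),
                              drop_rate = 0,
                              fiveprime_dropout = 0,
                              long_read_fraction = 0.5,
                              long_read_depth = 5,
                              n_duplications = 4L,
                              inversion_probability = 0.5,
                              inter_contig_probability = 0,
                              rng_seed = 42L) {
  noise <- match.arg(noise)
  probs <- c(unlist(error_rates), drop_rate, fiveprime_dropout,
             inversion_probability, inter_contig_probability,
             long_read_fraction)
  stopifnot(all(probs >= 0), all(probs <= 1),
            all(exons_per_gene >= 1), all(exon_length >= 30),
            all(intron_length >= 4), intergenic_gap[1] >= 200,
            n_genes >= 1, contig_length > 0, n_contigs >= 1)
  structure(as.list(environment()), class = "simulation_recipe")
}

rng_scope <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

rint <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(range[1]:range[2], n, replace = TRUE)
}

NON_STOP_CODONS <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a genome with true gene models
#'
#' Places multi-exon protein-coding genes on random contigs. Every gene has
#' an ATG start, an in-frame stop in its last exon, no internal stop codons,
#' GT-AG introns and at least 200 bp of intergenic separation. CDS segments
#' coincide with exons (coding-only true models); UTR annotation is exercised
#' by the curation rules, not planted here.
#'
#' @param recipe a [simulation_recipe()].
#' @return list with `genome` (named character vector), `models` (true gene
#'   models) and `truth` (per-gene table with expression and planted-error
#'   slots).
#' @export
simulate_genome_and_genes <- function(recipe) {
  stopifnot(inherits(recipe, "simulation_recipe"))
  rng_scope(recipe$rng_seed, {
    n_per <- diff(round(seq(0, recipe$n_genes, length.out = recipe$n_contigs + 1)))
    genome <- character(recipe$n_contigs)
    names(genome) <- paste0("ctg", seq_len(recipe$n_contigs))
    models <- list()
    truth <- list()
    gidx <- 0L
    for (ci in seq_len(recipe$n_contigs)) {
      seqid <- names(genome)[ci]
      cursor <- 0L
      seq_parts <- character()
      for (k in seq_len(n_per[ci])) {
        gidx <- gidx + 1L
        gid <- sprintf("g%04d", gidx)
        gap <- rint(1, recipe$intergenic_gap)
        n_ex <- rint(1, recipe$exons_per_gene)
        ex_len <- rint(n_ex, recipe$exon_length)
        ex_len[n_ex] <- ex_len[n_ex] + (3L - sum(ex_len) %% 3L) %% 3L
        in_len <- if (n_ex > 1) rint(n_ex - 1, recipe$intron_length) else integer()
        strand <- sample(c("+", "-"), 1)
        n_cod <- sum(ex_len) / 3L
        cds <- paste0("ATG",
                      paste(sample(NON_STOP_CODONS, n_cod - 2L, replace = TRUE),
                            collapse = ""),
                      "TAA")
        # cut spliced CDS into exons, thread GT..AG introns between them
        ex_seq <- substring(cds, cumsum(c(1L, ex_len[-n_ex])),
                            cumsum(ex_len))
        introns <- vapply(in_len, function(l)
          paste0("GT", random_dna(l - 4L), "AG"), "")
        block <- paste(c(rbind(c(ex_seq[-n_ex]), introns), ex_seq[n_ex]),
                       collapse = "")
        if (n_ex == 1L) block <- ex_seq
        L <- nchar(block)
        # exon coordinates within the block (plus-orientation layout)
        starts <- integer(n_ex); ends <- integer(n_ex)
        pos <- 1L
        for (i in seq_len(n_ex)) {
          starts[i] <- pos; ends[i] <- pos + ex_len[i] - 1L
          pos <- ends[i] + 1L + if (i < n_ex) in_len[i] else 0L
        }
        if (strand == "-") {
          block <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(block)))
          tmp <- starts
          starts <- L - ends + 1L; ends <- L - tmp + 1L
          o <- order(starts); starts <- starts[o]; ends <- ends[o]
        }
        g_start <- cursor + gap + 1L
        if (g_start + L - 1L > recipe$contig_length - 200L)
          stop("recipe infeasible: genes do not fit contig ", seqid)
        seq_parts <- c(seq_parts, random_dna(gap), block)
        cursor <- g_start + L - 1L
        ex <- data.frame(start = starts + g_start - 1L,
                         end = ends + g_start - 1L)
        tx <- transcript(paste0(gid, ".t1"), seqid, strand, ex, ex, gid)
        models[[gid]] <- gene_model(gid, list(tx))
        truth[[gid]] <- data.frame(gene_id = gid, seqid = seqid,
                                   strand = strand, start = g_start,
                                   end = cursor, n_exons = n_ex,
                                   tpm = NA_real_)
      }
      tail_len <- recipe$contig_length - cursor
      seq_parts <- c(seq_parts, random_dna(tail_len))
      genome[ci] <- paste(seq_parts, collapse = "")
    }
    truth <- do.call(rbind, truth)
    tpm <- pmax(stats::rlnorm(nrow(truth), recipe$tpm_meanlog,
                              recipe$tpm_sdlog), recipe$tpm_floor)
    truth$tpm <- round(tpm, 2)
    truth$error <- "none"
    truth$error_detail <- ""
    truth$predicted_ids <- truth$gene_id
    rownames(truth) <- NULL
    list(genome = genome, models = sort_models(models), truth = truth)
  })
}

#' Plant prediction errors into a true annotation set
#'
#' Applies the three structural error classes seen in automated gene
#' prediction: a *split* emits one true gene as two models broken at an
#' internal intron; a *fusion* merges two adjacent same-strand genes into one
#' model whose bridging intron cuts into the flanking exons (so the upstream
#' gene's stop codon ends up inside the spurious intron); an *intron-chain*
#' error shifts one junction into the intron, removes a junction (retained
#' intron) or adds a spurious one. At most one error is planted per gene;
#' genes drawn under `drop_rate` are deleted outright (de-novo cases).
#'
#' @param true_models list of true gene models from
#'   [simulate_genome_and_genes()].
#' @param recipe the [simulation_recipe()].
#' @param truth the truth table from the simulate step.
#' @return list with `models` (predicted set) and `truth` (updated table).
#' @export
corrupt_annotation <- function(true_models, recipe, truth) {
  rng_scope(recipe$rng_seed + 1L, {
    rates <- recipe$error_rates
    truth$error <- "none"; truth$error_detail <- ""
    truth$predicted_ids <- truth$gene_id
    avail <- truth$gene_id
    pick <- function(ids, rate) {
      n <- round(rate * nrow(truth))
      if (n > length(ids)) n <- length(ids)
      if (n == 0L) character() else sort(sample(ids, n))
    }
    multi <- truth$gene_id[truth$n_exons >= 2L]
    split_ids <- pick(intersect(avail, multi), rates$split %||% 0)
    avail <- setdiff(avail, split_ids)

    # adjacent same-strand pairs among remaining genes
    n_fus <- round((rates$fusion %||% 0) * nrow(truth))
    fusion_pairs <- list()
    if (n_fus > 0) {
      tab <- truth[order(truth$seqid, truth$start), ]
      cand <- list()
      for (i in seq_len(nrow(tab) - 1L)) {
        a <- tab$gene_id[i]; b <- tab$gene_id[i + 1L]
        if (tab$seqid[i] == tab$seqid[i + 1L] &&
            tab$strand[i] == tab$strand[i + 1L] &&
            a %in% avail && b %in% avail)
          cand[[length(cand) + 1L]] <- c(a, b)
      }
      # greedy non-overlapping selection in random order
      ord <- if (length(cand)) sample(seq_along(cand)) else integer()
      used <- character()
      for (i in ord) {
        if (length(fusion_pairs) >= n_fus) break
        p <- cand[[i]]
        if (!any(p %in% used)) {
          fusion_pairs[[length(fusion_pairs) + 1L]] <- p
          used <- c(used, p)
        }
      }
      if (length(fusion_pairs) < n_fus)
        warning("only ", length(fusion_pairs),
                " adjacent same-strand pairs available for fusion planting")
      avail <- setdiff(avail, used)
    }
    ic_ids <- pick(intersect(avail, multi), rates$intron_chain %||% 0)
    avail <- setdiff(avail, ic_ids)
    drop_ids <- pick(avail, recipe$drop_rate)

    out <- list()
    fused_partner <- unlist(lapply(fusion_pairs, `[`, 2))
    fused_lead <- unlist(lapply(fusion_pairs, `[`, 1))
    for (gid in truth$gene_id) {
      g <- true_models[[gid]]
      tx <- g$transcripts[[1]]
      if (gid %in% drop_ids) {
        truth[truth$gene_id == gid, c("error", "predicted_ids")] <-
          c("dropped", "")
      } else if (gid %in% split_ids) {
        n_ex <- nrow(tx$exons)
        at <- sample(seq_len(n_ex - 1L), 1)  # break after exon `at`
        ex1 <- tx$exons[seq_len(at), , drop = FALSE]
        ex2 <- tx$exons[(at + 1L):n_ex, , drop = FALSE]
        id1 <- paste0(gid, ".s1"); id2 <- paste0(gid, ".s2")
        out[[id1]] <- gene_model(id1, list(
          transcript(paste0(id1, ".t1"), g$seqid, g$strand, ex1, ex1)))
        out[[id2]] <- gene_model(id2, list(
          transcript(paste0(id2, ".t1"), g$seqid, g$strand, ex2, ex2)))
        truth[truth$gene_id == gid, c("error", "error_detail", "predicted_ids")] <-
          c("split", sprintf("break_after_exon=%d", at),
            paste(id1, id2, sep = ","))
      } else if (gid %in% fused_lead) {
        partner <- fusion_pairs[[which(fused_lead == gid)]][2]
        g2 <- true_models[[partner]]
        tx2 <- g2$transcripts[[1]]
        exA <- tx$exons; exB <- tx2$exons
        cut <- 30L
        exA$end[nrow(exA)] <- exA$end[nrow(exA)] - cut
        exB$start[1] <- exB$start[1] + cut
        fid <- paste0(gid, "-", partner, ".fused")
        ex <- rbind(exA, exB)
        out[[fid]] <- gene_model(fid, list(
          transcript(paste0(fid, ".t1"), g$seqid, g$strand, ex, ex)))
        detail <- sprintf("partner=%s", partner)
        truth[truth$gene_id %in% c(gid, partner),
              c("error", "error_detail", "predicted_ids")] <-
          list("fusion", detail, fid)
      } else if (gid %in% fused_partner) {
        # handled with its lead gene
      } else if (gid %in% ic_ids) {
        kind <- sample(c("shift", "remove", "add"), 1)
        ex <- tx$exons
        n_ex <- nrow(ex)
        if (kind == "add" && !any(ex$end - ex$start + 1L >= 80L))
          kind <- "shift"
        if (kind == "shift") {
          i <- sample(seq_len(n_ex - 1L), 1)
          ex$end[i] <- ex$end[i] + 6L  # exon extended into the intron
          detail <- sprintf("shift_intron=%d", i)
        } else if (kind == "remove") {
          i <- sample(seq_len(n_ex - 1L), 1)
          ex$end[i] <- ex$end[i + 1L]
          ex <- ex[-(i + 1L), , drop = FALSE]
          detail <- sprintf("removed_intron=%d", i)
        } else {
          wide <- which(ex$end - ex$start + 1L >= 80L)
          i <- if (length(wide) == 1L) wide else sample(wide, 1)
          mid <- ex$start[i] + (ex$end[i] - ex$start[i]) %/% 2L - 10L
          newrow <- data.frame(start = mid + 20L, end = ex$end[i])
          ex$end[i] <- mid - 1L
          ex <- rbind(ex[seq_len(i), , drop = FALSE], newrow,
                      if (i < nrow(ex)) ex[(i + 1L):nrow(ex), , drop = FALSE])
          detail <- sprintf("added_intron_after=%d", i)
        }
        out[[gid]] <- gene_model(gid, list(
          transcript(paste0(gid, ".t1"), g$seqid, g$strand, ex, ex)))
        truth[truth$gene_id == gid, c("error", "error_detail")] <-
          c("intron_chain", detail)
      } else {
        out[[gid]] <- g
      }
    }
    list(models = sort_models(out), truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate RNA evidence consistent with a true annotation
#'
#' Exonic short-read depth follows each gene's expression level (exact under
#' `noise = "none"`, Poisson otherwise); intronic and intergenic depth is zero
#' apart from a sparse Poisson background. Every true intron of an expressed
#' gene yields a junction record with support proportional to expression.
#' The better-expressed `long_read_fraction` of genes contribute full-length
#' long-read transcript models (and a long-read coverage track).
#' `fiveprime_dropout` suppresses first-exon coverage and first-junction
#' support, emulating 5'-underrepresented cDNA libraries.
#'
#' @param genome named contig sequences.
#' @param true_models true gene models.
#' @param recipe the [simulation_recipe()].
#' @param expression named per-gene TPM vector (defaults to the values drawn
#'   by [simulate_genome_and_genes()] when its truth table is passed).
#' @return an [evidence_bundle()].
#' @export
simulate_evidence <- function(genome, true_models, recipe, expression) {
  rng_scope(recipe$rng_seed + 2L, {
    pois <- recipe$noise == "poisson"
    depth_of <- function(lambda, n) {
      if (pois) stats::rpois(n, lambda) else rep(round(lambda), n)
    }
    cov_s <- lapply(genome, function(s) numeric(nchar(s)))
    cov_l <- lapply(genome, function(s) numeric(nchar(s)))
    if (pois && recipe$noise_depth > 0)
      cov_s <- lapply(cov_s, function(v) v + stats::rpois(length(v),
                                                          recipe$noise_depth))
    juncs <- list()
    ord <- names(true_models)
    tpm_rank <- rank(-expression[ord], ties.method = "first")
    has_long <- tpm_rank <= round(recipe$long_read_fraction * length(ord))
    names(has_long) <- ord
    long_chains <- list()
    for (gid in ord) {
      g <- true_models[[gid]]
      tx <- g$transcripts[[1]]
      lambda <- expression[[gid]] * recipe$cov_per_tpm
      ex <- exons_5to3(tx)
      for (i in seq_len(nrow(ex))) {
        lam <- if (i == 1L) lambda * (1 - recipe$fiveprime_dropout) else lambda
        idx <- ex$start[i]:ex$end[i]
        cov_s[[g$seqid]][idx] <- cov_s[[g$seqid]][idx] +
          depth_of(lam, length(idx))
      }
      intr <- tx_introns(tx)
      if (nrow(intr) && lambda > 0) {
        # introns in 5'->3' order for dropout bookkeeping
        iord <- if (tx$strand == "-") rev(seq_len(nrow(intr))) else
          seq_len(nrow(intr))
        for (k in seq_along(iord)) {
          i <- iord[k]
          lam <- if (k == 1L) lambda * (1 - recipe$fiveprime_dropout) else lambda
          cnt <- if (pois) stats::rpois(1, lam) else round(lam)
          if (cnt >= 1)
            juncs[[length(juncs) + 1L]] <- data.frame(
              seqid = g$seqid, start = intr$start[i], end = intr$end[i],
              strand = tx$strand, read_count = as.integer(cnt),
              source = "short")
        }
      }
      if (has_long[[gid]] && expression[[gid]] > 0) {
        lr <- tx
        if (recipe$fiveprime_dropout > 0 && nrow(lr$exons) > 1L &&
            stats::runif(1) < recipe$fiveprime_dropout) {
          drop_i <- if (lr$strand == "+") 1L else nrow(lr$exons)
          lr$exons <- lr$exons[-drop_i, , drop = FALSE]
        }
        lr$transcript_id <- paste0(gid, ".lr1")
        lr$cds <- lr$exons[0, , drop = FALSE]
        long_chains[[length(long_chains) + 1L]] <- lr
        for (i in seq_len(nrow(lr$exons))) {
          idx <- lr$exons$start[i]:lr$exons$end[i]
          cov_l[[g$seqid]][idx] <- cov_l[[g$seqid]][idx] +
            depth_of(recipe$long_read_depth, length(idx))
        }
        intr <- tx_introns(lr)
        for (i in seq_len(nrow(intr)))
          juncs[[length(juncs) + 1L]] <- data.frame(
            seqid = g$seqid, start = intr$start[i], end = intr$end[i],
            strand = lr$strand,
            read_count = max(1L, round(recipe$long_read_depth)),
            source = "long")
      }
    }
    j <- if (length(juncs)) do.call(rbind, juncs) else empty_junctions()
    j <- j[order(j$seqid, j$start, j$end, j$source), , drop = FALSE]
    rownames(j) <- NULL
    evidence_bundle(cov_s, j, coverage_long = cov_l,
                    long_chains = long_chains)
  })
}

#' One-shot synthetic dataset
#'
#' Convenience wrapper running [simulate_genome_and_genes()],
#' [corrupt_annotation()] and [simulate_evidence()] with a shared recipe.
#'
#' @param recipe a [simulation_recipe()].
#' @return list with `genome`, `true_models`, `predicted_models`, `evidence`,
#'   `truth`, `recipe`.
#' @export
simulate_dataset <- function(recipe = simulation_recipe()) {
  sim <- simulate_genome_and_genes(recipe)
  corr <- corrupt_annotation(sim$models, recipe, sim$truth)
  expr <- setNames(corr$truth$tpm, corr$truth$gene_id)
  ev <- simulate_evidence(sim$genome, sim$models, recipe, expr)
  list(genome = sim$genome, true_models = sim$models,
       predicted_models = corr$models, evidence = ev, truth = corr$truth,
       recipe = recipe)
}
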