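#' Reciprocal best hits from forward and backward searches
#'
#' The best hit per query is the minimum e-value, ties broken by maximum
#' bitscore, residual ties by lexicographic subject id; duplicate
#' (query, subject) rows collapse to their best-scoring row. A pair is kept
#' iff each side is the other's best hit, giving at most one reciprocal hit
#' per gene. When an isoform-to-gene map is supplied, isoforms are collapsed
#' to their gene (best-scoring isoform representative) before pairing.
#'
#' @param forward,backward data.frames as from [read_blast_tab()].
#' @param gene_map optional named character vector mapping sequence ids to
#'   gene ids.
#' @return data.frame with `query`, `subject` (one row per reciprocal pair),
#'   sorted by query.
#' @export
reciprocal_best_hits <- function(forward, backward, gene_map = NULL) {
  remap <- function(h) {
    if (is.null(gene_map)) return(h)
    h$query <- ifelse(h$query %in% names(gene_map), gene_map[h$query],
                      h$query)
    h$subject <- ifelse(h$subject %in% names(gene_map), gene_map[h$subject],
                        h$subject)
    h
  }
  best_per_query <- function(h) {
    h <- h[h$query != h$subject | TRUE, , drop = FALSE]
    h <- h[order(h$query, h$evalue, -h$bitscore, h$subject), , drop = FALSE]
    h[!duplicated(h$query), , drop = FALSE]
  }
  fwd <- best_per_query(remap(forward))
  bwd <- best_per_query(remap(backward))
  bwd_best <- setNames(bwd$subject, bwd$query)
  keep <- !is.na(bwd_best[fwd$subject]) &
    bwd_best[fwd$subject] == fwd$query
  keep[is.na(keep)] <- FALSE
  out <- fwd[keep, c("query", "subject"), drop = FALSE]
  out <- out[order(out$query), , drop = FALSE]
  rownames(out) <- NULL
  out
}

LENGTH_BINS <- c("identical", "(0,5]", "(5,10]", "(10,25]", ">25")

#' Bin a percent protein-length difference
#' @param pct_diff numeric vector of percent differences (>= 0).
#' @return factor with levels identical, (0,5], (5,10], (10,25], >25.
#' @export
length_bin <- function(pct_diff) {
  stopifnot(all(pct_diff >= 0))
  out <- character(length(pct_diff))
  out[pct_diff == 0] <- "identical"
  out[pct_diff > 0 & pct_diff <= 5] <- "(0,5]"
  out[pct_diff > 5 & pct_diff <= 10] <- "(5,10]"
  out[pct_diff > 10 & pct_diff <= 25] <- "(10,25]"
  out[pct_diff > 25] <- ">25"
  factor(out, levels = LENGTH_BINS)
}

#' Protein-length accuracy of reciprocal-best-hit pairs
#'
#' Computes, for each pair, the percent protein-length difference relative
#' to the reference (N2-side) ortholog length, and bins it as identical,
#' within 5%, 5-10%, 10-25% or over 25%.
#'
#' @param pairs data.frame with `query`, `subject` (from
#'   [reciprocal_best_hits()]).
#' @param query_lengths,subject_lengths named integer vectors of protein
#'   lengths (aa); the subject side is the reference denominator.
#' @return list with `records` (per-pair data.frame with `len_query`,
#'   `len_ref`, `pct_diff`, `bin`) and `counts` (named per-bin counts).
#' @export
length_accuracy <- function(pairs, query_lengths, subject_lengths) {
  lq <- query_lengths[pairs$query]
  lr <- subject_lengths[pairs$subject]
  if (any(is.na(lq)) || any(is.na(lr)))
    stop("missing protein length for some pair members")
  if (any(lq <= 0) || any(lr <= 0)) stop("zero-length protein")
  pct <- 100 * abs(as.numeric(lq) - as.numeric(lr)) / as.numeric(lr)
  bin <- length_bin(pct)
  records <- data.frame(query = pairs$query, subject = pairs$subject,
                        len_query = as.integer(lq), len_ref = as.integer(lr),
                        pct_diff = pct, bin = bin)
  counts <- table(bin)
  list(records = records,
       counts = setNames(as.integer(counts), names(counts)))
}

#' Classify orthogroup copy patterns across three strains
#'
#' @param orthogroups data.frame from [read_orthogroups_tsv()] (or any
#'   data.frame with `orthogroup` and three `n_<strain>` count columns in
#'   the order first-strain : second-strain : reference).
#' @return list with `patterns` (orthogroup + `copy_pattern` string),
#'   `single_copy` (orthogroup ids with pattern 1:1:1), `two_one_one`
#'   (first strain exactly 2, others 1) and `multi_first` (first strain >= 2,
#'   others 1).
#' @export
classify_orthogroups <- function(orthogroups) {
  ncols <- grep("^n_", names(orthogroups), value = TRUE)
  stopifnot(length(ncols) == 3L)
  counts <- as.matrix(orthogroups[, ncols])
  pattern <- apply(counts, 1, paste, collapse = ":")
  patterns <- data.frame(orthogroup = orthogroups$orthogroup,
                         copy_pattern = pattern)
  list(patterns = patterns,
       single_copy = orthogroups$orthogroup[pattern == "1:1:1"],
       two_one_one = orthogroups$orthogroup[pattern == "2:1:1"],
       multi_first = orthogroups$orthogroup[
         counts[, 1] >= 2 & counts[, 2] == 1 & counts[, 3] == 1])
}

#' Agreement between RBH pairs and single-copy orthogroups
#'
#' For each single-copy orthogroup pair (strain gene, reference gene):
#' *agree* when the gene's RBH partner is the orthogroup partner, *disagree*
#' when an RBH exists but differs, *novel* when the gene has no RBH.
#'
#' @param rbh_pairs data.frame with `query`, `subject`.
#' @param og_pairs data.frame with `query`, `subject` — the single-copy
#'   orthogroup pairings on the same gene universe.
#' @return list with counts and fractions (`agree`, `disagree`, `novel`;
#'   fractions sum to 1).
#' @export
rbh_orthogroup_agreement <- function(rbh_pairs, og_pairs) {
  partner <- setNames(rbh_pairs$subject, rbh_pairs$query)
  status <- vapply(seq_len(nrow(og_pairs)), function(i) {
    p <- partner[og_pairs$query[i]]
    if (is.na(p)) "novel"
    else if (p == og_pairs$subject[i]) "agree"
    else "disagree"
  }, "")
  n <- length(status)
  counts <- c(agree = sum(status == "agree"),
              disagree = sum(status == "disagree"),
              novel = sum(status == "novel"))
  list(counts = counts,
       fractions = if (n > 0) counts / n else counts * NA_real_)
}

#' Fraction of pairs near-identical in protein length
#'
#' Share of records whose percent length difference is at most `threshold`
#' (the concordance statistic used for cross-strain comparisons).
#'
#' @param records per-pair data.frame from [length_accuracy()], or a numeric
#'   vector of percent differences.
#' @param threshold percent difference treated as near-identical (default 5).
#' @return fraction in \[0, 1\].
#' @export
near_identical_fraction <- function(records, threshold = 5) {
  pct <- if (is.data.frame(records)) records$pct_diff else records
  mean(pct <= threshold)
}
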