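#' Run the full curation rule set over an annotation
#'
#' Orchestrates the detectors with the exclusion contract: low-coverage genes
#' are identified first and skipped by every structural detector; fusion
#' candidates are detected before intron-chain comparison and excluded from
#' it (a fused model's chain necessarily mismatches the two underlying
#' genes, and would otherwise be double-flagged). Flags come back in a
#' stable order (contig, start, type).
#'
#' @param models predicted gene models (named list).
#' @param evidence an [evidence_bundle()].
#' @param genome named contig sequences.
#' @param config a [curation_config()].
#' @param stages subset of
#'   `c("low_coverage","fusion","split","intron_chain","de_novo","isoform","utr")`.
#' @return list of [curation_flag()] objects.
#' @export
curate <- function(models, evidence, genome, config = curation_config(),
                   stages = c("low_coverage", "fusion", "split",
                              "intron_chain", "de_novo", "isoform", "utr")) {
  models <- sort_models(models)
  flags <- list()
  low_ids <- character()
  if ("low_coverage" %in% stages) {
    low <- preserve_low_coverage(models, evidence, config)
    low_ids <- unlist(lapply(low, `[[`, "gene_ids"))
    flags <- c(flags, low)
  }
  fusion_ids <- character()
  if ("fusion" %in% stages) {
    fus <- detect_fusion_candidates(models, evidence, genome, config,
                                    exclude = low_ids)
    fusion_ids <- unlist(lapply(fus, `[[`, "gene_ids"))
    flags <- c(flags, fus)
  }
  if ("split" %in% stages)
    flags <- c(flags, detect_split_candidates(models, evidence, genome,
                                              config, exclude = low_ids))
  if ("intron_chain" %in% stages)
    flags <- c(flags, detect_intron_chain_mismatch(
      models, evidence, config, exclude = c(low_ids, fusion_ids),
      genome = genome))
  if ("de_novo" %in% stages)
    flags <- c(flags, detect_de_novo(models, evidence, genome, config))
  if ("isoform" %in% stages) {
    skip <- c(low_ids, fusion_ids)
    for (g in models)
      if (!g$gene_id %in% skip)
        flags <- c(flags, enumerate_isoforms(g, evidence, genome, config))
  }
  if ("utr" %in% stages) {
    for (g in models)
      if (!g$gene_id %in% low_ids)
        flags <- c(flags, extend_utrs(g, evidence, models, config))
  }
  sort_flags(flags)
}

#' Apply accepted curation flags to an annotation set
#'
#' Produces the curated model list: split candidates replace their two parts
#' with the merged model, fusion candidates replace the fused model with its
#' two cut genes, intron-chain mismatches replace the primary transcript
#' with the corrected one, de novo candidates are added, isoform candidates
#' are added (or, for removal recommendations, dropped), and UTR extensions
#' move the terminal exon boundary. Flags touching already-consumed genes
#' are skipped.
#'
#' @param models named list of gene models.
#' @param flags list of [curation_flag()] objects (typically from
#'   [curate()]).
#' @return curated named list of gene models, canonically sorted.
#' @export
apply_flags <- function(models, flags) {
  out <- models
  consumed <- character()
  for (f in flags) {
    if (any(f$gene_ids %in% consumed)) next
    if (f$flag_type == "SPLIT_CANDIDATE" && length(f$proposed_fix)) {
      out[f$gene_ids] <- NULL
      m <- f$proposed_fix[[1]]
      out[[m$gene_id]] <- m
      consumed <- c(consumed, f$gene_ids)
    } else if (f$flag_type == "FUSION_CANDIDATE" && length(f$proposed_fix)) {
      out[f$gene_ids] <- NULL
      for (m in f$proposed_fix) out[[m$gene_id]] <- m
      consumed <- c(consumed, f$gene_ids)
    } else if (f$flag_type == "INTRON_CHAIN_MISMATCH" &&
               length(f$proposed_fix)) {
      g <- out[[f$gene_ids[1]]]
      if (is.null(g)) next
      tx <- f$proposed_fix[[1]]
      tx$transcript_id <- primary_tx(g)$transcript_id
      g$transcripts[[1]] <- tx
      out[[g$gene_id]] <- g
    } else if (f$flag_type == "DE_NOVO_CANDIDATE" && length(f$proposed_fix)) {
      m <- f$proposed_fix[[1]]
      out[[m$gene_id]] <- m
    } else if (f$flag_type == "ISOFORM_CANDIDATE") {
      g <- out[[f$gene_ids[1]]]
      if (is.null(g)) next
      if (identical(f$subtype, "REMOVE_UNSUPPORTED")) {
        tid <- f$evidence$transcript_id
        if (length(g$transcripts) > 1L && tid %in% names(g$transcripts)) {
          g$transcripts[[tid]] <- NULL
          out[[g$gene_id]] <- g
        }
      } else if (length(f$proposed_fix)) {
        tx <- f$proposed_fix[[1]]
        g$transcripts[[tx$transcript_id]] <- tx
        out[[g$gene_id]] <- gene_model(g$gene_id, g$transcripts)
      }
    } else if (f$flag_type == "UTR_EXTENSION") {
      g <- out[[f$gene_ids[1]]]
      if (is.null(g)) next
      tid <- f$evidence$transcript_id
      if (!tid %in% names(g$transcripts)) next
      tx <- g$transcripts[[tid]]
      prop <- f$evidence$proposed_terminus
      if (prop < tx$exons$start[1]) tx$exons$start[1] <- prop
      if (prop > tx$exons$end[nrow(tx$exons)])
        tx$exons$end[nrow(tx$exons)] <- prop
      g$transcripts[[tid]] <- tx
      out[[g$gene_id]] <- g
    }
  }
  sort_models(out)
}

#' Score recovery of planted errors
#'
#' Matches structural flags (split/fusion/intron-chain) against the planted
#' truth of a simulated dataset and returns sensitivity and precision.
#'
#' @param flags list of [curation_flag()] objects.
#' @param truth truth table from [corrupt_annotation()].
#' @return list with `sensitivity`, `precision`, `tp`, `fn`, `fp` and the
#'   per-gene `detail` table.
#' @export
flag_recovery_stats <- function(flags, truth) {
  structural <- flags[vapply(flags, function(f)
    f$flag_type %in% c("SPLIT_CANDIDATE", "FUSION_CANDIDATE",
                       "INTRON_CHAIN_MISMATCH"), logical(1))]
  key_of_flag <- function(f) {
    type <- switch(f$flag_type, SPLIT_CANDIDATE = "split",
                   FUSION_CANDIDATE = "fusion",
                   INTRON_CHAIN_MISMATCH = "intron_chain")
    paste(type, paste(sort(f$gene_ids), collapse = ","))
  }
  flag_keys <- vapply(structural, key_of_flag, "")
  planted <- truth[truth$error %in% c("split", "fusion", "intron_chain"), ,
                   drop = FALSE]
  planted <- planted[!duplicated(planted$predicted_ids), , drop = FALSE]
  want <- vapply(seq_len(nrow(planted)), function(i) {
    ids <- strsplit(planted$predicted_ids[i], ",")[[1]]
    paste(planted$error[i], paste(sort(ids), collapse = ","))
  }, "")
  tp <- sum(want %in% flag_keys)
  fn <- sum(!want %in% flag_keys)
  fp <- sum(!flag_keys %in% want)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       tp = tp, fn = fn, fp = fp,
       detail = data.frame(expected = want, found = want %in% flag_keys))
}
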