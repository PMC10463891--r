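#' Build a combined summary report from stage outputs
#'
#' Accepts whatever stages were run and summarizes them: gene/transcript
#' totals and transcripts-per-gene per annotation set, flag counts by type,
#' protein-length accuracy bin counts, change-class percentages, and
#' duplication subtotals (intra- vs inter-chromosomal). Missing stages are
#' marked absent rather than failing.
#'
#' @param stage_outputs named list; recognized entries are `annotations`
#'   (named list of model lists), `flags` (list of curation flags),
#'   `changes` (records from [match_and_classify()]), `length_bins` (counts
#'   from [length_accuracy()]), `events` (from [find_duplications()]).
#' @return named list of data.frames (one table per present section).
#' @export
build_report <- function(stage_outputs) {
  stopifnot(length(stage_outputs) >= 1L)
  out <- list()
  if (!is.null(stage_outputs[["annotations"]])) {
    out$annotation_summary <- do.call(rbind, lapply(
      names(stage_outputs[["annotations"]]), function(nm) {
        models <- stage_outputs[["annotations"]][[nm]]
        n_tx <- sum(vapply(models, function(g) length(g$transcripts), 1L))
        data.frame(set = nm, n_genes = length(models),
                   n_transcripts = n_tx,
                   transcripts_per_gene = transcripts_per_gene(
                     c(n_tx, length(models))))
      }))
  }
  if (!is.null(stage_outputs[["flags"]])) {
    tab <- flags_table(stage_outputs[["flags"]])
    counts <- table(tab$flag_type)
    out$flag_summary <- data.frame(flag_type = names(counts),
                                   n = as.integer(counts))
  }
  if (!is.null(stage_outputs[["changes"]]))
    out$change_summary <- summarize_changes(stage_outputs[["changes"]])
  if (!is.null(stage_outputs[["length_bins"]]))
    out$length_accuracy <- data.frame(
      bin = names(stage_outputs[["length_bins"]]),
      n = as.integer(stage_outputs[["length_bins"]]))
  if (!is.null(stage_outputs[["events"]])) {
    ev <- stage_outputs[["events"]]
    out$duplication_summary <- data.frame(
      subset = c("all", "intra_chromosomal", "inter_chromosomal",
                 "with_inversion"),
      n_events = c(nrow(ev), sum(ev$same_chromosome),
                   sum(!ev$same_chromosome), sum(ev$any_inverted)))
  }
  absent <- setdiff(c("annotations", "flags", "changes", "length_bins",
                      "events"), names(stage_outputs))
  if (length(absent))
    out$absent_sections <- data.frame(section = absent, status = "absent")
  out
}

#' Write a run manifest
#'
#' Records the subcommand, configuration snapshot, input paths with MD5
#' checksums, seed and package version alongside every output directory.
#'
#' @param dir output directory.
#' @param subcommand name of the stage.
#' @param inputs named character vector of input paths.
#' @param config a [curation_config()] (or any list).
#' @param seed integer seed used.
#' @return path to the manifest, invisibly.
#' @export
write_manifest <- function(dir, subcommand, inputs = character(),
                           config = list(), seed = NA_integer_) {
  manifest <- list(
    subcommand = subcommand,
    config = unclass(config),
    inputs = lapply(inputs, function(p)
      list(path = p,
           md5 = if (file.exists(p) && !dir.exists(p))
             unname(tools::md5sum(p)) else NA)),
    seed = seed,
    tool_version = as.character(utils::packageVersion("annocurate")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
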