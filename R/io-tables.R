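#' Read BLAST tabular (outfmt 6) hits
#'
#' Standard 12-column tab-separated BLAST output. Rows with a different
#' column count raise an error naming the line.
#'
#' @param path outfmt-6 TSV file.
#' @return data.frame with `query`, `subject`, `pident`, `length`, `evalue`,
#'   `bitscore` (numeric columns parsed as numeric).
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(query = character(), subject = character(),
                      pident = numeric(), length = integer(),
                      evalue = numeric(), bitscore = numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(fields)
  if (any(nc != 12L))
    stop("malformed BLAST outfmt-6 line ", which(nc != 12L)[1],
         ": expected 12 columns, got ", nc[nc != 12L][1])
  m <- do.call(rbind, fields)
  data.frame(query = m[, 1], subject = m[, 2],
             pident = as.numeric(m[, 3]), length = as.integer(m[, 4]),
             evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]))
}

#' Write BLAST outfmt-6 rows
#' @param hits data.frame as from [read_blast_tab()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  lines <- sprintf("%s\t%s\t%.3f\t%d\t0\t0\t1\t%d\t1\t%d\t%.3g\t%.1f",
                   hits$query, hits$subject, hits$pident, hits$length,
                   hits$length, hits$length, hits$evalue, hits$bitscore)
  writeLines(lines, path)
  invisible(path)
}

#' Read whole-genome alignment coordinates (show-coords -T layout)
#'
#' Parses the tab-separated table produced by `show-coords -T`: columns
#' S1 E1 S2 E2 LEN1 LEN2 %IDY plus the two sequence tags. Header lines (file
#' paths, "NUCMER", column headers, separator) are skipped. A query record
#' with S2 > E2 is marked inverted and its coordinates normalized.
#'
#' @param path coords TSV file.
#' @return data.frame with `ref_seqid`, `ref_start`, `ref_end`, `qry_seqid`,
#'   `qry_start`, `qry_end`, `inverted`, `pct_identity` (1-based inclusive).
#' @export
read_coords <- function(path) {
  lines <- readLines(path)
  keep <- grepl("^[0-9]", lines)
  if (!any(keep))
    return(data.frame(ref_seqid = character(), ref_start = integer(),
                      ref_end = integer(), qry_seqid = character(),
                      qry_start = integer(), qry_end = integer(),
                      inverted = logical(), pct_identity = numeric()))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nc <- lengths(fields)
  if (any(nc != 9L))
    stop("malformed coords line ", which(keep)[nc != 9L][1],
         ": expected 9 tab-separated columns, got ", nc[nc != 9L][1])
  m <- do.call(rbind, fields)
  s2 <- as.integer(m[, 3]); e2 <- as.integer(m[, 4])
  inverted <- s2 > e2
  out <- data.frame(ref_seqid = m[, 8],
                    ref_start = as.integer(m[, 1]),
                    ref_end = as.integer(m[, 2]),
                    qry_seqid = m[, 9],
                    qry_start = pmin(s2, e2),
                    qry_end = pmax(s2, e2),
                    inverted = inverted,
                    pct_identity = as.numeric(m[, 7]))
  if (any(out$ref_end < out$ref_start))
    stop("coords record with reference end < start")
  out
}

#' Write alignment coordinates in show-coords -T layout
#' @param coords data.frame as from [read_coords()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_coords <- function(coords, path) {
  hdr <- c("ref.fa qry.fa", "NUCMER", "",
           paste("[S1]", "[E1]", "[S2]", "[E2]", "[LEN 1]", "[LEN 2]",
                 "[% IDY]", "[TAGS]", sep = "\t"))
  s2 <- ifelse(coords$inverted, coords$qry_end, coords$qry_start)
  e2 <- ifelse(coords$inverted, coords$qry_start, coords$qry_end)
  rows <- sprintf("%d\t%d\t%d\t%d\t%d\t%d\t%.2f\t%s\t%s",
                  coords$ref_start, coords$ref_end, s2, e2,
                  coords$ref_end - coords$ref_start + 1L,
                  coords$qry_end - coords$qry_start + 1L,
                  coords$pct_identity, coords$ref_seqid, coords$qry_seqid)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an OrthoFinder-style Orthogroups.tsv
#'
#' First column is the orthogroup id; remaining columns are per-species
#' comma-separated member lists (empty cell = no members).
#'
#' @param path Orthogroups.tsv file.
#' @return data.frame with `orthogroup`, one list-column of member ids per
#'   species, and integer `n_<species>` copy counts.
#' @export
read_orthogroups_tsv <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, quote = "",
                    colClasses = "character", check.names = FALSE,
                    na.strings = NULL)
  species <- names(tab)[-1]
  out <- data.frame(orthogroup = tab[[1]])
  for (sp in species) {
    members <- lapply(tab[[sp]], function(x) {
      if (is.na(x) || !nzchar(x)) character() else
        trimws(strsplit(x, ",", fixed = TRUE)[[1]])
    })
    out[[sp]] <- I(members)
    out[[paste0("n_", sp)]] <- lengths(members)
  }
  out
}

#' Write an Orthogroups.tsv table
#' @param og data.frame as from [read_orthogroups_tsv()] (list-columns of
#'   members per species).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_orthogroups_tsv <- function(og, path) {
  species <- names(og)[!grepl("^n_", names(og)) & names(og) != "orthogroup"]
  cells <- vapply(seq_len(nrow(og)), function(i) {
    paste(vapply(species, function(sp)
      paste(og[[sp]][[i]], collapse = ", "), ""), collapse = "\t")
  }, "")
  writeLines(c(paste(c("Orthogroup", species), collapse = "\t"),
               paste(og$orthogroup, cells, sep = "\t")), path)
  invisible(path)
}
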