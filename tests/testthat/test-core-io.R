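test_that("GFF3 hierarchy round-trips through write/read", {
  ds <- fixture_dataset()
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ds$predicted_models, path)
  back <- read_gff3(path)
  expect_equal(back, ds$predicted_models)
  # second write is byte-identical (canonical formatting)
  path2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("minimal GFF3 fixtures parse into the expected hierarchy", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t400\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t100\t400\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\tmRNA\t100\t400\t.\t+\t.\tID=g1.t2;Parent=g1",
    "chr1\tsrc\texon\t100\t200\t.\t+\t.\tParent=g1.t1",
    "chr1\tsrc\texon\t300\t400\t.\t+\t.\tParent=g1.t1",
    "chr1\tsrc\tCDS\t120\t200\t.\t+\t0\tParent=g1.t1",
    "chr1\tsrc\tCDS\t300\t380\t.\t+\t2\tParent=g1.t1",
    "chr1\tsrc\texon\t100\t200\t.\t+\t.\tParent=g1.t2",
    "chr1\tsrc\texon\t350\t400\t.\t+\t.\tParent=g1.t2"), path)
  models <- read_gff3(path)
  expect_length(models, 1L)
  g <- models$g1
  expect_length(g$transcripts, 2L)
  expect_equal(nrow(g$transcripts[["g1.t1"]]$exons), 2L)
  expect_equal(nrow(g$transcripts[["g1.t1"]]$cds), 2L)
  expect_equal(g$transcripts[["g1.t1"]]$cds$start, c(120L, 300L))
})

test_that("CDS outside its exon and orphan parents are rejected", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t400\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t100\t400\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\texon\t100\t200\t.\t+\t.\tParent=g1.t1",
    "chr1\tsrc\tCDS\t120\t201\t.\t+\t0\tParent=g1.t1"), path)
  expect_error(read_gff3(path), "g1\\.t1")

  path2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t400\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t100\t400\t.\t+\t.\tID=g1.t1;Parent=gX",
    "chr1\tsrc\texon\t100\t200\t.\t+\t.\tParent=g1.t1"), path2)
  expect_error(read_gff3(path2), "Parent")
})

test_that("write_gff3 refuses invalid models, sorts unsorted input, and an
           empty list gives a header-only file", {
  g <- toy_gene()
  bad <- g
  bad$transcripts[[1]]$cds$end[1] <- 10000L  # CDS escapes its exon
  path <- withr::local_tempfile(fileext = ".gff3")
  expect_error(write_gff3(list(bad), path), "CDS")

  g2 <- toy_gene("gB", start = 1001L)
  write_gff3(list(g2, g), path)  # deliberately unsorted
  back <- read_gff3(path)
  expect_identical(names(back), c("gA", "gB"))

  write_gff3(list(), path)
  expect_identical(readLines(path), "##gff-version 3")
  expect_length(read_gff3(path), 0L)
})

test_that("bedGraph reading densifies, zero-fills, and guards bounds", {
  path <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chrI\t0\t10\t5", path)
  track <- read_coverage_bedgraph(path, c(chrI = 20L))
  expect_equal(track$chrI, c(rep(5, 10), rep(0, 10)))

  writeLines(c("chrI\t0\t10\t5", "chrI\t5\t12\t2"), path)
  expect_warning(track <- read_coverage_bedgraph(path, c(chrI = 20L)),
                 "last record wins")
  expect_equal(track$chrI[6:12], rep(2, 7))
  expect_equal(track$chrI[1:5], rep(5, 5))

  writeLines("chrI\t0\t30\t5", path)
  expect_error(read_coverage_bedgraph(path, c(chrI = 20L)), "beyond")

  file.create(path2 <- withr::local_tempfile(fileext = ".bedgraph"))
  track <- read_coverage_bedgraph(path2, c(chrI = 7L))
  expect_equal(track$chrI, rep(0, 7))
})

test_that("junction BED coordinates convert to first/last intronic base and
           strandless junctions get GT-AG inference", {
  genome <- c(chrT = paste0(strrep("A", 10), "GT", strrep("C", 6), "AG",
                            strrep("A", 10)))
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrT\t10\t20\tj1\t7\t.", path)
  j <- read_junctions_bed(path, genome = genome)
  expect_equal(j$start, 11L)
  expect_equal(j$end, 20L)
  expect_equal(j$read_count, 7L)
  expect_equal(j$strand, "+")  # GT..AG inferred
  j2 <- read_junctions_bed(path)
  expect_equal(j2$strand, "*")
})

test_that("BLAST outfmt-6 parsing types numeric fields and rejects malformed
           rows with their line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste("q1", "s1", "98.5", "100", "1", "0", "1", "100", "5",
                   "104", "1e-50", "203.7", sep = "\t"), path)
  h <- read_blast_tab(path)
  expect_identical(h$evalue, 1e-50)
  expect_identical(h$bitscore, 203.7)
  writeLines("q1\ts1\t98.5", path)
  expect_error(read_blast_tab(path), "12 columns")
})

test_that("coords parsing normalizes inverted query records", {
  path <- withr::local_tempfile(fileext = ".coords")
  coords <- data.frame(ref_seqid = "I", ref_start = 100L, ref_end = 200L,
                       qry_seqid = "I", qry_start = 500L, qry_end = 600L,
                       inverted = TRUE, pct_identity = 99.1)
  write_coords(coords, path)
  back <- read_coords(path)
  expect_true(back$inverted)
  expect_lt(back$qry_start, back$qry_end)
  expect_equal(back$pct_identity, 99.1)
})

test_that("orthogroup tables parse empty cells as zero copies", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Orthogroup\tA\tB\tC",
               "OG1\ta1, a2\tb1\tc1",
               "OG2\t\tb2\tc2"), path)
  og <- read_orthogroups_tsv(path)
  expect_equal(og$n_A, c(2L, 0L))
  expect_equal(og$n_B, c(1L, 1L))
  expect_equal(og$A[[1]], c("a1", "a2"))
  expect_equal(og$A[[2]], character())
})

test_that("config files override defaults and unknown keys fail", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("min_edit_coverage: 3", "min_junction_reads: 5"), path)
  cfg <- read_config(path)
  expect_equal(cfg$min_edit_coverage, 3)
  expect_equal(cfg$min_junction_reads, 5)
  expect_equal(cfg$coverage_gap_min_len, 20)
  writeLines("not_a_key: 1", path)
  expect_error(read_config(path), "unknown config keys")
  expect_error(curation_config(intergenic_cov_fraction = 0))
})
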