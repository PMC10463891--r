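# hand-built two-gene locus used by the split/fusion rule tests:
# one real gene split into two predicted models at its middle intron
split_fixture <- function(gap_zero_run = 0L) {
  set.seed(77)
  r <- simulation_recipe(n_genes = 2L, n_contigs = 1L,
                         contig_length = 8000L, exons_per_gene = c(2L, 2L),
                         error_rates = list(split = 0.5, fusion = 0,
                                            intron_chain = 0),
                         noise = "none", rng_seed = 1L)
  ds <- simulate_dataset(r)
  if (gap_zero_run > 0) {
    tr <- ds$truth[ds$truth$error == "split", ][1, ]
    ids <- strsplit(tr$predicted_ids, ",")[[1]]
    a <- gene_span(ds$predicted_models[[ids[1]]])
    b <- gene_span(ds$predicted_models[[ids[2]]])
    mid <- (a[2] + b[1]) %/% 2
    # erase junction evidence across part of the gap
    j <- ds$evidence$junctions
    ds$evidence$junctions <- j[!(j$start > a[2] & j$end < b[1]), ]
    ds$evidence$long_chains <- list()
    ds$evidence$coverage_long <- NULL
  }
  ds
}

test_that("a planted split with a bridged intergenic gap is flagged once,
           with a merged proposal spanning both coding regions", {
  ds <- split_fixture()
  tr <- ds$truth[ds$truth$error == "split", ]
  expect_equal(nrow(tr), 1L)
  fl <- detect_split_candidates(ds$predicted_models, ds$evidence, ds$genome)
  expect_length(fl, 1L)
  f <- fl[[1]]
  expect_setequal(f$gene_ids, strsplit(tr$predicted_ids, ",")[[1]])
  merged <- f$proposed_fix[[1]]
  true_tx <- ds$true_models[[tr$gene_id]]$transcripts[[1]]
  expect_equal(merged$transcripts[[1]]$exons, true_tx$exons)
  expect_equal(merged$transcripts[[1]]$cds, true_tx$cds)
})

test_that("a zero-coverage run in the intergenic gap suppresses the split
           flag", {
  ds <- split_fixture(gap_zero_run = 25L)
  fl <- detect_split_candidates(ds$predicted_models, ds$evidence, ds$genome)
  expect_length(fl, 0L)
})

test_that("a merger whose re-predicted frame cannot span both genes is
           reverted (no flag)", {
  # two adjacent same-strand genes with fully covered intergenic region but
  # incompatible frames: the gap sequence carries an in-frame stop
  contig <- paste0(strrep("C", 100),
                   "ATG", strrep("GGA", 30), # gene A CDS, no stop yet
                   strrep("T", 2), "TAATAATAA", strrep("T", 2),  # poisoned gap
                   "ATG", strrep("GCA", 30), "TAA",
                   strrep("C", 100))
  genome <- c(chrT = contig)
  exA <- data.frame(start = 101L, end = 193L)
  exB <- data.frame(start = 207L, end = 302L)
  mA <- gene_model("gA", list(transcript("gA.t1", "chrT", "+", exA, exA)))
  mB <- gene_model("gB", list(transcript("gB.t1", "chrT", "+", exB, exB)))
  cov <- list(chrT = rep(5, nchar(contig)))
  ev <- evidence_bundle(cov)
  fl <- detect_split_candidates(list(gA = mA, gB = mB), ev, genome)
  expect_length(fl, 0L)
})

test_that("planted fusions are flagged at the bridging intron and the
           proposal cuts at the coverage gap", {
  ds <- fixture_dataset()
  fused <- unique(ds$truth$predicted_ids[ds$truth$error == "fusion"])
  fl <- detect_fusion_candidates(ds$predicted_models, ds$evidence, ds$genome)
  got <- unlist(lapply(fl, `[[`, "gene_ids"))
  expect_setequal(got, fused)
  # proposals re-derive two clean genes
  for (f in fl) {
    expect_gte(length(f$proposed_fix), 1L)
    for (m in f$proposed_fix) {
      aa <- tx_protein(m$transcripts[[1]], ds$genome)
      expect_false(grepl("\\*", aa))
    }
  }
})

test_that("an intron with a coverage gap but no covered in-frame stop, or
           full coverage (retained intron), is not a fusion", {
  # gene with one real intron; intron interior uncovered but stop-free scan
  contig <- paste0(strrep("C", 50), "ATG", strrep("GGA", 20),
                   "GT", strrep("C", 56), "AG",
                   strrep("GCA", 20), "TAA", strrep("C", 50))
  genome <- c(chrT = contig)
  ex <- data.frame(start = c(51L, 174L), end = c(113L, 236L))
  g <- gene_model("g1", list(transcript("g1.t1", "chrT", "+", ex, ex)))
  cov <- rep(0, nchar(contig))
  for (i in seq_len(nrow(ex))) cov[ex$start[i]:ex$end[i]] <- 8
  ev <- evidence_bundle(list(chrT = cov))
  expect_length(detect_fusion_candidates(list(g1 = g), ev, genome), 0L)
  # retained intron: interior fully covered -> no gap, no fusion flag
  cov2 <- cov; cov2[114:173] <- 8
  ev2 <- evidence_bundle(list(chrT = cov2))
  expect_length(detect_fusion_candidates(list(g1 = g), ev2, genome), 0L)
})

test_that("planted intron-chain errors are flagged with the right sub-type
           and the proposed transcript equals the truth", {
  ds <- fixture_dataset()
  ic <- ds$truth[ds$truth$error == "intron_chain", ]
  low <- preserve_low_coverage(ds$predicted_models, ds$evidence)
  fus <- detect_fusion_candidates(ds$predicted_models, ds$evidence,
                                  ds$genome)
  excl <- c(unlist(lapply(low, `[[`, "gene_ids")),
            unlist(lapply(fus, `[[`, "gene_ids")))
  fl <- detect_intron_chain_mismatch(ds$predicted_models, ds$evidence,
                                     exclude = excl, genome = ds$genome)
  got <- vapply(fl, function(f) f$gene_ids[1], "")
  expect_setequal(got, ic$gene_id)
  sub_of <- setNames(vapply(fl, `[[`, "", "subtype"), got)
  for (i in seq_len(nrow(ic))) {
    kind <- sub("=.*", "", ic$error_detail[i])
    want <- c(shift_intron = "JUNCTION_SHIFT",
              removed_intron = "MISSING_EXON",
              added_intron_after = "EXTRA_EXON")[[kind]]
    expect_identical(unname(sub_of[ic$gene_id[i]]), want)
    f <- fl[[which(got == ic$gene_id[i])]]
    expect_gte(length(f$proposed_fix), 1L)
    true_tx <- ds$true_models[[ic$gene_id[i]]]$transcripts[[1]]
    expect_equal(f$proposed_fix[[1]]$exons, true_tx$exons)
    expect_equal(f$proposed_fix[[1]]$cds, true_tx$cds)
  }
  # annotation matching the consensus is never flagged
  clean <- ds$truth$gene_id[ds$truth$error == "none"]
  expect_length(intersect(got, clean), 0L)
})

test_that("a long-read chain contradicting a well-supported short-read
           junction keeps both alternative models", {
  ds <- fixture_dataset()
  ic <- ds$truth[ds$truth$error == "intron_chain" &
                   grepl("shift", ds$truth$error_detail), ]
  with_chain <- vapply(seq_len(nrow(ic)), function(k) {
    g <- ds$predicted_models[[ic$gene_id[k]]]
    any(vapply(ds$evidence$long_chains, function(ch)
      ch$seqid == g$seqid && ch$strand == g$strand &&
        gene_span(ch)[1] <= gene_span(g)[2] &&
        gene_span(ch)[2] >= gene_span(g)[1], logical(1)))
  }, logical(1))
  expect_true(any(with_chain))
  row <- ic[which(with_chain)[1], ]
  gid <- row$gene_id
  g <- ds$predicted_models[[gid]]
  tx <- g$transcripts[[1]]
  intr <- tx_introns(tx)
  # fabricate strong short-read support for the (wrong) annotated intron:
  # now the long-read consensus disagrees with a trusted junction
  ev <- ds$evidence
  i <- as.integer(sub(".*=", "", row$error_detail))
  ev$junctions <- rbind(ev$junctions, data.frame(
    seqid = g$seqid, start = intr$start[i], end = intr$end[i],
    strand = g$strand, read_count = 50L, source = "short"))
  fl <- detect_intron_chain_mismatch(list(g), ev, genome = ds$genome)
  expect_length(fl, 1L)
  expect_true(isTRUE(fl[[1]]$evidence$conflict))
  expect_length(fl[[1]]$proposed_fix, 2L)
})

test_that("genes below 2x mean exonic coverage are preserved and excluded
           from structural detectors, with a strict-less-than boundary", {
  ds <- fixture_dataset()
  ev <- ds$evidence
  tr <- ds$truth[ds$truth$error == "intron_chain", ]
  gid <- tr$gene_id[1]
  g <- ds$predicted_models[[gid]]
  # deflate this gene's coverage to 1.2x
  ex <- gene_exon_union(g)
  for (i in seq_len(nrow(ex)))
    ev$coverage_short[[g$seqid]][ex$start[i]:ex$end[i]] <- 1.2
  low <- preserve_low_coverage(ds$predicted_models, ev)
  low_ids <- unlist(lapply(low, `[[`, "gene_ids"))
  expect_true(gid %in% low_ids)
  fl <- curate(ds$predicted_models, ev, ds$genome,
               stages = c("low_coverage", "fusion", "split", "intron_chain"))
  structural <- fl[vapply(fl, function(f)
    f$flag_type != "LOW_COVERAGE_PRESERVED", logical(1))]
  expect_false(gid %in% unlist(lapply(structural, `[[`, "gene_ids")))

  # boundary: exactly 2.0 is editable (strict less-than)
  for (i in seq_len(nrow(ex)))
    ev$coverage_short[[g$seqid]][ex$start[i]:ex$end[i]] <- 2.0
  low2 <- preserve_low_coverage(ds$predicted_models, ev)
  expect_false(gid %in% unlist(lapply(low2, `[[`, "gene_ids")))

  # zero-coverage gene passes through apply_flags byte-identically
  for (i in seq_len(nrow(ex)))
    ev$coverage_short[[g$seqid]][ex$start[i]:ex$end[i]] <- 0
  fl3 <- curate(ds$predicted_models, ev, ds$genome,
                stages = c("low_coverage", "fusion", "split", "intron_chain"))
  cur <- apply_flags(ds$predicted_models, fl3)
  expect_equal(cur[[gid]], ds$predicted_models[[gid]])
})

test_that("a gene deleted from predictions is recovered de novo with its
           true intron chain; single-exon blobs and ORF-less chains are not", {
  r <- simulation_recipe(n_genes = 8L, n_contigs = 1L,
                         contig_length = 25000L,
                         error_rates = list(split = 0, fusion = 0,
                                            intron_chain = 0),
                         drop_rate = 0.25, noise = "none", rng_seed = 13L)
  ds <- simulate_dataset(r)
  dropped <- ds$truth$gene_id[ds$truth$error == "dropped"]
  expect_equal(length(dropped), 2L)
  fl <- detect_de_novo(ds$predicted_models, ds$evidence, ds$genome)
  expect_length(fl, length(dropped))
  for (f in fl) {
    cand <- f$proposed_fix[[1]]$transcripts[[1]]
    hit <- dropped[vapply(dropped, function(gid) {
      sp <- gene_span(ds$true_models[[gid]])
      f$start <= sp[2] && f$end >= sp[1]
    }, logical(1))]
    expect_length(hit, 1L)
    true_tx <- ds$true_models[[hit]]$transcripts[[1]]
    expect_equal(tx_introns(cand), tx_introns(true_tx))
  }
  # a single-exon covered blob (no junctions) is never a candidate
  contig <- strrep("C", 2000)
  cov <- rep(0, 2000); cov[500:900] <- 10
  ev <- evidence_bundle(list(chrT = cov))
  expect_length(detect_de_novo(list(), ev, c(chrT = contig)), 0L)
  # junction-linked blocks with no ORF anywhere are discarded
  cov2 <- rep(0, 2000); cov2[c(500:700, 801:1000)] <- 10
  ev2 <- evidence_bundle(list(chrT = cov2),
                         data.frame(seqid = "chrT", start = 701L, end = 800L,
                                    strand = "*", read_count = 10L,
                                    source = "short"))
  expect_length(detect_de_novo(list(), ev2, c(chrT = contig)), 0L)
})
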