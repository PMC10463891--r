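# compact hand-built locus: 3-exon plus-strand gene whose middle acceptor
# has an evidence-supported alternative 3' splice site
iso_fixture <- function() {
  set.seed(31)
  r <- simulation_recipe(n_genes = 1L, n_contigs = 1L,
                         contig_length = 6000L, exons_per_gene = c(3L, 3L),
                         error_rates = list(split = 0, fusion = 0,
                                            intron_chain = 0),
                         long_read_fraction = 0, noise = "none",
                         rng_seed = 21L)
  ds <- simulate_dataset(r)
  g <- ds$predicted_models[[1]]
  ds$gene <- g
  ds
}

test_that("an alternative splice site yields at most one extra isoform with
           a continuous first-to-last-exon ORF", {
  ds <- iso_fixture()
  g <- ds$gene
  intr <- tx_introns(g$transcripts[[1]])
  # add an alternative acceptor 9 bp downstream of intron 1 (same donor)
  alt <- data.frame(seqid = g$seqid, start = intr$start[1],
                    end = intr$end[1] + 9L, strand = g$strand,
                    read_count = 20L, source = "short")
  ev <- ds$evidence
  ev$junctions <- rbind(ev$junctions, alt)
  fl <- enumerate_isoforms(g, ev, ds$genome)
  perms <- fl[vapply(fl, function(f)
    identical(f$subtype, "PERMUTATION"), logical(1))]
  expect_lte(length(perms), 2L)
  for (f in perms) {
    tx <- f$proposed_fix[[1]]
    expect_true(nrow(tx$cds) > 0)
    aa <- tx_protein(tx, ds$genome)
    expect_false(grepl("\\*", aa))
    # coding sequence reaches both terminal exons
    first_ex <- tx$exons[1, ]; last_ex <- tx$exons[nrow(tx$exons), ]
    expect_true(any(tx$cds$start <= first_ex$end &
                      tx$cds$end >= first_ex$start))
    expect_true(any(tx$cds$start <= last_ex$end &
                      tx$cds$end >= last_ex$start))
  }
})

test_that("permutations whose ORF cannot thread all exons are excluded and
           evidence-matching annotations produce no candidates", {
  ds <- iso_fixture()
  g <- ds$gene
  # evidence exactly matching the annotation: nothing to propose
  fl <- enumerate_isoforms(g, ds$evidence, ds$genome)
  expect_length(fl[vapply(fl, function(f)
    identical(f$subtype, "PERMUTATION"), logical(1))], 0L)
  # an alternative junction that swallows the start codon kills the ORF:
  # splice from inside exon 1 across the original ATG region
  tx <- g$transcripts[[1]]
  sp <- gene_span(g)
  bad <- data.frame(seqid = g$seqid, start = sp[1] + 1L,
                    end = tx_introns(tx)$end[1], strand = g$strand,
                    read_count = 20L, source = "short")
  ev <- ds$evidence
  ev$junctions <- rbind(ev$junctions, bad)
  fl2 <- enumerate_isoforms(g, ev, ds$genome)
  perms <- fl2[vapply(fl2, function(f)
    identical(f$subtype, "PERMUTATION"), logical(1))]
  # the swallowed-ATG permutation must not be among the proposals
  for (f in perms)
    expect_false(identical(tx_introns(f$proposed_fix[[1]])$start[1],
                           bad$start))
})

test_that("annotated isoforms without any junction or long-read support are
           recommended for removal", {
  ds <- iso_fixture()
  g <- ds$gene
  tx <- g$transcripts[[1]]
  fake <- tx
  fake$transcript_id <- paste0(g$gene_id, ".t2")
  # both donors moved: no junction of this isoform matches any evidence
  fake$exons$end[1] <- fake$exons$end[1] - 15L
  fake$exons$end[2] <- fake$exons$end[2] - 15L
  fake$cds <- fake$exons[0, ]
  g2 <- gene_model(g$gene_id, list(tx, fake))
  fl <- enumerate_isoforms(g2, ds$evidence, ds$genome)
  removals <- fl[vapply(fl, function(f)
    identical(f$subtype, "REMOVE_UNSUPPORTED"), logical(1))]
  expect_length(removals, 1L)
  expect_identical(removals[[1]]$evidence$transcript_id,
                   paste0(g$gene_id, ".t2"))
})

test_that("structurally unique long-read chains become isoform candidates", {
  ds <- iso_fixture()
  g <- ds$gene
  tx <- g$transcripts[[1]]
  chain <- tx
  chain$transcript_id <- "lr.alt"
  intr <- tx_introns(tx)
  chain$exons$end[1] <- intr$start[1] + 14L  # exitron-ish variant donor
  chain$cds <- chain$exons[0, ]
  ev <- ds$evidence
  ev$long_chains <- list(chain)
  fl <- enumerate_isoforms(g, ev, ds$genome)
  lr <- fl[vapply(fl, function(f)
    identical(f$subtype, "LONG_READ"), logical(1))]
  expect_length(lr, 1L)
  expect_identical(lr[[1]]$evidence$chain_id, "lr.alt")
})

test_that("UTR proposals follow long-read termini, fall back to covered
           blocks, and are suppressed toward covered same-strand neighbors", {
  ds <- iso_fixture()
  g <- ds$gene
  sp <- gene_span(g)
  cov <- ds$evidence$coverage_short[[g$seqid]]
  # covered read block running 80 bp past the 3' end
  cov[(sp[2] + 1):(sp[2] + 80)] <- 6
  ev <- ds$evidence
  ev$coverage_short[[g$seqid]] <- cov
  fl <- extend_utrs(g, ev, list(g), curation_config())
  side <- if (g$strand == "+") "3PRIME" else "5PRIME"
  hit <- fl[vapply(fl, function(f) identical(f$subtype, side), logical(1))]
  expect_length(hit, 1L)
  expect_equal(hit[[1]]$evidence$proposed_terminus, sp[2] + 80L)

  # a long-read chain covering the CDS wins over the covered block
  chain <- g$transcripts[[1]]
  chain$transcript_id <- "lr.full"
  chain$exons$end[nrow(chain$exons)] <- sp[2] + 120L
  chain$cds <- chain$exons[0, ]
  ev$long_chains <- list(chain)
  fl2 <- extend_utrs(g, ev, list(g), curation_config())
  hit2 <- fl2[vapply(fl2, function(f) identical(f$subtype, side), logical(1))]
  expect_equal(hit2[[1]]$evidence$proposed_terminus, sp[2] + 120L)

  # continuous coverage into a same-strand neighbor suppresses the flag
  nb_ex <- data.frame(start = sp[2] + 81L, end = sp[2] + 200L)
  nb <- gene_model("gNB", list(
    transcript("gNB.t1", g$seqid, g$strand, nb_ex, nb_ex)))
  ev$long_chains <- list()
  fl3 <- extend_utrs(g, ev, list(g, nb), curation_config())
  expect_length(fl3[vapply(fl3, function(f)
    identical(f$subtype, side), logical(1))], 0L)
})

test_that("isoforms sharing an identical terminal exon receive identical
           proposed UTR boundaries", {
  ds <- iso_fixture()
  g <- ds$gene
  tx <- g$transcripts[[1]]
  sp <- gene_span(g)
  tx2 <- tx
  tx2$transcript_id <- paste0(g$gene_id, ".t2")
  tx2$exons$end[1] <- tx2$exons$end[1] - 9L  # same terminal (last) exon
  tx2$cds <- tx2$exons
  g2 <- gene_model(g$gene_id, list(tx, tx2))
  cov <- ds$evidence$coverage_short[[g$seqid]]
  cov[(sp[2] + 1):(sp[2] + 50)] <- 6
  ev <- ds$evidence
  ev$coverage_short[[g$seqid]] <- cov
  fl <- extend_utrs(g2, ev, list(g2), curation_config())
  side <- if (g$strand == "+") "3PRIME" else "5PRIME"
  # both isoforms end at the same genomic right edge
  props <- Filter(function(f)
    f$evidence$current_terminus == sp[2], fl)
  termini <- vapply(props, function(f) f$evidence$proposed_terminus, 1L)
  expect_gte(length(termini), 2L)
  expect_equal(length(unique(termini)), 1L)
})
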