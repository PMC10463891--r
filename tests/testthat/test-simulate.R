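test_that("the generator is byte-deterministic under a fixed seed", {
  r <- simulation_recipe(n_genes = 12L, n_contigs = 1L,
                         contig_length = 25000L, rng_seed = 42L)
  a <- simulate_dataset(r)
  b <- simulate_dataset(r)
  expect_identical(a, b)
  m1 <- simulate_misassembly(a$genome, a$true_models, r)
  m2 <- simulate_misassembly(b$genome, b$true_models, r)
  expect_identical(m1, m2)
  o1 <- simulate_ortholog_lengths(20, list(A = 1, B = 1.04), seed = 3)
  o2 <- simulate_ortholog_lengths(20, list(A = 1, B = 1.04), seed = 3)
  expect_identical(o1, o2)
})

test_that("generated genes have clean single-ORF anatomy: ATG start, terminal
           stop, no internal stops, GT-AG introns", {
  ds <- fixture_dataset()
  for (g in ds$true_models) {
    tx <- g$transcripts[[1]]
    s <- spliced_sequence(tx, ds$genome)
    expect_identical(substr(s, 1, 3), "ATG")
    expect_identical(substr(s, nchar(s) - 2, nchar(s)), "TAA")
    expect_equal(nchar(s) %% 3, 0)
    aa <- tx_protein(tx, ds$genome, strip_stop = FALSE)
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
    intr <- tx_introns(tx)
    contig <- ds$genome[[g$seqid]]
    for (i in seq_len(nrow(intr))) {
      don <- substr(contig, intr$start[i], intr$start[i] + 1)
      acc <- substr(contig, intr$end[i] - 1, intr$end[i])
      if (g$strand == "+") expect_identical(paste0(don, acc), "GTAG")
      else expect_identical(paste0(don, acc), "CTAC")
    }
  }
  # genes separated by at least 200 bp
  tab <- models_table(ds$true_models)
  for (sq in unique(tab$seqid)) {
    sub <- tab[tab$seqid == sq, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1)
      expect_true(all(sub$start[-1] - sub$end[-nrow(sub)] - 1 >= 200))
  }
})

test_that("single-exon recipes yield no junctions and an infeasible recipe
           errors", {
  r <- simulation_recipe(n_genes = 6L, n_contigs = 1L,
                         contig_length = 15000L,
                         error_rates = list(split = 0, fusion = 0,
                                            intron_chain = 0),
                         exons_per_gene = c(1L, 1L), rng_seed = 5L)
  ds <- simulate_dataset(r)
  expect_true(all(vapply(ds$true_models, function(g)
    nrow(g$transcripts[[1]]$exons), 1L) == 1L))
  expect_equal(nrow(ds$evidence$junctions), 0L)

  bad <- simulation_recipe(n_genes = 100L, n_contigs = 1L,
                           contig_length = 5000L, rng_seed = 1L)
  expect_error(simulate_genome_and_genes(bad), "infeasible")
})

test_that("corruption plants the requested error classes and records them", {
  r <- simulation_recipe(n_genes = 10L, n_contigs = 1L,
                         contig_length = 30000L,
                         exons_per_gene = c(3L, 4L),
                         error_rates = list(split = 1, fusion = 0,
                                            intron_chain = 0),
                         rng_seed = 9L)
  sim <- simulate_genome_and_genes(r)
  corr <- corrupt_annotation(sim$models, r, sim$truth)
  expect_length(corr$models, 20L)  # every gene emitted as two halves
  expect_equal(sum(corr$truth$error == "split"), 10L)

  r0 <- simulation_recipe(n_genes = 10L, n_contigs = 1L,
                          contig_length = 30000L,
                          error_rates = list(split = 0, fusion = 0,
                                             intron_chain = 0),
                          rng_seed = 9L)
  sim0 <- simulate_genome_and_genes(r0)
  corr0 <- corrupt_annotation(sim0$models, r0, sim0$truth)
  expect_equal(corr0$models, sim0$models)  # all rates zero: identity

  ds <- fixture_dataset()
  n_fus <- sum(ds$truth$error == "fusion") / 2   # one event joins two genes
  n_split <- sum(ds$truth$error == "split")      # one event emits two models
  expect_equal(length(ds$predicted_models),
               length(ds$true_models) + n_split - n_fus)
})

test_that("evidence is consistent with truth: expressed introns have
           junctions, exon depth tracks expression, zero-expression genes are
           silent", {
  ds <- fixture_dataset()   # noise-free
  jkey <- paste(ds$evidence$junctions$seqid, ds$evidence$junctions$start,
                ds$evidence$junctions$end)
  for (g in ds$true_models) {
    intr <- tx_introns(g$transcripts[[1]])
    for (i in seq_len(nrow(intr)))
      expect_true(paste(g$seqid, intr$start[i], intr$end[i]) %in% jkey)
  }
  # zero expression silences a gene
  r <- simulation_recipe(n_genes = 4L, n_contigs = 1L,
                         contig_length = 15000L, tpm_floor = 0,
                         noise = "none", rng_seed = 3L)
  sim <- simulate_genome_and_genes(r)
  expr <- setNames(rep(0, 4), names(sim$models))
  ev <- simulate_evidence(sim$genome, sim$models, r, expr)
  g <- sim$models[[1]]
  expect_equal(mean_exonic_depth(g, ev), 0)
  expect_equal(nrow(ev$junctions), 0L)
})

test_that("mean exonic depth under Poisson noise is within 3 sigma of the
           analytic expectation", {
  r <- simulation_recipe(noise = "poisson", rng_seed = 42L)
  ds <- simulate_dataset(r)
  for (gid in head(names(ds$true_models), 8)) {
    g <- ds$true_models[[gid]]
    lam <- ds$truth$tpm[ds$truth$gene_id == gid] * r$cov_per_tpm +
      r$noise_depth
    ex <- g$transcripts[[1]]$exons
    n <- sum(ex$end - ex$start + 1L)
    got <- mean_exonic_depth(g, ds$evidence)
    expect_lt(abs(got - lam), 3 * sqrt(lam / n) + 1e-9)
  }
})

test_that("complete 5' dropout silences the first exon and its junction", {
  r <- simulation_recipe(n_genes = 6L, n_contigs = 1L,
                         contig_length = 20000L, exons_per_gene = c(3L, 3L),
                         fiveprime_dropout = 1, long_read_fraction = 0,
                         noise = "none", rng_seed = 11L)
  sim <- simulate_genome_and_genes(r)
  expr <- setNames(sim$truth$tpm, sim$truth$gene_id)
  ev <- simulate_evidence(sim$genome, sim$models, r, expr)
  for (g in sim$models) {
    tx <- g$transcripts[[1]]
    first <- exons_5to3(tx)[1, ]
    expect_equal(sum(ev$coverage_short[[g$seqid]][first$start:first$end]), 0)
    intr <- tx_introns(tx)
    i1 <- if (tx$strand == "+") 1L else nrow(intr)
    jkey <- paste(ev$junctions$seqid, ev$junctions$start, ev$junctions$end)
    expect_false(paste(g$seqid, intr$start[i1], intr$end[i1]) %in% jkey)
  }
})

test_that("the truth table is a complete record of every planted deviation", {
  ds <- fixture_dataset()
  tr <- ds$truth
  pred_ids <- names(ds$predicted_models)
  for (i in seq_len(nrow(tr))) {
    ids <- strsplit(tr$predicted_ids[i], ",")[[1]]
    if (tr$error[i] == "dropped") expect_length(ids, 0L)
    else expect_true(all(ids %in% pred_ids))
    if (tr$error[i] == "none") {
      expect_equal(ds$predicted_models[[tr$gene_id[i]]],
                   ds$true_models[[tr$gene_id[i]]])
    } else if (tr$error[i] == "intron_chain") {
      expect_false(isTRUE(all.equal(
        ds$predicted_models[[tr$gene_id[i]]]$transcripts[[1]]$exons,
        ds$true_models[[tr$gene_id[i]]]$transcripts[[1]]$exons)))
    }
  }
})
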