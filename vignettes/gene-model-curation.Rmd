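---
title: "Evidence-driven gene-model curation: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-driven gene-model curation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annocurate)
```

## The problem

Automated gene prediction on a newly assembled genome leaves a
characteristic spectrum of structural errors: gene splits (one locus, two
models), gene fusions (two loci, one model bridged by a spurious intron),
and intron-chain errors (extra, missing or shifted exon boundaries). Human
curators repair these by inspecting RNA-seq alignments in a genome editor.
`annocurate` encodes that decision logic as deterministic rules over three
evidence channels: a per-base short-read coverage track, a table of
spliced junctions weighted by supporting reads, and full-length long-read
transcript models. This vignette documents the rules, their tunable
parameters, the synthetic data used to validate them, and the design
decisions taken where practice is genuinely open.

## Data model and conventions

All coordinates are 1-based inclusive (GFF3 convention); bedGraph's
0-based half-open intervals and BED junction records are converted at the
file boundary. A junction's `start`/`end` are the first and last intronic
base — this makes junction sets directly comparable to transcript intron
chains. Strandless junctions are assigned a strand by GT–AG (or CT–AC)
inference against the genome when available, and otherwise match either
strand. Overlapping bedGraph records resolve last-writer-wins with a
warning, since the format itself does not define a semantics for overlap.

## The curation rules

**Editing threshold.** No structural edit is proposed for a gene whose
mean exonic short-read depth is strictly below `min_edit_coverage`
(default 2, i.e. "2×" coverage); such genes are flagged
`LOW_COVERAGE_PRESERVED` and pass through untouched. The mean over the
exon union was chosen over a minimum-depth criterion: a minimum is
dominated by single uncovered bases and would preserve (and hence freeze)
many correctable models.

**Gene splits.** For each same-strand adjacent pair of models the
intergenic region is tested for uninterrupted RNA coverage. A base counts
as covered when its short-read depth reaches `intergenic_min_depth`
(default 1), when it lies inside a junction supported by at least
`min_junction_reads` spliced reads, or when long-read coverage reaches it.
Counting spliced-read bridges as coverage is deliberate: when a predictor
splits a gene exactly at an intron, the gap between the two half-models
*is* that intron — unspliced coverage there is legitimately zero, and the
evidence connecting the halves is the junction whose reads span the gap.
If the covered fraction reaches `intergenic_cov_fraction` (default 1.0),
the two models are merged — bridging the gap as an intron when a supported
junction spans it, as an exon otherwise — and the coding sequence is
re-predicted. The pair is flagged only if the merged ORF spans both
original coding regions; a merger whose reading frame hits a premature
stop is discarded, mirroring the reverted-merger practice.

**Gene fusions.** An annotated intron is a fusion signature when (a) its
interior contains a run of sub-threshold depth of at least
`coverage_gap_min_len` bp (default 20) — the intergenic gap of the two
real genes — and (b) an in-frame stop codon, continuing the upstream
coding frame across the donor site, occurs at a covered position inside
the intron: the true stop of the upstream gene that the spurious intron
bypasses. Both conditions together separate fusions from ordinary introns
(uncovered interior, but no covered in-frame stop) and from retained
introns (covered interior, no gap). The proposal cuts the model in two at
the longest sub-threshold run, treating the covered intron flanks as
exonic tails, and re-predicts each side's ORF.

**Intron chains.** Where a long-read chain overlaps the locus it is
authoritative over the region it covers; otherwise the comparison is
against trusted short-read junctions (`min_junction_reads`, default 3).
The short-read rules are deliberately *evidence-positive* to protect
precision: an annotated intron is *extra* only when it is unsupported
**and** its interior is covered by reads (i.e. the RNA says the region is
exonic); a supported junction absent from the annotation is a *missing*
boundary; an unsupported annotated intron overlapping a supported junction
with different endpoints is a *shift*. An unsupported intron whose
interior is also uncovered is left alone — that is what a real intron of a
weakly expressed gene looks like, and flagging it would turn sampling
noise into edits. When the long-read chain contradicts a well-supported
short-read junction, both the corrected and the original transcript are
kept in the proposal, reflecting the keep-both-models convention for
unresolved conflicts. Flag sub-types report shifts before missing before
extra boundaries when several co-occur.

**Orchestration.** `curate()` runs fusion detection before the
intron-chain comparison and excludes fusion-flagged genes from it: a fused
model's chain necessarily mismatches both underlying genes, and
double-flagging would count the same planted error twice (once with the
wrong type). Low-coverage genes are excluded from every structural
detector.

**De novo genes, isoforms, UTRs.** Supported junctions outside every model
are chained through covered gaps and assembled into candidate transcripts;
a candidate survives only with a complete ORF (both strands are tried when
junction strand is ambiguous) and at least one junction (no single-exon
calls from coverage blobs alone). Isoform enumeration clusters junctions
that overlap or share endpoints into alternative groups, enumerates
one-choice-per-cluster permutations (capped at `max_isoform_clusters`
clusters and 256 permutations, with warnings — never silent truncation),
and keeps structures whose re-predicted ORF reaches both terminal exons;
structurally novel long-read chains are kept as candidates even with
shorter ORFs, and annotated isoforms none of whose introns has any
evidence are reported for removal. UTR termini follow the long-read
transcript when one covers the CDS, else the contiguous covered block at
the terminal exon; extension is suppressed toward the nearest same-strand
neighbor when the intergenic region is continuously covered (the two
genes' UTRs cannot be separated), and isoforms sharing an identical
terminal exon receive identical boundaries. "Close proximity" is
operationalized as the nearest same-strand neighbor, the paper-trail for
which lives with each flag's evidence summary.

## ORF selection

`select_orf()` pairs every ATG with its first in-frame stop and selects by
mode: `longest` takes the maximal-length complete ORF; `max_exon_span`
prefers the ORF whose coding sequence touches the most exons and breaks
ties by length — the manual override used when a shorter ORF distributes
coding sequence across more of the transcript's exons than the longest
one. Residual ties go to the most-5' start codon; this matters in first
exons with several in-frame ATGs, where any choice is arbitrary without
5'-end data, and the most-5' choice maximizes the annotated protein. Both
modes are validated against a brute-force all-ATG enumeration in the test
suite.

## The synthetic data generator

`simulation_recipe()` fixes the study conditions; every generator is
byte-deterministic under `rng_seed`.

* **Genes**: 60 genes over two 60 kb contigs by default, 2–6 exons of
  60–240 bp, introns 60–200 bp, GT–AG splice sites, a single clean ORF per
  gene (ATG start, terminal stop, no internal stops), and at least 200 bp
  of intergenic spacing so split detection has well-defined windows.
* **Expression**: log-normal TPM (`meanlog = log 40`, `sdlog = 0.8`)
  floored at 8 TPM, one coverage unit per TPM. The floor keeps the
  simulated cohort in the editable regime: the low-coverage preservation
  rule is exercised by dedicated tests that deflate individual genes
  rather than by randomizing which planted errors are detectable.
* **Noise**: per-base Poisson depth around the expression mean, plus a
  sparse Poisson background (rate 0.02/bp) outside exons; `noise = "none"`
  gives exact expected depth for the noise-free fixture.
* **Planted errors**: splits break a gene at an internal intron; fusions
  join two adjacent same-strand genes with a bridging intron that cuts
  ~30 bp into the flanking exons, so the upstream gene's true stop lies
  inside the spurious intron in covered sequence — which is precisely what
  makes real fusions detectable; intron-chain errors shift a boundary 6 bp
  into the intron, remove a junction, or insert a spurious 20 bp intron.
  At most one error per gene; a `drop_rate` deletes genes outright to
  plant de-novo cases. Every deviation is recorded in the truth table.
  Default rates (10% split, 10% fusion, 20% intron chain) are a
  deliberately error-dense regime for testing the detectors; real
  predictor error rates are not published and would be lower.
* **Long reads**: the better-expressed half of genes contribute full-length
  chains; `fiveprime_dropout` suppresses first-exon coverage, the first
  junction's support, and truncates a matching fraction of chains,
  emulating 5'-underrepresented cDNA libraries.
* **Misassembly**: gene-containing segments are re-inserted (tandem or
  distant, optionally reverse-complemented) and the by-construction
  alignment table is emitted with identity runs broken at source
  boundaries and insertion points — the coordinate signature an aligner
  produces at structural discontinuities. The duplication detector is
  therefore tested against exact planted truth rather than against an
  aligner's heuristics.

What the simulator does *not* model: sequencing errors, non-canonical
splice sites, overlapping or nested genes, alternative TSS/polyadenylation,
codon usage, repeat-driven mismapping. Passing tests therefore demonstrate
that the rules implement the stated logic faithfully under their stated
assumptions, not that the thresholds are optimal for any particular real
library.

## Duplication detection

Alignment records are clustered by reciprocal overlap of their truth-genome
intervals (single linkage, threshold `dup_min_reciprocal_overlap` = 0.5;
the published analysis gives no fraction, and 0.5 is the conventional
reciprocal-overlap cut for calling two intervals "the same segment").
Clusters with two or more distinct audited intervals become events, with
`same_chromosome` and `any_inverted` attributes and per-event affected-gene
lists (CDS overlap of at least 1 bp, globally de-duplicated). Pre-merging
of fragmented collinear records (gaps up to 500 bp on both genomes,
matching the aligner's max-gap setting) is available but off by default:
the by-construction coordinate tables are already maximal, and merging
across zero-gap structural breakpoints would hide them. Both
intra-chromosomal and inter-chromosomal subtotals are reported.

## Annotation diffing

Two gene sets on one genome are linked through same-strand CDS overlap
(≥ 1 bp; exon-only overlap does not link genes, since UTR changes are not
coding changes). Connected components classify as SPLIT (|A| ≥ 2, |B| = 1),
FUSION (1 vs ≥ 2), UNCHANGED/INTRON_CHAIN for 1–1 pairs by exact equality
of the translated longest-isoform protein, and UNCLASSIFIED for anything
more complex, including genes private to one set. Percentages are reported
over modified (non-UNCHANGED) genes to one decimal; transcripts-per-gene
to two decimals.

## Ortholog metrics

Best hits rank by e-value, then bitscore, then lexicographic subject id
(a documented, deterministic residual tie-break); reciprocal best pairs
are kept only when best-of-best holds in both directions, which yields at
most one reciprocal hit per gene. The percent length difference uses the
reference-species (N2-side) length as denominator. Bin edges are half-open
with `identical` as its own bin — a gene 5.0% off bins as `(0,5]`, 5.1% as
`(5,10]`; the bin labels in the source analyses imply the identical bin
but do not fix the edge convention, so the half-open choice is documented
here and enforced by a partition test. The cross-strain "near-identical"
concordance threshold is exposed as a parameter
(`near_identical_fraction(threshold = 5)`), since no numeric value is
published for it.

## Problem sizes and determinism

The default validation fixture is 60 genes over 120 kb with ~24 planted
errors, four planted duplications and 200-trio ortholog tables — small
enough that the full suite, including brute-force oracles (quadratic
duplication clustering up to ~120 records, exhaustive RBH enumeration up
to 200 genes, all-ATG ORF scans on 300-mers), runs in a few minutes on one
CPU, while every rule still meets each planted case in both its positive
and negated form. All stages are library functions; the CLI
(`inst/cli/annocurate`) adds only argument parsing and manifest writing,
and identical inputs produce byte-identical outputs under a fixed seed.

## Known limitations

* Consensus building trusts junction read counts linearly; there is no
  statistical model of junction noise (none is needed while junctions are
  only generated from real introns, but real aligners emit spurious
  junctions that would require a count model or filtering).
* Fusion detection requires the bypassed stop codon to retain coverage; a
  fusion of a silent gene with an expressed one is invisible, as it is to
  a human curator.
* Isoform enumeration is combinatorial with hard caps; loci with many
  alternative junction clusters are truncated with a warning rather than
  solved.
* The diff classifier's UNCLASSIFIED covers structurally complex
  components; published unclassified counts may instead reflect
  record-keeping gaps, so the two are not directly comparable.
* UTR proposals are coordinate extensions only; no polyadenylation or TSS
  signal model is consulted.
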