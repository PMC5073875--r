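# BAM/SAM traversal and featureCounts-compatible gene-level assignment.

simple_gtf <- function() {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chrT\tx\texon\t1001\t2000\t.\t+\t.\tgene_id "GA"; transcript_id "TA";',
    'chrT\tx\texon\t3001\t3500\t.\t+\t.\tgene_id "GA"; transcript_id "TA";',
    'chrT\tx\texon\t5001\t6000\t.\t-\t.\tgene_id "GB"; transcript_id "TB";',
    'chrT\tx\texon\t5901\t7000\t.\t+\t.\tgene_id "GC"; transcript_id "TC";'
  ), gtf)
  gtf
}

test_that("CIGAR operations map to the right reference blocks", {
  sam <- write_test_sam(data.frame(
    qname = c("ins", "spliced", "softclip", "del"),
    flag = 0L, chrom = "chrT",
    pos = c(101L, 101L, 101L, 101L),
    cigar = c("10M2I10M", "10M100N10M", "5S10M", "5M3D5M")))
  aln <- read_alignments(sam)
  bl <- GenomicAlignments::grglist(aln$gal)
  # insertion consumes no reference: one 20 bp block
  expect_equal(unname(as.data.frame(bl[[1]])[, c("start", "end")]),
               data.frame(start = 101, end = 120), ignore_attr = TRUE)
  # N splits into two blocks
  expect_equal(as.data.frame(bl[[2]])$start, c(101, 211))
  expect_equal(as.data.frame(bl[[2]])$end, c(110, 220))
  # soft clip consumes no reference
  expect_equal(as.data.frame(bl[[3]])$end - as.data.frame(bl[[3]])$start + 1, 10)
  # deletion consumes reference within one block
  expect_equal(as.data.frame(bl[[4]])$end - as.data.frame(bl[[4]])$start + 1, 13)
})

test_that("flags and NH are decoded; unmapped records are excluded but counted", {
  sam <- write_test_sam(data.frame(
    qname = c("a", "b", "c", "d"),
    flag = c(0L, 1040L, 256L, 4L),
    chrom = c("chrT", "chrT", "chrT", "*"),
    pos = c(101L, 101L, 201L, 0L),
    cigar = c("10M", "10M", "10M", "*"),
    nh = c(1L, 1L, 2L, 1L)))
  aln <- read_alignments(sam)
  mc <- S4Vectors::mcols(aln$gal)
  expect_equal(length(aln$gal), 3L)
  expect_equal(aln$n_unmapped, 1L)
  expect_equal(mc$is_duplicate, c(FALSE, TRUE, FALSE))
  expect_equal(mc$is_secondary, c(FALSE, FALSE, TRUE))
  expect_equal(mc$NH, c(1L, 1L, 2L))
  expect_error(read_alignments(tempfile(fileext = ".sam")), "not found")
})

test_that("assignment follows union-overlap rules with ambiguity discard", {
  gm <- read_gene_models(simple_gtf())
  idx <- build_index(gm)
  # fully inside GA's exon
  expect_equal(assign_unit(data.frame(chrom = "chrT", start = 1100, end = 1150),
                           "+", idx), "GA")
  # overlapping GB and GC (they share 5901..6000, 1-based)
  expect_equal(assign_unit(data.frame(chrom = "chrT", start = 5940, end = 5990),
                           "+", idx), "AMBIGUOUS")
  # intronic
  expect_equal(assign_unit(data.frame(chrom = "chrT", start = 2500, end = 2550),
                           "+", idx), "NO_FEATURE")
  # 1 bp overlap suffices
  expect_equal(assign_unit(data.frame(chrom = "chrT", start = 999, end = 1001),
                           "+", idx), "GA")
  # strandedness: GB is '-'
  expect_equal(assign_unit(data.frame(chrom = "chrT", start = 5100, end = 5150),
                           "+", idx, strandedness = 1), "NO_FEATURE")
  expect_equal(assign_unit(data.frame(chrom = "chrT", start = 5100, end = 5150),
                           "+", idx, strandedness = 2), "GB")
})

test_that("spliced reads hitting two exons of one gene count once for that gene", {
  gm <- read_gene_models(simple_gtf())
  # block 1 in GA exon 1, block 2 in GA exon 2 (0-based 3000..3010)
  sam <- write_test_sam(data.frame(
    qname = "sp", flag = 0L, chrom = "chrT", pos = 1991L,
    cigar = "10M1000N10M"))
  cs <- count_bam(sam, gm)
  expect_equal(cs$counts$allCounts[cs$counts$gene_id == "GA"], 1L)
  expect_equal(unname(cs$stats["assigned"]), 1L)
})

test_that("count tiers respect duplicate flags, NH and secondary records", {
  gm <- read_gene_models(simple_gtf())
  sam <- write_test_sam(data.frame(
    qname = c("u1", "u2", "m1", "m1", "d1"),
    flag = c(0L, 0L, 0L, 256L, 1024L),
    chrom = "chrT",
    pos = c(1101L, 1201L, 1301L, 5101L, 1401L),
    cigar = "50M",
    nh = c(1L, 1L, 2L, 2L, 1L)))
  cs <- count_bam(sam, gm)
  ga <- cs$counts[cs$counts$gene_id == "GA", ]
  expect_equal(ga$allCounts, 3L)          # u1, u2, d1 (NH == 1)
  expect_equal(ga$filteredCounts, 2L)     # d1 is a duplicate
  expect_equal(ga$allCountsMulti, 4L)     # + m1 primary
  expect_equal(ga$filteredCountsMulti, 3L)
  # secondary alignment of m1 on GB is never counted
  expect_equal(cs$counts$allCountsMulti[cs$counts$gene_id == "GB"], 0L)
  expect_equal(unname(cs$stats["secondary_skipped"]), 1L)
})

test_that("published-style row: 590 assigned reads, 319 duplicates on a 666 bp gene", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines('chrT\tx\texon\t1001\t1666\t.\t+\t.\tgene_id "ISG15"; transcript_id "T";',
             gtf)
  gm <- read_gene_models(gtf)
  expect_equal(gm$genes$length, 666)
  set.seed(11)
  pos <- sample(1001:1617, 590, replace = TRUE)
  dup <- rep(c(TRUE, FALSE), c(319, 271))
  sam <- write_test_sam(data.frame(
    qname = sprintf("r%03d", 1:590), flag = ifelse(dup, 1024L, 0L),
    chrom = "chrT", pos = pos, cigar = "50M"))
  cs <- count_bam(sam, gm)
  expect_equal(cs$counts$allCounts, 590L)
  expect_equal(cs$counts$filteredCounts, 271L)
  tab <- build_duprate_table(cs, gm)
  expect_equal(sprintf("%.2f", tab$dupRate), "0.54")
  expect_equal(sprintf("%.2f", tab$RPK), "885.89")
})

test_that("counting equals the brute-force oracle on a randomized library", {
  spec <- sim_spec(n_genes = 20, n_reads = 4000, frac_multimap = 0.05,
                   frac_intergenic = 0.05, seed = 101)
  lib <- mark_duplicates(pcr_amplify(simulate_library(spec), f = 0.7, seed = 5))
  sam <- tempfile(fileext = ".sam")
  write_sam(lib, sam)
  cs <- count_bam(sam, lib$models)
  want <- oracle_count(lib)
  expect_equal(cs$counts$allCounts, want$allCounts)
  expect_equal(cs$counts$filteredCounts, want$filteredCounts)
  expect_equal(cs$counts$allCountsMulti, want$allCountsMulti)
  expect_equal(cs$counts$filteredCountsMulti, want$filteredCountsMulti)
})

test_that("filtered <= all; unflagging all duplicates makes tiers equal", {
  spec <- sim_spec(n_genes = 15, n_reads = 3000, seed = 77)
  lib <- mark_duplicates(pcr_amplify(simulate_library(spec), f = 0.5, seed = 6))
  sam <- tempfile(fileext = ".sam")
  write_sam(lib, sam)
  cs <- count_bam(sam, lib$models)
  expect_true(all(cs$counts$filteredCounts <= cs$counts$allCounts))
  expect_true(all(cs$counts$filteredCountsMulti <= cs$counts$allCountsMulti))
  expect_true(all(cs$counts$allCounts <= cs$counts$allCountsMulti))

  lib$reads$dup <- FALSE
  write_sam(lib, sam)
  cs2 <- count_bam(sam, lib$models)
  expect_equal(cs2$counts$filteredCounts, cs2$counts$allCounts)
  expect_equal(cs2$counts$filteredCountsMulti, cs2$counts$allCountsMulti)
  # duplicate flags do not change the unfiltered tiers
  expect_equal(cs2$counts$allCounts, cs$counts$allCounts)
})

test_that("counting is invariant to record order (single-end)", {
  spec <- sim_spec(n_genes = 10, n_reads = 1500, seed = 9)
  lib <- mark_duplicates(pcr_amplify(simulate_library(spec), f = 0.6, seed = 2))
  sam <- tempfile(fileext = ".sam")
  write_sam(lib, sam)
  cs1 <- count_bam(sam, lib$models)
  set.seed(1)
  lib$reads <- lib$reads[sample.int(nrow(lib$reads)), ]
  write_sam(lib, sam)
  cs2 <- count_bam(sam, lib$models)
  expect_equal(cs1$counts, cs2$counts)
})

test_that("paired-end fragments count once, with OR-combined duplicate status", {
  gm <- read_gene_models(simple_gtf())
  # one proper pair inside GA; one pair with only mate 1 duplicate-flagged
  recs <- data.frame(
    qname = c("p1", "p1", "p2", "p2"),
    flag = c(1L + 2L + 64L, 1L + 2L + 128L + 16L,
             1L + 2L + 64L + 1024L, 1L + 2L + 128L + 16L),
    chrom = "chrT",
    pos = c(1101L, 1201L, 1301L, 1401L),
    cigar = "50M",
    rnext = "=", pnext = c(1201L, 1101L, 1401L, 1301L),
    tlen = c(150L, -150L, 150L, -150L))
  sam <- write_test_sam(recs)
  cs <- count_bam(sam, gm, paired = TRUE)
  ga <- cs$counts[cs$counts$gene_id == "GA", ]
  expect_equal(ga$allCounts, 2L)       # two fragments, not four reads
  expect_equal(ga$filteredCounts, 1L)  # p2 duplicate by either-mate rule
  expect_equal(unname(cs$stats["units"]), 2L)
})

test_that("paired mode warns on unpaired records and counts them as singles", {
  gm <- read_gene_models(simple_gtf())
  sam <- write_test_sam(data.frame(
    qname = "solo", flag = 0L, chrom = "chrT", pos = 1101L, cigar = "50M"))
  expect_warning(cs <- count_bam(sam, gm, paired = TRUE), "paired")
  expect_equal(cs$counts$allCounts[cs$counts$gene_id == "GA"], 1L)
})

test_that("empty and all-unmapped inputs give all-zero counts", {
  gm <- read_gene_models(simple_gtf())
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:chrT\tLN:200000"), sam)
  cs <- count_bam(sam, gm)
  expect_true(all(cs$counts$allCountsMulti == 0L))
  expect_equal(unname(cs$stats["units"]), 0L)
})
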