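# Shared fixtures: published-style 10-gene example table, GTF/SAM builders,
# and the brute-force counting oracle used for equivalence checks.

# 10-gene worked example (printed values frozen at 2-decimal formatting).
# librarySize implied by the printed RPK/RPKM pairs is ~2.07e7, so RPKM of
# this 10-gene excerpt is not reproducible from the excerpt alone; dupRate,
# dupsPerId and RPK are.
table1_fixture <- function() {
  data.frame(
    gene_id = c("LOC100288069", "LINC00115", "LOC643837", "FAM41C",
                "LOC100130417", "SAMD11", "NOC2L", "KLHL17", "ISG15", "AGRN"),
    geneLength = c(1371, 1317, 9233, 1706, 496, 2554, 2800, 2564, 666, 7326),
    allCounts = c(17, 28, 281, 1, 0, 0, 329, 2, 590, 3),
    filteredCounts = c(15, 28, 246, 1, 0, 0, 273, 2, 271, 3),
    dupRate_printed = c("0.12", "0.00", "0.12", "0.00", "NA", "NA",
                        "0.17", "0.00", "0.54", "0.00"),
    dupsPerId_printed = c(2, 0, 35, 0, 0, 0, 56, 0, 319, 0),
    RPK_printed = c("12.40", "21.26", "30.43", "0.59", "0.00", "0.00",
                    "117.50", "0.78", "885.89", "0.41"),
    RPKM_printed = c("0.60", "1.03", "1.47", "0.03", "0.00", "0.00",
                     "5.67", "0.04", "42.78", "0.02"),
    stringsAsFactors = FALSE
  )
}

# GTF with one gene per fixture row, exons summing to the fixture lengths
# (two overlapping transcripts for the first gene to exercise exon merging).
write_table1_gtf <- function(path = tempfile(fileext = ".gtf")) {
  fx <- table1_fixture()
  lines <- character(0)
  cursor <- 1000L
  for (i in seq_len(nrow(fx))) {
    len <- fx$geneLength[i]
    w1 <- len %/% 2
    w2 <- len - w1
    s1 <- cursor
    e1 <- s1 + w1 - 1L
    s2 <- e1 + 501L
    e2 <- s2 + w2 - 1L
    attr <- sprintf('gene_id "%s"; transcript_id "%s.t1";',
                    fx$gene_id[i], fx$gene_id[i])
    lines <- c(lines,
      sprintf("chrT\thavana\texon\t%d\t%d\t.\t+\t.\t%s", s1, e1, attr),
      sprintf("chrT\thavana\texon\t%d\t%d\t.\t+\t.\t%s", s2, e2, attr))
    if (i == 1L) {  # second transcript overlapping the first exon
      attr2 <- sub("t1", "t2", attr)
      lines <- c(lines,
        sprintf("chrT\thavana\texon\t%d\t%d\t.\t+\t.\t%s",
                s1, min(e1, s1 + 99L), attr2))
    }
    cursor <- e2 + 2000L
  }
  writeLines(lines, path)
  path
}

# Hand-built SAM: `recs` is a data.frame with qname, flag, chrom, pos (1-based),
# cigar, and optional rnext/pnext/tlen/nh columns.
write_test_sam <- function(recs, sq = c(chrT = 200000L),
                           path = tempfile(fileext = ".sam")) {
  n <- nrow(recs)
  rnext <- recs$rnext %||% rep("*", n)
  pnext <- recs$pnext %||% rep(0L, n)
  tlen <- recs$tlen %||% rep(0L, n)
  nh <- recs$nh %||% rep(1L, n)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), as.integer(sq)))
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t%s\t%d\t%d\t*\t*\tNH:i:%d",
                  recs$qname, recs$flag, recs$chrom, recs$pos, recs$cigar,
                  rnext, as.integer(pnext), as.integer(tlen), as.integer(nh))
  writeLines(c(hdr, body), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force counting oracle over a sim_library's ground-truth read table:
# a per-unit loop with a linear overlap scan over gene exons, independent of
# the GenomicRanges-based counting path. Returns the four per-gene tiers in
# model order.
oracle_count <- function(lib, strandedness = 0, paired = FALSE) {
  models <- lib$models
  reads <- lib$reads[!lib$reads$secondary, , drop = FALSE]
  exons <- lapply(models$exons, function(g)
    data.frame(start = GenomicRanges::start(g) - 1L,
               end = GenomicRanges::end(g)))
  gstrand <- models$genes$strand
  gids <- models$genes$gene_id
  ng <- length(gids)

  # units: rows grouped by qname (paired) or one row each (single-end)
  if (paired) {
    uq <- unique(reads$qname)
    uf <- match(reads$qname, uq)
  } else {
    uq <- reads$qname
    uf <- seq_len(nrow(reads))
  }
  nu <- length(uq)
  bs <- reads$pos
  be <- bs + reads$len

  # unit strand: the single read / first mate
  first_mate <- reads$mate %in% c(0L, 1L)
  ustr <- character(nu)
  ustr[uf[first_mate]] <- reads$strand[first_mate]
  no_fm <- ustr == ""             # stray second mates only
  if (any(no_fm)) ustr[uf][no_fm[uf]] <- reads$strand[no_fm[uf]]

  unit_dup <- as.logical(rowsum(as.integer(reads$dup), uf)[, 1] > 0)
  unit_uni <- as.logical(rowsum(as.integer(reads$NH > 1L), uf)[, 1] == 0)

  # per-gene linear scan over exons, vectorized over records
  hitmat <- matrix(FALSE, nrow = nu, ncol = ng)
  for (g in seq_len(ng)) {
    ex <- exons[[g]]
    rec_hit <- reads$chrom == models$genes$chrom[g]
    acc <- rep(FALSE, nrow(reads))
    for (e in seq_len(nrow(ex))) {
      acc <- acc | (bs < ex$end[e] & be > ex$start[e])
    }
    rec_hit <- rec_hit & acc
    uhit <- as.logical(rowsum(as.integer(rec_hit), uf)[, 1] > 0)
    if (strandedness != 0 && !gstrand[g] %in% c("*", ".")) {
      ok <- if (strandedness == 1) ustr == gstrand[g] else ustr != gstrand[g]
      uhit <- uhit & ok
    }
    hitmat[, g] <- uhit
  }
  ngenes_hit <- rowSums(hitmat)
  assigned <- ngenes_hit == 1L
  gene_of <- ifelse(assigned, max.col(hitmat, ties.method = "first"), NA)

  tally <- function(sel) tabulate(gene_of[assigned & sel], nbins = ng)
  data.frame(
    allCounts = tally(unit_uni),
    filteredCounts = tally(unit_uni & !unit_dup),
    allCountsMulti = tally(TRUE),
    filteredCountsMulti = tally(!unit_dup),
    row.names = gids
  )
}
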