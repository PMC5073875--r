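## Read counting against gene models: featureCounts-compatible union-overlap
## assignment at gene level, default parameters, with four count tiers per
## gene: (all vs duplicate-filtered) x (unique-only vs multi-mapper-included).

#' Read alignments from a BAM or SAM file
#'
#' Loads mapped records with the fields the counting layer needs: CIGAR-derived
#' reference blocks (M/=/X/D consume reference, N splits a read into separate
#' blocks, I/S/H/P do not consume reference), FLAG bits, MAPQ and the NH tag
#' (number of reported alignments; 1 when absent). SAM input is converted on
#' the fly via `Rsamtools::asBam`.
#'
#' @param path BAM or SAM file (extension decides; `.sam` is converted).
#' @return an object of class `alignments`: list with
#'   \describe{
#'     \item{gal}{`GAlignments` of all mapped records (primary, secondary and
#'       supplementary; unmapped records are excluded) with metadata columns
#'       `qname`, `flag`, `mapq`, `NH`, and derived logicals `is_duplicate`,
#'       `is_secondary`, `is_supplementary`, `is_paired`, `is_proper_pair`,
#'       `is_first_mate`.}
#'     \item{n_unmapped}{number of unmapped records in the file.}
#'   }
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- tryCatch(
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("failed to parse SAM '", path, "': ",
                               conditionMessage(e))
    )
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq"), tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  gal <- tryCatch(
    GenomicAlignments::readGAlignments(bam, param = param),
    error = function(e) stop("failed to read alignments from '", path, "': ",
                             conditionMessage(e))
  )
  mc <- S4Vectors::mcols(gal)
  nh <- mc$NH
  nh[is.na(nh)] <- 1L
  if (any(nh < 1L)) stop("invalid NH tag (< 1) in ", path)
  mc$NH <- nh
  fl <- mc$flag
  mc$is_duplicate     <- bitwAnd(fl, 0x400L) > 0L
  mc$is_secondary     <- bitwAnd(fl, 0x100L) > 0L
  mc$is_supplementary <- bitwAnd(fl, 0x800L) > 0L
  mc$is_paired        <- bitwAnd(fl, 0x1L)   > 0L
  mc$is_proper_pair   <- bitwAnd(fl, 0x2L)   > 0L
  mc$is_first_mate    <- bitwAnd(fl, 0x40L)  > 0L
  S4Vectors::mcols(gal) <- mc
  n_unmapped <- Rsamtools::countBam(
    bam, param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE)))$records
  structure(list(gal = gal, n_unmapped = n_unmapped, path = path),
            class = "alignments")
}

#' @export
print.alignments <- function(x, ...) {
  cat("alignments:", length(x$gal), "mapped records (",
      x$n_unmapped, "unmapped ) from", x$path, "\n")
  invisible(x)
}

#' Assign a counting unit to a gene
#'
#' Implements the featureCounts default gene-level rule: a unit is assigned to
#' a gene iff exactly one gene's merged exons overlap any of the unit's blocks
#' by at least one base (after the strandedness filter); overlaps with more
#' than one gene make the unit ambiguous and it is discarded.
#'
#' @param blocks data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) -- the unit's aligned reference blocks.
#' @param strand read orientation, `"+"` or `"-"`.
#' @param index a `gene_index`.
#' @param strandedness 0 (unstranded), 1 (stranded: read strand must equal
#'   gene strand) or 2 (reversely stranded), mirroring featureCounts `-s`.
#' @return the assigned gene id, or `"AMBIGUOUS"`, or `"NO_FEATURE"`.
#' @export
assign_unit <- function(blocks, strand, index, strandedness = 0) {
  stopifnot(nrow(blocks) > 0)
  hits <- unique(unlist(lapply(seq_len(nrow(blocks)), function(i) {
    query_index(index, blocks$chrom[i], blocks$start[i], blocks$end[i])
  })))
  if (strandedness != 0 && length(hits)) {
    gs <- index$genes$strand[match(hits, index$genes$gene_id)]
    want <- if (strandedness == 1) strand else setdiff(c("+", "-"), strand)
    hits <- hits[gs == want | gs == "*" | gs == "."]
  }
  if (length(hits) == 0L) "NO_FEATURE"
  else if (length(hits) > 1L) "AMBIGUOUS"
  else hits
}

## Internal: strand-compatibility filter on a Hits object between counting
## units and genes. `unit_strand`/`gene_strand` are character vectors.
strand_compatible <- function(unit_strand, gene_strand, strandedness) {
  if (strandedness == 0) return(rep(TRUE, length(unit_strand)))
  same <- unit_strand == gene_strand
  any_strand <- gene_strand == "*" | gene_strand == "."
  if (strandedness == 1) same | any_strand else (!same) | any_strand
}

#' Count reads per gene from a duplicate-marked alignment file
#'
#' Produces the four per-gene count tiers the duplication-rate profile is
#' built from:
#' \describe{
#'   \item{allCounts}{uniquely mapping units (NH == 1), duplicates included.}
#'   \item{filteredCounts}{uniquely mapping units not flagged as duplicates.}
#'   \item{allCountsMulti}{all units including multi-mappers (counted once,
#'     on their primary alignment), duplicates included.}
#'   \item{filteredCountsMulti}{as above, duplicate-flagged units removed.}
#' }
#'
#' The counting unit is a read (single-end) or a fragment/template
#' (paired-end: the two mates' blocks are combined and the fragment is counted
#' once; a fragment is a duplicate if either mate carries FLAG 0x400).
#' Secondary (0x100) and supplementary (0x800) records are never counted; NH
#' is used only to separate the unique tier.
#'
#' @param x an `alignments` object or a path to a BAM/SAM file.
#' @param models a `gene_models` object (or prebuilt `gene_index`).
#' @param strandedness 0/1/2 as in [assign_unit()].
#' @param paired logical; count fragments instead of reads. Records without
#'   the paired FLAG in paired mode are counted as single units with a
#'   warning.
#' @param min_mapq minimum MAPQ for a record to be counted (default 0).
#' @return object of class `count_set`: list with
#'   \describe{
#'     \item{counts}{data.frame `gene_id`, `allCounts`, `filteredCounts`,
#'       `allCountsMulti`, `filteredCountsMulti`, one row per annotated gene
#'       in annotation order (zero rows included).}
#'     \item{stats}{named vector: `assigned`, `ambiguous`, `no_feature`,
#'       `unmapped`, `secondary_skipped`, `supplementary_skipped`,
#'       `mapq_skipped`, `units`.}
#'   }
#' @export
count_bam <- function(x, models, strandedness = 0, paired = FALSE,
                      min_mapq = 0) {
  stopifnot(strandedness %in% 0:2)
  aln <- if (inherits(x, "alignments")) x else read_alignments(x)
  index <- if (inherits(models, "gene_index")) models else build_index(models)
  genes <- index$genes
  gal <- aln$gal
  mc <- S4Vectors::mcols(gal)

  sec_skip <- sum(mc$is_secondary)
  sup_skip <- sum(mc$is_supplementary)
  keep <- !mc$is_secondary & !mc$is_supplementary
  mapq_skip <- sum(keep & !is.na(mc$mapq) & mc$mapq < min_mapq)
  keep <- keep & (is.na(mc$mapq) | mc$mapq >= min_mapq)
  gal <- gal[keep]
  mc <- S4Vectors::mcols(gal)

  blocks <- GenomicAlignments::grglist(gal)   # N-split reference blocks
  rstrand <- as.character(GenomicAlignments::strand(gal))

  if (paired) {
    is_p <- mc$is_paired
    if (any(!is_p)) {
      warning(sum(!is_p), " record(s) without the paired flag in paired ",
              "mode; counted as single-end units")
    }
    # fragment id: qname for paired records, qname+mate-slot for strays
    unit_key <- ifelse(is_p, mc$qname, paste0(mc$qname, "\r", seq_along(gal)))
    uf <- factor(unit_key, levels = unique(unit_key))
    ublocks <- unlist(blocks)
    ublocks_unit <- rep(as.integer(uf), times = S4Vectors::elementNROWS(blocks))
    unit_blocks <- S4Vectors::split(
      ublocks, factor(ublocks_unit, levels = seq_len(nlevels(uf))))
    first <- !duplicated(uf)
    # unit strand: orientation of the first mate where present, else the
    # first record of the unit
    strand_src <- ifelse(mc$is_first_mate | !is_p, rstrand, NA_character_)
    ustrand <- tapply(strand_src, uf, function(s) {
      s <- s[!is.na(s)]; if (length(s)) s[1L] else "+"
    })
    ustrand <- as.character(ustrand)
    unit_nh  <- tapply(mc$NH, uf, max)
    unit_dup <- tapply(mc$is_duplicate, uf, any)   # OR over mates
    n_units <- nlevels(uf)
  } else {
    unit_blocks <- blocks
    ublocks_unit <- seq_along(gal)
    ustrand <- rstrand
    unit_nh <- mc$NH
    unit_dup <- mc$is_duplicate
    n_units <- length(gal)
  }

  if (n_units == 0L) {
    counts <- data.frame(gene_id = genes$gene_id,
                         allCounts = 0L, filteredCounts = 0L,
                         allCountsMulti = 0L, filteredCountsMulti = 0L)
    stats <- c(assigned = 0L, ambiguous = 0L, no_feature = 0L,
               unmapped = aln$n_unmapped, secondary_skipped = sec_skip,
               supplementary_skipped = sup_skip, mapq_skipped = mapq_skip,
               units = 0L)
    return(structure(list(counts = counts, stats = stats),
                     class = "count_set"))
  }

  # overlap any block of a unit with any merged exon, >= 1 bp
  flat <- if (paired) unlist(unit_blocks) else unlist(blocks)
  flat_unit <- if (paired) {
    rep(seq_len(n_units), times = S4Vectors::elementNROWS(unit_blocks))
  } else {
    rep(ublocks_unit, times = S4Vectors::elementNROWS(blocks))
  }
  hits <- GenomicRanges::findOverlaps(flat, index$exons, ignore.strand = TRUE)
  hu <- flat_unit[S4Vectors::queryHits(hits)]
  hg <- match(index$gene_of_exon[S4Vectors::subjectHits(hits)], genes$gene_id)
  ok <- strand_compatible(ustrand[hu], genes$strand[hg], strandedness)
  hu <- hu[ok]; hg <- hg[ok]
  pair_key <- !duplicated(hu * (nrow(genes) + 1) + hg)  # distinct (unit, gene)
  hu <- hu[pair_key]; hg <- hg[pair_key]

  genes_per_unit <- tabulate(hu, nbins = n_units)
  assigned_units <- which(genes_per_unit == 1L)
  sel <- hu %in% assigned_units
  au <- hu[sel]; ag <- hg[sel]

  ng <- nrow(genes)
  tally <- function(which_units) tabulate(ag[au %in% which_units], nbins = ng)
  is_uni <- unit_nh == 1L
  all_multi  <- tabulate(ag, nbins = ng)
  filt_multi <- tally(assigned_units[!unit_dup[assigned_units]])
  all_uni    <- tally(assigned_units[is_uni[assigned_units]])
  filt_uni   <- tally(assigned_units[is_uni[assigned_units] &
                                     !unit_dup[assigned_units]])

  counts <- data.frame(gene_id = genes$gene_id,
                       allCounts = all_uni, filteredCounts = filt_uni,
                       allCountsMulti = all_multi,
                       filteredCountsMulti = filt_multi)
  stats <- c(assigned = length(assigned_units),
             ambiguous = sum(genes_per_unit > 1L),
             no_feature = sum(genes_per_unit == 0L),
             unmapped = aln$n_unmapped,
             secondary_skipped = sec_skip,
             supplementary_skipped = sup_skip,
             mapq_skipped = mapq_skip,
             units = n_units)
  structure(list(counts = counts, stats = stats), class = "count_set")
}

#' @export
print.count_set <- function(x, ...) {
  cat("count_set:", nrow(x$counts), "genes;",
      x$stats["assigned"], "assigned,",
      x$stats["ambiguous"], "ambiguous,",
      x$stats["no_feature"], "unassigned units\n")
  invisible(x)
}

#' Write a counting summary report
#'
#' @param countset a `count_set`.
#' @param path output TSV path (`category <tab> count`).
#' @return invisibly, the path.
#' @export
write_count_report <- function(countset, path) {
  stopifnot(inherits(countset, "count_set"))
  df <- data.frame(category = names(countset$stats),
                   count = as.integer(countset$stats))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
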