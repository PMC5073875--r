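#' Merge genomic intervals into a minimal disjoint cover
#'
#' Collapses a set of intervals on one chromosome into the minimal sorted set
#' of disjoint, non-adjacent intervals covering the same bases. Adjacent
#' intervals (`end` of one equals `start` of the next) are merged, so each
#' exonic base is represented exactly once -- the property gene length
#' calculations rely on.
#'
#' Coordinates are 0-based half-open throughout the package: an interval
#' covers positions `start, ..., end - 1` and has width `end - start`.
#'
#' @param intervals data.frame with integer columns `start` and `end`
#'   (0-based half-open, `start < end`).
#' @return data.frame with columns `start`, `end`, sorted by `start`,
#'   pairwise disjoint and non-adjacent. Empty input gives an empty frame.
#' @examples
#' merge_intervals(data.frame(start = c(0, 5), end = c(10, 15)))
#' @export
merge_intervals <- function(intervals) {
  stopifnot(is.data.frame(intervals), all(c("start", "end") %in% names(intervals)))
  if (nrow(intervals) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  if (any(intervals$start >= intervals$end)) {
    stop("invalid interval: 'start' must be < 'end' (0-based half-open)")
  }
  # IRanges is 1-based closed: [start+1, end]
  ir <- IRanges::reduce(IRanges::IRanges(intervals$start + 1L, intervals$end))
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

## Internal: light pre-validation so malformed GTF lines are reported with a
## line number before handing the file to rtracklayer.
validate_gtf_lines <- function(path, max_lines = Inf) {
  con <- file(path, "r")
  on.exit(close(con))
  i <- 0L
  repeat {
    chunk <- readLines(con, n = 10000L)
    if (length(chunk) == 0L) break
    for (ln in chunk) {
      i <- i + 1L
      if (i > max_lines) return(invisible(TRUE))
      if (!nzchar(ln) || startsWith(ln, "#")) next
      nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1L]])
      if (nf < 9L) {
        stop(sprintf("malformed GTF line %d: expected >= 9 tab-separated fields, got %d", i, nf))
      }
    }
  }
  invisible(TRUE)
}

#' Read gene models from a GTF annotation
#'
#' Parses a GTF file, selects features of one type (exons by default), groups
#' them by a grouping attribute (`gene_id` by default) and merges the exons of
#' all transcripts of each gene into a disjoint exon set. The resulting gene
#' length is the number of distinct exonic bases, matching the
#' featureCounts definition. Both quoted (`gene_id "X";`) and unquoted
#' attribute dialects are accepted.
#'
#' Genes whose features span several chromosomes or strands (annotation
#' pathologies) are reduced, with a warning, to the chromosome/strand
#' combination holding the most exonic bases.
#'
#' @param path path to a GTF file. GTF coordinates are 1-based inclusive and
#'   are converted to the package-internal 0-based half-open convention.
#' @param feature feature type to select from column 3 (default `"exon"`),
#'   mirroring featureCounts `-t`.
#' @param attribute grouping attribute (default `"gene_id"`), mirroring
#'   featureCounts `-g`.
#' @return an object of class `gene_models`: a list with
#'   \describe{
#'     \item{exons}{named `GRangesList`, one element per gene, reduced
#'       (disjoint, sorted) exon ranges.}
#'     \item{genes}{data.frame with `gene_id`, `chrom`, `strand`, `length`
#'       (bp of merged exons), in annotation order of first appearance.}
#'   }
#' @export
read_gene_models <- function(path, feature = "exon", attribute = "gene_id") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  validate_gtf_lines(path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("failed to parse GTF '", path, "': ", conditionMessage(e))
  )
  gr <- gr[S4Vectors::mcols(gr)$type == feature]
  if (length(gr) == 0L) {
    stop("empty annotation: no '", feature, "' features found in ", path)
  }
  if (!attribute %in% names(S4Vectors::mcols(gr))) {
    stop("attribute '", attribute, "' not present on '", feature, "' features")
  }
  ids <- as.character(S4Vectors::mcols(gr)[[attribute]])
  if (anyNA(ids)) {
    stop("attribute '", attribute, "' missing on ",
         sum(is.na(ids)), " '", feature, "' feature(s)")
  }
  gene_models_from_granges(gr, ids)
}

## Internal constructor shared by the GTF reader and the simulator.
## `gr` carries one range per exon feature; `ids` the grouping id per range.
gene_models_from_granges <- function(gr, ids) {
  ord_ids <- unique(ids)
  ch <- as.character(GenomicRanges::seqnames(gr))
  st <- as.character(GenomicRanges::strand(gr))

  # Resolve genes annotated on several chromosomes or strands: keep the
  # chromosome+strand combination carrying most exonic bases.
  combo_first <- !duplicated(paste(ids, ch, st, sep = "\r"))
  n_combo <- table(factor(ids[combo_first], levels = ord_ids))
  bad_ids <- ord_ids[n_combo > 1L]
  if (length(bad_ids)) {
    warning("gene(s) spanning multiple chromosomes/strands reduced to the ",
            "majority combination: ", paste(bad_ids, collapse = ", "))
    drop <- logical(length(gr))
    w <- GenomicRanges::width(gr)
    for (id in bad_ids) {
      rows <- which(ids == id)
      key <- paste(ch[rows], st[rows])
      bases <- tapply(w[rows], key, sum)
      drop[rows[key != names(bases)[which.max(bases)]]] <- TRUE
    }
    gr <- gr[!drop]; ids <- ids[!drop]
    ch <- ch[!drop]; st <- st[!drop]
  }

  grl <- GenomicRanges::reduce(S4Vectors::split(gr, factor(ids, levels = ord_ids)))
  flat <- unlist(grl, use.names = FALSE)
  gidx <- rep(seq_along(grl), times = S4Vectors::elementNROWS(grl))
  first <- !duplicated(gidx)
  info <- data.frame(
    gene_id = ord_ids,
    chrom = as.character(GenomicRanges::seqnames(flat))[first],
    strand = as.character(GenomicRanges::strand(flat))[first],
    length = as.numeric(rowsum(GenomicRanges::width(flat), gidx)[, 1L]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(exons = grl, genes = info), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  cat("  total merged-exon length:", sum(x$genes$length), "bp\n")
  invisible(x)
}

#' Gene lengths of a gene_models object
#'
#' @param models a `gene_models` object.
#' @return named numeric vector of merged-exon lengths (bp).
#' @export
gene_lengths <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  stats::setNames(models$genes$length, models$genes$gene_id)
}

#' Build an overlap index over gene models
#'
#' Flattens the merged exons of all genes into one indexed structure that
#' answers interval overlap queries, returning exactly the genes whose merged
#' exons overlap a query interval (identical to a linear scan over all genes).
#'
#' @param models a `gene_models` object.
#' @return an object of class `gene_index`.
#' @export
build_index <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  if (anyDuplicated(models$genes$gene_id)) {
    stop("duplicate gene_id in models: ",
         paste(unique(models$genes$gene_id[duplicated(models$genes$gene_id)]),
               collapse = ", "))
  }
  flat <- unlist(models$exons, use.names = FALSE)
  gene_of_exon <- rep(models$genes$gene_id,
                      times = S4Vectors::elementNROWS(models$exons))
  structure(list(exons = flat, gene_of_exon = gene_of_exon,
                 genes = models$genes, exons_by_gene = models$exons),
            class = "gene_index")
}

#' Query a gene index for overlapping genes
#'
#' @param index a `gene_index` from [build_index()].
#' @param chrom chromosome name.
#' @param start,end query interval, 0-based half-open.
#' @return character vector of gene ids whose merged exons overlap the query
#'   by at least one base (strand is ignored at this level; strand-aware
#'   filtering happens during read assignment).
#' @export
query_index <- function(index, chrom, start, end) {
  stopifnot(inherits(index, "gene_index"), start < end)
  if (!chrom %in% GenomicRanges::seqnames(GenomicRanges::seqinfo(index$exons))) {
    return(character(0))
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  hits <- GenomicRanges::findOverlaps(q, index$exons, ignore.strand = TRUE)
  unique(index$gene_of_exon[S4Vectors::subjectHits(hits)])
}
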