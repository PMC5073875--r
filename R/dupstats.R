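## Per-gene duplication-rate statistics: turn count tiers and gene lengths
## into the duplication-rate matrix consumed by the fit and the plots.

#' Per-gene duplication rate
#'
#' `dupRate = (allCounts - filteredCounts) / allCounts`, the fraction of a
#' gene's reads flagged as duplicates. Undefined (NA) for genes without reads.
#'
#' @param allCounts,filteredCounts non-negative integer vectors,
#'   `filteredCounts <= allCounts` element-wise.
#' @return numeric vector in \[0, 1\], NA where `allCounts == 0`.
#' @export
dup_rate <- function(allCounts, filteredCounts) {
  if (any(filteredCounts > allCounts)) {
    stop("invariant violation: filteredCounts > allCounts")
  }
  if (any(allCounts < 0 | filteredCounts < 0)) stop("negative counts")
  ifelse(allCounts == 0, NA_real_, (allCounts - filteredCounts) / allCounts)
}

#' Reads per kilobase of merged-exon gene model
#'
#' `RPK = allCounts / (geneLength / 1000)`, the package's proxy for relative
#' gene expression. At RPK = 1000 a gene carries one read per exonic base,
#' the level beyond which read duplication is unavoidable.
#'
#' @param allCounts read counts per gene.
#' @param geneLength merged-exon gene length in bp (must be >= 1).
#' @return numeric vector of RPK values.
#' @export
rpk <- function(allCounts, geneLength) {
  if (any(geneLength < 1)) stop("geneLength must be >= 1 bp")
  allCounts / (geneLength / 1000)
}

#' RPK scaled per million library reads
#'
#' @param rpk_value RPK values from [rpk()].
#' @param librarySize total counted reads of the library (> 0); the package
#'   uses the sum of per-gene assigned counts of the corresponding tier.
#' @return numeric vector of RPKM values.
#' @export
rpkm <- function(rpk_value, librarySize) {
  if (librarySize <= 0) stop("librarySize must be > 0")
  rpk_value / (librarySize / 1e6)
}

#' Build the per-gene duplication-rate table
#'
#' One row per annotated gene (zero-count genes included), in annotation
#' order, with the full statistics for both tiers: the multi-mapper-included
#' tier first, then the unique-read tier. Values are stored at full precision;
#' rounding happens only when printing or writing.
#'
#' @param counts a `count_set` from [count_bam()], or a data.frame with
#'   columns `gene_id`, `allCounts`, `filteredCounts` (and optionally
#'   `allCountsMulti`, `filteredCountsMulti`; they default to the unique
#'   tier) -- the entry point for precomputed count tables.
#' @param models a `gene_models` object, or a named numeric vector of gene
#'   lengths (bp) covering every gene in `counts`.
#' @return data.frame of class `duprate_table` with columns `ID`,
#'   `geneLength`, `allCountsMulti`, `filteredCountsMulti`, `dupRateMulti`,
#'   `dupsPerIdMulti`, `RPKMulti`, `RPKMMulti`, `allCounts`,
#'   `filteredCounts`, `dupRate`, `dupsPerId`, `RPK`, `RPKM`.
#' @export
build_duprate_table <- function(counts, models) {
  cdf <- if (inherits(counts, "count_set")) counts$counts else counts
  stopifnot(is.data.frame(cdf),
            all(c("gene_id", "allCounts", "filteredCounts") %in% names(cdf)))
  if (is.null(cdf$allCountsMulti)) cdf$allCountsMulti <- cdf$allCounts
  if (is.null(cdf$filteredCountsMulti)) {
    cdf$filteredCountsMulti <- cdf$filteredCounts
  }
  lens <- if (inherits(models, "gene_models")) gene_lengths(models) else models
  missing <- setdiff(cdf$gene_id, names(lens))
  if (length(missing)) {
    stop("no gene length for: ", paste(missing, collapse = ", "))
  }
  len <- unname(lens[match(cdf$gene_id, names(lens))])

  lib_uni   <- sum(cdf$allCounts)
  lib_multi <- sum(cdf$allCountsMulti)
  rpk_uni   <- rpk(cdf$allCounts, len)
  rpk_multi <- rpk(cdf$allCountsMulti, len)

  tab <- data.frame(
    ID = cdf$gene_id,
    geneLength = len,
    allCountsMulti = cdf$allCountsMulti,
    filteredCountsMulti = cdf$filteredCountsMulti,
    dupRateMulti = dup_rate(cdf$allCountsMulti, cdf$filteredCountsMulti),
    dupsPerIdMulti = cdf$allCountsMulti - cdf$filteredCountsMulti,
    RPKMulti = rpk_multi,
    RPKMMulti = if (lib_multi > 0) rpkm(rpk_multi, lib_multi) else 0 * rpk_multi,
    allCounts = cdf$allCounts,
    filteredCounts = cdf$filteredCounts,
    dupRate = dup_rate(cdf$allCounts, cdf$filteredCounts),
    dupsPerId = cdf$allCounts - cdf$filteredCounts,
    RPK = rpk_uni,
    RPKM = if (lib_uni > 0) rpkm(rpk_uni, lib_uni) else 0 * rpk_uni,
    stringsAsFactors = FALSE
  )
  class(tab) <- c("duprate_table", "data.frame")
  tab
}

#' Write a duplication-rate table to TSV
#'
#' Values are written at full precision; undefined duplication rates appear
#' as `NA`. An optional fit summary is prepended as `#`-comment lines so one
#' file carries both the matrix and the model.
#'
#' @param tab a `duprate_table`.
#' @param path output path; the file is written to a temporary sibling and
#'   renamed into place, so no partial file is left on failure.
#' @param fit optional `duprate_fit` whose summary is embedded as comments.
#' @return invisibly, the path.
#' @export
write_duprate_table <- function(tab, path, fit = NULL) {
  stopifnot(inherits(tab, "duprate_table"))
  tmp <- paste0(path, ".tmp", Sys.getpid())
  con <- file(tmp, "w")
  ok <- FALSE
  on.exit({
    close(con)
    if (ok) file.rename(tmp, path) else unlink(tmp)
  })
  if (!is.null(fit)) {
    writeLines(paste0("# ", c(
      sprintf("intercept=%.10g", fit$intercept),
      sprintf("slope=%.10g", fit$slope),
      sprintf("baseline=%.10g", fit$baseline),
      sprintf("n_genes_used=%d", fit$n_genes_used),
      sprintf("converged=%s", tolower(as.character(fit$converged)))
    )), con)
  }
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  ok <- TRUE
  invisible(path)
}

#' Read a duplication-rate table written by [write_duprate_table()]
#'
#' @param path TSV path; `#`-comment header lines are skipped.
#' @return a `duprate_table` data.frame.
#' @export
read_duprate_table <- function(path) {
  if (!file.exists(path)) stop("table file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           na.strings = "NA", stringsAsFactors = FALSE)
  need <- c("ID", "geneLength", "allCounts", "filteredCounts")
  if (!all(need %in% names(tab))) {
    stop("malformed duplication-rate table '", path, "': missing column(s) ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  class(tab) <- c("duprate_table", "data.frame")
  tab
}

#' Format a duplication-rate table the way it is reported
#'
#' Rounds rate and expression columns to 2 decimals for display; counts stay
#' integer. Used by the print method and by tests against published-style
#' output; computation always uses the unrounded table.
#'
#' @param tab a `duprate_table`.
#' @return data.frame of character/integer columns, 2-decimal formatting.
#' @export
format_duprate_table <- function(tab) {
  out <- as.data.frame(tab)
  twodp <- intersect(c("dupRateMulti", "RPKMulti", "RPKMMulti",
                       "dupRate", "RPK", "RPKM"), names(out))
  for (cn in twodp) {
    out[[cn]] <- ifelse(is.na(out[[cn]]), "NA", sprintf("%.2f", out[[cn]]))
  }
  out
}

#' @export
print.duprate_table <- function(x, ...) {
  cat("duprate_table:", nrow(x), "genes,",
      sum(x$allCounts), "assigned unique reads, overall dupRate",
      sprintf("%.3f", sum(x$dupsPerId) / max(1, sum(x$allCounts))), "\n")
  print(utils::head(format_duprate_table(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
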