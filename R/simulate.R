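## Synthetic duplicate-marked RNA-Seq libraries: gene-model generation, read
## placement proportional to expression, PCR amplification by subsample +
## Poisson re-amplification, and a coordinate-based duplicate marker.

## Run `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Specify a synthetic RNA-Seq library
#'
#' Bundles the parameters of the synthetic-library generator. Per-gene
#' expression (expected RPK) is log-normal; reads are placed uniformly within
#' exons with per-gene counts proportional to expression x length. Defaults
#' emulate a small bulk RNA-Seq experiment: a few hundred genes spanning the
#' typical protein-coding length range, ~4 decades of expression, 50 bp
#' single-end reads, a few percent of intergenic and multi-mapping reads.
#'
#' @param n_genes number of genes (default 200).
#' @param gene_length_range min/max merged-exon gene length in bp
#'   (default c(500, 5000)).
#' @param expr_meanlog,expr_sdlog log-normal parameters of per-gene expected
#'   RPK (defaults `log(50)` and 1.2, i.e. a median of 50 RPK with most genes
#'   between ~2 and ~1000 RPK).
#' @param n_reads total reads N in the library (default 1e5).
#' @param read_length read length in bp (default 50).
#' @param exons_per_gene min/max exons per gene (default c(1, 3); introns of
#'   100--2000 bp are inserted between exons).
#' @param frac_intergenic fraction of reads placed between genes, exercising
#'   unassigned counting (default 0.03).
#' @param frac_multimap fraction of gene reads given NH = 2 with a secondary
#'   alignment elsewhere (default 0.02).
#' @param paired generate paired-end fragments (two mates per unit) instead
#'   of single-end reads (default FALSE).
#' @param stranded_protocol 0 = unstranded (read strand random), 1 = read
#'   strand equals gene strand, 2 = opposite (default 0).
#' @param unique_positions place every read at a distinct start coordinate
#'   (sampling exonic positions without replacement), so the pristine library
#'   contains no coordinate duplicates (default FALSE).
#' @param seed RNG seed (default 1).
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(n_genes = 200, gene_length_range = c(500, 5000),
                     expr_meanlog = log(50), expr_sdlog = 1.2,
                     n_reads = 1e5, read_length = 50,
                     exons_per_gene = c(1, 3),
                     frac_intergenic = 0.03, frac_multimap = 0.02,
                     paired = FALSE, stranded_protocol = 0,
                     unique_positions = FALSE, seed = 1) {
  stopifnot(n_genes >= 1, n_reads >= 1, read_length >= 1,
            length(gene_length_range) == 2,
            gene_length_range[1] <= gene_length_range[2],
            frac_intergenic >= 0, frac_intergenic < 1,
            frac_multimap >= 0, frac_multimap < 1,
            stranded_protocol %in% 0:2)
  structure(as.list(environment()), class = "sim_spec")
}

#' Generate a synthetic duplicate-marked-ready library
#'
#' Builds gene models laid out along two synthetic chromosomes and a read set
#' placed uniformly within exons, with per-gene read counts multinomial with
#' probabilities proportional to expression x gene length. Reads carry ground
#' truth: their template id and origin (`original` vs `pcr`); duplicate flags
#' start out all unset. Deterministic given the spec's seed.
#'
#' @param spec a [sim_spec()].
#' @return object of class `sim_library`: list with `models` (a
#'   `gene_models`), `expression` (named vector of drawn per-gene expected
#'   RPK), `reads` (data.frame: `qname`, `mate` (0 = single-end,
#'   1/2 = mate index), `chrom`, `pos` (0-based), `strand`, `len`,
#'   `NH`, `secondary`, `dup`, `origin`, `template`, `gene`),
#'   `chrom_lengths`, and `spec`.
#' @export
simulate_library <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    L <- spec$read_length
    M <- if (spec$paired) 3L * L else L   # placement margin: max unit span
    ng <- spec$n_genes

    # --- gene models on chr_sim1 / chr_sim2, sequential layout with gaps
    glen <- round(stats::runif(ng, spec$gene_length_range[1],
                               spec$gene_length_range[2]))
    nex <- sample(seq(spec$exons_per_gene[1], spec$exons_per_gene[2]),
                  ng, replace = TRUE)
    gstrand <- sample(c("+", "-"), ng, replace = TRUE)
    gchrom <- rep(c("chr_sim1", "chr_sim2"), length.out = ng)

    exon_chrom <- character(0); exon_start <- integer(0)
    exon_end <- integer(0); exon_gene <- character(0)
    gap <- 3000L
    cursor <- c(chr_sim1 = 1000L, chr_sim2 = 1000L)
    gene_ids <- sprintf("SIMG%04d", seq_len(ng))
    minw <- max(M, 150L)   # every exon can hold at least one unit
    if (min(glen) < minw) {
      stop("infeasible spec: unit span ", M,
           " bp exceeds the shortest gene (", min(glen), " bp)")
    }
    for (i in seq_len(ng)) {
      # split gene length into exon widths, each >= minw
      k <- max(1L, min(nex[i], glen[i] %/% minw))
      w <- minw + as.integer(stats::rmultinom(1, glen[i] - k * minw,
                                              rep(1, k)))
      introns <- if (k > 1) as.integer(round(stats::runif(k - 1L, 100, 2000)))
                 else integer(0)
      s <- cursor[[gchrom[i]]] + cumsum(c(0L, w[-k] + introns))
      exon_chrom <- c(exon_chrom, rep(gchrom[i], k))
      exon_start <- c(exon_start, s)
      exon_end <- c(exon_end, s + w)
      exon_gene <- c(exon_gene, rep(gene_ids[i], k))
      cursor[[gchrom[i]]] <- s[k] + w[k] + gap
    }
    gr <- GenomicRanges::GRanges(
      exon_chrom, IRanges::IRanges(exon_start + 1L, exon_end),
      strand = rep(gstrand, times = tabulate(match(exon_gene, gene_ids), ng))
    )
    models <- gene_models_from_granges(gr, exon_gene)
    chrom_lengths <- c(chr_sim1 = unname(cursor["chr_sim1"]) + 10000L,
                       chr_sim2 = unname(cursor["chr_sim2"]) + 10000L)

    # --- per-gene read counts: multinomial, p ~ expression * length
    exp_rpk <- stats::rlnorm(ng, spec$expr_meanlog, spec$expr_sdlog)
    n_genic <- round(spec$n_reads * (1 - spec$frac_intergenic))
    n_inter <- spec$n_reads - n_genic
    p <- exp_rpk * glen
    gcounts <- as.integer(stats::rmultinom(1, n_genic, p))

    # eligible start offsets per gene: positions where a read (or fragment)
    # fits entirely within one exon
    exon_by_gene <- split(data.frame(start = exon_start, end = exon_end,
                                     chrom = exon_chrom),
                          factor(exon_gene, levels = gene_ids))

    place <- function(i, n) {
      ex <- exon_by_gene[[i]]
      w <- ex$end - ex$start
      fit <- which(w >= M)
      if (length(fit) == 0L) {
        stop("infeasible spec: unit span ", M,
             " exceeds every exon of gene ", gene_ids[i])
      }
      elig <- w[fit] - M + 1L
      tot <- sum(elig)
      off <- if (spec$unique_positions) {
        if (n > tot) {
          stop("infeasible spec: cannot place ", n,
               " distinct reads in gene ", gene_ids[i],
               " (", tot, " eligible positions)")
        }
        sample.int(tot, n)
      } else {
        sample.int(tot, n, replace = TRUE)
      }
      ei <- findInterval(off - 1L, cumsum(c(0L, elig)),
                         rightmost.closed = FALSE)
      ex$start[fit[ei]] + (off - cumsum(c(0L, elig))[ei] - 1L)
    }

    pos <- integer(0); chrom <- character(0); gene <- character(0)
    for (i in seq_len(ng)) {
      if (gcounts[i] == 0L) next
      pos <- c(pos, place(i, gcounts[i]))
      chrom <- c(chrom, rep(gchrom[i], gcounts[i]))
      gene <- c(gene, rep(gene_ids[i], gcounts[i]))
    }
    rg <- rep(seq_len(ng), times = gcounts)
    strand <- switch(as.character(spec$stranded_protocol),
      "0" = sample(c("+", "-"), length(pos), replace = TRUE),
      "1" = gstrand[rg],
      "2" = ifelse(gstrand[rg] == "+", "-", "+"))

    # intergenic reads: in the upstream margin of each chromosome
    if (n_inter > 0L) {
      ic <- sample(names(chrom_lengths), n_inter, replace = TRUE)
      ip <- as.integer(floor(stats::runif(n_inter, 0, 900 - M)))
      pos <- c(pos, ip); chrom <- c(chrom, ic)
      gene <- c(gene, rep(NA_character_, n_inter))
      strand <- c(strand, sample(c("+", "-"), n_inter, replace = TRUE))
    }
    n <- length(pos)
    qname <- sprintf("simr%07d", seq_len(n))
    nh <- rep(1L, n)

    reads <- data.frame(
      qname = qname, mate = 0L, chrom = chrom, pos = pos, strand = strand,
      len = L, NH = nh, secondary = FALSE, dup = FALSE,
      origin = "original", template = qname, gene = gene,
      stringsAsFactors = FALSE
    )

    if (spec$paired) {
      # second mate at the far end of a fragment of up to 3 read lengths,
      # still inside the same exon by construction of the placement margin
      flen <- pmin(3L * L, pmax(L, L + as.integer(stats::rgeom(n, 1 / L))))
      m2 <- reads
      m2$mate <- 2L
      reads$mate <- 1L
      m2$pos <- reads$pos + flen - L
      m2$strand <- ifelse(reads$strand == "+", "-", "+")
      reads <- rbind(reads, m2)
      reads <- reads[order(match(reads$qname, qname), reads$mate), ]
      rownames(reads) <- NULL
    }

    # multi-mappers: NH = 2 on a fraction of genic units, secondary hit in
    # the intergenic margin
    if (spec$frac_multimap > 0) {
      genic_units <- unique(reads$qname[!is.na(reads$gene)])
      nm <- round(spec$frac_multimap * length(genic_units))
      if (nm > 0) {
        mm <- sample(genic_units, nm)
        reads$NH[reads$qname %in% mm] <- 2L
        sec <- reads[reads$qname %in% mm & reads$mate %in% c(0L, 1L), ]
        sec$secondary <- TRUE
        sec$mate <- 0L
        sec$chrom <- sample(names(chrom_lengths), nrow(sec), replace = TRUE)
        sec$pos <- as.integer(floor(stats::runif(nrow(sec), 0, 900 - L)))
        sec$gene <- NA_character_
        reads <- rbind(reads, sec)
        rownames(reads) <- NULL
      }
    }

    structure(list(models = models, reads = reads,
                   chrom_lengths = chrom_lengths, spec = spec,
                   expression = stats::setNames(exp_rpk, gene_ids)),
              class = "sim_library")
  })
}

#' @export
print.sim_library <- function(x, ...) {
  cat("sim_library:", length(unique(x$reads$template)), "templates,",
      nrow(x$reads), "records,", nrow(x$models$genes), "genes;",
      sprintf("%.1f%%", 100 * duplicate_fraction(x)), "duplicate-flagged\n")
  invisible(x)
}

#' Subsample and PCR-amplify a synthetic library
#'
#' Emulates excess PCR amplification at library preparation: each template
#' (read, or fragment for paired-end data) is kept independently with
#' probability `f`; every kept template is then emitted `1 + Poisson(lambda)`
#' times. With the default `lambda = 1/f - 1` the expected output size equals
#' the input size, and the expected fraction of coordinate duplicates in the
#' output is `1 - f` (e.g. 50 % at f = 0.5, 90 % at f = 0.1) when the input
#' templates occupy distinct coordinates.
#'
#' @param lib a `sim_library`.
#' @param f keep-fraction in (0, 1].
#' @param lambda Poisson amplification rate (>= 0; default `1/f - 1`).
#' @param seed RNG seed for the subsample and copy-count draws.
#' @return a new `sim_library`; PCR copies carry `origin = "pcr"`, share
#'   coordinates with their template, and have fresh (unset) duplicate flags.
#' @export
pcr_amplify <- function(lib, f, lambda = 1 / f - 1, seed = 1) {
  stopifnot(inherits(lib, "sim_library"))
  if (f <= 0 || f > 1) stop("keep-fraction f must be in (0, 1]")
  if (lambda < 0) stop("amplification rate lambda must be >= 0")
  with_seed(seed, {
    reads <- lib$reads
    prim <- reads[!reads$secondary, , drop = FALSE]
    sec  <- reads[reads$secondary, , drop = FALSE]
    tpl <- unique(prim$template)
    keep <- tpl[stats::runif(length(tpl)) < f]
    copies <- 1L + stats::rpois(length(keep), lambda)
    cp_row <- copies[match(prim$template, keep)]   # NA for dropped templates
    cp_row[is.na(cp_row)] <- 0L
    out <- prim[rep(seq_len(nrow(prim)), times = cp_row), , drop = FALSE]
    k <- sequence(cp_row)                          # copy index within template
    out$origin <- ifelse(k == 1L, out$origin, "pcr")
    out$qname <- ifelse(k == 1L, out$qname,
                        sprintf("%s_pcr%d", out$qname, k - 1L))
    out$dup <- FALSE
    # secondary alignments follow their (kept, un-amplified first copy) unit
    sec <- sec[sec$template %in% keep, , drop = FALSE]
    out <- rbind(out, sec)
    rownames(out) <- NULL
    structure(list(models = lib$models, reads = out,
                   chrom_lengths = lib$chrom_lengths, spec = lib$spec),
              class = "sim_library")
  })
}

#' Mark coordinate duplicates
#'
#' Groups primary records by (chromosome, strand-adjusted 5' alignment start,
#' strand) -- for paired data by the combined key of both mates -- and flags
#' every record of a group except the first-seen one with the duplicate bit,
#' the grouping used by coordinate-based duplicate markers. Secondary
#' alignments inherit the status of their unit.
#'
#' @param lib a `sim_library`.
#' @return the library with `reads$dup` set accordingly.
#' @export
mark_duplicates <- function(lib) {
  stopifnot(inherits(lib, "sim_library"))
  reads <- lib$reads
  fivep <- ifelse(reads$strand == "+", reads$pos, reads$pos + reads$len)
  rkey <- paste(reads$chrom, fivep, reads$strand, sep = "\r")
  prim <- !reads$secondary
  if (any(reads$mate[prim] > 0L)) {
    # fragment key: both mates' coordinate keys, mate-order normalized
    pr <- which(prim)
    o <- pr[order(reads$qname[pr], rkey[pr])]
    ukey <- tapply(rkey[o], reads$qname[o], paste, collapse = "\n")
    first_seen <- !duplicated(unname(ukey[unique(reads$qname[prim])]))
    dup_units <- unique(reads$qname[prim])[!first_seen]
    reads$dup <- reads$qname %in% dup_units
  } else {
    dup_rows <- duplicated(rkey[prim])
    dupq <- reads$qname[prim][dup_rows]
    reads$dup <- reads$qname %in% dupq
  }
  lib$reads <- reads
  lib
}

#' Fraction of duplicate-flagged primary records
#'
#' @param lib a `sim_library`.
#' @return fraction in \[0, 1\].
#' @export
duplicate_fraction <- function(lib) {
  stopifnot(inherits(lib, "sim_library"))
  prim <- lib$reads[!lib$reads$secondary, , drop = FALSE]
  mean(prim$dup)
}

#' Write a synthetic library as SAM text
#'
#' Emits a valid header (`@SQ` lines from the gene-model chromosomes) and one
#' record per alignment: duplicate bit 0x400, secondary bit 0x100, pairing
#' bits for paired data, `NH` tags, CIGAR `<len>M`, `*` sequence/quality.
#'
#' @param lib a `sim_library`.
#' @param path output SAM path (written atomically).
#' @return invisibly, the path.
#' @export
write_sam <- function(lib, path) {
  stopifnot(inherits(lib, "sim_library"))
  r <- lib$reads
  flag <- ifelse(r$strand == "-", 16L, 0L) +
    ifelse(r$dup, 1024L, 0L) +
    ifelse(r$secondary, 256L, 0L)
  rnext <- "*"; pnext <- 0L; tlen <- 0L
  if (any(r$mate > 0L)) {
    paired <- r$mate > 0L
    flag <- flag + ifelse(paired, 1L + 2L, 0L) +
      ifelse(r$mate == 1L, 64L, 0L) + ifelse(r$mate == 2L, 128L, 0L)
    # mate coordinates: the other mate of the same qname
    ix <- seq_len(nrow(r))
    key <- paste(r$qname, ifelse(r$mate == 1L, 2L, 1L))
    own <- paste(r$qname, r$mate)
    m <- match(key, own)
    has_mate <- paired & !is.na(m)
    flag <- flag + ifelse(has_mate & r$strand[ifelse(is.na(m), ix, m)] == "-",
                          32L, 0L)
    rnext <- ifelse(has_mate, "=", "*")
    pnext <- ifelse(has_mate, r$pos[ifelse(is.na(m), ix, m)] + 1L, 0L)
    span <- function(a, b) pmax(a + r$len, b + r$len) - pmin(a, b)
    tl <- ifelse(has_mate, span(r$pos, r$pos[ifelse(is.na(m), ix, m)]), 0L)
    tlen <- ifelse(has_mate & r$pos > pnext - 1L, -tl, tl)
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lib$chrom_lengths),
                   as.integer(lib$chrom_lengths)))
  rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t%s\t%d\t%d\t*\t*\tNH:i:%d",
                 r$qname, flag, r$chrom, r$pos + 1L, r$len,
                 rnext, pnext, tlen, r$NH)
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writeLines(c(hdr, rec), tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write the ground-truth sidecar of a synthetic library
#'
#' @param lib a `sim_library`.
#' @param path output TSV path (`qname`, `mate`, `origin`, `template`,
#'   `gene`, `dup`).
#' @return invisibly, the path.
#' @export
write_truth <- function(lib, path) {
  stopifnot(inherits(lib, "sim_library"))
  tmp <- paste0(path, ".tmp", Sys.getpid())
  utils::write.table(
    lib$reads[, c("qname", "mate", "origin", "template", "gene", "dup")],
    tmp, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  file.rename(tmp, path)
  invisible(path)
}

#' Write gene models as GTF
#'
#' One `exon` feature per merged exon, quoted `gene_id`/`transcript_id`
#' attributes, 1-based inclusive coordinates.
#'
#' @param models a `gene_models`.
#' @param path output GTF path.
#' @return invisibly, the path.
#' @export
write_gtf <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  flat <- unlist(models$exons, use.names = FALSE)
  gid <- rep(models$genes$gene_id, S4Vectors::elementNROWS(models$exons))
  lines <- sprintf(
    "%s\tdupscope_sim\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";",
    as.character(GenomicRanges::seqnames(flat)),
    GenomicRanges::start(flat), GenomicRanges::end(flat),
    as.character(GenomicRanges::strand(flat)), gid, gid)
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}
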