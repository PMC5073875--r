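## Diagnostic plots: duplication rate vs expression (density scatter + fitted
## logit curve), per-expression-bin boxplots, expression histogram, and a
## multi-sample baseline bar chart. Every plot function returns its
## underlying numeric data so results can be checked without touching pixels.

## Internal: open a png/svg device for `out` (extension decides), run `code`,
## close. `out = NULL` draws on the current device.
with_device <- function(out, code, width = 7, height = 7) {
  if (!is.null(out)) {
    if (grepl("\\.svg$", out, ignore.case = TRUE)) {
      grDevices::svg(out, width = width, height = height)
    } else {
      grDevices::png(out, width = width * 100, height = height * 100, res = 100)
    }
    on.exit(grDevices::dev.off())
  }
  force(code)
}

#' Duplication rate vs expression plot
#'
#' The package's main diagnostic: per-gene duplication rate against
#' log10(RPK), shaded by local point density (2-D binned counts), with the
#' fitted logit curve overlaid, the fit's intercept and slope in the legend,
#' and a reference line at 1 read/bp (RPK = 1000). Genes with undefined
#' duplication rate are excluded.
#'
#' @param tab a `duprate_table`.
#' @param fit optional `duprate_fit`; when given, curve and legend are drawn.
#' @param out optional image path (`.png` or `.svg`); when NULL draws on the
#'   current device.
#' @param nbins number of density bins per axis (default 60).
#' @param main plot title.
#' @return invisibly, a list with `points` (data.frame `ID`, `x` = log10 RPK,
#'   `y` = dupRate, `density` = bin count), `curve` (the fit curve or NULL)
#'   and `n_plotted`.
#' @export
duprate_exp_plot <- function(tab, fit = NULL, out = NULL, nbins = 60,
                             main = "duplication rate vs expression") {
  stopifnot(is.data.frame(tab), all(c("dupRate", "RPK") %in% names(tab)))
  keep <- !is.na(tab$dupRate) & tab$RPK > 0
  if (!any(keep)) stop("no plottable genes (all dupRate undefined or RPK 0)")
  x <- log10(tab$RPK[keep])
  y <- tab$dupRate[keep]
  ids <- if (!is.null(tab$ID)) tab$ID[keep] else as.character(which(keep))

  # 2-D binned density for shading
  xb <- cut(x, breaks = nbins, labels = FALSE, include.lowest = TRUE)
  yb <- cut(y, breaks = seq(0, 1, length.out = nbins + 1), labels = FALSE,
            include.lowest = TRUE)
  dens <- as.integer(stats::ave(x, interaction(xb, yb, drop = TRUE),
                                FUN = length))
  pts <- data.frame(ID = ids, x = x, y = y, density = dens,
                    stringsAsFactors = FALSE)
  curve_df <- if (!is.null(fit)) fit$curve else NULL

  with_device(out, {
    pal <- grDevices::colorRampPalette(c("grey80", "steelblue4", "red3"))(32)
    col <- pal[pmin(32L, 1L + as.integer(31 * log1p(dens) / max(log1p(dens))))]
    graphics::plot(x, y, pch = 16, cex = 0.6, col = col,
                   xlab = "expression  [log10 reads/kb]",
                   ylab = "duplication rate", ylim = c(0, 1), main = main)
    graphics::abline(v = 3, lty = 3, col = "grey40")  # 1 read/bp (RPK = 1000)
    graphics::mtext("1 read/bp", side = 3, at = 3, cex = 0.7, col = "grey40")
    if (!is.null(curve_df)) {
      graphics::lines(curve_df$x, curve_df$y, lwd = 2, col = "black")
      graphics::legend("topleft", bty = "n", legend = sprintf(
        "intercept = %.2f\nslope = %.2f", fit$intercept, fit$slope))
    }
  })
  invisible(list(points = pts, curve = curve_df, n_plotted = nrow(pts)))
}

#' Duplication rate boxplot per expression bin
#'
#' Partitions genes into `n_bins` equal-width bins of log10(RPK) and draws one
#' box of duplication rates per bin; empty bins are rendered empty.
#'
#' @param tab a `duprate_table`.
#' @param n_bins number of bins (>= 2, default 10).
#' @param out optional image path.
#' @param main plot title.
#' @return invisibly, a list with `bins` (data.frame `bin`, `x_lo`, `x_hi`,
#'   `n`, `q1`, `median`, `q3`) and `n_plotted`.
#' @export
duprate_boxplot <- function(tab, n_bins = 10, out = NULL,
                            main = "duplication rate per expression bin") {
  stopifnot(n_bins >= 2)
  keep <- !is.na(tab$dupRate) & tab$RPK > 0
  if (!any(keep)) stop("no plottable genes")
  x <- log10(tab$RPK[keep])
  y <- tab$dupRate[keep]
  brk <- seq(min(x), max(x), length.out = n_bins + 1)
  brk[1] <- brk[1] - 1e-9
  bin <- cut(x, breaks = brk, labels = FALSE, include.lowest = TRUE)
  qs <- function(v, p) if (length(v)) unname(stats::quantile(v, p)) else NA_real_
  bins <- data.frame(
    bin = seq_len(n_bins),
    x_lo = brk[-length(brk)], x_hi = brk[-1],
    n = tabulate(bin, n_bins),
    q1 = vapply(seq_len(n_bins), function(b) qs(y[bin == b], 0.25), 1),
    median = vapply(seq_len(n_bins), function(b) qs(y[bin == b], 0.5), 1),
    q3 = vapply(seq_len(n_bins), function(b) qs(y[bin == b], 0.75), 1)
  )
  with_device(out, {
    graphics::boxplot(split(y, factor(bin, levels = seq_len(n_bins))),
                      names = sprintf("%.1f", (bins$x_lo + bins$x_hi) / 2),
                      xlab = "expression bin midpoint [log10 reads/kb]",
                      ylab = "duplication rate", ylim = c(0, 1), main = main)
  })
  invisible(list(bins = bins, n_plotted = length(y)))
}

#' Histogram of per-gene expression
#'
#' Histogram of log10(RPK) over genes with RPK > 0; bin counts sum to the
#' number of such genes.
#'
#' @param tab a `duprate_table`.
#' @param breaks passed to [graphics::hist()] (default 30).
#' @param out optional image path.
#' @param main plot title.
#' @return invisibly, a list with `counts`, `mids`, `breaks`, `n` (total
#'   genes with RPK > 0).
#' @export
expression_hist <- function(tab, breaks = 30, out = NULL,
                            main = "expression distribution") {
  x <- log10(tab$RPK[!is.na(tab$RPK) & tab$RPK > 0])
  if (length(x) == 0L) {
    return(invisible(list(counts = integer(0), mids = numeric(0),
                          breaks = numeric(0), n = 0L)))
  }
  h <- with_device(out, {
    graphics::hist(x, breaks = breaks, main = main,
                   xlab = "expression  [log10 reads/kb]")
  })
  invisible(list(counts = h$counts, mids = h$mids, breaks = h$breaks,
                 n = length(x)))
}

#' Compare baseline duplication rates across samples
#'
#' Convenience bar chart for multi-sample QC reports: one bar per sample at
#' its fitted baseline duplication rate.
#'
#' @param baselines named numeric vector of baseline rates in \[0, 1\].
#' @param out optional image path.
#' @param main plot title.
#' @return invisibly, the input vector.
#' @export
baseline_barplot <- function(baselines, out = NULL,
                             main = "baseline duplication rate per sample") {
  stopifnot(is.numeric(baselines), length(baselines) >= 1)
  with_device(out, {
    graphics::barplot(baselines, ylim = c(0, 1), main = main,
                      ylab = "baseline duplication rate", las = 2)
  })
  invisible(baselines)
}
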