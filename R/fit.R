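## Logistic model of duplication rate vs expression, and the derived
## baseline duplication rate used as the library-quality indicator.

#' Fit the duplication-rate vs expression logit model
#'
#' Models the per-gene duplication rate as a logistic function of expression,
#' `dupRate = expit(intercept + slope * log10(RPK))`, by iteratively
#' reweighted least squares on the fractional response (quasi-binomial
#' likelihood, each gene one unweighted observation). Genes with no reads or
#' non-positive RPK are excluded. The intercept's inverse logit is the
#' baseline duplication rate: the predicted rate at RPK = 1, i.e. for lowly
#' expressed genes, where any appreciable duplication signals technical
#' (PCR / library-complexity) artifacts rather than over-sequencing.
#'
#' @param tab a `duprate_table` (or any data.frame with columns `dupRate` and
#'   `RPK`, plus `allCounts`/`dupsPerId`/`filteredCounts` when `weighted`).
#' @param weighted if TRUE, fit the count-weighted binomial variant
#'   (successes = `dupsPerId`, trials = `allCounts`) instead of the
#'   unweighted fractional-response fit.
#' @param maxit maximum IRLS iterations (default 50).
#' @param epsilon IRLS convergence tolerance on the deviance change
#'   (default 1e-8).
#' @return object of class `duprate_fit`: list with `intercept`, `slope`,
#'   `baseline` (= `plogis(intercept)`), `converged`, `n_genes_used`,
#'   `weighted`, and `curve` (data.frame `x` = log10 RPK, `y` = predicted
#'   dupRate over the observed expression range).
#' @export
fit_duprate <- function(tab, weighted = FALSE, maxit = 50, epsilon = 1e-8) {
  stopifnot(is.data.frame(tab), all(c("dupRate", "RPK") %in% names(tab)))
  keep <- !is.na(tab$dupRate) & tab$RPK > 0
  if (!is.null(tab$allCounts)) keep <- keep & tab$allCounts > 0
  d <- tab[keep, , drop = FALSE]
  if (nrow(d) < 10) {
    stop("need >= 10 genes with reads to fit the model; got ", nrow(d))
  }
  if (all(d$dupRate == 0) || all(d$dupRate == 1)) {
    stop("perfect separation: every gene has duplication rate ",
         d$dupRate[1], "; the logit model is not identifiable ",
         "(is the input duplicate-marked?)")
  }
  x <- log10(d$RPK)
  ctrl <- stats::glm.control(epsilon = epsilon, maxit = maxit)
  if (weighted) {
    succ <- d$dupRate * d$allCounts
    fail <- d$allCounts - succ
    fit <- suppressWarnings(stats::glm(cbind(succ, fail) ~ x,
                                       family = stats::binomial("logit"),
                                       control = ctrl))
  } else {
    y <- d$dupRate
    fit <- stats::glm(y ~ x, family = stats::quasibinomial("logit"),
                      control = ctrl)
  }
  if (!fit$converged) {
    warning("IRLS did not converge in ", maxit,
            " iterations; returning the last iterate")
  }
  cf <- unname(stats::coef(fit))
  grid <- seq(min(x), max(x), length.out = 101)
  res <- structure(list(
    intercept = cf[1], slope = cf[2],
    baseline = stats::plogis(cf[1]),
    converged = fit$converged,
    n_genes_used = nrow(d),
    weighted = weighted,
    curve = data.frame(x = grid, y = stats::plogis(cf[1] + cf[2] * grid))
  ), class = "duprate_fit")
  res
}

#' Baseline duplication rate of a fitted model
#'
#' The inverse-logit of the intercept: the model's predicted duplication rate
#' at RPK = 1 (log10 RPK = 0). Near 0 for healthy libraries; elevated values
#' indicate PCR artifacts or low library complexity.
#'
#' @param fit a `duprate_fit`.
#' @return fraction in (0, 1).
#' @export
baseline_rate <- function(fit) {
  stopifnot(inherits(fit, "duprate_fit"))
  fit$baseline
}

#' Predicted duplication rate along an expression grid
#'
#' @param object a `duprate_fit`.
#' @param grid numeric vector of log10(RPK) values (default: the fit's
#'   internal grid).
#' @param ... unused.
#' @return data.frame with `x` (log10 RPK) and `y` (predicted dupRate).
#' @export
predict.duprate_fit <- function(object, grid = NULL, ...) {
  if (is.null(grid)) return(object$curve)
  data.frame(x = grid,
             y = stats::plogis(object$intercept + object$slope * grid))
}

#' Serialize a fit summary as JSON
#'
#' @param fit a `duprate_fit`.
#' @param path optional output path; written atomically when given.
#' @return the JSON string, invisibly when `path` is given.
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "duprate_fit"))
  js <- jsonlite::toJSON(list(intercept = fit$intercept, slope = fit$slope,
                              baseline = fit$baseline,
                              n_genes_used = fit$n_genes_used,
                              converged = fit$converged),
                         auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writeLines(js, tmp)
  file.rename(tmp, path)
  invisible(js)
}

#' @export
print.duprate_fit <- function(x, ...) {
  cat(sprintf(paste0("duprate_fit (%s): intercept %.4f, slope %.4f\n",
                     "  baseline duplication rate %.4f  (n = %d genes%s)\n"),
              if (x$weighted) "count-weighted binomial"
              else "quasi-binomial, unweighted",
              x$intercept, x$slope, x$baseline, x$n_genes_used,
              if (x$converged) "" else "; NOT converged"))
  invisible(x)
}
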