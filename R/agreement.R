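#' @include AllClasses.R
NULL

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked data (tie-corrected), i.e.
#' `stats::cor(x, y, method = "spearman")` with explicit input checks:
#' at least three pairs, equal lengths, and no constant vector (a
#' constant vector leaves the correlation undefined and raises an error
#' rather than returning NA).
#'
#' @param x,y numeric measurement vectors.
#' @return rho in \[-1, 1\].
#' @examples
#' spearmanRho(1:4, c(1, 3, 2, 4))  # 0.8
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant measurement vector")
  stats::cor(x, y, method = "spearman")
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b`; bias is `mean(d)`, the SD uses the sample
#' (n - 1) denominator, and the limits of agreement are
#' `bias +/- multiplier * SD` with the conventional normal-approximation
#' multiplier 1.96. Per-pair means are returned for plotting.
#'
#' @param a,b paired measurements (mm) from the two methods.
#' @param multiplier limit-of-agreement multiplier (default 1.96).
#' @return list with `biasMm`, `sdMm`, `loaLowerMm`, `loaUpperMm`, `n`,
#'   and a `pairs` data.frame (`a`, `b`, `mean`, `diff`).
#' @examples
#' blandAltman(c(10, 12), c(11, 11))  # d = c(-1, 1)
#' @export
blandAltman <- function(a, b, multiplier = 1.96) {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2L) stop("insufficient data: need at least 2 complete pairs")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  list(biasMm = bias, sdMm = s,
       loaLowerMm = bias - multiplier * s,
       loaUpperMm = bias + multiplier * s,
       n = length(a),
       pairs = data.frame(a = a, b = b, mean = (a + b) / 2, diff = d))
}

#' Full method-agreement report for paired stricture lengths
#'
#' Computes the Spearman rank correlation and the Bland-Altman summary
#' for a table of paired measurements, optionally writing a JSON report
#' and a Bland-Altman scatter plot (per-pair mean vs difference with
#' bias and limit lines). Rows with missing or non-numeric entries are
#' dropped with a message stating how many.
#'
#' @param pairs data.frame with the two measurement columns.
#' @param cols names of the two columns (defaults: first two numeric
#'   columns, or `length_a_mm` / `length_b_mm` when present).
#' @param multiplier limit-of-agreement multiplier.
#' @param reportJson optional path for the JSON report.
#' @param plotFile optional path for a PNG Bland-Altman plot.
#' @return an [AgreementReport-class].
#' @export
agreementReport <- function(pairs, cols = NULL, multiplier = 1.96,
                            reportJson = NULL, plotFile = NULL) {
  if (is.null(cols)) {
    cols <- if (all(c("length_a_mm", "length_b_mm") %in% names(pairs)))
      c("length_a_mm", "length_b_mm")
    else names(pairs)[vapply(pairs, is.numeric, logical(1))][1:2]
  }
  a <- suppressWarnings(as.numeric(pairs[[cols[1]]]))
  b <- suppressWarnings(as.numeric(pairs[[cols[2]]]))
  keep <- is.finite(a) & is.finite(b)
  if (any(!keep))
    message(sum(!keep), " incomplete pair(s) dropped")
  ba <- blandAltman(a[keep], b[keep], multiplier = multiplier)
  rho <- spearmanRho(a[keep], b[keep])
  rep <- new("AgreementReport",
             spearmanRho = rho,
             biasMm = ba$biasMm, sdMm = ba$sdMm,
             loaLowerMm = ba$loaLowerMm, loaUpperMm = ba$loaUpperMm,
             limitMultiplier = multiplier,
             n = as.integer(ba$n), pairs = ba$pairs)
  if (!is.null(reportJson)) writeAgreementReport(rep, reportJson)
  if (!is.null(plotFile)) plotBlandAltman(rep, plotFile)
  rep
}

#' Write / read an AgreementReport as JSON
#'
#' The JSON round-trips: reading back a written report reproduces the
#' statistics and pair table exactly.
#'
#' @param report an [AgreementReport-class].
#' @param path JSON file path.
#' @return `path` invisibly (write) or an [AgreementReport-class] (read).
#' @export
writeAgreementReport <- function(report, path) {
  jsonlite::write_json(list(
    spearman_rho = report@spearmanRho,
    bias_mm = report@biasMm,
    sd_mm = report@sdMm,
    loa_lower_mm = report@loaLowerMm,
    loa_upper_mm = report@loaUpperMm,
    limit_multiplier = report@limitMultiplier,
    n = report@n,
    pairs = report@pairs
  ), path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname writeAgreementReport
#' @export
readAgreementReport <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("AgreementReport",
      spearmanRho = j$spearman_rho,
      biasMm = j$bias_mm, sdMm = j$sd_mm,
      loaLowerMm = j$loa_lower_mm, loaUpperMm = j$loa_upper_mm,
      limitMultiplier = j$limit_multiplier,
      n = as.integer(j$n),
      pairs = as.data.frame(j$pairs))
}

#' Bland-Altman plot
#'
#' Per-pair mean against difference, with horizontal lines at the bias
#' and at both limits of agreement.
#'
#' @param report an [AgreementReport-class].
#' @param file optional PNG path; plots to the active device when NULL.
#' @return `file` (or NULL), invisibly.
#' @export
plotBlandAltman <- function(report, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 720, height = 560)
    on.exit(grDevices::dev.off())
  }
  p <- report@pairs
  ylim <- range(c(p$diff, report@loaLowerMm, report@loaUpperMm))
  graphics::plot(p$mean, p$diff, pch = 19, col = "steelblue",
                 xlab = "Mean of methods (mm)",
                 ylab = "Difference a - b (mm)",
                 main = sprintf("Bland-Altman (n = %d)", report@n),
                 ylim = ylim + c(-0.5, 0.5))
  graphics::abline(h = report@biasMm, lwd = 2)
  graphics::abline(h = c(report@loaLowerMm, report@loaUpperMm),
                   lty = 2, col = "firebrick")
  invisible(file)
}
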