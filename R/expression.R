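# Expression breadth/level classification: cubic baseline of median
# intensity on hybridization percentage, HE/LE split, SR/WR breadth
# classes, HE+/LE+ extremes outside a central residual band.

#' Classify genes by expression level and breadth
#'
#' Fits the median expression intensity as a cubic polynomial of the
#' hybridization percentage (third-order linear regression) by ordinary
#' least squares. Genes strictly above the fitted base line are HE (high
#' expression), the rest LE. Breadth classes use fixed thresholds on the
#' hybridization percentage: SR (small range) strictly below
#' `sr_threshold`, WR (wide range) strictly above `wr_threshold`. The
#' extremes HE+/LE+ lie outside a central band around the base line holding
#' `interval_level` of the mass: with `band = "normal"` the half-width is
#' `qnorm(0.5 + interval_level/2)` residual standard deviations; with
#' `band = "empirical"` the band edges are the corresponding residual
#' quantiles.
#'
#' @param points A data.frame with columns `hybridization_pct` (0-100) and
#'   `median_intensity`, and optionally `gene_id`.
#' @param sr_threshold,wr_threshold Breadth thresholds in percent (defaults
#'   15 and 85).
#' @param interval_level Central band mass (default 0.60).
#' @param band `"normal"` or `"empirical"`.
#' @return An object of class `expression_classes` with a per-gene table
#'   (`gene_id`, inputs, `baseline`, logical `HE`, `SR`, `WR`, `HEplus`,
#'   `LEplus`), the cubic coefficients, the residual scale and band edges.
#'   Has `coef`, `fitted`, `residuals`, `summary` and `plot` methods.
#' @export
classify_expression <- function(points, sr_threshold = 15, wr_threshold = 85,
                                interval_level = 0.60,
                                band = c("normal", "empirical")) {
  band <- match.arg(band)
  stopifnot(is.data.frame(points),
            all(c("hybridization_pct", "median_intensity") %in% names(points)))
  x <- points$hybridization_pct
  y <- points$median_intensity
  if (any(x < 0 | x > 100)) stop("hybridization_pct must be within [0, 100]")
  if (length(x) < 10) stop("need at least 10 points")
  if (length(unique(x)) < 3) stop("need at least 3 distinct hybridization values")
  if (!(interval_level > 0 && interval_level < 1))
    stop("'interval_level' must be in (0, 1)")
  fit <- lm(y ~ x + I(x^2) + I(x^3))
  baseline <- unname(fitted(fit))
  res <- y - baseline
  s <- sqrt(sum(res^2) / (length(x) - 4L))
  # "above the base line" is read strictly: points on the line (up to
  # numerical roundoff of the fit) are LE
  tol <- sqrt(.Machine$double.eps) * max(1, diff(range(y)))
  if (band == "normal") {
    half <- qnorm(0.5 + interval_level / 2) * s
    lo <- -half; hi <- half
  } else {
    qs <- quantile(res, c(0.5 - interval_level / 2, 0.5 + interval_level / 2),
                   names = FALSE)
    lo <- qs[1L]; hi <- qs[2L]
  }
  gene_id <- if ("gene_id" %in% names(points)) as.character(points$gene_id)
             else sprintf("g%04d", seq_along(x))
  tab <- data.frame(
    gene_id = gene_id, hybridization_pct = x, median_intensity = y,
    baseline = baseline,
    HE = res > tol,
    SR = x < sr_threshold,
    WR = x > wr_threshold,
    HEplus = y > baseline + hi,
    LEplus = y < baseline + lo,
    stringsAsFactors = FALSE)
  counts <- c(HE = sum(tab$HE), LE = sum(!tab$HE),
              SR = sum(tab$SR), WR = sum(tab$WR),
              `HE+` = sum(tab$HEplus), `LE+` = sum(tab$LEplus),
              `SR-HE+` = sum(tab$SR & tab$HEplus),
              `SR-LE+` = sum(tab$SR & tab$LEplus),
              `WR-HE+` = sum(tab$WR & tab$HEplus),
              `WR-LE+` = sum(tab$WR & tab$LEplus))
  structure(list(table = tab, coefficients = coef(fit), residual_scale = s,
                 band = band, band_edges = c(lower = lo, upper = hi),
                 interval_level = interval_level,
                 sr_threshold = sr_threshold, wr_threshold = wr_threshold,
                 counts = counts),
            class = "expression_classes")
}

#' @export
coef.expression_classes <- function(object, ...) object$coefficients

#' @export
fitted.expression_classes <- function(object, ...) object$table$baseline

#' @export
residuals.expression_classes <- function(object, ...)
  object$table$median_intensity - object$table$baseline

#' @export
print.expression_classes <- function(x, ...) {
  cat(sprintf("expression_classes: %d genes (cubic baseline, %s %d%% band)\n",
              nrow(x$table), x$band, round(100 * x$interval_level)))
  print(x$counts)
  invisible(x)
}

#' @export
summary.expression_classes <- function(object, ...) {
  cat("Cubic baseline coefficients:\n")
  print(object$coefficients)
  cat(sprintf("Residual scale: %.4g; band edges [%+.4g, %+.4g] (%s)\n",
              object$residual_scale, object$band_edges[1],
              object$band_edges[2], object$band))
  print(object$counts)
  invisible(object)
}

#' Plot expression classes
#'
#' Cloud of genes with the cubic base line and the central band; HE+/LE+
#' genes highlighted.
#'
#' @param x An `expression_classes` object.
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.expression_classes <- function(x, ...) {
  tab <- x$table
  plot(tab$hybridization_pct, tab$median_intensity, pch = 16, cex = 0.4,
       col = adjustcolor(ifelse(tab$HE, "firebrick", "steelblue"), 0.5),
       xlab = "hybridization (%)", ylab = "median intensity", ...)
  o <- order(tab$hybridization_pct)
  lines(tab$hybridization_pct[o], tab$baseline[o], lwd = 2)
  lines(tab$hybridization_pct[o], tab$baseline[o] + x$band_edges[2], lty = 2)
  lines(tab$hybridization_pct[o], tab$baseline[o] + x$band_edges[1], lty = 2)
  abline(v = c(x$sr_threshold, x$wr_threshold), col = "grey50", lty = 3)
  invisible(x)
}
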