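# Post-processing: curvature-resolved sorting maps and autocorrelation-
# corrected error estimates for Monte Carlo series.

#' Fractional excess coverage
#'
#' \eqn{\bar\Gamma(i) = n(i)/n_0(i) - 1}: local occupancy relative to the
#' expectation from the global composition. Bounded below by -1; undefined
#' (NA) where the expectation vanishes.
#'
#' @param n observed occupancy (count or amount)
#' @param n0 expected occupancy from the global composition
#' @export
fractionalExcess <- function(n, n0) {
  out <- n / n0 - 1
  out[n0 == 0] <- NA_real_
  out
}

#' Curvature-resolved sorting map
#'
#' Bins a per-face property (by default the fractional excess peptide
#' coverage) over two geometric variables (by default mean and Gaussian
#' curvature), averaging snapshot-wise first to preserve spatial
#' correlations and then pooling across snapshots. Sparse bins below the
#' occupancy quantile \code{excludeQuantile} are masked as outliers, and
#' bins violating \eqn{H^2 \ge K_G} (no real surface) are flagged.
#'
#' @param snapshots list of per-face matrices as returned in
#'   \code{runMC(...)$snapshots} (columns area, H, KG, np, fractions...),
#'   or a single such matrix
#' @param value column to average: "np" is converted to fractional excess
#'   against the snapshot-mean occupancy per area
#' @param xvar,yvar binning variables (column names; default "H", "KG")
#' @param nbins bins per axis
#' @param excludeQuantile mask bins whose face count falls below this
#'   quantile of the non-empty bin counts
#' @return list of class \code{sortingMap}: xmid, ymid, mean matrix, count
#'   matrix, mask matrix, unphysical flag matrix
#' @export
binAverage2D <- function(snapshots, value = "np", xvar = "H", yvar = "KG",
                         nbins = 12, excludeQuantile = 0.02) {
  if (is.matrix(snapshots)) snapshots <- list(snapshots)
  if (!length(snapshots)) stop("need at least one snapshot")
  getcol <- function(sm, nm) {
    cn <- colnames(sm)
    if (!nm %in% cn) stop("snapshot lacks column ", nm)
    sm[, nm]
  }
  allx <- unlist(lapply(snapshots, getcol, xvar))
  ally <- unlist(lapply(snapshots, getcol, yvar))
  xbr <- seq(min(allx), max(allx), length.out = nbins + 1)
  ybr <- seq(min(ally), max(ally), length.out = nbins + 1)
  sums <- matrix(0, nbins, nbins)
  cnts <- matrix(0, nbins, nbins)
  for (sm in snapshots) {
    xv <- getcol(sm, xvar); yv <- getcol(sm, yvar)
    if (value == "np") {
      np <- getcol(sm, "np"); ar <- getcol(sm, "area")
      n0 <- sum(np) * ar / sum(ar)     # expected occupancy by face area
      val <- fractionalExcess(np, n0)
    } else val <- getcol(sm, value)
    ix <- pmin(pmax(findInterval(xv, xbr, rightmost.closed = TRUE), 1), nbins)
    iy <- pmin(pmax(findInterval(yv, ybr, rightmost.closed = TRUE), 1), nbins)
    ok <- is.finite(val)
    for (k in which(ok)) {
      sums[ix[k], iy[k]] <- sums[ix[k], iy[k]] + val[k]
      cnts[ix[k], iy[k]] <- cnts[ix[k], iy[k]] + 1
    }
  }
  mean <- sums / cnts
  mean[cnts == 0] <- NA_real_
  thr <- stats::quantile(cnts[cnts > 0], excludeQuantile)
  mask <- cnts < thr
  xmid <- (head(xbr, -1) + tail(xbr, -1)) / 2
  ymid <- (head(ybr, -1) + tail(ybr, -1)) / 2
  unphys <- outer(xmid^2, ymid, function(h2, k) h2 < k)
  structure(list(xmid = xmid, ymid = ymid, mean = mean, counts = cnts,
                 mask = mask, unphysical = unphys,
                 xvar = xvar, yvar = yvar, value = value),
            class = "sortingMap")
}

#' @export
print.sortingMap <- function(x, ...) {
  cat("sortingMap:", x$value, "binned over", x$xvar, "x", x$yvar, "(",
      length(x$xmid), "x", length(x$ymid), "bins,",
      sum(!is.na(x$mean) & !x$mask), "populated )\n")
  invisible(x)
}

#' Write a sorting map as a TSV matrix plus JSON metadata
#' @param map a sortingMap
#' @param path base path (writes \code{path.tsv} and \code{path.json})
#' @export
writeSortingMap <- function(map, path) {
  m <- map$mean
  m[map$mask] <- NA
  utils::write.table(m, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  meta <- list(xvar = map$xvar, yvar = map$yvar, value = map$value,
               xmid = map$xmid, ymid = map$ymid)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Statistical inefficiency and corrected error estimate
#'
#' Integrates the normalized autocorrelation function of a Monte Carlo
#' series up to its first zero crossing (automatic windowing):
#' \eqn{s = 1 + 2 \sum_{k=1}^{K} C(k)}. The corrected standard error of the
#' mean is \eqn{\sigma \sqrt{s / N}} and the 95% confidence interval uses
#' the 1.96 z-score. White noise gives s near 1; an AR(1) process with
#' coefficient \eqn{\rho} gives \eqn{s \to (1+\rho)/(1-\rho)}.
#'
#' @param series numeric series (length at least 100)
#' @return list: mean, sd (population), s, neff, se (corrected), ci95
#' @export
statisticalInefficiency <- function(series) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 100) stop("need a series of at least 100 points")
  sdev <- stats::sd(series)
  if (sdev == 0)
    return(list(mean = series[1], sd = 0, s = 1, neff = n, se = 0, ci95 = 0))
  lagMax <- n %/% 2
  # integrate C(k) lag by lag up to the first zero crossing (automatic
  # windowing); computing each lag on demand keeps long, weakly correlated
  # series cheap
  x <- series - mean(series)
  denom <- sum(x^2)
  acsum <- 0
  crossed <- FALSE
  for (k in seq_len(lagMax)) {
    ck <- sum(x[seq_len(n - k)] * x[(k + 1):n]) / denom
    if (ck <= 0) { crossed <- TRUE; break }
    acsum <- acsum + ck
  }
  if (!crossed)
    warning("autocorrelation has no zero crossing within N/2; capping window")
  s <- max(1, 1 + 2 * acsum)
  se <- sdev * sqrt(s / n)
  list(mean = mean(series), sd = sdev, s = s, neff = n / s, se = se,
       ci95 = 1.96 * se)
}
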