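# Half-sibling regression: the mark-specific signal y_h and the shared
# chromatin bias x are both driven by the same confounder (accessibility x
# mappability), while the true enrichment s_h is assumed independent of x.
# Regressing log y_h on log x and subtracting the prediction therefore
# removes the confounder:  log s_hat = log y - E[log y | log x].
# Subtraction in log scale is division in linear scale, so s_hat is a
# fold-change track.

#' Fit the half-sibling log-regression of a mark on the chromatin bias
#'
#' Ordinary least squares of `log(y)` on `log(x)`, fitted only on bins where
#' both are positive (optionally restricted to a subset, e.g. the
#' factorization's training bins). A constant `x` degenerates to slope 0 and
#' intercept `mean(log y)`.
#'
#' @param y mark-specific signal (per bin, >= 0).
#' @param x chromatin-bias signal (per bin, >= 0).
#' @param subset optional integer vector of candidate bins.
#' @return list with `intercept`, `slope`, `n_fit`, and the fitted bin
#'   indices `fit_bins`.
#' @export
fit_hsr <- function(y, x, subset = NULL) {
  stopifnot(length(y) == length(x))
  idx <- if (is.null(subset)) seq_along(y) else subset
  idx <- idx[y[idx] > 0 & x[idx] > 0]
  if (length(idx) < 2L)
    stop("need at least 2 bins with positive y and x to fit the regression")
  ly <- log(y[idx]); lx <- log(x[idx])
  if (stats::sd(lx) == 0) {
    warning("chromatin-bias signal is constant on the fit bins; slope set to 0")
    return(list(intercept = mean(ly), slope = 0,
                n_fit = length(idx), fit_bins = idx))
  }
  slope <- stats::cov(lx, ly) / stats::var(lx)
  list(intercept = mean(ly) - slope * mean(lx), slope = slope,
       n_fit = length(idx), fit_bins = idx)
}

#' Remove the chromatin bias from a mark's signal
#'
#' Divides the signal by the regression-predicted background,
#' `divisor = exp(intercept + slope * log(x))`, floored at `floor` so the
#' signal is amplified at most by a factor of `1/floor` (10 at the default
#' 0.1). Bins with `x = 0` use the floored divisor.
#'
#' @param y mark-specific signal.
#' @param x chromatin-bias signal.
#' @param params a [fit_hsr()] fit.
#' @param floor minimum divisor (default 0.1).
#' @return Fold-change vector `s_hat` with the divisor attached as attribute
#'   `divisor`.
#' @export
debias <- function(y, x, params, floor = 0.1) {
  stopifnot(length(y) == length(x), floor > 0)
  divisor <- rep(floor, length(x))
  pos <- x > 0
  divisor[pos] <- pmax(exp(params$intercept + params$slope * log(x[pos])),
                       floor)
  structure(y / divisor, divisor = divisor)
}

#' Pairwise correlations and 2D coverage histograms of signal tracks
#'
#' Pearson correlations over shared bins, plus pairwise 2D log-density
#' histograms of the paired coverages (the standard visual check that
#' de-biased signals no longer co-vary with the control).
#'
#' @param tracks numeric matrix (bins x tracks) with column names, or a
#'   named list of equal-length vectors.
#' @param nbins number of histogram cells per axis.
#' @return A `correlation_report`: list with the correlation matrix `cor`
#'   and `hist2d`, a list of `x`/`y` break midpoints and count matrices per
#'   track pair.
#' @export
correlation_report <- function(tracks, nbins = 50L) {
  M <- if (is.list(tracks) && !is.data.frame(tracks))
    do.call(cbind, tracks) else as.matrix(tracks)
  if (nrow(M) < 2L) stop("need at least 2 bins to correlate")
  if (is.null(colnames(M))) colnames(M) <- paste0("track", seq_len(ncol(M)))
  cm <- stats::cor(M)
  lg <- log1p(M)
  pairs <- utils::combn(ncol(M), 2)
  h2 <- apply(pairs, 2, function(p) {
    bx <- seq(min(lg[, p[1]]), max(lg[, p[1]]), length.out = nbins + 1L)
    by <- seq(min(lg[, p[2]]), max(lg[, p[2]]), length.out = nbins + 1L)
    ix <- pmin(findInterval(lg[, p[1]], bx, all.inside = TRUE), nbins)
    iy <- pmin(findInterval(lg[, p[2]], by, all.inside = TRUE), nbins)
    list(tracks = colnames(M)[p],
         counts = unclass(table(factor(ix, 1:nbins), factor(iy, 1:nbins))),
         xmid = (head(bx, -1) + tail(bx, -1)) / 2,
         ymid = (head(by, -1) + tail(by, -1)) / 2)
  })
  structure(list(cor = cm, hist2d = h2), class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("Pairwise Pearson correlations:\n")
  print(round(x$cor, 3))
  invisible(x)
}

#' @export
plot.correlation_report <- function(x, pair = 1L, ...) {
  h <- x$hist2d[[pair]]
  image(h$xmid, h$ymid, log1p(h$counts),
        col = hcl.colors(64, "viridis"),
        xlab = paste0("log1p ", h$tracks[1]),
        ylab = paste0("log1p ", h$tracks[2]), ...)
  invisible(x)
}
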