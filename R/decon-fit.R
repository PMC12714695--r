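#' Assemble the factorization data matrix from binned tracks
#'
#' The data matrix is the concatenation of all samples, controls first then
#' treatments grouped by condition; the number of latent components `l` is
#' the number of experimental conditions (treatment conditions + control).
#'
#' @param tracks a [binned_tracks()] object.
#' @return list with `V` (G x N matrix), `l`, `conditions` (treatment
#'   conditions followed by the control label), and per-column metadata.
#' @export
assemble_matrix <- function(tracks) {
  stopifnot(inherits(tracks, "binned_tracks"))
  s <- tracks$samples
  treat_conds <- unique(s$condition[!s$is_control])
  list(V = tracks$values,
       l = length(treat_conds) + 1L,
       conditions = c(treat_conds, "background"),
       samples = s)
}

#' Joint deconvolution and de-biasing of multi-assay ChIP-seq tracks
#'
#' Fits the full model: a three-stage constrained KL non-negative matrix
#' factorization separates the samples into one signal per treatment
#' condition plus a shared chromatin-bias signal (controls-only rank-1 fit;
#' background coefficients for the treatments; rank-1 fits of the
#' background-subtracted residuals; relaxed alternating optimization of the
#' full factorization), the mixing matrix learned on a training subset of
#' bins is fixed to extend the signals genome-wide, signal columns are
#' rescaled to a unit 98th percentile, and half-sibling regression removes
#' the remaining chromatin confounder from each mark, yielding fold-change
#' tracks.
#'
#' @param tracks a [binned_tracks()] object (see [preprocess_samples()] or
#'   [simulate_experiment()]).
#' @param n_train_bins number of training bins for the factorization;
#'   default 100000 (use ~400000 for deeply sequenced real data, 5000 for
#'   small simulated genomes), capped at the number of eligible bins.
#' @param min_train_coverage minimum cross-sample mean coverage of a
#'   training bin (use >1 for real data; 0 for simulated data).
#' @param lambda_w,lambda_k L2 regularization weights on the signal and
#'   mixing matrices (defaults 0.01 and 0.001).
#' @param max_iter maximum iterations per factorization stage (default 500).
#' @param tol relative loss-improvement stopping tolerance (default 1e-6).
#' @param rescale_percentile percentile of each signal column aligned to 1.
#' @param hsr_floor minimum half-sibling-regression divisor (default 0.1,
#'   i.e. at most 10-fold amplification).
#' @param seed integer seed driving every stochastic choice (training-bin
#'   sampling); `NULL` uses the current RNG state.
#' @return A `chipdeconv` object: list with `W` (G x l signal matrix, the
#'   chromatin bias `x` in the last column), `K` (l x N mixing matrix),
#'   `s_hat` (G x (l-1) fold-change matrix), `hsr` (per-mark regression
#'   fits), `loss` (per-stage traces), `train_bins`, `conditions`, `bins`,
#'   `samples`, `tracks` and the configuration.
#' @examples
#' sim <- simulate_experiment(sim_config(genome_length = 1e5), seed = 1)
#' fit <- chipdeconv(sim$tracks, n_train_bins = 500, seed = 1)
#' fit
#' @export
chipdeconv <- function(tracks, n_train_bins = 100000L, min_train_coverage = 0,
                       lambda_w = 0.01, lambda_k = 0.001,
                       max_iter = 500L, tol = 1e-6,
                       rescale_percentile = 0.98, hsr_floor = 0.1,
                       seed = NULL) {
  asm <- assemble_matrix(tracks)
  V <- asm$V
  l <- asm$l
  is_ctrl <- asm$samples$is_control
  cond <- asm$samples$condition
  treat_conds <- head(asm$conditions, -1)

  train <- select_training_bins(V, n_train_bins, min_train_coverage,
                                seed = derive_seed(seed, 11L))
  Vt <- V[train, , drop = FALSE]

  # stage 1: chromatin bias from the controls alone
  if (any(is_ctrl)) {
    s1 <- fit_control_stage(Vt[, is_ctrl, drop = FALSE],
                            lambda_w, lambda_k, max_iter, tol)
  } else {
    # no-control mode: the background is fit to all samples jointly
    s1 <- fit_control_stage(Vt, lambda_w, lambda_k, max_iter, tol)
    s1$k_control <- numeric(0)
  }
  # stage 2: explain each treatment as much as possible with the background
  beta <- fit_background_coefficients(Vt[, !is_ctrl, drop = FALSE],
                                      s1$x, lambda_k)
  # stage 3: mark-specific signals from the clipped residuals
  s3 <- fit_specific_stage(Vt[, !is_ctrl, drop = FALSE], s1$x, beta,
                           cond[!is_ctrl], lambda_w, lambda_k, max_iter, tol)

  W0 <- cbind(s3$Y[, treat_conds, drop = FALSE], background = s1$x)
  K0 <- matrix(0, l, ncol(V),
               dimnames = list(c(treat_conds, "background"), colnames(V)))
  if (any(is_ctrl)) K0[l, is_ctrl] <- s1$k_control
  K0[l, !is_ctrl] <- beta
  for (h in seq_along(treat_conds)) {
    j <- !is_ctrl & cond == treat_conds[h]
    K0[h, j] <- s3$k_specific[match(which(j), which(!is_ctrl))]
  }

  # stage 4: relax the block structure and alternate on the training bins
  s4 <- relax_and_alternate(Vt, W0, K0, lambda_w, lambda_k, max_iter, tol)

  # fix K, extend the signals genome-wide, align the 98th percentile to 1
  W_full <- extend_genomewide(V, s4$K, lambda_w)
  rs <- rescale_result(W_full, s4$K, rescale_percentile)
  W <- rs$W
  K <- rs$K
  colnames(W) <- rownames(K)

  # half-sibling regression per mark, fitted on the training bins
  x <- W[, l]
  hsr <- vector("list", length(treat_conds))
  names(hsr) <- treat_conds
  s_hat <- matrix(0, nrow(W), length(treat_conds),
                  dimnames = list(NULL, treat_conds))
  for (h in seq_along(treat_conds)) {
    fitp <- fit_hsr(W[, h], x, subset = train)
    sh <- debias(W[, h], x, fitp, floor = hsr_floor)
    hsr[[h]] <- c(fitp, list(floor = hsr_floor))
    s_hat[, h] <- sh
  }

  structure(list(
    W = W, K = K, s_hat = s_hat, hsr = hsr,
    loss = list(control = s1$loss, specific = s3$loss, relaxed = s4$loss),
    train_bins = train, conditions = asm$conditions,
    bins = tracks$bins, samples = asm$samples, tracks = tracks,
    config = list(n_train_bins = n_train_bins,
                  min_train_coverage = min_train_coverage,
                  lambda_w = lambda_w, lambda_k = lambda_k,
                  max_iter = max_iter, tol = tol,
                  rescale_percentile = rescale_percentile,
                  hsr_floor = hsr_floor, seed = seed),
    call = match.call()), class = "chipdeconv")
}

#' @export
print.chipdeconv <- function(x, ...) {
  cat("Joint ChIP-seq deconvolution fit\n")
  cat(sprintf("  %d bins x %d samples -> %d signals (%s)\n",
              nrow(x$W), ncol(x$K), ncol(x$W),
              paste(colnames(x$W), collapse = ", ")))
  cat(sprintf("  training bins: %d; final regularized KL: %.6g\n",
              length(x$train_bins), tail(x$loss$relaxed, 1)))
  invisible(x)
}

#' @method summary chipdeconv
#' @export
summary.chipdeconv <- function(object, ...) {
  diag <- diagnose_mixing(object)
  hsr <- do.call(rbind, lapply(names(object$hsr), function(h)
    data.frame(mark = h, intercept = object$hsr[[h]]$intercept,
               slope = object$hsr[[h]]$slope, n_fit = object$hsr[[h]]$n_fit)))
  out <- list(mixing = diag, hsr = hsr,
              final_loss = tail(object$loss$relaxed, 1))
  class(out) <- "summary.chipdeconv"
  out
}

#' @export
print.summary.chipdeconv <- function(x, ...) {
  cat("Mixing-matrix diagnostics (background fraction per sample):\n")
  print(x$mixing, digits = 3)
  cat("\nHalf-sibling regressions:\n")
  print(x$hsr, digits = 3)
  cat(sprintf("\nFinal regularized KL loss: %.6g\n", x$final_loss))
  invisible(x)
}

#' Mixing-matrix coefficients of a fit
#' @param object a `chipdeconv` fit.
#' @param ... unused.
#' @return The l x N mixing matrix `K`.
#' @export
coef.chipdeconv <- function(object, ...) object$K

#' @export
fitted.chipdeconv <- function(object, ...) object$W %*% object$K

#' @export
residuals.chipdeconv <- function(object, ...)
  object$tracks$values - fitted(object)

#' Plot signal tracks of a fit along a genomic window
#'
#' Draws, for one mark, the mean raw treatment coverage, the chromatin-bias
#' signal and the de-biased fold-change over a window of bins.
#'
#' @param x a `chipdeconv` fit.
#' @param mark mark (treatment condition) to show; default first.
#' @param window integer range of bin indices to display.
#' @param ... passed to [graphics::plot()].
#' @export
plot.chipdeconv <- function(x, mark = NULL, window = NULL, ...) {
  mark <- mark %||% x$conditions[1]
  window <- window %||% seq_len(min(500L, nrow(x$W)))
  raw <- rowMeans(x$tracks$values[window,
    x$samples$condition == mark, drop = FALSE])
  pos <- start(x$bins)[window]
  graphics::plot(pos, raw / max(raw), type = "l", col = "grey40",
                 xlab = "position (bp)", ylab = "scaled signal",
                 main = paste("chipdeconv:", mark), ...)
  lines(pos, x$W[window, ncol(x$W)] / max(x$W[window, ncol(x$W)]),
        col = "tan3")
  lines(pos, x$s_hat[window, mark] / max(x$s_hat[window, mark]),
        col = "steelblue")
  legend("topright", bty = "n", lty = 1,
         col = c("grey40", "tan3", "steelblue"),
         legend = c("raw mean", "chromatin bias", "fold-change"))
  invisible(x)
}

#' Antibody-quality diagnostic from the mixing matrix
#'
#' For every sample, the fraction of its mixing coefficients assigned to the
#' background row, `K[background, j] / sum(K[, j])`. A low-specificity
#' antibody leaves more of its signal explained by the background, so a high
#' fraction in a treatment sample flags a questionable antibody.
#'
#' @param fit a `chipdeconv` fit, or a mixing matrix with the background row
#'   last.
#' @param flag_fraction treatments above this background fraction are
#'   flagged (default 0.9).
#' @return data.frame with one row per sample: `sample`, `condition`,
#'   `is_control`, `background_fraction`, `flagged`.
#' @export
diagnose_mixing <- function(fit, flag_fraction = 0.9) {
  K <- if (inherits(fit, "chipdeconv")) fit$K else as.matrix(fit)
  frac <- K[nrow(K), ] / colSums(K)
  if (inherits(fit, "chipdeconv")) {
    s <- fit$samples
    data.frame(sample = colnames(K), condition = s$condition,
               is_control = s$is_control, background_fraction = frac,
               flagged = !s$is_control & frac > flag_fraction,
               row.names = NULL)
  } else {
    data.frame(sample = colnames(K) %||% paste0("s", seq_len(ncol(K))),
               background_fraction = frac,
               flagged = frac > flag_fraction, row.names = NULL)
  }
}

#' Call enriched regions for one mark of a fit
#'
#' @param fit a `chipdeconv` fit.
#' @param mark treatment condition name; default first.
#' @param ... passed to [call_regions()].
#' @return A [call_regions()] region set.
#' @export
call_peaks <- function(fit, mark = NULL, ...) {
  stopifnot(inherits(fit, "chipdeconv"))
  mark <- mark %||% colnames(fit$s_hat)[1]
  call_regions(fit$s_hat[, mark], fit$bins, name = mark, ...)
}
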