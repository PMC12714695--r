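# Constrained KL non-negative matrix factorization.
#
# All stages minimize the generalized Kullback-Leibler divergence
#   D(V || WK) = sum V log(V / WK) - V + WK
# plus L2 penalties lambda_w * ||W||^2 + lambda_k * ||K||^2, using exact
# majorization-minimization updates: each element solves the quadratic
# 2*lambda*w^2 + B*w - C = 0 arising from the standard KL auxiliary
# function, which reduces to the classic multiplicative update at lambda = 0
# and keeps the regularized loss monotonically non-increasing.

#' Regularized generalized KL divergence
#'
#' @param V data matrix (non-negative).
#' @param WK current reconstruction `W %*% K`.
#' @param lambda_w,lambda_k L2 weights on `W` and `K`.
#' @param W,K current factors (needed only when the penalties are nonzero).
#' @return The scalar loss.
#' @export
kl_loss <- function(V, WK, lambda_w = 0, lambda_k = 0, W = NULL, K = NULL) {
  pos <- V > 0
  d <- sum(WK) - sum(V[pos]) + sum(V[pos] * log(V[pos] / pmax(WK[pos], .EPS)))
  if (lambda_w > 0) d <- d + lambda_w * sum(W^2)
  if (lambda_k > 0) d <- d + lambda_k * sum(K^2)
  d
}

# V/(WK) with the 0/0 convention 0; guards vanishing reconstructions
.kl_ratio <- function(V, WK) {
  R <- V / pmax(WK, .EPS)
  R[V == 0] <- 0
  R
}

# solve 2*lambda*w^2 + B*w - C = 0 elementwise (non-negative root)
.mm_solve <- function(C, B, lambda) {
  if (lambda > 0) (sqrt(B^2 + 8 * lambda * C) - B) / (4 * lambda)
  else ifelse(B > 0, C / B, 0)
}

.mm_update_w <- function(V, W, K, lambda_w) {
  R <- .kl_ratio(V, W %*% K)
  C <- W * (R %*% t(K))
  B <- matrix(rowSums(K), nrow(W), ncol(W), byrow = TRUE)
  .mm_solve(C, B, lambda_w)
}

.mm_update_k <- function(V, W, K, lambda_k) {
  R <- .kl_ratio(V, W %*% K)
  C <- K * (t(W) %*% R)
  B <- matrix(colSums(W), nrow(K), ncol(K))
  .mm_solve(C, B, lambda_k)
}

#' Alternating regularized KL-NMF
#'
#' Alternates exact majorization-minimization updates of `W` and `K` (either
#' may be held fixed) until the relative loss improvement drops below `tol`
#' or `max_iter` iterations.
#'
#' @param V non-negative data matrix.
#' @param W,K initial factors.
#' @param lambda_w,lambda_k L2 penalty weights.
#' @param update_w,update_k whether to update each factor.
#' @param max_iter,tol stopping rule.
#' @return list with `W`, `K`, and the per-iteration `loss` trace.
#' @export
kl_nmf <- function(V, W, K, lambda_w = 0, lambda_k = 0,
                   update_w = TRUE, update_k = TRUE,
                   max_iter = 500L, tol = 1e-6) {
  loss <- numeric(max_iter)
  prev <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    if (update_w) W <- .mm_update_w(V, W, K, lambda_w)
    if (update_k) K <- .mm_update_k(V, W, K, lambda_k)
    cur <- kl_loss(V, W %*% K, lambda_w, lambda_k, W, K)
    loss[it] <- cur
    if (cur > prev + 1e-8 * (1 + abs(prev)))
      stop(sprintf("KL loss increased at iteration %d (%.6g -> %.6g)",
                   it, prev, cur))
    if (is.finite(prev) && (prev - cur) <= tol * (1 + abs(prev))) break
    prev <- cur
  }
  list(W = W, K = K, loss = loss[seq_len(it)])
}

#' Stage 1: factorize the control block alone
#'
#' Rank-1 regularized KL-NMF of the control columns, `V_c ~ x k_c'`; `x` is
#' the shared chromatin-bias signal and `k_c` the per-control mixing
#' coefficients.
#'
#' @param V_controls G x r_c matrix of control columns.
#' @param lambda_w,lambda_k,max_iter,tol see [kl_nmf()].
#' @return list with `x`, `k_control`, `loss`.
#' @export
fit_control_stage <- function(V_controls, lambda_w = 0.01, lambda_k = 0.001,
                              max_iter = 500L, tol = 1e-6) {
  V_controls <- as.matrix(V_controls)
  if (all(V_controls == 0)) stop("control block is identically zero")
  x0 <- rowMeans(V_controls)
  k0 <- colSums(V_controls) / max(sum(x0), .EPS)
  fit <- kl_nmf(V_controls, cbind(x0), rbind(k0),
                lambda_w = lambda_w, lambda_k = lambda_k,
                max_iter = max_iter, tol = tol)
  list(x = drop(fit$W), k_control = drop(fit$K), loss = fit$loss)
}

#' Stage 2: background coefficients of the treatment columns
#'
#' With the chromatin-bias signal `x` fixed, finds for every treatment
#' column the scalar `beta >= 0` minimizing `KL(V_j || beta x) +
#' lambda_k beta^2`, i.e. explaining as much of the treatment as possible
#' with the control signal alone. The regularized 1-D objective has the
#' closed-form minimizer of `2 lambda beta^2 + sum(x) beta - sum(v) = 0`
#' (the sum of `v` taken over bins where `x > 0`).
#'
#' @param V_treatments G x n_t matrix of treatment columns.
#' @param x fixed chromatin-bias signal.
#' @param lambda_k L2 weight on the coefficients.
#' @return Numeric vector of background coefficients, one per column.
#' @export
fit_background_coefficients <- function(V_treatments, x, lambda_k = 0.001) {
  V_treatments <- as.matrix(V_treatments)
  if (all(x == 0)) stop("chromatin-bias signal is identically zero")
  S_x <- sum(x)
  S_v <- unname(colSums(V_treatments[x > 0, , drop = FALSE]))
  if (lambda_k > 0) (sqrt(S_x^2 + 8 * lambda_k * S_v) - S_x) / (4 * lambda_k)
  else S_v / S_x
}

#' Stage 3: mark-specific signals from the background-subtracted residual
#'
#' Subtracts each treatment column's background component `beta_j x`,
#' clips at zero, and factorizes each condition's residual block rank-1 to
#' obtain the mark-specific signal `y_h` and per-replicate coefficients.
#'
#' @param V_treatments G x n_t treatment matrix.
#' @param x fixed chromatin-bias signal.
#' @param beta stage-2 background coefficients.
#' @param condition per-column condition labels (length n_t).
#' @param lambda_w,lambda_k,max_iter,tol see [kl_nmf()].
#' @return list with `Y` (G x n_conditions), `k_specific` (per column), and
#'   per-condition `loss` traces.
#' @export
fit_specific_stage <- function(V_treatments, x, beta, condition,
                               lambda_w = 0.01, lambda_k = 0.001,
                               max_iter = 500L, tol = 1e-6) {
  V_treatments <- as.matrix(V_treatments)
  R <- pmax(V_treatments - outer(x, beta), 0)
  conds <- unique(condition)
  Y <- matrix(0, nrow(R), length(conds), dimnames = list(NULL, conds))
  k_specific <- numeric(ncol(R))
  losses <- vector("list", length(conds))
  names(losses) <- conds
  for (h in seq_along(conds)) {
    cols <- which(condition == conds[h])
    Rh <- R[, cols, drop = FALSE]
    if (all(Rh == 0)) {
      warning("residual for condition '", conds[h],
              "' is identically zero; its signal is set to 0")
      next
    }
    y0 <- rowMeans(Rh)
    k0 <- colSums(Rh) / max(sum(y0), .EPS)
    fit <- kl_nmf(Rh, cbind(y0), rbind(k0),
                  lambda_w = lambda_w, lambda_k = lambda_k,
                  max_iter = max_iter, tol = tol)
    Y[, h] <- drop(fit$W)
    k_specific[cols] <- drop(fit$K)
    losses[[h]] <- fit$loss
  }
  list(Y = Y, k_specific = k_specific, loss = losses)
}

#' Stage 4: relax the mixing-matrix structure and alternate
#'
#' Releases the hard block structure of the staged mixing matrix (exact
#' zeros are unlocked to a small positive value so the multiplicative
#' updates can move them) and alternates regularized KL updates of `W` and
#' `K` from the staged initialization, capturing imperfect antibody
#' specificity as off-block mixing coefficients.
#'
#' @param V full training matrix (G x N).
#' @param W0,K0 staged initialization.
#' @param lambda_w,lambda_k,max_iter,tol see [kl_nmf()].
#' @param unlock_eps relative size of the value used to unlock exact zeros.
#' @return list with `W`, `K`, `loss`.
#' @export
relax_and_alternate <- function(V, W0, K0, lambda_w = 0.01, lambda_k = 0.001,
                                max_iter = 500L, tol = 1e-6,
                                unlock_eps = 1e-6) {
  W0[W0 <= 0] <- unlock_eps * max(W0)
  K0[K0 <= 0] <- unlock_eps * max(K0)
  kl_nmf(V, W0, K0, lambda_w = lambda_w, lambda_k = lambda_k,
         max_iter = max_iter, tol = tol)
}

#' Rescale signal columns to a unit upper percentile
#'
#' Divides each signal column by its 98th percentile and multiplies the
#' matching mixing-matrix row by the same factor, so the reconstruction
#' `W %*% K` is unchanged while per-sample depth factors concentrate in the
#' mixing coefficients. The percentile (rather than the maximum) avoids
#' outlier influence.
#'
#' @param W signal matrix.
#' @param K mixing matrix.
#' @param percentile percentile to align to 1 (default 0.98).
#' @return list with rescaled `W`, `K` and the per-column scale factors `q`.
#' @export
rescale_result <- function(W, K, percentile = 0.98) {
  q <- apply(W, 2, stats::quantile, probs = percentile, names = FALSE)
  for (j in seq_along(q)) {
    if (q[j] <= 0) {
      warning("column ", j, " has a zero ", round(100 * percentile),
              "th percentile; left unscaled")
      q[j] <- 1
    }
    W[, j] <- W[, j] / q[j]
    K[j, ] <- K[j, ] * q[j]
  }
  list(W = W, K = K, q = q)
}

#' Select training bins for the factorization
#'
#' Uniform sample without replacement among bins whose cross-sample mean
#' coverage exceeds `min_mean`; deterministic under `seed`. If fewer bins are
#' eligible than requested, all eligible bins are used with a warning.
#'
#' @param V data matrix.
#' @param n number of bins requested.
#' @param min_mean minimum cross-sample mean coverage for eligibility.
#' @param seed optional integer seed.
#' @return Sorted integer vector of bin indices.
#' @export
select_training_bins <- function(V, n, min_mean = 0, seed = NULL) {
  eligible <- which(rowMeans(V) > min_mean)
  if (length(eligible) == 0L) stop("no bins exceed the coverage threshold")
  if (length(eligible) <= n) {
    if (length(eligible) < n)
      warning("only ", length(eligible), " eligible bins for ", n,
              " requested; using all of them")
    return(eligible)
  }
  sort(with_seed(seed, sample(eligible, n)))
}

#' Extend the signal matrix genome-wide under a fixed mixing matrix
#'
#' For each bin independently, finds non-negative signal weights minimizing
#' the regularized KL divergence to that bin's row of `V` with `K` fixed.
#' The solve is strictly row-local (deterministic initialization from the
#' row itself, a fixed number of majorization-minimization updates), so
#' chunked and whole-genome execution give identical results.
#'
#' @param V full G x N matrix.
#' @param K fixed mixing matrix.
#' @param lambda_w L2 weight on the signal matrix.
#' @param n_iter number of updates (default 200).
#' @return G x l signal matrix.
#' @export
extend_genomewide <- function(V, K, lambda_w = 0.01, n_iter = 200L) {
  V <- as.matrix(V)
  W <- matrix(rowSums(V) / max(sum(K), .EPS), nrow(V), nrow(K))
  for (it in seq_len(n_iter)) W <- .mm_update_w(V, W, K, lambda_w)
  colnames(W) <- rownames(K)
  W
}
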