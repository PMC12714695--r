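suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# --- read-level fixtures ----------------------------------------------------

# stranded single-end reads from fragments of length `fraglen` centred at
# `centers`: plus reads start at the fragment 5' end, minus reads end at the
# fragment 3' end
make_stranded_reads <- function(centers, fraglen, read_len = 50L,
                                chrom = "chrT", chrom_len = 1e6L) {
  half <- fraglen / 2
  n <- length(centers)
  plus <- seq_len(n) %% 2L == 0L
  start5 <- round(centers - half)
  end3 <- round(centers + half)
  gr <- GRanges(chrom,
                IRanges(start = ifelse(plus, start5, end3 - read_len + 1L),
                        width = read_len),
                strand = ifelse(plus, "+", "-"),
                seqlengths = setNames(chrom_len, chrom))
  suppressWarnings(trim(gr))
}

# write a small SAM and convert it to BAM (text-only fixture, built at test
# time); reads is a data.frame: qname, flag, chrom, pos, seq_len
make_test_bam <- function(reads, chrom_lens, dir = tempdir()) {
  sam <- file.path(dir, paste0("fx", as.integer(stats::runif(1, 1, 1e8)), ".sam"))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lens), chrom_lens))
  reads <- reads[order(match(reads$chrom, names(chrom_lens)), reads$pos), ]
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                  reads$qname, reads$flag, reads$chrom, reads$pos,
                  reads$seq_len,
                  vapply(reads$seq_len, function(n)
                    paste(rep("A", n), collapse = ""), ""),
                  vapply(reads$seq_len, function(n)
                    paste(rep("I", n), collapse = ""), ""))
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, sub("\\.sam$", "", sam), overwrite = TRUE)
  bam
}

# --- matrix fixtures --------------------------------------------------------

# exact low-rank instance of the generative structure: sparse specific signal
# plus a smooth positive background, combined by a positive mixing matrix
make_model_toy <- function(G, n_ctrl, n_treat, seed, noise = TRUE) {
  set.seed(seed)
  x <- exp(rnorm(G, 1, 0.4))
  y <- numeric(G)
  pk <- sample(G, round(G / 5))
  y[pk] <- exp(rnorm(length(pk), 1.5, 0.3))
  W <- cbind(y, x)
  K <- rbind(c(rep(0.02, n_ctrl), runif(n_treat, 2, 3)),
             c(runif(n_ctrl, 4, 5), runif(n_treat, 3, 4)))
  E <- W %*% K
  V <- if (noise) matrix(rpois(length(E), E), G) else E
  cond <- c(rep("ctrl", n_ctrl), rep("mark", n_treat))
  list(V = V * 1.0, W = W, K = K,
       is_ctrl = cond == "ctrl", cond = cond)
}

# independent plain multiplicative-update regularized KL-NMF (the classic
# heuristic with additive L2 terms in the denominator), used as an oracle
ref_kl_nmf <- function(V, l, lambda_w, lambda_k, n_iter = 2000L, seed = 1L) {
  set.seed(seed)
  G <- nrow(V); N <- ncol(V)
  W <- matrix(runif(G * l, 0.1, 1) * mean(V), G, l)
  K <- matrix(runif(l * N, 0.1, 1), l, N)
  for (it in seq_len(n_iter)) {
    WK <- W %*% K; R <- V / pmax(WK, 1e-12); R[V == 0] <- 0
    W <- W * (R %*% t(K)) /
      (matrix(rowSums(K), G, l, byrow = TRUE) + 2 * lambda_w * W + 1e-12)
    WK <- W %*% K; R <- V / pmax(WK, 1e-12); R[V == 0] <- 0
    K <- K * (t(W) %*% R) /
      (matrix(colSums(W), l, N) + 2 * lambda_k * K + 1e-12)
  }
  ref_kl_loss(V, W, K, lambda_w, lambda_k)
}

ref_kl_loss <- function(V, W, K, lambda_w, lambda_k) {
  WK <- pmax(W %*% K, 1e-300)
  pos <- V > 0
  sum(WK) - sum(V[pos]) + sum(V[pos] * log(V[pos] / WK[pos])) +
    lambda_w * sum(W^2) + lambda_k * sum(K^2)
}

# staged+relaxed factorization of a toy matrix, returning the final
# regularized KL (mirrors the fitting path on a bare matrix)
staged_toy_loss <- function(V, is_ctrl, cond, lambda_w = 0.01,
                            lambda_k = 0.001, max_iter = 200000L) {
  s1 <- fit_control_stage(V[, is_ctrl, drop = FALSE], lambda_w, lambda_k,
                          max_iter = 5000L, tol = 1e-12)
  beta <- fit_background_coefficients(V[, !is_ctrl, drop = FALSE], s1$x,
                                      lambda_k)
  s3 <- fit_specific_stage(V[, !is_ctrl, drop = FALSE], s1$x, beta,
                           cond[!is_ctrl], lambda_w, lambda_k, 5000L, 1e-12)
  tc <- unique(cond[!is_ctrl])
  W0 <- cbind(s3$Y[, tc, drop = FALSE], s1$x)
  l <- length(tc) + 1L
  K0 <- matrix(0, l, ncol(V))
  K0[l, is_ctrl] <- s1$k_control
  K0[l, !is_ctrl] <- beta
  for (h in seq_along(tc)) {
    j <- !is_ctrl & cond == tc[h]
    K0[h, j] <- s3$k_specific[match(which(j), which(!is_ctrl))]
  }
  s4 <- relax_and_alternate(V, W0, K0, lambda_w, lambda_k,
                            max_iter = max_iter, tol = 1e-15)
  tail(s4$loss, 1)
}

# --- shared simulation fit (memoized within a test run) ---------------------

.fit_cache <- new.env(parent = emptyenv())

default_sim_fit <- function(seed) {
  key <- paste0("s", seed)
  if (is.null(.fit_cache[[key]])) {
    sim <- simulate_experiment(sim_config(), seed = seed)
    fit <- chipdeconv(sim$tracks, n_train_bins = 5000, seed = seed)
    .fit_cache[[key]] <- list(sim = sim, fit = fit)
  }
  .fit_cache[[key]]
}

small_sample_sheet_csv <- function(path = tempfile(fileext = ".csv")) {
  df <- data.frame(
    filepath = c("wce1.bam", "wce2.bam",
                 sprintf("k4_%d.bam", 1:3), sprintf("k27_%d.bam", 1:3)),
    condition = c("WCE", "WCE", rep("H3K4me3", 3), rep("H3K27me3", 3)),
    is_control = c(TRUE, TRUE, rep(FALSE, 6)),
    replicate = c(1, 2, 1:3, 1:3))
  utils::write.csv(df, path, row.names = FALSE)
  path
}
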