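test_that("regularized KL loss is monotone non-increasing under the updates", {
  set.seed(1)
  V <- matrix(rpois(200, 6), 20, 10) * 1.0
  W0 <- matrix(runif(60, 0.5, 1.5), 20, 3)
  K0 <- matrix(runif(30, 0.5, 1.5), 3, 10)
  fit <- kl_nmf(V, W0, K0, lambda_w = 0.01, lambda_k = 0.001,
                max_iter = 300, tol = 0)
  expect_true(all(diff(fit$loss) <= 1e-10))
  expect_true(all(fit$W >= 0))
  expect_true(all(fit$K >= 0))

  # and with the penalties off (classic multiplicative updates)
  fit0 <- kl_nmf(V, W0, K0, max_iter = 300, tol = 0)
  expect_true(all(diff(fit0$loss) <= 1e-10))
})

test_that("control stage recovers exact rank-1 structure", {
  set.seed(2)
  c1 <- rpois(60, 10) + 1
  # identical columns: x proportional to the column, equal coefficients
  s <- fit_control_stage(cbind(c1, c1), lambda_w = 0, lambda_k = 0, tol = 1e-12)
  expect_gt(cor(s$x, c1), 1 - 1e-10)
  expect_equal(s$k_control[1], s$k_control[2], tolerance = 1e-8)

  # scaled columns: coefficient ratio equals the scale
  s2 <- fit_control_stage(cbind(c1, 2 * c1), lambda_w = 0, lambda_k = 0,
                          tol = 1e-12)
  expect_equal(s2$k_control[2] / s2$k_control[1], 2, tolerance = 1e-6)
  expect_lt(tail(s2$loss, 1), 1e-8)

  expect_error(fit_control_stage(matrix(0, 5, 2)), "identically zero")
})

test_that("control stage matches a 500-restart independent rank-1 reference", {
  set.seed(5)
  V <- matrix(rpois(100, 8), 50, 2) * 1.0
  ours <- fit_control_stage(V, 0.01, 0.001, max_iter = 5000, tol = 1e-12)
  ours_loss <- ref_kl_loss(V, cbind(ours$x), rbind(ours$k_control),
                           0.01, 0.001)
  best <- min(vapply(1:500, function(s)
    ref_kl_nmf(V, 1, 0.01, 0.001, n_iter = 1000, seed = s), numeric(1)))
  expect_lt(ours_loss, best + 1e-6)
})

test_that("background coefficients solve the 1-D KL objective", {
  set.seed(6)
  x <- exp(rnorm(50))
  # exact multiple (no regularization): beta recovers the multiplier
  expect_equal(fit_background_coefficients(cbind(3 * x), x, lambda_k = 0),
               3, tolerance = 1e-12)
  # orthogonal support: nothing can be explained by the background
  x0 <- x; x0[1:25] <- 0
  v0 <- numeric(50); v0[1:25] <- 5
  expect_equal(fit_background_coefficients(cbind(v0), x0, lambda_k = 0.001),
               0)
  # random column: closed form matches an independent 1-D minimizer
  v <- rpois(50, 5 * x) * 1.0
  b <- fit_background_coefficients(cbind(v), x, lambda_k = 0.001)
  f <- function(beta) {
    wk <- beta * x
    pos <- v > 0 & x > 0
    sum(beta * x) - sum(v[pos]) + sum(v[pos] * log(v[pos] / wk[pos])) +
      0.001 * beta^2
  }
  grid <- seq(b / 3, b * 3, length.out = 20000)
  b_grid <- grid[which.min(vapply(grid, f, numeric(1)))]
  b_ref <- optimize(f, c(b_grid / 1.1, b_grid * 1.1), tol = 1e-12)$minimum
  expect_equal(b, b_ref, tolerance = 1e-6)

  expect_error(fit_background_coefficients(cbind(v), numeric(50)),
               "identically zero")
})

test_that("specific stage factorizes residual blocks per condition", {
  set.seed(7)
  x <- exp(rnorm(40))
  y <- numeric(40); y[sample(40, 10)] <- rpois(10, 8) + 1
  # two replicates that are exact multiples: exact rank-1, zero KL
  V <- cbind(2 * y + 1 * x, 4 * y + 2 * x)
  s <- fit_specific_stage(V, x, beta = c(1, 2), condition = c("h", "h"),
                          lambda_w = 0, lambda_k = 0, tol = 1e-13,
                          max_iter = 2000)
  expect_gt(cor(s$Y[, 1], y), 1 - 1e-8)
  expect_equal(s$k_specific[2] / s$k_specific[1], 2, tolerance = 1e-6)

  # single replicate: the signal is the residual up to its coefficient
  s1 <- fit_specific_stage(cbind(3 * y + x), x, beta = 1, condition = "h",
                           lambda_w = 0, lambda_k = 0, tol = 1e-13)
  expect_equal(s1$Y[, 1] * s1$k_specific[1], 3 * y, tolerance = 1e-8)

  # an identically-zero residual warns and yields a zero signal
  expect_warning(
    s0 <- fit_specific_stage(cbind(x), x, beta = 1, condition = "h"),
    "identically zero")
  expect_true(all(s0$Y == 0))
})

test_that("an exact factorization is a fixed point of the relaxed stage", {
  set.seed(8)
  W0 <- matrix(runif(60, 0.5, 2), 20, 3)
  K0 <- matrix(runif(12, 0.5, 2), 3, 4)
  V <- W0 %*% K0
  fit <- relax_and_alternate(V, W0, K0, lambda_w = 0, lambda_k = 0,
                             max_iter = 50, tol = 0)
  expect_lt(tail(fit$loss, 1), 1e-9)
})

test_that("percentile rescaling is an exact reparameterization", {
  set.seed(9)
  W <- matrix(rexp(300), 100, 3)
  K <- matrix(runif(12, 0.5, 2), 3, 4)
  rs <- rescale_result(W, K)
  expect_equal(apply(rs$W, 2, quantile, 0.98, names = FALSE), rep(1, 3),
               tolerance = 1e-12)
  expect_equal(rs$W %*% rs$K, W %*% K, tolerance = 1e-12)
  # a column of ones is already aligned
  W1 <- cbind(rep(1, 100))
  rs1 <- rescale_result(W1, matrix(1, 1, 2))
  expect_identical(rs1$W, W1)
  expect_warning(rescale_result(cbind(numeric(100)), matrix(1, 1, 1)),
                 "zero")
})

test_that("training-bin selection is uniform over eligible bins", {
  V <- matrix(5, 50, 2)
  expect_identical(select_training_bins(V, 50, min_mean = 0), 1:50)
  V[1:10, ] <- 0  # ineligible at threshold 1
  expect_warning(idx <- select_training_bins(V, 45, min_mean = 1),
                 "eligible")
  expect_identical(idx, 11:50)

  counts <- integer(50)
  for (s in 1:200) {
    idx <- select_training_bins(V + 1, 10, min_mean = 0, seed = s)
    counts[idx] <- counts[idx] + 1L
  }
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("genome-wide extension is row-local and chunk-invariant", {
  set.seed(10)
  V <- matrix(rpois(500, 6), 100, 5) * 1.0
  V[7, ] <- 0
  K <- matrix(runif(10, 0.5, 2), 2, 5)
  W <- extend_genomewide(V, K, lambda_w = 0.01)
  expect_true(all(W[7, ] == 0))
  chunks <- rbind(extend_genomewide(V[1:40, ], K, lambda_w = 0.01),
                  extend_genomewide(V[41:100, ], K, lambda_w = 0.01))
  expect_identical(W, unname(chunks))
})

test_that("replicate order within a condition does not change the signals", {
  sim <- simulate_experiment(sim_config(genome_length = 1e5), seed = 21)
  tr <- sim$tracks
  fit1 <- chipdeconv(tr, n_train_bins = 500, seed = 3)

  perm <- seq_len(ncol(tr$values))
  swap <- which(tr$samples$condition == "narrow_mark")[c(2, 1, 3)]
  perm[which(tr$samples$condition == "narrow_mark")] <- swap
  tr2 <- tr
  tr2$values <- tr$values[, perm]
  tr2$samples <- tr$samples[perm, ]
  tr2$samples$replicate <- tr$samples$replicate
  fit2 <- chipdeconv(tr2, n_train_bins = 500, seed = 3)

  # equivariant up to numerical tolerance: summation order differs slightly
  # and the flat scale direction amplifies rounding over many iterations
  expect_equal(fit1$W, fit2$W, tolerance = 0.01)
  expect_equal(unname(fit1$K[, perm]), unname(fit2$K), tolerance = 0.01)
})

test_that("the chromatin-bias column tracks the true compound bias", {
  res <- default_sim_fit(1)
  truth_x <- res$sim$truth$a * res$sim$truth$m * res$sim$truth$n
  x <- res$fit$W[, "background"]
  expect_gt(cor(log(x + 1e-9), log(truth_x)), 0.9)
})

test_that("low-specificity samples show higher background mixing fractions", {
  res <- default_sim_fit(1)
  diag <- diagnose_mixing(res$fit)
  k <- res$sim$truth$k
  treat <- !res$sim$truth$sheet$is_control
  # the paper's antibody-quality readout: background fraction anti-correlates
  # with the simulated specificity k across treatment samples
  expect_lt(cor(k[treat], diag$background_fraction[treat]), 0)
  # and every control is essentially pure background
  expect_true(all(diag$background_fraction[!treat] > 0.95))
  # fractions over rows sum to one per sample by construction
  K <- coef(res$fit)
  expect_equal(colSums(K / rep(colSums(K), each = nrow(K))),
               rep(1, ncol(K)), ignore_attr = TRUE)
})
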