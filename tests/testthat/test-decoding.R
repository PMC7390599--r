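# One-versus-one ridge classification, penalty tuning, cross-temporal
# decoding, permutation significance and p-value aggregation.

test_that("OVO builds one classifier per class pair and votes correctly", {
  set.seed(1)
  n <- 40
  y4 <- rep(1:4, each = n / 4)
  X <- cbind(y4 + rnorm(n, sd = 0.05), rnorm(n))
  fit <- fit_ridge_ovo(X, y4, lambda = 0.01)
  expect_length(fit$fits, 6) # 4 classes -> 6 binary classifiers
  y2 <- rep(1:2, each = n / 2)
  expect_length(fit_ridge_ovo(X, y2, lambda = 0.01)$fits, 1)
  expect_error(fit_ridge_ovo(X, rep(1, n)), "2 classes")
  # linearly separable toy problem: perfect accuracy at small lambda
  expect_equal(mean(predict(fit, X) == y4), 1)
})

test_that("vote ties resolve by summed signed margins, then class index", {
  pairs <- utils::combn(1:4, 2)
  # class 4 loses all pairs; 1>2, 2>3, 3>1 cycle: votes (2, 2, 2, 0)
  margins <- matrix(0, 1, 6)
  colnames_pairs <- apply(pairs, 2, paste, collapse = "-")
  m <- c("1-2" = 0.1, "1-3" = -0.2, "1-4" = 0.5,
         "2-3" = 0.9, "2-4" = 0.5, "3-4" = 0.5)
  margins[1, ] <- m[colnames_pairs]
  # summed signed margins: s1 = .1 - .2 + .5 = .4; s2 = -.1 + .9 + .5 = 1.3;
  # s3 = .2 - .9 + .5 = -.2 -> class 2 wins the tie
  expect_equal(valuedyn:::.ovo_predict(margins, pairs, 1:4), 2)
  # exact three-way score tie -> lowest class index
  m0 <- c("1-2" = 0.1, "1-3" = -0.1, "1-4" = 0.5,
          "2-3" = 0.1, "2-4" = 0.5, "3-4" = 0.5)
  margins[1, ] <- m0[colnames_pairs]
  # s1 = .5, s2 = .5, s3 = .5
  expect_equal(valuedyn:::.ovo_predict(margins, pairs, 1:4), 1)
})

test_that("closed-form ridge matches an independent numerical optimiser", {
  set.seed(2)
  Z <- matrix(rnorm(60), 20, 3)
  y <- ifelse(rnorm(20) > 0, 1, -1)
  lambda <- 2.5
  fit <- valuedyn:::.ridge_coef(Z, y, lambda)
  obj <- function(par) {
    w <- par[1:3]; b <- par[4]
    sum((y - Z %*% w - b)^2) + lambda * sum(w^2)
  }
  opt <- stats::optim(rep(0, 4), obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(fit$w), opt$par[1:3], tolerance = 1e-5)
  expect_equal(fit$b0, opt$par[4], tolerance = 1e-5)
  # the SVD path and the dual kernel form agree with the primal solution
  path <- valuedyn:::.ridge_path(Z, y, c(0.1, lambda, 10))
  expect_equal(unname(path$W[, 2]), unname(fit$w), tolerance = 1e-10)
  K <- tcrossprod(Z)
  Kte <- Z %*% t(Z)
  dual <- valuedyn:::.dual_ridge_margins(K, Kte, seq_len(20), y, lambda)
  expect_equal(dual, drop(Z %*% fit$w + fit$b0), tolerance = 1e-10)
  # the sufficient-statistics pair solver equals the direct fit
  y4 <- rep(1:4, 5)
  pairs <- utils::combn(1:4, 2)
  fits <- valuedyn:::.ridge_pairs(valuedyn:::.class_stats(Z, y4, 1:4),
                                  pairs, 1:4, lambda)
  for (pr in 1:6) {
    rows <- y4 %in% pairs[, pr]
    ref <- valuedyn:::.ridge_coef(Z[rows, , drop = FALSE],
                                  ifelse(y4[rows] == pairs[1, pr], 1, -1),
                                  lambda)
    expect_equal(unname(fits$W[, pr]), unname(ref$w), tolerance = 1e-10)
    expect_equal(fits$b0[pr], ref$b0, tolerance = 1e-10)
  }
  # the vectorised 3-feature batch solver matches per-pair fits on every bin
  Parr <- array(rnorm(20 * 4 * 3), dim = c(20, 4, 3))
  fb <- valuedyn:::.ridge_pairs_batch3(Parr, y4, 1:4, pairs, lambda)
  for (b in 1:4) {
    ref_b <- valuedyn:::.ridge_pairs(
      valuedyn:::.class_stats(Parr[, b, ], y4, 1:4), pairs, 1:4, lambda)
    expect_equal(unname(fb$W[, , b]), unname(ref_b$W), tolerance = 1e-10)
    expect_equal(unname(fb$b0[, b]), unname(ref_b$b0), tolerance = 1e-10)
  }
  # stacked margins agree with the per-bin products
  Zt <- matrix(rnorm(30), 10, 3)
  sm <- valuedyn:::.stack_margins(Zt, fb)
  for (b in 1:4)
    expect_equal(sm[(b - 1) * 10 + 1:10, ],
                 Zt %*% fb$W[, , b] +
                   matrix(fb$b0[, b], 10, 6, byrow = TRUE),
                 tolerance = 1e-12)
})

test_that("lambda grid has 15 candidates and ties go to the smallest", {
  expect_length(decoder_config()$lambda_grid, 15)
  expect_equal(decoder_config()$lambda_grid[1], 1e-2)
  expect_equal(decoder_config()$lambda_grid[15], 1e5)
  # perfectly separable toy data: accuracy flat in lambda -> smallest returned
  labels <- expand.grid(value = 1:4, type = 1:2)
  labels <- labels[rep(1:8, each = 6), ]; rownames(labels) <- NULL
  n <- nrow(labels)
  set.seed(3)
  X <- array(rnorm(n * 2 * 3, sd = 1e-6), dim = c(n, 2, 3))
  X[, 1, ] <- X[, 1, ] + labels$value * 10
  X[, 2, ] <- X[, 2, ] + labels$value * 5 # both features informative
  pop <- structure(list(
    X = X, labels = labels,
    bins = data.frame(epoch = "cue", t_rel = c(0.5, 1, 1.5),
                      t_abs = c(0.5, 1, 1.5), abs_start = c(.45, .95, 1.45),
                      abs_end = c(.55, 1.05, 1.55), width = .1),
    task = task_config(), unit_ids = c("a", "b"), dataset = 1, seed = 1),
    class = "pseudopop")
  cfg <- quick_config()
  lam <- tune_lambda(pop, cfg, seed = 4)
  expect_equal(as.numeric(lam), cfg$lambda_grid[1])
  expect_true(all(attr(lam, "accuracy") == 1))
  # determinism
  expect_identical(as.numeric(tune_lambda(pop, cfg, seed = 4)),
                   as.numeric(lam))
})

test_that("CTD diagonal equals standard decoding under shared folds", {
  pops <- tiny_pops(seed = 5)
  cfg <- quick_config()
  ctd <- cross_temporal_decode(pops[[1]], cfg, seed = 6)
  std <- decode_timecourse(pops[[1]], cfg, lambda = ctd$lambda, seed = 6)
  expect_identical(std$diagonal, ctd$diagonal)
  expect_true(all(ctd$accuracy >= 0 & ctd$accuracy <= 1))
})

test_that("a stable population generalises across time; accuracy high", {
  pops <- tiny_pops(seed = 7, composition = c(stable_linear = 10),
                    trials_per_condition = 12, draw = 10,
                    param_ranges = list(value_gain = c(5, 7)))
  cfg <- quick_config()
  ctd <- cross_temporal_decode(pops[[1]], cfg, seed = 8)
  delay <- which(pops[[1]]$bins$t_abs[ctd$train_bins] >= 0.6)
  expect_gt(mean(diag(ctd$accuracy)[delay]), 0.9)
  # off-diagonal close to diagonal for a time-invariant code
  expect_gt(mean(ctd$accuracy[delay, delay]), 0.8)
})

test_that("a sequential population concentrates accuracy near the diagonal", {
  pops <- tiny_pops(seed = 9, composition = c(sequential = 24),
                    trials_per_condition = 16, draw = 14,
                    param_ranges = list(seq_gain = c(8, 12),
                                        bump_sd = c(0.10, 0.15)))
  cfg <- quick_config()
  ctd <- cross_temporal_decode(pops[[1]], cfg, seed = 10)
  gap <- diag_offdiag_gap(ctd)
  expect_gt(gap, 0.2)
})

test_that("bin-permuting the tensor permutes the accuracy matrix exactly", {
  pops <- tiny_pops(seed = 11, composition = c(stable_linear = 6, untuned = 4))
  pop <- pops[[1]]
  cfg <- quick_config()
  nb <- dim(pop$X)[3]
  bins_idx <- seq_len(nb)
  ctd <- cross_temporal_decode(pop, cfg, lambda = 10, seed = 12,
                               train_bins = bins_idx, test_bins = bins_idx)
  set.seed(13)
  perm <- sample(nb)
  pop2 <- pop
  pop2$X <- pop$X[, , perm]
  ctd2 <- cross_temporal_decode(pop2, cfg, lambda = 10, seed = 12,
                                train_bins = bins_idx, test_bins = bins_idx)
  expect_equal(ctd2$accuracy, ctd$accuracy[perm, perm], tolerance = 1e-12)
})

test_that("label-shuffled decoding sits at 4-class chance", {
  cfg <- quick_config()
  accs <- vapply(1:4, function(k) {
    pops <- tiny_pops(seed = 20 + k, composition = c(untuned = 8),
                      n_datasets = 1)
    mean(cross_temporal_decode(pops[[1]], cfg, seed = k)$accuracy)
  }, numeric(1))
  se <- stats::sd(accs) / 2
  expect_lt(abs(mean(accs) - 0.25), max(3 * se, 0.05))
})

test_that("permutation p-values: boundary zero flag and null calibration", {
  cfg <- quick_config()
  # strong signal: observed beats every permutation -> p = 0, flagged
  pops <- tiny_pops(seed = 30, composition = c(stable_linear = 8),
                    param_ranges = list(value_gain = c(4, 6)), n_datasets = 1)
  pt <- permutation_test(pops[[1]], cfg, seed = 31, n_perm = 20,
                         train_bins = bins_in_window(pops[[1]]$bins,
                                                     c(1, 2))[1:2])
  expect_true(all(pt$p[cbind(1:2, match(pt$observed$train_bins,
                                        pt$observed$test_bins))] == 0))
  expect_true(any(pt$zero_flag))
  # pure noise: p roughly uniform
  popsn <- tiny_pops(seed = 32, composition = c(untuned = 6), n_datasets = 1)
  tb <- bins_in_window(popsn[[1]]$bins, c(1, 2))[1:2]
  ptn <- permutation_test(popsn[[1]], cfg, seed = 33, n_perm = 40,
                          train_bins = tb, test_bins = tb)
  expect_gt(mean(ptn$p), 0.25)
  expect_lt(mean(ptn$p), 0.75)
})

test_that("p-value aggregation follows 2x mean with a cap", {
  expect_equal(aggregate_pvalues(as.list(rep(0.002, 5))), 0.004)
  expect_equal(aggregate_pvalues(as.list(rep(1, 5))), 1)
  expect_equal(aggregate_pvalues(list(0, 0, 0, 0, 0.05)), 0.02)
  expect_error(aggregate_pvalues(list(0.1, 0.2)), "5 datasets")
  # elementwise on matrices and monotone in each input
  m <- lapply(1:5, function(i) matrix(i / 100, 2, 2))
  expect_equal(aggregate_pvalues(m), matrix(0.06, 2, 2))
  base <- aggregate_pvalues(list(0.1, 0.1, 0.1, 0.1, 0.1))
  up <- aggregate_pvalues(list(0.1, 0.1, 0.1, 0.1, 0.2))
  expect_gt(up, base)
})

test_that("sub-sampling at full size reproduces the original curve", {
  pops <- tiny_pops(seed = 40, composition = c(stable_linear = 5, untuned = 3))
  cfg <- quick_config()
  n_units <- dim(pops[[1]]$X)[2]
  sm <- subsample_match(pops[[1]], n_units, n_draws = 2, config = cfg,
                        lambda = 10, seed = 41)
  orig <- decode_timecourse(pops[[1]], cfg, lambda = 10, seed = 41)
  expect_equal(sm$mean_accuracy, unname(orig$diagonal), tolerance = 1e-12)
  expect_equal(sm$per_draw[1, ], sm$per_draw[2, ], tolerance = 1e-12)
  expect_error(subsample_match(pops[[1]], n_units + 1), "exceeds")
})
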