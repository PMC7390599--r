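# Per-unit encoding statistics: ANOVA sweep, run-length rule, encoding
# strength, stability measure, d-prime, split-half and region comparisons.

test_that("the ANOVA sweep reproduces anova(lm()) F-test p-values", {
  g <- gaussian_tensor(n_per_cond = 6, n_units = 3, n_bins = 4,
                       effect = function(v, ty, u, b)
                         0.4 * v * (u == 1) + 0.8 * (ty == 2) * (u == 2),
                       seed = 42)
  res <- fit_bin_anova(g$X, g$labels)
  for (u in 1:3) for (b in c(1, 4)) {
    fit <- stats::lm(g$X[, u, b] ~ factor(g$labels$value) * factor(g$labels$type))
    a <- stats::anova(fit)
    expect_equal(res$value[u, b], a$`Pr(>F)`[1], tolerance = 1e-12)
    expect_equal(res$type[u, b], a$`Pr(>F)`[2], tolerance = 1e-12)
    expect_equal(res$interaction[u, b], a$`Pr(>F)`[3], tolerance = 1e-12)
  }
  # linear-value model
  resl <- fit_bin_anova(g$X, g$labels, value_as = "linear")
  fitl <- stats::lm(g$X[, 1, 1] ~ g$labels$value * factor(g$labels$type))
  al <- stats::anova(fitl)
  expect_equal(resl$value[1, 1], al$`Pr(>F)`[1], tolerance = 1e-12)
  # zero-variance bin -> p = 1, flagged
  g$X[, 2, 2] <- 3
  res0 <- fit_bin_anova(g$X, g$labels)
  expect_equal(res0$value[2, 2], 1)
  expect_true(res0$flagged[2, 2])
})

test_that("per-bin false positives for untuned activity occur at alpha", {
  g <- gaussian_tensor(n_per_cond = 8, n_units = 50, n_bins = 40, seed = 7)
  res <- fit_bin_anova(g$X, g$labels)
  n_cells <- length(res$value)
  se <- sqrt(0.01 * 0.99 / n_cells) # binomial SE under the null
  expect_lt(abs(mean(res$value < 0.01) - 0.01), 3 * se)
  # shuffled labels have the same calibration (exchangeability)
  set.seed(1)
  lab2 <- g$labels[sample(nrow(g$labels)), ]
  res2 <- fit_bin_anova(g$X, lab2)
  expect_lt(abs(mean(res2$value < 0.01) - 0.01), 3 * se)
})

test_that("run-length rule marks only runs of at least k bins", {
  p7 <- c(rep(0.5, 3), rep(0.005, 7), rep(0.5, 2))
  r7 <- significance_runs(p7, alpha = 0.01, k = 7)
  expect_equal(which(r7$mask), 4:10)
  expect_equal(r7$latency, 4) # index scale when times are absent

  p6 <- c(rep(0.5, 3), rep(0.005, 6), rep(0.5, 3))
  expect_false(any(significance_runs(p6, k = 7)$mask))

  # [6-run, gap, 8-run]: only the 8-run qualifies; latency at its first bin
  p <- c(rep(0.005, 6), 0.5, rep(0.005, 8), 0.5)
  r <- significance_runs(p, alpha = 0.01, k = 7,
                         times = seq(0, by = 0.025, length.out = length(p)))
  expect_equal(which(r$mask), 8:15)
  expect_equal(r$latency, 7 * 0.025)
  expect_equal(r$peak_bin, 8) # minimal p among significant bins (first)
})

test_that("encoding strength is the mean negative log10 p", {
  expect_equal(as.numeric(encoding_strength(rep(0.01, 12))), 2)
  expect_equal(as.numeric(encoding_strength(rep(1e-3, 5))), 3)
  expect_equal(as.numeric(encoding_strength(c(1e-2, 1e-4))), 3)
  z <- encoding_strength(c(0.01, 0))
  expect_true(attr(z, "clamped"))
  # invariant to bin order
  set.seed(2)
  p <- runif(40)
  expect_equal(as.numeric(encoding_strength(p)),
               as.numeric(encoding_strength(rev(p))))
})

test_that("stability measure saturates, cancels and pools as defined", {
  expect_equal(pooled_sd(4, 16), sqrt(10))
  Tn <- 20
  # constant +5 Hz separation, unit pooled SD -> tanh(50) ~ 1 -> S ~ 1
  xbar <- rbind(rep(10, Tn), rep(5, Tn), rep(0, Tn), rep(-5, Tn))
  svar <- matrix(1, 4, Tn)
  expect_equal(as.numeric(stability_measure(xbar, svar)), 1, tolerance = 1e-6)
  # antisymmetric reversal cancels the time sum
  half <- c(rep(5, Tn / 2), rep(-5, Tn / 2))
  xbar2 <- rbind(half, -half, 3 * half, -3 * half)
  expect_lt(as.numeric(stability_measure(xbar2, svar)), 1e-10)
  # S is sensitive to bin order (a reversal is not, a sort is)
  set.seed(3)
  xbar3 <- rbind(cumsum(rnorm(Tn)), cumsum(rnorm(Tn)),
                 cumsum(rnorm(Tn)), cumsum(rnorm(Tn)))
  ord <- sample(Tn)
  s_orig <- as.numeric(stability_measure(xbar3, svar))
  s_perm <- as.numeric(stability_measure(xbar3[, ord], svar[, ord]))
  expect_equal(s_orig, s_perm) # permuting both columns jointly: sum unchanged
  xbar4 <- xbar3
  xbar4[1, ] <- xbar3[1, Tn:1] # reversing one value's time course changes S
  expect_false(isTRUE(all.equal(s_orig,
                                as.numeric(stability_measure(xbar4, svar)))))
  # zero pooled SD handling
  s0 <- stability_measure(rbind(rep(1, 2), rep(0, 2), rep(0, 2), rep(0, 2)),
                          matrix(0, 4, 2))
  expect_true(attr(s0, "flagged"))
})

test_that("planted reversing units score lower S than matched stable units", {
  task <- task_config(trials_per_condition = 12)
  specs <- c(
    lapply(1:10, function(i) unit_spec(i, "stable_linear", 6, value_gain = 2)),
    lapply(11:20, function(i) unit_spec(i, "reversing", 6, value_gain = 2,
                                        reversal_time = 1.8)))
  s <- generate_session(specs, task, seed = 21)
  prof <- encoding_profile(epoch_and_bin(s, step = 0.05))
  S_stable <- prof$stats$S[1:10]
  S_rev <- prof$stats$S[11:20]
  wt <- stats::wilcox.test(S_rev, S_stable, alternative = "less")
  expect_lt(wt$p.value, 0.01)
})

test_that("d-prime behaves as a standardised separation", {
  set.seed(4)
  value <- rep(1:4, each = 30)
  expect_equal(dprime_unit(rnorm(120)[order(runif(120))] * 0 + 1, value),
               NA_real_) # identical constant distributions -> undefined
  x <- rnorm(120)
  expect_lt(dprime_unit(x, value), 0.5) # identical distributions ~ 0
  # means 1 apart, unit SD: adjacent pairs ~ 1
  y <- rnorm(120, sd = 1) + value
  d <- dprime_unit(y, value)
  exp_d <- mean(abs(outer(1:4, 1:4, "-"))[lower.tri(matrix(0, 4, 4))])
  expect_equal(d, exp_d, tolerance = 0.2)
  # monotone in planted gain
  gains <- c(0.2, 0.6, 1.2)
  ds <- vapply(gains, function(g)
    dprime_unit(rnorm(120) + g * value, value), numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("split-half peak bins are consistent for sequential populations", {
  task <- task_config(trials_per_condition = 14)
  specs <- sample_population(c(sequential = 16), task,
                             param_ranges = list(seq_gain = c(4, 6)),
                             seed = 31)
  s <- generate_session(specs, task, seed = 32)
  rmat <- epoch_and_bin(s, step = 0.05)
  sh <- split_half_sequence_analysis(rmat, seed = 33)
  expect_gt(length(sh$units), 5)
  expect_gt(sh$R_peak, 0.7)
  expect_lt(sh$p_peak, 0.01)
  # identical halves give perfect correlation by construction
  expect_equal(suppressWarnings(stats::cor(sh$peak_train, sh$peak_train,
                                           method = "spearman")), 1)
})

test_that("coverage distribution and KS comparison behave", {
  cv <- coverage_distribution(rep(0.5, 10))
  expect_true(all(cv$fraction[cv$coverage <= 0.5] == 1))
  expect_true(all(cv$fraction[cv$coverage > 0.5] == 0))
  expect_equal(ks_durations(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))$stat, 0)
  set.seed(5)
  a <- runif(150, 0, 0.4)
  b <- runif(150, 0.2, 1)
  expect_lt(ks_durations(a, b)$p, 0.05)
})

test_that("non-linear value coders are identified and linear ones are not", {
  task <- task_config(trials_per_condition = 16)
  specs <- c(
    lapply(1:6, function(i) {
      off <- c(0, 0, 6, 0)
      unit_spec(i, "stable_nonmonotonic", 5, off)
    }),
    lapply(7:12, function(i) unit_spec(i, "stable_linear", 5, value_gain = 3)),
    lapply(13:16, function(i) unit_spec(i, "untuned", 5)))
  s <- generate_session(specs, task, seed = 41)
  prof <- encoding_profile(epoch_and_bin(s, step = 0.05))
  nl <- classify_nonlinear_value_units(prof)
  expect_true(mean(nl$flag[1:6]) >= 0.5)   # peak-at-3 units flagged
  expect_true(all(!nl$flag[7:12]))         # linear coders excluded
  expect_true(all(!nl$flag[13:16]))        # untuned excluded
})

test_that("region comparisons: chi-squared and Kruskal-Wallis", {
  # equal proportions -> chi-squared 0, p 1 (closed form)
  t_eq <- rbind(c(50, 50), c(50, 50))
  ct <- suppressWarnings(stats::chisq.test(t_eq, correct = FALSE))
  expect_equal(unname(ct$statistic), 0)
  expect_equal(ct$p.value, 1)
  # 80/100 vs 40/100: closed-form 2x2 chi-squared = 33.33
  t2 <- rbind(c(80, 20), c(40, 60))
  ct2 <- suppressWarnings(stats::chisq.test(t2, correct = FALSE))
  n <- sum(t2)
  expected <- outer(rowSums(t2), colSums(t2)) / n
  expect_equal(unname(ct2$statistic), sum((t2 - expected)^2 / expected),
               tolerance = 1e-12)
  expect_lt(ct2$p.value, 0.01)

  # full path on planted profiles
  task <- task_config(trials_per_condition = 10)
  strong <- list(value_gain = c(4, 6))
  sA <- generate_session(sample_population(
    c(stable_linear = 8, untuned = 2), task, strong, seed = 51), task,
    seed = 52)
  sB <- generate_session(sample_population(
    c(stable_linear = 2, untuned = 8), task, strong, seed = 53), task,
    seed = 54)
  pA <- encoding_profile(epoch_and_bin(sA, step = 0.05))
  pB <- encoding_profile(epoch_and_bin(sB, step = 0.05))
  rc <- region_comparisons(pA, pB)
  expect_lt(rc$overall$p, 0.05)
  # identical regions: no proportion difference; identical latency samples
  # give a zero KW statistic (NaN when every latency ties exactly)
  rcs <- region_comparisons(pA, pA)
  expect_true(is.na(rcs$latency_kw$stat) || rcs$latency_kw$stat < 1e-8)
  expect_equal(rcs$overall$chisq, 0, tolerance = 1e-12)
  kw <- stats::kruskal.test(list(c(0.1, 0.3, 0.7), c(0.1, 0.3, 0.7)))
  expect_lt(unname(kw$statistic), 1e-10)
})
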