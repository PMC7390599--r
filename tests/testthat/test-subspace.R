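# Value-subspace construction, projection geometry, leakage-free protocol.

make_onehot_pop <- function(g = 10, noise = 0.05, n_per_cond = 6, n_bins = 4,
                            seed = 1) {
  set.seed(seed)
  labels <- expand.grid(value = 1:4, type = 1:2)
  labels <- labels[rep(1:8, each = n_per_cond), ]
  rownames(labels) <- NULL
  n <- nrow(labels)
  X <- array(rnorm(n * 4 * n_bins, sd = noise), dim = c(n, 4, n_bins))
  for (i in seq_len(n)) X[i, labels$value[i], ] <- X[i, labels$value[i], ] + g
  structure(list(
    X = X, labels = labels,
    bins = data.frame(epoch = "cue", t_rel = seq_len(n_bins) / 2,
                      t_abs = seq_len(n_bins) / 2,
                      abs_start = seq_len(n_bins) / 2 - 0.05,
                      abs_end = seq_len(n_bins) / 2 + 0.05, width = 0.1),
    task = task_config(), unit_ids = paste0("u", 1:4), dataset = 1, seed = 1),
    class = "pseudopop")
}

test_that("four values give a three-dimensional subspace", {
  pop <- make_onehot_pop()
  ss <- build_value_subspace(pop)
  expect_equal(ss$ncomp, 3)
  expect_false(ss$degenerate)
  # components are orthonormal
  expect_equal(crossprod(ss$components), diag(3), tolerance = 1e-10)
  expect_equal(dim(ss$class_means), c(4L, 4L))
})

test_that("identical class means are flagged degenerate", {
  pop <- make_onehot_pop(g = 0, noise = 0) # all class means equal
  ss <- build_value_subspace(pop)
  expect_true(ss$degenerate)
  expect_lt(max(ss$sdev), 1e-10)
})

test_that("orthogonal one-hot class means project to an equilateral simplex", {
  # hand-computable case: class means = g * I4; centred PCA puts the four
  # centroids at the vertices of a regular tetrahedron in 3-D
  pop <- make_onehot_pop(g = 8, noise = 1e-4)
  ss <- build_value_subspace(pop)
  cent <- sweep(ss$class_means, 2, ss$center) %*% ss$components
  D <- as.matrix(stats::dist(cent))
  offd <- D[upper.tri(D)]
  expect_equal(max(offd) / min(offd), 1, tolerance = 1e-3)
  # hand calculation: pairwise distance of g*I4 rows is g*sqrt(2), preserved
  # by the orthonormal projection that spans the centred row space
  expect_equal(mean(offd), 8 * sqrt(2), tolerance = 1e-2)
})

test_that("projection reproduces direct multiplication", {
  pop <- make_onehot_pop()
  ss <- build_value_subspace(pop)
  proj <- project_subspace(ss, pop$X)
  expect_equal(dim(proj), c(dim(pop$X)[1], 3L, dim(pop$X)[3]))
  b <- 2
  expect_equal(proj[, , b],
               sweep(pop$X[, , b], 2, ss$center) %*% ss$components,
               tolerance = 1e-12)
})

test_that("subspace CTD decodes a planted stable code well above chance", {
  pops <- tiny_pops(seed = 61, composition = c(stable_linear = 8, untuned = 4),
                    trials_per_condition = 10, draw = 8,
                    param_ranges = list(value_gain = c(5, 7)), n_datasets = 1)
  cfg <- quick_config()
  sc <- subspace_ctd(pops[[1]], cfg, seed = 62)
  delay <- which(pops[[1]]$bins$t_abs[sc$train_bins] >= 0.6)
  expect_gt(min(sc$accuracy[delay, delay]), 0.5)
  expect_gt(mean(diag(sc$accuracy)), 0.8)
})

test_that("label-shuffled subspace decoding stays at chance", {
  accs <- vapply(1:3, function(k) {
    pops <- tiny_pops(seed = 70 + k, composition = c(stable_linear = 6),
                      n_datasets = 1,
                      param_ranges = list(value_gain = c(4, 6)))
    pop <- pops[[1]]
    set.seed(k)
    pop$labels$value <- sample(pop$labels$value)
    mean(subspace_ctd(pop, quick_config(), seed = k)$accuracy)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.25), max(3 * stats::sd(accs) / sqrt(3), 0.05))
})

test_that("fitting the subspace on test trials inflates accuracy on noise", {
  # the deliberate-leak mode exists to show why the split/swap protocol is
  # needed: on pure noise it scores above the honest protocol
  diffs <- vapply(1:3, function(k) {
    pops <- tiny_pops(seed = 80 + k, composition = c(untuned = 10),
                      trials_per_condition = 10, draw = 8, n_datasets = 1)
    cfg <- quick_config()
    honest <- subspace_ctd(pops[[1]], cfg, lambda = 1, seed = k)
    leaky <- subspace_ctd(pops[[1]], cfg, lambda = 1, seed = k,
                          leak_subspace = TRUE)
    mean(leaky$accuracy) - mean(honest$accuracy)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("stability score averages the requested window", {
  acc <- matrix(0.25, 4, 4)
  diag(acc) <- 1
  expect_equal(stability_score(acc), mean(acc))
  expect_equal(stability_score(matrix(0.25, 3, 3)), 0.25)
  # window restriction on a ctd_result
  pops <- tiny_pops(seed = 90, n_datasets = 1)
  cfg <- quick_config()
  ctd <- cross_temporal_decode(pops[[1]], cfg, lambda = 10, seed = 91)
  s_all <- stability_score(ctd)
  s_delay <- stability_score(ctd, window = c(0.6, 3))
  dl <- which(pops[[1]]$bins$t_abs[ctd$train_bins] >= 0.6 &
              pops[[1]]$bins$t_abs[ctd$train_bins] <= 3)
  expect_equal(s_delay, mean(ctd$accuracy[dl, dl]))
  expect_equal(s_all, mean(ctd$accuracy))
})
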