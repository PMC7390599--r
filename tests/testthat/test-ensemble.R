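# Greedy backward ensemble selection, contributions, overlap and enrichment.

test_that("greedy trace has n-1 removals and selected >= full score", {
  pops <- tiny_pops(seed = 101, composition = c(stable_linear = 4,
                                                sequential = 3, untuned = 3),
                    n_datasets = 1)
  cfg <- quick_config()
  tr <- greedy_backward_ensemble(pops[[1]], "stability", cfg, lambda = 10,
                                 with_subspace = TRUE, seed = 102)
  n <- dim(pops[[1]]$X)[2]
  expect_length(tr$removal_order, n - 1)
  expect_length(tr$scores, n)
  expect_gte(max(tr$scores), tr$scores[1])
  expect_setequal(c(tr$removal_order,
                    setdiff(seq_len(n), tr$removal_order)), seq_len(n))
  expect_equal(tr$scores[tr$selected_step], max(tr$scores))
  # contributions: defined for removed units except the last removal; the
  # never-removed unit is NA
  last_removed <- tr$removal_order[n - 1]
  never_removed <- setdiff(seq_len(n), tr$removal_order)
  expect_true(is.na(tr$contribution[last_removed]))
  expect_true(is.na(tr$contribution[never_removed]))
  expect_equal(sum(!is.na(tr$contribution)), n - 2)
  # deltas reproduce the trace
  first_removed <- tr$removal_order[1]
  expect_equal(tr$contribution[first_removed], tr$scores[1] - tr$scores[2])
  # determinism
  tr2 <- greedy_backward_ensemble(pops[[1]], "stability", cfg, lambda = 10,
                                  with_subspace = TRUE, seed = 102)
  expect_identical(tr$removal_order, tr2$removal_order)
})

test_that("greedy matches exhaustive subset search on 8-unit populations", {
  for (k in 1:3) {
    pops <- tiny_pops(seed = 110 + k,
                      composition = c(stable_linear = 3, sequential = 2,
                                      untuned = 3), n_datasets = 1)
    pop <- pops[[1]]
    cfg <- quick_config()
    fold <- valuedyn:::.make_folds(pop$labels, "value", 2, 111)
    win <- bins_in_window(pop$bins, c(0, 3))
    ctx <- valuedyn:::.search_context(pop, cfg, fold, 1, win, 111)
    ev <- valuedyn:::.make_stability_evaluator(ctx, lambda = 10)
    tr <- valuedyn:::.greedy_run(8, ev)
    sz <- length(tr$selected)
    subsets <- utils::combn(8, sz, simplify = FALSE)
    best <- max(vapply(subsets, ev$eval_set, numeric(1)))
    greedy_score <- max(tr$scores)
    expect_gte(greedy_score, best * 0.95) # within 5% of the exhaustive optimum
  }
})

test_that("contribution transform follows the signed square root", {
  expect_equal(contribution_transform(-0.04), -0.2)
  expect_equal(contribution_transform(0.09), 0.3)
  expect_equal(contribution_transform(0), 0)
  # rank-preserving: Spearman correlations are unchanged
  set.seed(6)
  x <- rnorm(50); yv <- rnorm(50)
  r1 <- stats::cor(x, yv, method = "spearman")
  r2 <- stats::cor(contribution_transform(x), yv, method = "spearman")
  expect_equal(r1, r2)
})

test_that("accuracy_contribution computes leave-one-out deltas", {
  weights <- c(0.05, -0.02, 0.01)
  score_fn <- function(units) sum(weights[units])
  res <- accuracy_contribution(score_fn, 1:3, 2)
  expect_equal(res$delta, -0.02)
  expect_equal(res$ac, -sqrt(0.02))
  expect_error(accuracy_contribution(score_fn, 1:2, 3), "not in ensemble")
})

test_that("overlap test: identical ensembles significant, random ones not", {
  ids <- lapply(1:6, function(i) sort(sample.int(60, 25)))
  res_same <- ensemble_overlap_test(ids, ids, n_units = 60)
  expect_true(all(res_same$significant))
  set.seed(7)
  a <- lapply(1:20, function(i) sample.int(200, 60))
  b <- lapply(1:20, function(i) sample.int(200, 60))
  res_rand <- ensemble_overlap_test(a, b, n_units = 200)
  expect_lte(sum(res_rand$significant), 1)
  # degenerate margins skipped
  res_deg <- ensemble_overlap_test(list(1:10), list(1:10), n_units = 10)
  expect_true(res_deg$skipped)
})

test_that("hypergeometric enrichment detects planted pools", {
  res <- ensemble_enrichment(selected = 1:20, pool = 1:25, n_units = 100)
  expect_equal(res$overlap, 20)
  expect_lt(res$p, 1e-10)
  expect_equal(res$expected, 5)
  res0 <- ensemble_enrichment(selected = 26:45, pool = 1:25, n_units = 100)
  expect_gt(res0$p, 0.99)
  # agrees with stats::phyper direct call
  expect_equal(res$p, stats::phyper(19, 25, 75, 20, lower.tail = FALSE))
})

test_that("stable search keeps planted stable units over sequential ones", {
  pops <- tiny_pops(seed = 120,
                    composition = c(stable_linear = 6, sequential = 5,
                                    untuned = 5),
                    trials_per_condition = 12, draw = 10,
                    param_ranges = list(value_gain = c(4, 6)), n_datasets = 1)
  cfg <- quick_config()
  cp <- combined_stable_pipeline(pops[[1]], cfg, seed = 121)
  sel <- cp$ensembles[[1]]
  enr <- ensemble_enrichment(sel, 1:6, 16)
  expect_gt(enr$overlap / min(length(sel), 6), 0.5)
  expect_gt(mean(cp$result$accuracy), 0.3)
})

test_that("dynamic pipeline selects a temporally local ensemble", {
  pops <- tiny_pops(seed = 130,
                    composition = c(sequential = 10, untuned = 6),
                    trials_per_condition = 12, draw = 10,
                    param_ranges = list(seq_gain = c(8, 12),
                                        bump_sd = c(0.1, 0.15)), n_datasets = 1)
  cfg <- quick_config()
  dp <- dynamic_ensemble_pipeline(pops[[1]], cfg, seed = 131)
  expect_gt(length(dp$ensembles[[1]]), 0)
  expect_gt(diag_offdiag_gap(dp$result), 0)
})
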