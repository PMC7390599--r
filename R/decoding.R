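# Population decoding: cross-temporal decoding with a one-versus-one ridge
# classifier, nested cross-validation for the penalty, permutation
# significance and p-value aggregation across pseudo-population datasets.

#' Decoder configuration
#'
#' @param lambda_grid Ridge penalty candidates; default every power of ten from
#'   1e-2 to 1e5 in 0.5 log10 steps (15 candidates).
#' @param n_outer_folds Outer cross-validation folds (default 5).
#' @param n_inner_folds Inner folds for penalty tuning (default 4).
#' @param n_perm Label permutations for significance (default 1000).
#' @param alpha Significance threshold on aggregated p-values (default 0.01).
#' @param target Variable to decode: `"value"` or `"type"`.
#' @param window Analysis window `c(lo, hi)` in s relative to cue onset; NULL
#'   means cue onset to reward.
#' @return An object of class `decoder_config`.
#' @export
decoder_config <- function(lambda_grid = 10^seq(-2, 5, by = 0.5),
                           n_outer_folds = 5, n_inner_folds = 4,
                           n_perm = 1000, alpha = 0.01,
                           target = c("value", "type"), window = NULL) {
  target <- match.arg(target)
  if (length(lambda_grid) == 0 || is.unsorted(lambda_grid))
    stop("lambda_grid must be nonempty and sorted", call. = FALSE)
  structure(list(lambda_grid = lambda_grid,
                 n_outer_folds = as.integer(n_outer_folds),
                 n_inner_folds = as.integer(n_inner_folds),
                 n_perm = as.integer(n_perm), alpha = alpha,
                 target = target, window = window),
            class = "decoder_config")
}

.config_window <- function(config, task) {
  if (!is.null(config$window)) config$window else c(task$cue_on, task$reward)
}

# Stratified fold assignment: within each (value, type) condition trials are
# shuffled and folds dealt cyclically. Errors if any fold misses a target class.
.make_folds <- function(labels, target, k, seed) {
  rng <- .local_seed(.sub_seed(seed, 1717))
  on.exit(rng())
  strata <- interaction(labels$value, labels$type, drop = TRUE)
  fold <- integer(nrow(labels))
  for (ix in split(seq_len(nrow(labels)), strata)) {
    ix <- sample(ix)
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  y <- labels[[target]]
  for (f in seq_len(k))
    if (length(unique(y[fold != f])) < length(unique(y)) ||
        !all(unique(y) %in% y[fold == f]))
      stop("stratification error: fold ", f, " misses a class", call. = FALSE)
  fold
}

# Per-(unit, bin) training z-scoring statistics.
.zstats <- function(X, train_idx, bins_idx) {
  nu <- dim(X)[2]
  mu <- matrix(0, nu, length(bins_idx))
  sd_ <- matrix(1, nu, length(bins_idx))
  for (j in seq_along(bins_idx)) {
    M <- X[train_idx, , bins_idx[j], drop = FALSE][, , 1]
    if (is.null(dim(M))) M <- matrix(M, ncol = nu)
    mu[, j] <- colMeans(M)
    s <- apply(M, 2, stats::sd)
    s[s == 0 | is.na(s)] <- 1
    sd_[, j] <- s
  }
  list(mu = mu, sd = sd_)
}

# Scaled feature matrix at one bin.
.zbin <- function(X, idx, bin, zs, j) {
  M <- X[idx, , bin, drop = FALSE][, , 1]
  if (is.null(dim(M))) M <- matrix(M, ncol = dim(X)[2])
  sweep(sweep(M, 2, zs$mu[, j]), 2, zs$sd[, j], "/")
}

# Flattened scaled test features over several bins; rows grouped by bin
# (trial index varies fastest).
.zflat <- function(X, idx, bins, zs, jmap) {
  do.call(rbind, lapply(seq_along(bins), function(j)
    .zbin(X, idx, bins[j], zs, jmap[j])))
}

#' Tune the ridge penalty by nested cross-validation
#'
#' Selects the single penalty maximising mean same-bin decoding accuracy over
#' the analysis window, by `n_inner_folds`-fold cross-validation inside the
#' supplied training trials (by default the training set of the first outer
#' fold, so outer test trials never inform the choice). Grid ties go to the
#' smallest penalty.
#'
#' @param pop A `pseudopop`.
#' @param config A [decoder_config()].
#' @param seed Seed (must match the decoding call to share folds).
#' @param train_idx Optional explicit training-trial indices.
#' @return The selected penalty (scalar), with attribute `accuracy` (per-grid
#'   mean accuracy).
#' @export
tune_lambda <- function(pop, config = decoder_config(), seed = 1L,
                        train_idx = NULL) {
  stopifnot(inherits(pop, "pseudopop"))
  y_all <- pop$labels[[config$target]]
  if (is.null(train_idx)) {
    fold <- .make_folds(pop$labels, config$target, config$n_outer_folds, seed)
    train_idx <- which(fold != 1L)
  }
  win_bins <- bins_in_window(pop$bins, .config_window(config, pop$task))
  lab_tr <- pop$labels[train_idx, , drop = FALSE]
  inner <- .make_folds(lab_tr, config$target, config$n_inner_folds,
                       .sub_seed(seed, 23))
  L <- length(config$lambda_grid)
  correct <- numeric(L)
  total <- 0
  classes <- sort(unique(y_all))
  pairs <- .ovo_pairs(y_all)
  for (f in seq_len(config$n_inner_folds)) {
    tr <- train_idx[inner != f]
    te <- train_idx[inner == f]
    zs <- .zstats(pop$X, tr, win_bins)
    ytr <- y_all[tr]; yte <- y_all[te]
    for (j in seq_along(win_bins)) {
      Ztr <- .zbin(pop$X, tr, win_bins[j], zs, j)
      Zte <- .zbin(pop$X, te, win_bins[j], zs, j)
      margins <- array(0, dim = c(length(te), ncol(pairs), L))
      for (pr in seq_len(ncol(pairs))) {
        v <- pairs[1, pr]; w <- pairs[2, pr]
        rows <- ytr %in% c(v, w)
        path <- .ridge_path(Ztr[rows, , drop = FALSE],
                            ifelse(ytr[rows] == v, 1, -1),
                            config$lambda_grid)
        margins[, pr, ] <- Zte %*% path$W +
          matrix(path$b0, length(te), L, byrow = TRUE)
      }
      for (l in seq_len(L)) {
        pred <- .ovo_predict(margins[, , l, drop = FALSE][, , 1, drop = TRUE],
                             pairs, classes)
        correct[l] <- correct[l] + sum(pred == yte)
      }
      total <- total + length(te)
    }
  }
  acc <- correct / total
  best <- which(acc == max(acc))[1] # tie -> smallest lambda (grid is sorted)
  structure(config$lambda_grid[best], accuracy = acc)
}

#' Cross-temporal decoding
#'
#' Trains the one-versus-one ridge classifier at every training bin and tests
#' it at every testing bin on out-of-sample trials (stratified
#' `n_outer_folds`-fold cross-validation). The diagonal (train bin = test bin)
#' is the standard decoding time course.
#'
#' @param pop A `pseudopop`.
#' @param config A [decoder_config()].
#' @param lambda Ridge penalty; NULL tunes it with [tune_lambda()].
#' @param seed Seed controlling fold assignment (and tuning).
#' @param train_bins,test_bins Bin indices (default: all bins in the window).
#' @param diag_only If TRUE, evaluate only train bin = test bin (standard
#'   decoding; requires identical train and test bins).
#' @return An object of class `ctd_result`: `accuracy` (train x test matrix),
#'   `diagonal`, `train_bins`, `test_bins`, `bins`, `lambda`, `fold`, `target`.
#' @export
cross_temporal_decode <- function(pop, config = decoder_config(),
                                  lambda = NULL, seed = 1L,
                                  train_bins = NULL, test_bins = NULL,
                                  diag_only = FALSE) {
  stopifnot(inherits(pop, "pseudopop"))
  win <- bins_in_window(pop$bins, .config_window(config, pop$task))
  if (is.null(train_bins)) train_bins <- win
  if (is.null(test_bins)) test_bins <- if (diag_only) train_bins else win
  if (diag_only && !identical(train_bins, test_bins))
    stop("diag_only requires identical train and test bins", call. = FALSE)
  y <- pop$labels[[config$target]]
  classes <- sort(unique(y))
  pairs <- .ovo_pairs(y)
  fold <- .make_folds(pop$labels, config$target, config$n_outer_folds, seed)
  if (is.null(lambda))
    lambda <- as.numeric(tune_lambda(pop, config, seed,
                                     train_idx = which(fold != 1L)))

  all_bins <- sort(unique(c(train_bins, test_bins)))
  jmap_tr <- match(train_bins, all_bins)
  jmap_te <- match(test_bins, all_bins)
  B1 <- length(train_bins); B2 <- length(test_bins)
  acc_num <- matrix(0, B1, B2)
  n_total <- 0
  for (f in seq_len(config$n_outer_folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    zs <- .zstats(pop$X, tr, all_bins)
    ytr <- y[tr]; yte <- y[te]
    nte <- length(te)
    Zte_flat <- if (diag_only) NULL else .zflat(pop$X, te, test_bins, zs, jmap_te)
    for (i1 in seq_len(B1)) {
      Ztr <- .zbin(pop$X, tr, train_bins[i1], zs, jmap_tr[i1])
      W <- matrix(0, ncol(Ztr), ncol(pairs))
      b0 <- numeric(ncol(pairs))
      for (pr in seq_len(ncol(pairs))) {
        v <- pairs[1, pr]; w <- pairs[2, pr]
        rows <- ytr %in% c(v, w)
        fit <- .ridge_coef(Ztr[rows, , drop = FALSE],
                           ifelse(ytr[rows] == v, 1, -1), lambda)
        W[, pr] <- fit$w; b0[pr] <- fit$b0
      }
      if (diag_only) {
        Zte <- .zbin(pop$X, te, train_bins[i1], zs, jmap_tr[i1])
        margins <- Zte %*% W + matrix(b0, nte, ncol(pairs), byrow = TRUE)
        pred <- .ovo_predict(margins, pairs, classes)
        acc_num[i1, i1] <- acc_num[i1, i1] + sum(pred == yte)
      } else {
        margins <- Zte_flat %*% W +
          matrix(b0, nrow(Zte_flat), ncol(pairs), byrow = TRUE)
        pred <- .ovo_predict(margins, pairs, classes)
        correct <- matrix(pred == rep(yte, B2), nte, B2)
        acc_num[i1, ] <- acc_num[i1, ] + colSums(correct)
      }
    }
    n_total <- n_total + nte
  }
  accuracy <- acc_num / n_total
  diag_idx <- match(train_bins, test_bins)
  diagonal <- ifelse(is.na(diag_idx), NA_real_,
                     accuracy[cbind(seq_len(B1), diag_idx)])
  structure(list(accuracy = accuracy, diagonal = diagonal,
                 train_bins = train_bins, test_bins = test_bins,
                 bins = pop$bins, lambda = lambda, fold = fold,
                 target = config$target, seed = seed, n_trials = n_total),
            class = "ctd_result")
}

#' Standard (same-bin) decoding time course
#'
#' Convenience wrapper: [cross_temporal_decode()] with `diag_only = TRUE`.
#' Under the same seed and penalty its accuracies equal the diagonal of the
#' full cross-temporal matrix exactly (identical folds and fits).
#'
#' @inheritParams cross_temporal_decode
#' @return A `ctd_result` whose `diagonal` is the decoding time course.
#' @export
decode_timecourse <- function(pop, config = decoder_config(), lambda = NULL,
                              seed = 1L, train_bins = NULL) {
  cross_temporal_decode(pop, config, lambda, seed, train_bins,
                        test_bins = train_bins, diag_only = TRUE)
}

#' @export
print.ctd_result <- function(x, ...) {
  cat(sprintf("Cross-temporal decoding of %s: %d x %d bins, lambda %.3g\n",
              x$target, length(x$train_bins), length(x$test_bins), x$lambda))
  cat(sprintf("  diagonal accuracy: mean %.3f, max %.3f\n",
              mean(x$diagonal, na.rm = TRUE), max(x$diagonal, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.ctd_result <- function(x, main = NULL, ...) {
  t1 <- x$bins$t_abs[x$train_bins]
  t2 <- x$bins$t_abs[x$test_bins]
  graphics::image(t2, t1, t(x$accuracy), xlab = "testing time (s)",
                  ylab = "training time (s)",
                  main = main %||% sprintf("CTD of %s", x$target),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permutation test of decoding accuracy
#'
#' Shuffles the target labels `n_perm` times and recomputes the full
#' cross-validated cross-temporal accuracy for each shuffle (same folds, same
#' penalty, same z-scoring protocol). The per-pair p-value is the fraction of
#' permutations with accuracy strictly higher than observed; an observed
#' accuracy above every permutation is reported as 0 (i.e. < 1/n_perm) and
#' flagged.
#'
#' Internally the permuted refits use the dual (kernel) form of ridge
#' regression with precomputed Gram matrices, which is algebraically identical
#' to the primal fit.
#'
#' @inheritParams cross_temporal_decode
#' @param n_perm Number of permutations (default from `config`).
#' @param observed Optional precomputed `ctd_result` from
#'   [cross_temporal_decode()] with the same arguments.
#' @return List: `observed` (`ctd_result`), `p` (train x test matrix),
#'   `zero_flag` (logical matrix, p = 0 cells), `n_perm`.
#' @export
permutation_test <- function(pop, config = decoder_config(), lambda = NULL,
                             seed = 1L, n_perm = config$n_perm,
                             train_bins = NULL, test_bins = NULL,
                             observed = NULL) {
  stopifnot(inherits(pop, "pseudopop"))
  win <- bins_in_window(pop$bins, .config_window(config, pop$task))
  if (is.null(train_bins)) train_bins <- win
  if (is.null(test_bins)) test_bins <- win
  if (is.null(observed))
    observed <- cross_temporal_decode(pop, config, lambda, seed,
                                      train_bins, test_bins)
  lambda <- observed$lambda
  fold <- observed$fold
  y <- pop$labels[[config$target]]
  classes <- sort(unique(y))
  pairs <- .ovo_pairs(y)
  B1 <- length(train_bins); B2 <- length(test_bins)
  n <- length(y)

  rng <- .local_seed(.sub_seed(seed, 4242))
  on.exit(rng())
  perms <- replicate(n_perm, sample(y))

  all_bins <- sort(unique(c(train_bins, test_bins)))
  jmap_tr <- match(train_bins, all_bins)
  jmap_te <- match(test_bins, all_bins)
  perm_num <- array(0, dim = c(B1, B2, n_perm))
  n_total <- 0
  for (f in seq_len(config$n_outer_folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    zs <- .zstats(pop$X, tr, all_bins)
    nte <- length(te)
    Zte_flat <- .zflat(pop$X, te, test_bins, zs, jmap_te)
    Ks <- vector("list", B1); Ktes <- vector("list", B1)
    for (i1 in seq_len(B1)) {
      Ztr <- .zbin(pop$X, tr, train_bins[i1], zs, jmap_tr[i1])
      Ks[[i1]] <- tcrossprod(Ztr)              # n_tr x n_tr
      Ktes[[i1]] <- tcrossprod(Zte_flat, Ztr)  # (nte*B2) x n_tr
    }
    nb_rows <- nte * B2
    for (pm in seq_len(n_perm)) {
      yp <- perms[, pm]
      yptr <- yp[tr]
      margins_all <- matrix(0, B1 * nb_rows, ncol(pairs))
      pair_rows <- lapply(seq_len(ncol(pairs)), function(pr)
        which(yptr %in% pairs[, pr]))
      pair_y <- lapply(seq_len(ncol(pairs)), function(pr)
        ifelse(yptr[pair_rows[[pr]]] == pairs[1, pr], 1, -1))
      for (i1 in seq_len(B1)) {
        rows_out <- (i1 - 1L) * nb_rows + seq_len(nb_rows)
        for (pr in seq_len(ncol(pairs)))
          margins_all[rows_out, pr] <- .dual_ridge_margins(
            Ks[[i1]], Ktes[[i1]], pair_rows[[pr]], pair_y[[pr]], lambda)
      }
      pred <- .ovo_predict(margins_all, pairs, classes)
      correct <- pred == rep_len(rep(yp[te], B2), length(pred))
      perm_num[, , pm] <- perm_num[, , pm] +
        t(matrix(colSums(matrix(correct, nte, B2 * B1)), B2, B1))
    }
    n_total <- n_total + nte
  }
  perm_acc <- perm_num / n_total
  obs <- observed$accuracy
  p <- matrix(NA_real_, B1, B2)
  for (i1 in seq_len(B1))
    for (i2 in seq_len(B2))
      p[i1, i2] <- sum(perm_acc[i1, i2, ] > obs[i1, i2]) / n_perm
  list(observed = observed, p = p, zero_flag = p == 0, n_perm = n_perm)
}

# Dual-form ridge prediction margins with unpenalised intercept.
# K: full training Gram, Kte: test-x-train kernel, rows: training subset,
# yy: +/-1 targets on the subset. Centring is folded into the coefficient
# vector so prediction is a single product against the full kernel.
.dual_ridge_margins <- function(K, Kte, rows, yy, lambda) {
  Ks <- K[rows, rows, drop = FALSE]
  m <- length(rows)
  rm_ <- rowMeans(Ks)
  mm <- mean(rm_)
  # double-centred Gram: K_ij - rowmean_i - rowmean_j + grand mean
  Kc <- Ks - rm_ - rep(rm_, each = m) + mm
  diag(Kc) <- diag(Kc) + lambda
  R <- chol(Kc)
  alpha <- backsolve(R, backsolve(R, yy - mean(yy), transpose = TRUE))
  s_alpha <- sum(alpha)
  v <- numeric(ncol(Kte))
  v[rows] <- alpha - s_alpha / m
  drop(Kte %*% v) + (mm * s_alpha - sum(rm_ * alpha) + mean(yy))
}

#' Aggregate permutation p-values across datasets
#'
#' `p_agg = min(1, 2 * mean(p))` over the five pseudo-population datasets (an
#' aggregation valid for dependent p-values). Vectorised: inputs may be
#' matrices (aggregated elementwise).
#'
#' @param p_list List of 5 p-value scalars or matrices.
#' @return Aggregated p (same shape as the inputs).
#' @export
#' @examples
#' aggregate_pvalues(as.list(rep(0.002, 5))) # 0.004
aggregate_pvalues <- function(p_list) {
  if (length(p_list) != 5L)
    stop("expected p-values from exactly 5 datasets", call. = FALSE)
  m <- Reduce(`+`, p_list) / length(p_list)
  pmin(2 * m, 1)
}

#' Decode several pseudo-population datasets and aggregate
#'
#' Runs [cross_temporal_decode()] (and optionally [permutation_test()]) on each
#' dataset; reports the mean accuracy over datasets and, when permutations are
#' run on 5 datasets, the aggregated p-value per time-bin pair.
#'
#' @param pops List of `pseudopop` datasets.
#' @param config A [decoder_config()].
#' @param lambda Penalty; NULL tunes per dataset.
#' @param n_perm Permutations per dataset (0 = no significance).
#' @param seed Base seed; dataset d uses a derived sub-seed.
#' @param train_bins,test_bins Bin indices (default: window).
#' @return List of class `ctd_agg`: `accuracy` (mean over datasets), `p_agg`
#'   (or NULL), `per_dataset` (list of `ctd_result`), `p_per_dataset`,
#'   `train_bins`, `test_bins`, `bins`, `alpha`.
#' @export
ctd_datasets <- function(pops, config = decoder_config(), lambda = NULL,
                         n_perm = 0, seed = 1L,
                         train_bins = NULL, test_bins = NULL) {
  res <- vector("list", length(pops))
  pvals <- vector("list", length(pops))
  for (d in seq_along(pops)) {
    sd_ <- .sub_seed(seed, 100 + d)
    if (n_perm > 0) {
      pt <- permutation_test(pops[[d]], config, lambda, sd_, n_perm,
                             train_bins, test_bins)
      res[[d]] <- pt$observed
      pvals[[d]] <- pt$p
    } else {
      res[[d]] <- cross_temporal_decode(pops[[d]], config, lambda, sd_,
                                        train_bins, test_bins)
    }
  }
  acc <- Reduce(`+`, lapply(res, `[[`, "accuracy")) / length(res)
  p_agg <- if (n_perm > 0 && length(pops) == 5L) aggregate_pvalues(pvals)
           else NULL
  structure(list(accuracy = acc, p_agg = p_agg, per_dataset = res,
                 p_per_dataset = if (n_perm > 0) pvals else NULL,
                 train_bins = res[[1]]$train_bins,
                 test_bins = res[[1]]$test_bins,
                 bins = pops[[1]]$bins, alpha = config$alpha),
            class = "ctd_agg")
}

#' @export
print.ctd_agg <- function(x, ...) {
  cat(sprintf("CTD over %d datasets: mean diagonal accuracy %.3f\n",
              length(x$per_dataset),
              mean(diag(x$accuracy)[!is.na(diag(x$accuracy))])))
  if (!is.null(x$p_agg))
    cat(sprintf("  significant pairs (p_agg <= %.3g): %.1f%%\n", x$alpha,
                100 * mean(x$p_agg <= x$alpha)))
  invisible(x)
}

#' Size-matched sub-sampling of a population
#'
#' Randomly sub-samples `target_size` units `n_draws` times and averages the
#' standard (diagonal) decoding accuracy over draws, for fair comparison of
#' populations of unequal unit counts.
#'
#' @param pop A `pseudopop`.
#' @param target_size Units per draw (must not exceed the population size).
#' @param n_draws Number of draws (default 200).
#' @param config,lambda,seed As in [cross_temporal_decode()].
#' @return List: `mean_accuracy` (per window bin), `per_draw` (draws x bins),
#'   `train_bins`.
#' @export
subsample_match <- function(pop, target_size, n_draws = 200,
                            config = decoder_config(), lambda = NULL,
                            seed = 1L) {
  n_units <- dim(pop$X)[2]
  if (target_size > n_units)
    stop("target_size exceeds the population size", call. = FALSE)
  rng <- .local_seed(.sub_seed(seed, 31))
  draws <- replicate(n_draws, sample.int(n_units, target_size),
                     simplify = FALSE)
  rng()
  # one shared fold assignment across draws: subsets are compared under
  # identical cross-validation, and a full-size draw reproduces the original
  acc <- t(vapply(seq_len(n_draws), function(i) {
    sub <- subset_pop(pop, units = draws[[i]])
    r <- decode_timecourse(sub, config, lambda, seed = seed)
    r$diagonal
  }, numeric(length(bins_in_window(pop$bins,
                                   .config_window(config, pop$task))))))
  list(mean_accuracy = colMeans(acc), per_draw = acc,
       train_bins = bins_in_window(pop$bins, .config_window(config, pop$task)))
}
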