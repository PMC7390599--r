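# Value-subspace extraction: PCA of time- and trial-averaged per-class
# population activity, projection, and cross-temporal decoding inside the
# subspace with a nested split/swap protocol that keeps subspace-defining
# trials disjoint from decoder test trials.

# Class-mean matrix: mean over window bins, then over trials per class.
# Returns n_classes x n_units.
.class_means <- function(X, trials, y, window_bins) {
  tav <- .time_avg(X, trials, window_bins)
  # rowsum and table both order groups by sorted unique labels
  rowsum(tav, y) / as.vector(table(y))
}

# Per-trial activity averaged over a set of bins: n_trials x n_units.
.time_avg <- function(X, trials, window_bins) {
  out <- 0
  for (b in window_bins) {
    M <- X[trials, , b, drop = FALSE][, , 1]
    if (is.null(dim(M))) M <- matrix(M, ncol = dim(X)[2])
    out <- out + M
  }
  out / length(window_bins)
}

# PCA of the class-mean matrix; at most n_classes - 1 components.
.pca_class_means <- function(M, tol = 1e-10) {
  ctr <- colMeans(M)
  Mc <- sweep(M, 2, ctr)
  sv <- svd(Mc, nu = 0)
  dmax <- max(sv$d, .Machine$double.eps)
  rank <- sum(sv$d > tol * dmax)
  ncomp <- min(nrow(M) - 1L, rank)
  degenerate <- ncomp < nrow(M) - 1L
  if (ncomp == 0L) { # identical class means: keep one null direction
    V <- matrix(0, ncol(M), 1)
    V[1, 1] <- 1
    ncomp <- 1L
  } else V <- sv$v[, seq_len(ncomp), drop = FALSE]
  list(components = V, center = ctr, sdev = sv$d, ncomp = ncomp,
       degenerate = degenerate)
}

#' Build a value subspace from training trials
#'
#' Activity is averaged over time (cue onset to reward by default) and over the
#' trials sharing each value, giving a class-mean matrix with one row per value
#' and one column per unit. A PCA of this matrix yields at most
#' `n_values - 1` components (3 for four values): the directions capturing
#' value-related variance while discarding temporal dynamics. Populations whose
#' class means are rank-deficient yield fewer components and are flagged
#' degenerate.
#'
#' @param pop A `pseudopop`.
#' @param trials Trial indices used to define the subspace (training only).
#' @param window `c(lo, hi)` time window (s); NULL = cue onset to reward.
#' @param target Label used for class means (default `"value"`).
#' @return An object of class `value_subspace`: `class_means`, `components`
#'   (units x ncomp), `weights` (alias of components), `center`, `sdev`,
#'   `ncomp`, `degenerate`, `trials`.
#' @export
build_value_subspace <- function(pop, trials = seq_len(dim(pop$X)[1]),
                                 window = NULL, target = "value") {
  stopifnot(inherits(pop, "pseudopop"))
  if (is.null(window)) window <- c(pop$task$cue_on, pop$task$reward)
  wb <- bins_in_window(pop$bins, window)
  y <- pop$labels[[target]][trials]
  if (length(unique(y)) < 2)
    stop("need all classes present in the subspace trials", call. = FALSE)
  cm <- .class_means(pop$X, trials, y, wb)
  p <- .pca_class_means(cm)
  structure(list(class_means = cm, components = p$components,
                 weights = p$components, center = p$center, sdev = p$sdev,
                 ncomp = p$ncomp, degenerate = p$degenerate,
                 trials = trials, window = window, target = target),
            class = "value_subspace")
}

#' @export
print.value_subspace <- function(x, ...) {
  cat(sprintf("Value subspace: %d components over %d units%s\n", x$ncomp,
              ncol(x$class_means),
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Project population activity onto a value subspace
#'
#' @param subspace A [build_value_subspace()] object.
#' @param X Rate tensor `[trial, unit, bin]` (matching unit set).
#' @return Array `[trial, component, bin]`.
#' @export
project_subspace <- function(subspace, X) {
  stopifnot(inherits(subspace, "value_subspace"))
  n_b <- dim(X)[3]
  out <- array(0, dim = c(dim(X)[1], subspace$ncomp, n_b))
  for (b in seq_len(n_b)) {
    M <- X[, , b, drop = FALSE][, , 1]
    if (is.null(dim(M))) M <- matrix(M, ncol = dim(X)[2])
    out[, , b] <- sweep(M, 2, subspace$center) %*% subspace$components
  }
  out
}

# Flattened raw features over bins (rows grouped by bin, trial fastest).
.raw_flat <- function(X, idx, bins) {
  do.call(rbind, lapply(bins, function(b) {
    M <- X[idx, , b, drop = FALSE][, , 1]
    if (is.null(dim(M))) M <- matrix(M, ncol = dim(X)[2])
    M
  }))
}

# Stratified half split of a trial set.
.split_half_strat <- function(labels, idx, seed) {
  rng <- .local_seed(seed)
  on.exit(rng())
  strata <- interaction(labels$value[idx], labels$type[idx], drop = TRUE)
  h1 <- unlist(lapply(split(seq_along(idx), strata), function(ix) {
    ix <- sample(ix)
    ix[seq_len(floor(length(ix) / 2))]
  }), use.names = FALSE)
  list(h1 = idx[sort(h1)], h2 = idx[sort(setdiff(seq_along(idx), h1))])
}

# One swap direction of the subspace CTD protocol for one fold:
# subspace from S-half class means, decoder trained on D-half projections,
# tested on te. Returns counts of correct predictions per (train, test) bin
# and optionally the permutation counts (training labels shuffled).
.subspace_swap_eval <- function(X, y, S, D, te, window_bins, train_bins,
                                test_bins, lambda, classes, pairs,
                                perms = NULL) {
  eval_once <- function(yv) {
    cm <- .class_means(X, S, yv[S], window_bins)
    pca <- .pca_class_means(cm)
    V <- pca$components
    nD <- length(D); nte <- length(te)
    B1 <- length(train_bins); B2 <- length(test_bins)
    PD <- .raw_flat(X, D, train_bins) %*% V
    PT <- .raw_flat(X, te, test_bins) %*% V
    PD_arr <- array(PD, c(nD, B1, ncol(V)))
    PT_arr <- array(PT, c(nte, B2, ncol(V)))
    # z-scoring per (component, bin) from decoder-training trials; the PCA
    # centring constant cancels here
    mu <- apply(PD_arr, c(2, 3), mean)
    sd_ <- apply(PD_arr, c(2, 3), stats::sd)
    sd_[sd_ == 0 | is.na(sd_)] <- 1
    # test bins are standardised with the training stats of the same bin; when
    # a test bin is outside the training window, nearest training-bin stats
    jmap <- vapply(test_bins, function(b) {
      j <- match(b, train_bins)
      if (is.na(j)) which.min(abs(train_bins - b)) else j
    }, integer(1))
    for (cc in seq_len(ncol(V))) {
      PD_arr[, , cc] <- sweep(sweep(PD_arr[, , cc, drop = FALSE][, , 1], 2,
                                    mu[, cc]), 2, sd_[, cc], "/")
      PT_arr[, , cc] <- sweep(sweep(PT_arr[, , cc, drop = FALSE][, , 1], 2,
                                    mu[jmap, cc]), 2, sd_[jmap, cc], "/")
    }
    ZT_flat <- matrix(PT_arr, nte * B2, ncol(V))
    yD <- yv[D]
    if (ncol(V) == 3L) {
      fit <- .ridge_pairs_batch3(PD_arr, yD, classes, pairs, lambda)
      margins_all <- .stack_margins(ZT_flat, fit)
    } else {
      margins_all <- matrix(0, B1 * nte * B2, ncol(pairs))
      for (i1 in seq_len(B1)) {
        Ztr <- matrix(PD_arr[, i1, ], nD, ncol(V))
        fit <- .ridge_pairs(.class_stats(Ztr, yD, classes), pairs, classes,
                            lambda)
        rows <- (i1 - 1L) * nte * B2 + seq_len(nte * B2)
        margins_all[rows, ] <- ZT_flat %*% fit$W +
          matrix(fit$b0, nte * B2, ncol(pairs), byrow = TRUE)
      }
    }
    pred <- .ovo_predict(margins_all, pairs, classes)
    correct <- pred == rep_len(rep(y[te], B2), length(pred))
    # order: trial fastest, then test bin, then train bin
    t(matrix(colSums(matrix(correct, nte, B2 * B1)), B2, B1))
  }
  obs <- eval_once(y)
  perm_num <- NULL
  if (!is.null(perms)) {
    perm_num <- array(0, dim = c(nrow(obs), ncol(obs), ncol(perms)))
    tr_all <- c(S, D)
    for (pm in seq_len(ncol(perms))) {
      yp <- y
      yp[tr_all] <- perms[, pm] # shuffled training labels only
      perm_num[, , pm] <- eval_once(yp)
    }
  }
  list(num = obs, perm_num = perm_num, nte = length(te))
}

# Subspace CTD (+ optional training-label permutations) for a single fold.
.fold_subspace_ctd <- function(pop, f, fold, config, lambda, units = NULL,
                               train_bins, test_bins, n_perm = 0, seed = 1L,
                               leak_subspace = FALSE) {
  X <- pop$X
  if (!is.null(units)) X <- X[, units, , drop = FALSE]
  y <- pop$labels[[config$target]]
  classes <- sort(unique(y))
  pairs <- .ovo_pairs(y)
  wb <- bins_in_window(pop$bins, .config_window(config, pop$task))
  tr <- which(fold != f); te <- which(fold == f)
  hs <- .split_half_strat(pop$labels, tr, .sub_seed(seed, 900 + f))
  perms <- NULL
  if (n_perm > 0) {
    rng <- .local_seed(.sub_seed(seed, 5000 + f))
    perms <- replicate(n_perm, sample(y[tr]))
    rng()
  }
  S1 <- if (leak_subspace) c(tr, te) else hs$h1
  S2 <- if (leak_subspace) c(tr, te) else hs$h2
  e1 <- .subspace_swap_eval(X, y, S1, hs$h2, te, wb, train_bins, test_bins,
                            lambda, classes, pairs, perms)
  e2 <- .subspace_swap_eval(X, y, S2, hs$h1, te, wb, train_bins, test_bins,
                            lambda, classes, pairs, perms)
  num <- (e1$num + e2$num) / 2
  perm_num <- if (n_perm > 0) (e1$perm_num + e2$perm_num) / 2 else NULL
  list(num = num, perm_num = perm_num, nte = length(te))
}

#' Cross-temporal decoding in the value subspace
#'
#' For every outer fold, the training trials are split in half: one half
#' defines the value subspace (class-mean PCA), the other trains the ridge
#' decoder on the projected activity; the decoder is tested on the held-out
#' fold. The halves are then swapped and the two accuracy matrices averaged, so
#' the subspace never sees decoder-test trials. Permutations shuffle the labels
#' of the training trials only (subspace and decoder), keeping test labels
#' intact.
#'
#' @inheritParams cross_temporal_decode
#' @param units Optional unit subset (ensemble) to evaluate.
#' @param n_perm Training-label permutations (0 = no significance).
#' @param leak_subspace If TRUE (demonstration only), the subspace is fit on
#'   all trials including decoder-test trials, reproducing the optimistic bias
#'   the split/swap protocol removes.
#' @return A `ctd_result` with protocol `"subspace"` and, when `n_perm > 0`, a
#'   `p` matrix of per-pair permutation p-values.
#' @export
subspace_ctd <- function(pop, config = decoder_config(), lambda = NULL,
                         seed = 1L, units = NULL, train_bins = NULL,
                         test_bins = NULL, n_perm = 0, leak_subspace = FALSE) {
  stopifnot(inherits(pop, "pseudopop"))
  win <- bins_in_window(pop$bins, .config_window(config, pop$task))
  if (is.null(train_bins)) train_bins <- win
  if (is.null(test_bins)) test_bins <- win
  fold <- .make_folds(pop$labels, config$target, config$n_outer_folds, seed)
  if (is.null(lambda))
    lambda <- tune_lambda_subspace(pop, config, seed, units = units)
  B1 <- length(train_bins); B2 <- length(test_bins)
  num <- matrix(0, B1, B2); n_total <- 0
  perm_num <- if (n_perm > 0) array(0, dim = c(B1, B2, n_perm)) else NULL
  for (f in seq_len(config$n_outer_folds)) {
    r <- .fold_subspace_ctd(pop, f, fold, config, lambda, units,
                            train_bins, test_bins, n_perm, seed,
                            leak_subspace)
    num <- num + r$num
    if (n_perm > 0) perm_num <- perm_num + r$perm_num
    n_total <- n_total + r$nte
  }
  accuracy <- num / n_total
  p <- NULL
  if (n_perm > 0) {
    perm_acc <- perm_num / n_total
    p <- matrix(0, B1, B2)
    for (i1 in seq_len(B1)) for (i2 in seq_len(B2))
      p[i1, i2] <- sum(perm_acc[i1, i2, ] > accuracy[i1, i2]) / n_perm
  }
  diag_idx <- match(train_bins, test_bins)
  structure(list(accuracy = accuracy,
                 diagonal = ifelse(is.na(diag_idx), NA_real_,
                                   accuracy[cbind(seq_len(B1), diag_idx)]),
                 p = p, train_bins = train_bins, test_bins = test_bins,
                 bins = pop$bins, lambda = lambda, fold = fold,
                 target = config$target, seed = seed, n_trials = n_total,
                 protocol = if (leak_subspace) "subspace-leaky" else "subspace",
                 n_perm = n_perm),
            class = "ctd_result")
}

#' Tune the ridge penalty for subspace-projected features
#'
#' The subspace is built from the first outer fold's training trials and the
#' penalty tuned by inner cross-validation on the projected activity of those
#' same trials (outer test trials never used).
#'
#' @inheritParams subspace_ctd
#' @return Selected penalty (scalar).
#' @export
tune_lambda_subspace <- function(pop, config = decoder_config(), seed = 1L,
                                 units = NULL) {
  fold <- .make_folds(pop$labels, config$target, config$n_outer_folds, seed)
  tr <- which(fold != 1L)
  sub <- if (is.null(units)) pop else subset_pop(pop, units = units)
  sspace <- build_value_subspace(sub, trials = tr,
                                 window = .config_window(config, pop$task),
                                 target = config$target)
  proj <- project_subspace(sspace, sub$X)
  ppop <- sub
  ppop$X <- proj
  ppop$unit_ids <- paste0("pc", seq_len(dim(proj)[2]))
  as.numeric(tune_lambda(ppop, config, seed, train_idx = tr))
}

#' Mean cross-temporal accuracy over a time window (stability score)
#'
#' The stable-ensemble search objective: the mean of the accuracy matrix over
#' all (train, test) bin pairs whose centres both lie in the window (cue onset
#' to reward by default).
#'
#' @param x A `ctd_result` (or plain accuracy matrix, averaged as-is).
#' @param window `c(lo, hi)` in s; NULL = all supplied pairs.
#' @return Mean accuracy (scalar).
#' @export
stability_score <- function(x, window = NULL) {
  if (is.matrix(x)) {
    if (length(x) == 0) stop("empty accuracy window", call. = FALSE)
    return(mean(x))
  }
  stopifnot(inherits(x, "ctd_result") || inherits(x, "ctd_agg"))
  i1 <- seq_along(x$train_bins); i2 <- seq_along(x$test_bins)
  if (!is.null(window)) {
    i1 <- which(x$bins$t_abs[x$train_bins] >= window[1] &
                x$bins$t_abs[x$train_bins] <= window[2])
    i2 <- which(x$bins$t_abs[x$test_bins] >= window[1] &
                x$bins$t_abs[x$test_bins] <= window[2])
  }
  if (!length(i1) || !length(i2)) stop("empty accuracy window", call. = FALSE)
  mean(x$accuracy[i1, i2, drop = FALSE])
}
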