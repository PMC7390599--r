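# Greedy backward ensemble selection: iteratively remove the unit whose
# removal maximises the objective (stability score of the subspace CTD, or
# temporal-locality score of the raw CTD), keep the trace, and select the
# step with the best score. Searches run inside outer-fold training data;
# the held-out fold provides the reported accuracies.

# ---------------------------------------------------------------------------
# Search context: one outer fold's training data split into a fitting half (A)
# and a scoring half (B), with everything reusable across candidates
# precomputed once.
.search_context <- function(pop, config, fold, f, window_bins, seed) {
  tr <- which(fold != f)
  hs <- .split_half_strat(pop$labels, tr, .sub_seed(seed, 700 + f))
  A <- hs$h1; B <- hs$h2
  y <- pop$labels[[config$target]]
  X <- pop$X
  nA <- length(A); nB <- length(B); Bw <- length(window_bins)
  XA_flat <- .raw_flat(X, A, window_bins)
  XB_flat <- .raw_flat(X, B, window_bins)
  # per-(unit, bin) z-scoring statistics from the fitting half
  XA_arr <- array(XA_flat, c(nA, Bw, ncol(XA_flat)))
  mu <- apply(XA_arr, c(2, 3), mean)
  sd_ <- apply(XA_arr, c(2, 3), stats::sd)
  sd_[sd_ == 0 | is.na(sd_)] <- 1
  scale_flat <- function(Fl, n) {
    arr <- array(Fl, c(n, Bw, ncol(Fl)))
    for (u in seq_len(ncol(Fl)))
      arr[, , u] <- sweep(sweep(arr[, , u, drop = FALSE][, , 1], 2, mu[, u]),
                          2, sd_[, u], "/")
    matrix(arr, n * Bw, ncol(Fl))
  }
  list(A = A, B = B, yA = y[A], yB = y[B], nA = nA, nB = nB, Bw = Bw,
       window_bins = window_bins,
       t_centers = pop$bins$t_abs[window_bins],
       XA_flat = XA_flat, XB_flat = XB_flat,
       ZA_flat = scale_flat(XA_flat, nA), ZB_flat = scale_flat(XB_flat, nB),
       tavA = .time_avg(X, A, window_bins),
       classes = sort(unique(y)), pairs = .ovo_pairs(y))
}

# ---------------------------------------------------------------------------
# Stability objective via the value subspace: class-mean PCA on the fitting
# half, 1..3-dimensional ridge decoding, scored as mean accuracy over all
# (train, test) window-bin pairs on the scoring half.
#
# Candidate evaluations exploit two identities: column-centring of the
# class-mean matrix is per column, so dropping a unit just drops its column;
# and the PCA follows from the 4x4 Gram Mc Mc^T, so a candidate is a rank-one
# downdate plus a 4x4 eigendecomposition, and the projected activity is a
# (n x 4) x (4 x 3) product with a rank-one correction.
.make_stability_evaluator <- function(ctx, lambda, search_stride = 1L) {
  cm_full <- rowsum(ctx$tavA, ctx$yA) / as.vector(table(ctx$yA))
  nA <- ctx$nA; nB <- ctx$nB; Bw <- ctx$Bw
  tb <- seq(1L, Bw, by = search_stride) # objective sampled on this sub-grid
  ntb <- length(tb)
  pairs <- ctx$pairs; classes <- ctx$classes
  yA <- ctx$yA; yB <- ctx$yB
  n_units_all <- ncol(ctx$XA_flat)
  nclass <- nrow(cm_full)
  Mc_all <- sweep(cm_full, 2, colMeans(cm_full)) # column-centred class means
  tol <- 1e-10

  # score from projected activity PA (nA x Bw x nc) and PB (nB x Bw x nc):
  # mean accuracy over the (tb x tb) sub-grid of train/test bin pairs
  score_proj <- function(PA, PB) {
    nc <- dim(PA)[3]
    PA <- PA[, tb, , drop = FALSE]
    PB <- PB[, tb, , drop = FALSE]
    for (cc in seq_len(nc)) {
      Pc <- PA[, , cc, drop = FALSE][, , 1]
      m <- colMeans(Pc)
      s <- sqrt(pmax(colMeans(Pc * Pc) - m^2, 0) * nA / (nA - 1))
      s[s < 1e-12 | is.na(s)] <- 1
      PA[, , cc] <- sweep(sweep(Pc, 2, m), 2, s, "/")
      PB[, , cc] <- sweep(sweep(PB[, , cc, drop = FALSE][, , 1], 2, m),
                          2, s, "/")
    }
    ZB <- matrix(PB, nB * ntb, nc)
    if (nc == 3L) {
      fit <- .ridge_pairs_batch3(PA, yA, classes, pairs, lambda)
      margins_all <- .stack_margins(ZB, fit)
    } else {
      margins_all <- matrix(0, ntb * nB * ntb, ncol(pairs))
      for (i1 in seq_len(ntb)) {
        Ztr <- matrix(PA[, i1, ], nA, nc)
        fit <- .ridge_pairs(.class_stats(Ztr, yA, classes), pairs, classes,
                            lambda)
        rows <- (i1 - 1L) * nB * ntb + seq_len(nB * ntb)
        margins_all[rows, ] <- ZB %*% fit$W +
          matrix(fit$b0, nB * ntb, ncol(pairs), byrow = TRUE)
      }
    }
    pred <- .ovo_predict(margins_all, pairs, classes)
    mean(pred == rep_len(rep(yB, ntb), length(pred)))
  }

  eval_set <- function(E) {
    pca <- .pca_class_means(cm_full[, E, drop = FALSE])
    nc <- ncol(pca$components)
    V <- matrix(0, n_units_all, nc) # zero-padded loadings: no column subsets
    V[E, ] <- pca$components
    score_proj(array(ctx$XA_flat %*% V, c(nA, Bw, nc)),
               array(ctx$XB_flat %*% V, c(nB, Bw, nc)))
  }

  prepare <- function(C) {
    Mc <- Mc_all[, C, drop = FALSE]
    list(G4 = tcrossprod(Mc),            # 4 x 4 Gram of centred class means
         TA = ctx$XA_flat[, C, drop = FALSE] %*% t(Mc), # nA*Bw x 4
         TB = ctx$XB_flat[, C, drop = FALSE] %*% t(Mc),
         Mc = Mc)
  }

  eval_candidate <- function(state, C, i) {
    mc_u <- state$Mc[, i]
    G4 <- state$G4 - tcrossprod(mc_u)
    eg <- eigen(G4, symmetric = TRUE)
    keep <- which(eg$values > tol * max(eg$values, tol))
    keep <- keep[seq_len(min(length(keep), nclass - 1L))]
    if (length(keep) == 0L) keep <- 1L
    U <- eg$vectors[, keep, drop = FALSE]
    dinv <- 1 / sqrt(pmax(eg$values[keep], tol))
    # projection = (T - x_u mc_u^T) U D^{-1}
    UD <- U * rep(dinv, each = nclass)
    cu <- drop(crossprod(mc_u, UD)) # 1 x nc
    xa_u <- ctx$XA_flat[, C[i]]
    xb_u <- ctx$XB_flat[, C[i]]
    PA <- state$TA %*% UD - tcrossprod(xa_u, cu)
    PB <- state$TB %*% UD - tcrossprod(xb_u, cu)
    nc <- length(keep)
    score_proj(array(PA, c(nA, Bw, nc)), array(PB, c(nB, Bw, nc)))
  }

  list(prepare = prepare, eval_candidate = eval_candidate,
       eval_set = eval_set)
}

# ---------------------------------------------------------------------------
# Raw-feature objectives (locality, or stability without subspace). Training
# bins may be strided (the dynamic search trains on one in `stride` bins while
# testing on every window bin).
#
# Candidate evaluation runs in the dual: per (training bin, class pair) the
# centred pair-subset Gram (m x m, m = pair trials) and the test-versus-
# training kernel are maintained across greedy steps by rank-one downdates,
# and each candidate removal is a Sherman-Morrison update of the dual
# coefficients -- exact, and O(m^2 + rows x m) instead of O(k^3). The factors
# are rebuilt from scratch periodically to stop numerical drift, and a direct
# primal evaluation of arbitrary subsets is kept for step-0/final scores (and
# as the reference the dual path is tested against).
.make_raw_evaluator <- function(ctx, lambda, stride, objective_fn,
                                test_stride = 1L) {
  Bw <- ctx$Bw
  tb <- seq(1, Bw, by = stride)
  tbT <- seq(1L, Bw, by = test_stride) # scored test bins during the search
  ntT <- length(tbT)
  pairs <- ctx$pairs; classes <- ctx$classes
  yA <- ctx$yA; yB <- ctx$yB; nA <- ctx$nA; nB <- ctx$nB
  np <- ncol(pairs)
  ZB_sub <- ctx$ZB_flat[rep((tbT - 1L) * nB, each = nB) + seq_len(nB), ,
                        drop = FALSE]
  nbB <- nB * ntT
  pair_rows <- lapply(seq_len(np), function(pr) which(yA %in% pairs[, pr]))
  pair_y <- lapply(seq_len(np), function(pr)
    ifelse(yA[pair_rows[[pr]]] == pairs[1, pr], 1, -1))

  fx <- function(j, pr) (j - 1L) * np + pr
  fixed <- vector("list", length(tb) * np)
  for (j in seq_along(tb)) {
    rows_bin <- (tb[j] - 1L) * nA + seq_len(nA)
    Z1 <- ctx$ZA_flat[rows_bin, , drop = FALSE]
    for (pr in seq_len(np)) {
      S <- Z1[pair_rows[[pr]], , drop = FALSE]
      mu <- colMeans(S)
      yy <- pair_y[[pr]]
      fixed[[fx(j, pr)]] <- list(Sc = sweep(S, 2, mu), mu = mu,
                                 yc = yy - mean(yy), ybar = mean(yy))
    }
  }

  assemble_score <- function(margins_all) {
    pred <- .ovo_predict(margins_all, pairs, classes)
    correct <- pred == rep_len(rep(yB, ntT), length(pred))
    acc <- t(matrix(colSums(matrix(correct, nB, ntT * length(tb))) / nB,
                    ntT, length(tb)))
    objective_fn(acc, ctx$t_centers[tb], ctx$t_centers[tbT])
  }

  direct_score <- function(E) {
    margins_all <- matrix(0, length(tb) * nbB, np)
    ZBE <- ZB_sub[, E, drop = FALSE]
    for (j in seq_along(tb)) for (pr in seq_len(np)) {
      f <- fixed[[fx(j, pr)]]
      Zc <- f$Sc[, E, drop = FALSE]
      G <- crossprod(Zc)
      diag(G) <- diag(G) + lambda
      w <- solve(G, crossprod(Zc, f$yc))
      rows <- (j - 1L) * nbB + seq_len(nbB)
      margins_all[rows, pr] <- ZBE %*% w +
        (f$ybar - sum(f$mu[E] * w))
    }
    assemble_score(margins_all)
  }

  cache <- new.env(parent = emptyenv())
  cache$C <- NULL
  cache$age <- 0L

  rebuild <- function(C) {
    st <- vector("list", length(fixed))
    for (i in seq_along(fixed)) {
      f <- fixed[[i]]
      ScC <- f$Sc[, C, drop = FALSE]
      K <- tcrossprod(ScC)
      diag(K) <- diag(K) + lambda
      M <- chol2inv(chol(K))
      alpha <- drop(M %*% f$yc)
      XBc <- sweep(ZB_sub[, C, drop = FALSE], 2, f$mu[C])
      Ktec <- XBc %*% t(ScC)
      st[[i]] <- list(M = M, alpha = alpha, Ktec = Ktec,
                      m0 = drop(Ktec %*% alpha))
    }
    cache$st <- st
    cache$C <- C
    cache$age <- 0L
  }

  downdate <- function(u) {
    for (i in seq_along(fixed)) {
      f <- fixed[[i]]
      s <- cache$st[[i]]
      zc <- f$Sc[, u]
      Mz <- drop(s$M %*% zc)
      d <- 1 - sum(zc * Mz)
      M <- s$M + tcrossprod(Mz) / d
      alpha <- drop(M %*% f$yc)
      xc <- ZB_sub[, u] - f$mu[u]
      Ktec <- s$Ktec - tcrossprod(xc, zc)
      cache$st[[i]] <- list(M = M, alpha = alpha, Ktec = Ktec,
                            m0 = drop(Ktec %*% alpha))
    }
    cache$age <- cache$age + 1L
  }

  prepare <- function(C) {
    if (!is.null(cache$C) && cache$age < 25L &&
        length(C) == length(cache$C) - 1L && all(C %in% cache$C)) {
      downdate(setdiff(cache$C, C))
      cache$C <- C
    } else rebuild(C)
    NULL
  }

  eval_candidate <- function(state, C, i) {
    stopifnot(identical(C, cache$C))
    u <- C[i]
    margins_all <- matrix(0, length(tb) * nbB, np)
    for (ii in seq_along(fixed)) {
      f <- fixed[[ii]]
      s <- cache$st[[ii]]
      zc <- f$Sc[, u]
      Mz <- drop(s$M %*% zc)
      d <- 1 - sum(zc * Mz)
      gamma <- sum(zc * s$alpha) / d
      marg <- s$m0 + gamma * drop(s$Ktec %*% Mz) -
        gamma * (ZB_sub[, u] - f$mu[u]) + f$ybar
      j <- (ii - 1L) %/% np + 1L
      pr <- (ii - 1L) %% np + 1L
      rows <- (j - 1L) * nbB + seq_len(nbB)
      margins_all[rows, pr] <- marg
    }
    assemble_score(margins_all)
  }

  # all candidate removals of one greedy step, in chunks: per (bin, pair) the
  # Sherman-Morrison coefficients for a chunk of candidates come from two
  # small matrix products, and votes are taken for the whole chunk at once
  ntb <- length(tb)
  eval_all <- function(C, chunk = 16L) {
    prepare(C)
    k <- length(C)
    scores <- numeric(k)
    for (c0 in seq(1L, k, by = chunk)) {
      cand <- c0:min(c0 + chunk - 1L, k)
      nc <- length(cand)
      arr <- array(0, dim = c(nbB, ntb, nc, np))
      for (ii in seq_along(fixed)) {
        f <- fixed[[ii]]
        s <- cache$st[[ii]]
        Zc <- f$Sc[, C[cand], drop = FALSE]       # m x nc
        MZ <- s$M %*% Zc
        dvec <- 1 - colSums(Zc * MZ)
        gamma <- drop(crossprod(Zc, s$alpha)) / dvec
        CM <- s$Ktec %*% MZ                        # nbB x nc
        XBc <- sweep(ZB_sub[, C[cand], drop = FALSE], 2, f$mu[C[cand]])
        blk <- s$m0 + f$ybar +
          (CM - XBc) * matrix(gamma, nbB, nc, byrow = TRUE)
        j <- (ii - 1L) %/% np + 1L
        pr <- (ii - 1L) %% np + 1L
        arr[, j, , pr] <- blk
      }
      margins <- matrix(arr, nbB * ntb * nc, np)
      pred <- .ovo_predict(margins, pairs, classes)
      correct <- pred == rep_len(rep(yB, ntT), length(pred))
      cmat <- matrix(correct, nbB * ntb, nc)
      for (q in seq_len(nc)) {
        acc <- t(matrix(colSums(matrix(cmat[, q], nB, ntT * ntb)) / nB,
                        ntT, ntb))
        scores[cand[q]] <- objective_fn(acc, ctx$t_centers[tb],
                                        ctx$t_centers[tbT])
      }
    }
    scores
  }

  list(prepare = prepare, eval_candidate = eval_candidate,
       eval_all = eval_all, eval_set = direct_score)
}


.objective_stability <- function(acc, t_train, t_test) mean(acc)
.objective_locality <- function(acc, t_train, t_test)
  as.numeric(locality_score(acc, t_train, t_test))

# Training-bin stride giving roughly 250 ms spacing on the population's grid.
.auto_stride <- function(pop) {
  step <- stats::median(diff(pop$bins$t_abs[pop$bins$epoch ==
                                            pop$bins$epoch[1]]))
  max(1L, as.integer(round(0.25 / step)))
}

# ---------------------------------------------------------------------------
#' Square-root contribution transform
#'
#' `ac = sign(x) * sqrt(|x|)`: symmetric around 0 and rank-preserving; used to
#' display and correlate accuracy-contribution scores.
#'
#' @param x Raw contribution (accuracy difference).
#' @return Transformed value.
#' @export
#' @examples
#' contribution_transform(-0.04) # -0.2
contribution_transform <- function(x) sign(x) * sqrt(abs(x))

# Greedy backward elimination given an evaluator.
.greedy_run <- function(n_units, evaluator, min_size = 1L) {
  C <- seq_len(n_units)
  scores <- numeric(n_units - min_size + 1L)
  removal <- integer(0)
  scores[1] <- evaluator$eval_set(C)
  step <- 1L
  while (length(C) > min_size) {
    if (!is.null(evaluator$eval_all)) {
      cand <- evaluator$eval_all(C)
    } else {
      state <- evaluator$prepare(C)
      cand <- vapply(seq_along(C), function(i)
        evaluator$eval_candidate(state, C, i), numeric(1))
    }
    best <- which.max(cand)
    removal <- c(removal, C[best])
    step <- step + 1L
    scores[step] <- cand[best]
    C <- C[-best]
  }
  selected_step <- which.max(scores) # first max: ties keep the larger ensemble
  sel_removed <- if (selected_step > 1L) removal[seq_len(selected_step - 1L)]
                 else integer(0)
  selected <- setdiff(seq_len(n_units), sel_removed)
  contribution <- rep(NA_real_, n_units)
  if (length(removal) > 1L) {
    # step delta when the unit was removed; the final removal is discarded
    for (j in seq_len(length(removal) - 1L))
      contribution[removal[j]] <- scores[j] - scores[j + 1L]
  }
  structure(list(removal_order = removal, scores = scores,
                 selected = selected, selected_step = selected_step,
                 contribution = contribution,
                 contribution_ac = contribution_transform(contribution),
                 n_units = n_units),
            class = "ensemble_trace")
}

#' @export
print.ensemble_trace <- function(x, ...) {
  cat(sprintf("Greedy backward trace: %d units, %d removal steps\n",
              x$n_units, length(x$removal_order)))
  cat(sprintf("  score %.3f (full) -> %.3f (best, %d units at step %d)\n",
              x$scores[1], max(x$scores), length(x$selected),
              x$selected_step))
  invisible(x)
}

#' @export
plot.ensemble_trace <- function(x, ...) {
  sizes <- x$n_units - seq_along(x$scores) + 1L
  graphics::plot(sizes, x$scores, type = "l", xlab = "ensemble size",
                 ylab = "objective score", xlim = rev(range(sizes)), ...)
  graphics::abline(v = length(x$selected), lty = 2)
  invisible(x)
}

#' Greedy backward ensemble selection
#'
#' Starting from the full population, iteratively removes the unit whose
#' removal maximises the objective, recomputed on the remaining ensemble, down
#' to one unit; the selected ensemble is the trace's argmax (the full
#' population is a candidate, so the selected score is never below the full
#' score). The search runs inside one outer fold's training trials, split into
#' a fitting and a scoring half, so held-out fold trials never inform the
#' selection.
#'
#' Objectives: `"stability"` (mean cross-temporal accuracy over all window bin
#' pairs; computed in the value subspace when `with_subspace = TRUE`) and
#' `"locality"` (Gaussian temporal-locality measure of the raw cross-temporal
#' accuracy, trained on one in `stride` bins and tested on every bin).
#'
#' @param pop A `pseudopop`, typically on the coarse (200 ms non-overlapping)
#'   search grid.
#' @param objective `"stability"` or `"locality"`.
#' @param config A [decoder_config()].
#' @param lambda Ridge penalty used throughout the search (tuned on the full
#'   population when NULL).
#' @param with_subspace Evaluate candidates through the value subspace
#'   (stability objective only).
#' @param fold_id Outer fold assignment (computed from `seed` when NULL).
#' @param f Index of the outer fold whose training data hosts the search.
#' @param stride Training-bin stride for the locality objective; NULL picks
#'   the stride giving ~250 ms between training bins on the population's grid
#'   (1 on the 200 ms search grid, 5 on the 50 ms decoding grid).
#' @param search_stride Sub-sampling of the scored bin grid during the
#'   search (both axes for the stability objective, the testing axis for the
#'   locality objective); the final reported CTD always uses the full grid.
#' @param min_size Stop removing at this ensemble size (default 1).
#' @param seed Seed (fold assignment and half split).
#' @return An `ensemble_trace`: `removal_order`, `scores` (step 0 = full
#'   population), `selected`, `contribution` (step delta per unit, NA for the
#'   final removal and the never-removed unit), `contribution_ac`
#'   (square-root transformed).
#' @export
greedy_backward_ensemble <- function(pop, objective = c("stability", "locality"),
                                     config = decoder_config(), lambda = NULL,
                                     with_subspace = FALSE, fold_id = NULL,
                                     f = 1L, stride = NULL, min_size = 1L,
                                     search_stride = 1L, seed = 1L) {
  objective <- match.arg(objective)
  if (is.null(stride)) stride <- .auto_stride(pop)
  if (with_subspace && objective != "stability")
    stop("the subspace evaluator supports the stability objective",
         call. = FALSE)
  if (is.null(fold_id))
    fold_id <- .make_folds(pop$labels, config$target, config$n_outer_folds,
                           seed)
  win <- bins_in_window(pop$bins, .config_window(config, pop$task))
  if (is.null(lambda)) {
    lambda <- if (with_subspace)
      tune_lambda_subspace(pop, config, seed)
    else
      as.numeric(tune_lambda(pop, config, seed,
                             train_idx = which(fold_id != 1L)))
  }
  ctx <- .search_context(pop, config, fold_id, f, win, seed)
  ev <- if (with_subspace)
    .make_stability_evaluator(ctx, lambda, search_stride)
  else
    .make_raw_evaluator(ctx, lambda,
                        if (objective == "locality") stride else 1L,
                        if (objective == "locality") .objective_locality
                        else .objective_stability,
                        test_stride = search_stride)
  tr <- .greedy_run(dim(pop$X)[2], ev, min_size)
  tr$objective <- objective
  tr$with_subspace <- with_subspace
  tr$fold <- f
  tr$lambda <- lambda
  tr
}

#' Leave-one-out accuracy contribution of a unit
#'
#' `delta = score(ensemble) - score(ensemble without the unit)`, with the
#' square-root display transform `ac = sign(delta) * sqrt(|delta|)`.
#'
#' @param score_fn Function mapping a unit-index vector to an objective score.
#' @param ensemble Unit indices.
#' @param unit A unit in `ensemble`.
#' @return List: `delta`, `ac`.
#' @export
accuracy_contribution <- function(score_fn, ensemble, unit) {
  if (!unit %in% ensemble) stop("unit not in ensemble", call. = FALSE)
  delta <- score_fn(ensemble) - score_fn(setdiff(ensemble, unit))
  list(delta = delta, ac = contribution_transform(delta))
}

# ---------------------------------------------------------------------------
# Single-fold raw CTD with optional permutations (dual form), on a unit
# subset. shuffle = "all" permutes all labels (standard decoding null);
# "train" permutes training labels only.
.fold_raw_ctd_perm <- function(pop, f, fold, config, lambda, units = NULL,
                               train_bins, test_bins, n_perm = 0, seed = 1L,
                               shuffle = c("all", "train")) {
  shuffle <- match.arg(shuffle)
  X <- pop$X
  if (!is.null(units)) X <- X[, units, , drop = FALSE]
  y <- pop$labels[[config$target]]
  classes <- sort(unique(y)); pairs <- .ovo_pairs(y)
  tr <- which(fold != f); te <- which(fold == f)
  all_bins <- sort(unique(c(train_bins, test_bins)))
  jmap_tr <- match(train_bins, all_bins)
  jmap_te <- match(test_bins, all_bins)
  zs <- .zstats(X, tr, all_bins)
  nte <- length(te)
  B1 <- length(train_bins); B2 <- length(test_bins)
  Zte_flat <- .zflat(X, te, test_bins, zs, jmap_te)
  perms <- NULL
  if (n_perm > 0) {
    rng <- .local_seed(.sub_seed(seed, 6000 + f))
    perms <- if (shuffle == "all") replicate(n_perm, sample(y))
             else replicate(n_perm, sample(y[tr]))
    rng()
  }
  num <- matrix(0, B1, B2)
  perm_num <- if (n_perm > 0) array(0, dim = c(B1, B2, n_perm)) else NULL
  nb_rows <- nte * B2
  Ks <- vector("list", B1); Ktes <- vector("list", B1)
  margins_all <- matrix(0, B1 * nb_rows, ncol(pairs))
  for (i1 in seq_len(B1)) {
    Ztr <- .zbin(X, tr, train_bins[i1], zs, jmap_tr[i1])
    fit <- .ridge_pairs(.class_stats(Ztr, y[tr], classes), pairs, classes,
                        lambda)
    rows_out <- (i1 - 1L) * nb_rows + seq_len(nb_rows)
    margins_all[rows_out, ] <- Zte_flat %*% fit$W +
      matrix(fit$b0, nb_rows, ncol(pairs), byrow = TRUE)
    if (n_perm > 0) {
      Ks[[i1]] <- tcrossprod(Ztr)
      Ktes[[i1]] <- tcrossprod(Zte_flat, Ztr)
    }
  }
  pred <- .ovo_predict(margins_all, pairs, classes)
  correct <- pred == rep_len(rep(y[te], B2), length(pred))
  num <- t(matrix(colSums(matrix(correct, nte, B2 * B1)), B2, B1))
  for (pm in seq_len(if (n_perm > 0) n_perm else 0)) {
    if (shuffle == "all") {
      yptr <- perms[, pm][tr]; ypte <- perms[, pm][te]
    } else {
      yptr <- perms[, pm]; ypte <- y[te]
    }
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
    predp <- .ovo_predict(margins_all, pairs, classes)
    correctp <- predp == rep_len(rep(ypte, B2), length(predp))
    perm_num[, , pm] <- t(matrix(colSums(matrix(correctp, nte, B2 * B1)),
                                 B2, B1))
  }
  list(num = num, perm_num = perm_num, nte = nte)
}

# Combine per-fold counts into accuracy and permutation p-values.
.counts_to_result <- function(num, perm_num, n_total, train_bins, test_bins,
                              bins, lambda, target, n_perm) {
  accuracy <- num / n_total
  p <- NULL
  if (n_perm > 0) {
    perm_acc <- perm_num / n_total
    p <- matrix(0, nrow(num), ncol(num))
    for (i1 in seq_len(nrow(num))) for (i2 in seq_len(ncol(num)))
      p[i1, i2] <- sum(perm_acc[i1, i2, ] > accuracy[i1, i2]) / n_perm
  }
  diag_idx <- match(train_bins, test_bins)
  structure(list(accuracy = accuracy,
                 diagonal = ifelse(is.na(diag_idx), NA_real_,
                                   accuracy[cbind(seq_along(train_bins),
                                                  diag_idx)]),
                 p = p, train_bins = train_bins, test_bins = test_bins,
                 bins = bins, lambda = lambda, target = target,
                 n_trials = n_total, n_perm = n_perm),
            class = "ctd_result")
}

#' Stable-code extraction: subspace + greedy ensemble, one dataset
#'
#' Runs the greedy backward search with the subspace stability objective on
#' `n_search_folds` outer folds; each fold's selected ensemble is then
#' evaluated on that fold's held-out trials with the full split/swap subspace
#' protocol (training-label permutations for significance), and the fold
#' accuracies are pooled.
#'
#' @inheritParams greedy_backward_ensemble
#' @param n_search_folds Number of outer folds searched (1..n_outer_folds).
#' @param n_perm Training-label permutations for the final evaluation.
#' @param final_train_bins,final_test_bins Bins of the reported CTD (default:
#'   the analysis window on the population's grid).
#' @return List of class `ensemble_ctd`: `result` (`ctd_result` with `p`),
#'   `traces`, `ensembles` (per searched fold), `lambda_sub`.
#' @export
combined_stable_pipeline <- function(pop, config = decoder_config(),
                                     lambda = NULL, seed = 1L,
                                     n_search_folds = 1L, n_perm = 0,
                                     final_train_bins = NULL,
                                     final_test_bins = NULL,
                                     min_size = 1L, search_stride = 1L) {
  fold <- .make_folds(pop$labels, config$target, config$n_outer_folds, seed)
  win <- bins_in_window(pop$bins, .config_window(config, pop$task))
  if (is.null(final_train_bins)) final_train_bins <- win
  if (is.null(final_test_bins)) final_test_bins <- win
  if (is.null(lambda)) lambda <- tune_lambda_subspace(pop, config, seed)
  traces <- list(); ensembles <- list()
  num <- 0; perm_num <- 0; n_total <- 0
  for (f in seq_len(n_search_folds)) {
    tr <- greedy_backward_ensemble(pop, "stability", config, lambda,
                                   with_subspace = TRUE, fold_id = fold,
                                   f = f, min_size = min_size,
                                   search_stride = search_stride, seed = seed)
    traces[[f]] <- tr
    ensembles[[f]] <- tr$selected
    r <- .fold_subspace_ctd(pop, f, fold, config, lambda,
                            units = tr$selected, final_train_bins,
                            final_test_bins, n_perm, seed)
    num <- num + r$num
    if (n_perm > 0) perm_num <- perm_num + r$perm_num
    n_total <- n_total + r$nte
  }
  res <- .counts_to_result(num, perm_num, n_total, final_train_bins,
                           final_test_bins, pop$bins, lambda,
                           config$target, n_perm)
  res$protocol <- "subspace+ensemble"
  structure(list(result = res, traces = traces, ensembles = ensembles,
                 lambda_sub = lambda, fold = fold),
            class = "ensemble_ctd")
}

#' Dynamic-code extraction: greedy locality ensemble, one dataset
#'
#' Greedy backward search under the temporal-locality objective on raw
#' activity (training on one in `stride` bins); the selected ensemble's full
#' cross-temporal accuracy is evaluated on the held-out fold (label
#' permutations optional).
#'
#' @inheritParams combined_stable_pipeline
#' @param stride Training-bin stride during the search (NULL = ~250 ms
#'   between training bins).
#' @return List of class `ensemble_ctd`.
#' @export
dynamic_ensemble_pipeline <- function(pop, config = decoder_config(),
                                      lambda = NULL, seed = 1L,
                                      n_search_folds = 1L, n_perm = 0,
                                      stride = NULL,
                                      final_train_bins = NULL,
                                      final_test_bins = NULL,
                                      min_size = 1L, search_stride = 1L) {
  fold <- .make_folds(pop$labels, config$target, config$n_outer_folds, seed)
  win <- bins_in_window(pop$bins, .config_window(config, pop$task))
  if (is.null(final_train_bins)) final_train_bins <- win
  if (is.null(final_test_bins)) final_test_bins <- win
  if (is.null(lambda))
    lambda <- as.numeric(tune_lambda(pop, config, seed,
                                     train_idx = which(fold != 1L)))
  traces <- list(); ensembles <- list()
  num <- 0; perm_num <- 0; n_total <- 0
  for (f in seq_len(n_search_folds)) {
    tr <- greedy_backward_ensemble(pop, "locality", config, lambda,
                                   fold_id = fold, f = f, stride = stride,
                                   min_size = min_size,
                                   search_stride = search_stride, seed = seed)
    traces[[f]] <- tr
    ensembles[[f]] <- tr$selected
    r <- .fold_raw_ctd_perm(pop, f, fold, config, lambda,
                            units = tr$selected, final_train_bins,
                            final_test_bins, n_perm, seed, shuffle = "all")
    num <- num + r$num
    if (n_perm > 0) perm_num <- perm_num + r$perm_num
    n_total <- n_total + r$nte
  }
  res <- .counts_to_result(num, perm_num, n_total, final_train_bins,
                           final_test_bins, pop$bins, lambda,
                           config$target, n_perm)
  res$protocol <- "dynamic-ensemble"
  structure(list(result = res, traces = traces, ensembles = ensembles,
                 lambda = lambda, fold = fold),
            class = "ensemble_ctd")
}

#' @export
print.ensemble_ctd <- function(x, ...) {
  sizes <- vapply(x$ensembles, length, numeric(1))
  cat(sprintf("%s: %d search fold(s), ensemble size(s) %s\n",
              x$result$protocol, length(x$ensembles),
              paste(sizes, collapse = ", ")))
  print(x$result)
  invisible(x)
}

#' Extract the stable (or dynamic) value code across datasets
#'
#' Runs [combined_stable_pipeline()] (or [dynamic_ensemble_pipeline()]) on
#' each of the five pseudo-population datasets, averages the accuracy
#' matrices, and aggregates the permutation p-values per time-bin pair.
#'
#' @param pops List of `pseudopop` datasets.
#' @param config,seed,n_search_folds,n_perm,min_size As in the per-dataset
#'   pipelines.
#' @param ... Passed through to the per-dataset pipeline.
#' @return List of class `code_extraction`: `accuracy` (mean), `p_agg`,
#'   `per_dataset`, `ensembles` (one entry per dataset x searched fold),
#'   `kind`.
#' @export
extract_stable_code <- function(pops, config = decoder_config(), seed = 1L,
                                n_search_folds = 1L, n_perm = 0,
                                min_size = 1L, ...) {
  .extract_code(pops, config, seed, n_search_folds, n_perm, min_size,
                kind = "stable", ...)
}

#' @rdname extract_stable_code
#' @export
extract_dynamic_code <- function(pops, config = decoder_config(), seed = 1L,
                                 n_search_folds = 1L, n_perm = 0,
                                 min_size = 1L, ...) {
  .extract_code(pops, config, seed, n_search_folds, n_perm, min_size,
                kind = "dynamic", ...)
}

.extract_code <- function(pops, config, seed, n_search_folds, n_perm,
                          min_size, kind, ...) {
  per <- vector("list", length(pops))
  for (d in seq_along(pops)) {
    sd_ <- .sub_seed(seed, 100 + d)
    per[[d]] <- if (kind == "stable")
      combined_stable_pipeline(pops[[d]], config, seed = sd_,
                               n_search_folds = n_search_folds,
                               n_perm = n_perm, min_size = min_size, ...)
    else
      dynamic_ensemble_pipeline(pops[[d]], config, seed = sd_,
                                n_search_folds = n_search_folds,
                                n_perm = n_perm, min_size = min_size, ...)
  }
  acc <- Reduce(`+`, lapply(per, function(x) x$result$accuracy)) / length(per)
  p_agg <- if (n_perm > 0 && length(pops) == 5L)
    aggregate_pvalues(lapply(per, function(x) x$result$p)) else NULL
  ensembles <- unlist(lapply(per, `[[`, "ensembles"), recursive = FALSE)
  structure(list(accuracy = acc, p_agg = p_agg, per_dataset = per,
                 ensembles = ensembles, kind = kind,
                 train_bins = per[[1]]$result$train_bins,
                 test_bins = per[[1]]$result$test_bins,
                 bins = pops[[1]]$bins, alpha = config$alpha),
            class = "code_extraction")
}

#' @export
print.code_extraction <- function(x, ...) {
  cat(sprintf("%s code extraction over %d datasets\n", x$kind,
              length(x$per_dataset)))
  cat(sprintf("  mean accuracy %.3f", mean(x$accuracy)))
  if (!is.null(x$p_agg))
    cat(sprintf("; significant pairs (p_agg <= %.3g): %.1f%%",
                x$alpha, 100 * mean(x$p_agg <= x$alpha)))
  cat("\n")
  invisible(x)
}

#' Chance-overlap test between stable and dynamic ensembles
#'
#' For each instance (matched stable/dynamic ensemble pair from the same
#' dataset and fold), tests independence of unit membership with a 2x2
#' chi-squared test, then applies Benjamini-Hochberg FDR correction across
#' instances. Instances with degenerate margins (an ensemble empty or
#' containing every unit) are skipped and flagged.
#'
#' @param stable_ensembles,dynamic_ensembles Lists of unit-index vectors
#'   (equal length; instance i pairs element i of each).
#' @param n_units Total units in the population.
#' @param alpha Significance threshold after FDR (default 0.01).
#' @return data.frame per instance: `chisq`, `p`, `p_fdr`, `significant`,
#'   `skipped`, `overlap`, `expected_overlap`.
#' @export
ensemble_overlap_test <- function(stable_ensembles, dynamic_ensembles,
                                  n_units, alpha = 0.01) {
  stopifnot(length(stable_ensembles) == length(dynamic_ensembles))
  res <- do.call(rbind, lapply(seq_along(stable_ensembles), function(i) {
    s <- seq_len(n_units) %in% stable_ensembles[[i]]
    d <- seq_len(n_units) %in% dynamic_ensembles[[i]]
    ov <- sum(s & d)
    exp_ov <- sum(s) * sum(d) / n_units
    if (sum(s) %in% c(0, n_units) || sum(d) %in% c(0, n_units))
      return(data.frame(instance = i, chisq = NA_real_, p = NA_real_,
                        significant = FALSE, skipped = TRUE, overlap = ov,
                        expected_overlap = exp_ov))
    ct <- suppressWarnings(stats::chisq.test(table(s, d), correct = FALSE))
    data.frame(instance = i, chisq = unname(ct$statistic), p = ct$p.value,
               significant = FALSE, skipped = FALSE, overlap = ov,
               expected_overlap = exp_ov)
  }))
  ok <- !res$skipped
  res$p_fdr <- NA_real_
  res$p_fdr[ok] <- stats::p.adjust(res$p[ok], method = "BH")
  res$significant[ok] <- res$p_fdr[ok] <= alpha
  res
}

#' Hypergeometric enrichment of an ensemble for a planted pool
#'
#' Upper-tail hypergeometric test of whether `selected` contains more members
#' of `pool` than expected from a random draw of its size.
#'
#' @param selected Unit indices of the ensemble.
#' @param pool Unit indices of the planted pool.
#' @param n_units Total population size.
#' @return List: `overlap`, `expected`, `p`.
#' @export
ensemble_enrichment <- function(selected, pool, n_units) {
  k <- length(intersect(selected, pool))
  p <- stats::phyper(k - 1, length(pool), n_units - length(pool),
                     length(selected), lower.tail = FALSE)
  list(overlap = k, expected = length(selected) * length(pool) / n_units,
       p = p)
}

#' Unsigned subspace weights averaged over datasets
#'
#' Builds the value subspace on all trials of each dataset and returns the
#' per-unit L2 norm of the component loadings, averaged across datasets (a
#' unit's unsigned participation in the value subspace).
#'
#' @param pops List of `pseudopop` datasets.
#' @param window Time window for the class means (NULL = cue onset to reward).
#' @param target Label (default `"value"`).
#' @return Numeric vector, one weight per unit.
#' @export
subspace_weights <- function(pops, window = NULL, target = "value") {
  ws <- vapply(pops, function(pop) {
    ss <- build_value_subspace(pop, window = window, target = target)
    sqrt(rowSums(ss$components^2))
  }, numeric(dim(pops[[1]]$X)[2]))
  rowMeans(ws)
}
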