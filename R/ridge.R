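# Closed-form ridge regression and one-versus-one multi-class machinery.
# Features are z-scored with training statistics before fitting; the intercept
# is unpenalised (handled by centring). MASS::lm.ridge serves as an
# independent cross-check in the test suite.

# Ridge coefficients with unpenalised intercept. Z: n x p, y: numeric (+/-1).
.ridge_coef <- function(Z, y, lambda) {
  mz <- colMeans(Z)
  Zc <- sweep(Z, 2, mz)
  yc <- y - mean(y)
  p <- ncol(Z)
  A <- crossprod(Zc)
  diag(A) <- diag(A) + lambda
  w <- solve(A, crossprod(Zc, yc))
  b0 <- mean(y) - sum(mz * w)
  list(w = drop(w), b0 = b0)
}

# Ridge solution path over a lambda grid via one SVD. Returns p x n_lambda
# coefficient matrix and intercepts.
.ridge_path <- function(Z, y, lambdas) {
  mz <- colMeans(Z)
  Zc <- sweep(Z, 2, mz)
  yc <- y - mean(y)
  sv <- svd(Zc)
  uty <- drop(crossprod(sv$u, yc))
  shrink <- sv$d / outer(sv$d^2, lambdas, `+`) # [i, l] = d_i / (d_i^2 + l)
  W <- sv$v %*% (shrink * uty)
  b0 <- mean(y) - drop(crossprod(mz, W))
  list(W = W, b0 = b0)
}

# Unordered class pairs, columns (v, w) with v < w.
.ovo_pairs <- function(classes) utils::combn(sort(unique(classes)), 2)

# Majority vote over pair margins. margins: n x P (positive -> first class of
# the pair). Ties are broken by summed signed margins, then lowest class index.
# Vectorised via incidence matrices (one matrix product per aggregate).
.ovo_predict <- function(margins, pairs, classes) {
  C <- length(classes)
  P <- ncol(pairs)
  M1 <- matrix(0, P, C) # pair -> first class
  M2 <- matrix(0, P, C) # pair -> second class
  M1[cbind(seq_len(P), match(pairs[1, ], classes))] <- 1
  M2[cbind(seq_len(P), match(pairs[2, ], classes))] <- 1
  D <- M1 - M2
  pos <- (margins > 0) + 0
  votes <- pos %*% D + matrix(colSums(M2), nrow(margins), C, byrow = TRUE)
  score <- margins %*% D
  # composite key reproduces the ordering (votes, then summed signed margin,
  # then lowest class index) without a per-row loop: the margin term is
  # squashed into (0, 1) so it can never overturn a vote difference
  s_norm <- score / (2 * max(abs(score), 1e-300)) + 0.5
  pred <- max.col(votes + 0.999 * s_norm, ties.method = "first")
  classes[pred]
}

# Per-class sufficient statistics of a feature matrix: sums, Gram blocks and
# counts, from which every pair's centred ridge system is pure arithmetic.
.class_stats <- function(Z, y, classes) {
  lapply(classes, function(v) {
    Zi <- Z[y == v, , drop = FALSE]
    list(S = colSums(Zi), Q = crossprod(Zi), n = nrow(Zi))
  })
}

# Batched 3-feature ridge across all bins and class pairs. P: n x B x 3
# array of features, grouped per bin. Returns W [3, P, B] and b0 [P, B].
# Vectorised over bins via the closed-form symmetric 3x3 solve; must agree
# with .ridge_pairs exactly (asserted in the tests).
.ridge_pairs_batch3 <- function(P, y, classes, pairs, lambda) {
  B <- dim(P)[2]
  np <- ncol(pairs)
  # per-class sums and Gram components per bin
  cs <- lapply(classes, function(v) {
    Pi <- P[y == v, , , drop = FALSE]
    n <- dim(Pi)[1]
    S <- apply(Pi, c(2, 3), sum) # B x 3
    nb2 <- dim(Pi)[1:2]
    Q <- vapply(list(c(1, 1), c(1, 2), c(1, 3), c(2, 2), c(2, 3), c(3, 3)),
                function(ij) colSums(array(
                  Pi[, , ij[1], drop = FALSE] * Pi[, , ij[2], drop = FALSE],
                  dim = nb2)), # dimension-safe for 0/1-trial classes
                numeric(B)) # B x 6: xx xy xz yy yz zz
    list(S = S, Q = matrix(Q, B, 6), n = n)
  })
  W <- array(0, dim = c(3, np, B))
  b0 <- matrix(0, np, B)
  for (pr in seq_len(np)) {
    a <- cs[[match(pairs[1, pr], classes)]]
    b <- cs[[match(pairs[2, pr], classes)]]
    n <- a$n + b$n
    m <- (a$S + b$S) / n          # B x 3
    ybar <- (a$n - b$n) / n
    G <- a$Q + b$Q                # B x 6
    xx <- G[, 1] - n * m[, 1]^2 + lambda
    xy <- G[, 2] - n * m[, 1] * m[, 2]
    xz <- G[, 3] - n * m[, 1] * m[, 3]
    yy <- G[, 4] - n * m[, 2]^2 + lambda
    yz <- G[, 5] - n * m[, 2] * m[, 3]
    zz <- G[, 6] - n * m[, 3]^2 + lambda
    bc <- (a$S - b$S) - n * m * ybar # B x 3
    A11 <- yy * zz - yz^2; A12 <- xz * yz - xy * zz; A13 <- xy * yz - xz * yy
    A22 <- xx * zz - xz^2; A23 <- xy * xz - xx * yz; A33 <- xx * yy - xy^2
    det <- xx * A11 + xy * A12 + xz * A13
    w1 <- (A11 * bc[, 1] + A12 * bc[, 2] + A13 * bc[, 3]) / det
    w2 <- (A12 * bc[, 1] + A22 * bc[, 2] + A23 * bc[, 3]) / det
    w3 <- (A13 * bc[, 1] + A23 * bc[, 2] + A33 * bc[, 3]) / det
    W[1, pr, ] <- w1; W[2, pr, ] <- w2; W[3, pr, ] <- w3
    b0[pr, ] <- ybar - (m[, 1] * w1 + m[, 2] * w2 + m[, 3] * w3)
  }
  list(W = W, b0 = b0)
}

# Stacked test margins for a batch of per-bin OVO fits (from
# .ridge_pairs_batch3): one matrix product, rows grouped by training bin.
.stack_margins <- function(Zflat, fit) {
  np <- dim(fit$W)[2]
  B <- dim(fit$W)[3]
  n <- nrow(Zflat)
  Mbig <- Zflat %*% matrix(fit$W, 3, np * B)
  out <- matrix(aperm(array(Mbig, c(n, np, B)), c(1, 3, 2)), n * B, np)
  out + t(fit$b0)[rep(seq_len(B), each = n), , drop = FALSE]
}

# Ridge fits for every class pair from per-class statistics.
# Returns W (p x P) and b0 (length P); targets +1 for the pair's first class.
.ridge_pairs <- function(stats, pairs, classes, lambda) {
  p <- length(stats[[1]]$S)
  P <- ncol(pairs)
  W <- matrix(0, p, P)
  b0 <- numeric(P)
  for (pr in seq_len(P)) {
    a <- stats[[match(pairs[1, pr], classes)]]
    b <- stats[[match(pairs[2, pr], classes)]]
    n <- a$n + b$n
    m <- (a$S + b$S) / n
    ybar <- (a$n - b$n) / n
    Gc <- (a$Q + b$Q) - n * tcrossprod(m)
    diag(Gc) <- diag(Gc) + lambda
    bc <- (a$S - b$S) - n * m * ybar
    w <- solve(Gc, bc)
    W[, pr] <- w
    b0[pr] <- ybar - sum(m * w)
  }
  list(W = W, b0 = b0)
}

#' Fit a one-versus-one ridge classifier
#'
#' One L2-regularised linear regression per unordered class pair with targets
#' +1 (lower class index) and -1; prediction is by majority vote over pairs,
#' ties broken by summed signed margins, then lowest class index. Features are
#' z-scored using training statistics; the intercept is unpenalised. Four
#' classes yield six binary classifiers.
#'
#' @param x Training feature matrix (trials x units).
#' @param y Training class labels (>= 2 classes present).
#' @param lambda Ridge penalty.
#' @return An object of class `ovo_ridge` with a [predict][predict.ovo_ridge]
#'   method; `length(fit$fits)` is the number of binary classifiers.
#' @export
fit_ridge_ovo <- function(x, y, lambda = 1) {
  x <- as.matrix(x)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need >= 2 classes in training data",
                                call. = FALSE)
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  Z <- sweep(sweep(x, 2, mu), 2, sd_, "/")
  pairs <- .ovo_pairs(y)
  fits <- lapply(seq_len(ncol(pairs)), function(pr) {
    v <- pairs[1, pr]; w <- pairs[2, pr]
    rows <- y %in% c(v, w)
    .ridge_coef(Z[rows, , drop = FALSE],
                ifelse(y[rows] == v, 1, -1), lambda)
  })
  structure(list(fits = fits, pairs = pairs, classes = classes,
                 mu = mu, sd = sd_, lambda = lambda),
            class = "ovo_ridge")
}

#' Predict classes (or pair margins) from an OVO ridge classifier
#'
#' @param object An `ovo_ridge` fit.
#' @param newdata Feature matrix (trials x units).
#' @param type `"class"` (default) or `"margin"` (signed per-pair margins).
#' @param ... Unused.
#' @return Class labels, or an n x n_pairs margin matrix.
#' @export
predict.ovo_ridge <- function(object, newdata, type = c("class", "margin"),
                              ...) {
  type <- match.arg(type)
  Z <- sweep(sweep(as.matrix(newdata), 2, object$mu), 2, object$sd, "/")
  margins <- vapply(object$fits, function(f) drop(Z %*% f$w + f$b0),
                    numeric(nrow(Z)))
  margins <- matrix(margins, nrow = nrow(Z))
  if (type == "margin") return(margins)
  .ovo_predict(margins, object$pairs, object$classes)
}
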