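# Population-dynamics summaries: trajectory speed, linear regression of time
# from population activity, and the encoding-decoding correlation battery.

#' Population trajectory speed
#'
#' Euclidean distance between consecutive time-bin vectors of the
#' across-trial mean population activity (rate of change of the average
#' trajectory in neural state space). For temporally precise estimates, build
#' the input with a 50 ms SD smoothing kernel instead of the default 100 ms.
#' The scale grows with unit count; constant-rate units contribute nothing.
#'
#' @param x A `rate_matrix` or `pseudopop`.
#' @param per_trial If TRUE, also return per-trial speeds (mean over trials of
#'   single-trial trajectory speeds).
#' @return data.frame: `t` (midpoint between the two bin centres), `speed`
#'   (Hz), `epoch_junction` (TRUE where the step crosses concatenated epochs),
#'   and optionally `speed_trial`.
#' @export
trajectory_speed <- function(x, per_trial = FALSE) {
  if (inherits(x, "pseudopop")) {
    X <- x$X; bins <- x$bins
  } else {
    bins <- attr(x, "bins"); X <- unclass(x)
  }
  if (dim(X)[3] < 2) stop("need at least two bins", call. = FALSE)
  M <- apply(X, c(2, 3), mean) # units x bins
  d <- diff(t(M))              # (bins-1) x units
  speed <- sqrt(rowSums(d^2))
  tmid <- (bins$t_abs[-1] + bins$t_abs[-nrow(bins)]) / 2
  junction <- bins$epoch[-1] != bins$epoch[-nrow(bins)]
  out <- data.frame(t = tmid, speed = speed, epoch_junction = junction)
  if (per_trial) {
    sp_tr <- sapply(seq_len(dim(X)[1]), function(i) {
      di <- diff(t(X[i, , ]))
      sqrt(rowSums(di^2))
    })
    out$speed_trial <- rowMeans(sp_tr)
  }
  out
}

#' Predict elapsed time from population activity
#'
#' Ordinary least squares predicting the time-bin index from the per-trial
#' population rate vector, assessed with leave-one-trial-out cross-validation.
#' Reports the mean and SD of the held-out predictions per true bin and the
#' leave-one-out R-squared. When the design is (near) singular (more units
#' than observations), a tiny ridge penalty is added and flagged.
#'
#' @param x A `pseudopop` or `rate_matrix`.
#' @param window Time window `c(lo, hi)` in s (default 500 ms before cue onset
#'   to 500 ms after reward).
#' @return List: `per_bin` (data.frame bin, t, pred_mean, pred_sd),
#'   `r2_loo`, `ridged` (logical), `window_bins`.
#' @export
regress_time <- function(x, window = NULL) {
  if (inherits(x, "pseudopop")) {
    X <- x$X; bins <- x$bins; task <- x$task
  } else {
    bins <- attr(x, "bins"); task <- attr(x, "task"); X <- unclass(x)
  }
  if (is.null(window)) window <- c(task$cue_on - 0.5, task$reward + 0.5)
  wb <- bins_in_window(bins, window)
  n_tr <- dim(X)[1]; p <- dim(X)[2]; B <- length(wb)
  if (n_tr < 3) stop("need at least 3 trials for leave-one-out", call. = FALSE)
  yb <- seq_len(B) # target: integer bin index
  # stacked design: rows grouped by trial
  Xl <- lapply(seq_len(n_tr), function(i) cbind(1, t(X[i, , wb])))
  yl <- rep(list(yb), n_tr)
  G <- Reduce(`+`, lapply(Xl, crossprod))
  bvec <- Reduce(`+`, lapply(seq_len(n_tr), function(i) crossprod(Xl[[i]], yb)))
  ridged <- (n_tr - 1) * B <= p
  lam <- if (ridged) 1e-6 * mean(diag(G)[-1]) else 0
  preds <- matrix(NA_real_, n_tr, B)
  for (i in seq_len(n_tr)) {
    Gi <- G - crossprod(Xl[[i]])
    bi <- bvec - crossprod(Xl[[i]], yb)
    if (lam > 0) Gi[-1, -1] <- Gi[-1, -1] + diag(lam, p)
    w <- tryCatch(solve(Gi, bi), error = function(e) {
      ridged <<- TRUE
      l2 <- 1e-6 * mean(diag(Gi)[-1])
      Gi[-1, -1] <- Gi[-1, -1] + diag(l2, p)
      solve(Gi, bi)
    })
    preds[i, ] <- drop(Xl[[i]] %*% w)
  }
  sse <- sum((preds - matrix(yb, n_tr, B, byrow = TRUE))^2)
  sst <- sum((matrix(yb, n_tr, B, byrow = TRUE) - mean(yb))^2)
  list(per_bin = data.frame(bin = yb, t = bins$t_abs[wb],
                            pred_mean = colMeans(preds),
                            pred_sd = apply(preds, 2, stats::sd)),
       r2_loo = 1 - sse / sst, ridged = ridged, window_bins = wb)
}

#' Spearman correlations between encoding measures and decoding contributions
#'
#' Correlates per-unit encoding measures (encoding strength, duration,
#' stability measure) with per-unit decoding contributions (unsigned subspace
#' weight, stable-ensemble accuracy contribution, dynamic-ensemble locality
#' contribution). Mixed-sign contributions are additionally correlated
#' separately on their positive and negative strata. Spearman correlations are
#' rank-based, so monotone transforms of either variable (e.g. the square-root
#' contribution transform) leave them unchanged.
#'
#' @param measures data.frame of per-unit encoding measures (columns used as
#'   provided, e.g. `es`, `duration`, `S`).
#' @param contributions Named list of per-unit numeric vectors (NAs allowed).
#' @return data.frame: `measure`, `contribution`, `stratum`, `n`, `rho`, `p`
#'   (rho and p are NA when fewer than 3 units are available).
#' @export
correlation_battery <- function(measures, contributions) {
  stopifnot(is.data.frame(measures), is.list(contributions))
  rows <- list()
  for (mname in names(measures)) {
    for (cname in names(contributions)) {
      mvec <- measures[[mname]]
      cvec <- contributions[[cname]]
      strata <- list(all = rep(TRUE, length(cvec)))
      if (any(cvec > 0, na.rm = TRUE) && any(cvec < 0, na.rm = TRUE)) {
        strata$positive <- !is.na(cvec) & cvec > 0
        strata$negative <- !is.na(cvec) & cvec < 0
      }
      for (sname in names(strata)) {
        sel <- strata[[sname]] & !is.na(cvec) & !is.na(mvec)
        n <- sum(sel)
        if (n < 3) {
          rows[[length(rows) + 1]] <- data.frame(
            measure = mname, contribution = cname, stratum = sname,
            n = n, rho = NA_real_, p = NA_real_)
          next
        }
        ct <- suppressWarnings(stats::cor.test(mvec[sel], cvec[sel],
                                               method = "spearman",
                                               exact = FALSE))
        rows[[length(rows) + 1]] <- data.frame(
          measure = mname, contribution = cname, stratum = sname,
          n = n, rho = unname(ct$estimate), p = ct$p.value)
      }
    }
  }
  do.call(rbind, rows)
}
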