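# Per-unit encoding statistics: per-bin ANOVA, run-length significance,
# encoding strength, stability measure, d-prime, split-half analyses.

# Sequential-SS F tests for a fixed design across many response columns.
# Y: n x M response matrix; returns per-term p-value matrices (M columns).
# On a balanced design sequential (Type I) SS equal Type II/III.
.anova_sweep <- function(Y, value, type, categorical = TRUE) {
  n <- nrow(Y)
  vf <- if (categorical) factor(value) else as.numeric(value)
  has_type <- length(unique(type)) > 1L
  df <- if (has_type)
    stats::model.matrix(~ vf * factor(type))
  else
    stats::model.matrix(~ vf)
  asgn <- attr(df, "assign")
  qrX <- qr(df)
  if (qrX$rank < ncol(df)) stop("rank-deficient encoding design", call. = FALSE)
  eff <- qr.qty(qrX, Y)
  p <- ncol(df)
  ss_res <- colSums(eff[(p + 1):n, , drop = FALSE]^2)
  df_res <- n - p
  terms <- list(value = 1L, type = 2L, interaction = 3L)
  out <- list()
  for (nm in names(terms)) {
    k <- terms[[nm]]
    if (!has_type && nm != "value") { out[[nm]] <- NULL; next }
    rows <- which(asgn == k)
    ss_k <- colSums(eff[rows, , drop = FALSE]^2)
    Fv <- (ss_k / length(rows)) / (ss_res / df_res)
    pv <- stats::pf(Fv, length(rows), df_res, lower.tail = FALSE)
    # zero-variance (constant) responses: no evidence either way
    pv[ss_res < 1e-12 & ss_k < 1e-12] <- 1
    pv[is.na(pv)] <- 1
    out[[nm]] <- pv
  }
  out
}

#' Per-bin ANOVA of unit activity on value, type and their interaction
#'
#' For every unit and time bin, fits the linear model
#' `activity ~ C(value) + type + C(value):type` (value categorical) and returns
#' the F-test p-value of each term. With `value_as = "linear"` value enters as
#' a numeric regressor instead (used to identify non-linear value coders).
#' Zero-variance bins get p = 1 and are flagged.
#'
#' @param X Rate tensor `[trial, unit, bin]` (a `rate_matrix` or `pseudopop$X`).
#' @param labels data.frame with per-trial `value` and `type`.
#' @param value_as `"categorical"` (default) or `"linear"`.
#' @return List of `[unit, bin]` p-value matrices: `value`, `type`,
#'   `interaction` (the latter two NULL when only one type level is present),
#'   plus `flagged` (logical matrix of zero-variance cells).
#' @export
fit_bin_anova <- function(X, labels, value_as = c("categorical", "linear")) {
  value_as <- match.arg(value_as)
  if (length(dim(X)) == 2L) X <- array(X, dim = c(dim(X)[1], 1L, dim(X)[2]))
  stopifnot(length(dim(X)) == 3L, dim(X)[1] == nrow(labels))
  n_tr <- dim(X)[1]; n_u <- dim(X)[2]; n_b <- dim(X)[3]
  if (min(table(labels$value, labels$type)) < 2L)
    stop("need at least 2 trials per condition", call. = FALSE)
  Y <- matrix(X, nrow = n_tr) # columns ordered: unit varies first, then bin
  res <- .anova_sweep(Y, labels$value, labels$type,
                      categorical = value_as == "categorical")
  shape <- function(v) if (is.null(v)) NULL else matrix(v, n_u, n_b)
  flagged <- matrix(apply(Y, 2, stats::var) < 1e-12, n_u, n_b)
  list(value = shape(res$value), type = shape(res$type),
       interaction = shape(res$interaction), flagged = flagged)
}

#' Run-length significance rule
#'
#' A bin encodes a variable if it lies inside a run of at least `k` consecutive
#' bins with p < `alpha` (~175 ms with 25 ms steps and k = 7). Latency is the
#' time of the first bin of the first qualifying run.
#'
#' @param p Numeric vector of per-bin p-values (one unit, one variable).
#' @param alpha Per-bin threshold (default 0.01).
#' @param k Minimum run length (default 7).
#' @param times Optional bin-centre times used to report the latency.
#' @return List: `mask` (logical per bin), `latency` (time or NA), `peak_bin`
#'   (index of minimal p, NA if no significant bin).
#' @export
#' @examples
#' significance_runs(c(rep(0.5, 3), rep(0.005, 7), 0.5), k = 7)$mask
significance_runs <- function(p, alpha = 0.01, k = 7, times = NULL) {
  hit <- !is.na(p) & p < alpha
  r <- rle(hit)
  r$values <- r$values & r$lengths >= k
  mask <- inverse.rle(r)
  latency <- NA_real_
  peak_bin <- NA_integer_
  if (any(mask)) {
    first <- which(mask)[1]
    latency <- if (is.null(times)) first else times[first]
    sigp <- ifelse(mask, p, NA)
    peak_bin <- which.min(sigp)
  }
  list(mask = mask, latency = latency, peak_bin = peak_bin)
}

#' Encoding strength
#'
#' Mean negative log10 p-value across the delay bins:
#' `es = (1/T) * sum(-log10 p(t))`. Constant p = 0.01 over the delay gives
#' es = 2. Zero p-values are clamped to the double floor and flagged.
#'
#' @param p Per-bin p-values over the delay.
#' @return `es` (scalar, >= 0) with attribute `clamped` when p = 0 occurred.
#' @export
encoding_strength <- function(p) {
  if (length(p) < 1) stop("need at least one bin", call. = FALSE)
  clamped <- any(p <= 0, na.rm = TRUE)
  p <- pmax(p, .Machine$double.xmin)
  structure(mean(-log10(p)), clamped = clamped)
}

#' Pooled standard deviation of two groups
#'
#' `sp = sqrt((sv2 + sw2) / 2)`; vectorised over bins.
#'
#' @param sv2,sw2 Variances of the two groups.
#' @return Pooled SD.
#' @export
pooled_sd <- function(sv2, sw2) sqrt((sv2 + sw2) / 2)

#' Stability measure of a unit's value code
#'
#' For every unordered pair of values (v, w), the signed, noise-normalised
#' firing difference `tanh(10 * (xbar_v(t) - xbar_w(t)) / sp_vw(t))` is
#' averaged across delay bins and its absolute value taken; S is the mean over
#' the 6 pairs. A constant separation saturates S toward 1; a sign reversal of
#' the difference across the delay cancels the sum and drives S toward 0.
#' `sp = 0` terms are set to sign(difference) (0 when the difference is also 0)
#' and flagged.
#'
#' @param xbar Matrix `[value, bin]` of per-value mean rates.
#' @param svar Matrix `[value, bin]` of per-value across-trial variances.
#' @return S in `[0, 1]`, with attribute `flagged` when degenerate pooled SDs
#'   occurred.
#' @export
stability_measure <- function(xbar, svar) {
  stopifnot(is.matrix(xbar), all(dim(xbar) == dim(svar)))
  nv <- nrow(xbar)
  pairs <- utils::combn(nv, 2)
  flagged <- FALSE
  s_pairs <- apply(pairs, 2, function(pr) {
    d <- xbar[pr[1], ] - xbar[pr[2], ]
    sp <- pooled_sd(svar[pr[1], ], svar[pr[2], ])
    z <- ifelse(sp > 0, tanh(10 * d / sp), sign(d))
    if (any(sp == 0)) flagged <<- TRUE
    abs(mean(z))
  })
  structure(mean(s_pairs), flagged = flagged)
}

#' Sensitivity index (d-prime) of a unit for value
#'
#' Per-trial rates are averaged over the cue-to-reward window; for each value
#' pair d' = |mean_v - mean_w| / pooled SD, and the unit's d' is the mean over
#' pairs. Pairs with zero pooled SD are excluded (NA if all are degenerate).
#'
#' @param rates Per-trial scalar rates (e.g. window-averaged).
#' @param value Per-trial value labels.
#' @return Mean d' over value pairs.
#' @export
dprime_unit <- function(rates, value) {
  vals <- sort(unique(value))
  if (any(table(value) < 2)) stop("need >= 2 trials per value", call. = FALSE)
  pairs <- utils::combn(length(vals), 2)
  d <- apply(pairs, 2, function(pr) {
    a <- rates[value == vals[pr[1]]]
    b <- rates[value == vals[pr[2]]]
    sp <- pooled_sd(stats::var(a), stats::var(b))
    if (sp == 0) return(NA_real_)
    abs(mean(a) - mean(b)) / sp
  })
  if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE)
}

#' Per-unit encoding profiles
#'
#' Runs the per-bin ANOVA over all bins, applies the run-length rule per
#' variable over the cue-to-reward window, and computes the delay-based
#' measures (encoding strength, duration, stability, d').
#'
#' @param X Rate tensor `[trial, unit, bin]`.
#' @param labels data.frame with `value`, `type`.
#' @param bins Bin grid (from [bin_grid()] / attributes of the tensor).
#' @param task A [task_config()].
#' @param alpha,run_k Run-length rule parameters.
#' @return An object of class `encoding_profile`: list with `p` (list of
#'   `[unit, bin]` matrices incl. `value_linear`), `mask` (same shape, run-rule
#'   masks computed over the cue-to-reward window), `stats` (one row per unit:
#'   latency/peak/duration/es/S/dprime and any-time significance per variable),
#'   `bins`, `window` (cue-to-reward bin indices), `delay` (delay bin indices).
#' @export
encoding_profile <- function(X, labels, bins, task, alpha = 0.01, run_k = 7) {
  if (inherits(X, "rate_matrix")) {
    bins <- attr(X, "bins"); labels <- attr(X, "labels")
    task <- attr(X, "task")
    X <- unclass(X)
  }
  n_u <- dim(X)[2]
  win <- bins_in_window(bins, c(task$cue_on, task$reward))
  delay <- bins_in_window(bins, c(task$cue_off, task$reward))
  pv <- fit_bin_anova(X, labels, "categorical")
  pl <- fit_bin_anova(X, labels, "linear")
  p <- list(value = pv$value, type = pv$type, interaction = pv$interaction,
            value_linear = pl$value)

  vars <- names(p)[!vapply(p, is.null, logical(1))]
  mask <- lapply(p, function(m) {
    if (is.null(m)) return(NULL)
    out <- matrix(FALSE, n_u, ncol(m))
    out
  })
  lat <- matrix(NA_real_, n_u, length(vars), dimnames = list(NULL, vars))
  peak <- matrix(NA_integer_, n_u, length(vars), dimnames = list(NULL, vars))
  for (v in vars) {
    for (u in seq_len(n_u)) {
      r <- significance_runs(p[[v]][u, win], alpha, run_k,
                             times = bins$t_abs[win])
      mask[[v]][u, win] <- r$mask
      lat[u, v] <- r$latency
      peak[u, v] <- if (is.na(r$peak_bin)) NA_integer_ else win[r$peak_bin]
    }
  }

  # delay-based measures for value
  Tn <- length(delay)
  es <- duration <- S <- dp <- numeric(n_u)
  for (u in seq_len(n_u)) {
    es[u] <- as.numeric(encoding_strength(p$value[u, delay]))
    duration[u] <- mean(mask$value[u, delay])
    xbar <- t(vapply(seq_len(task$n_values), function(v)
      colMeans(X[labels$value == v, u, delay, drop = FALSE][, 1, ]),
      numeric(Tn)))
    svar <- t(vapply(seq_len(task$n_values), function(v)
      apply(X[labels$value == v, u, delay, drop = FALSE][, 1, ], 2, stats::var),
      numeric(Tn)))
    S[u] <- as.numeric(stability_measure(xbar, svar))
    dp[u] <- dprime_unit(rowMeans(X[, u, win, drop = FALSE][, 1, ]),
                         labels$value)
  }

  stats_df <- data.frame(
    unit = seq_len(n_u),
    sig_value = apply(mask$value, 1, any),
    sig_type = if (!is.null(mask$type)) apply(mask$type, 1, any) else NA,
    sig_interaction = if (!is.null(mask$interaction))
      apply(mask$interaction, 1, any) else NA,
    sig_value_linear = apply(mask$value_linear, 1, any),
    latency_value = lat[, "value"],
    latency_type = if ("type" %in% vars) lat[, "type"] else NA_real_,
    peak_bin_value = peak[, "value"],
    duration = duration, es = es, S = S, dprime = dp)

  structure(list(p = p, mask = mask, stats = stats_df, bins = bins,
                 window = win, delay = delay, alpha = alpha, run_k = run_k,
                 task = task),
            class = "encoding_profile")
}

#' @export
print.encoding_profile <- function(x, ...) {
  n <- nrow(x$stats)
  cat(sprintf("Encoding profiles for %d units (alpha %.3g, run >= %d bins)\n",
              n, x$alpha, x$run_k))
  cat(sprintf("  value-encoding (any time, cue->reward): %.1f%%\n",
              100 * mean(x$stats$sig_value)))
  if (!all(is.na(x$stats$sig_type)))
    cat(sprintf("  type-encoding: %.1f%%\n", 100 * mean(x$stats$sig_type)))
  cat(sprintf("  mean es %.2f | mean S %.2f | mean d' %.2f\n",
              mean(x$stats$es), mean(x$stats$S),
              mean(x$stats$dprime, na.rm = TRUE)))
  invisible(x)
}

#' Split-half consistency of sequential encoding
#'
#' Trials are split in half (stratified by condition); the per-bin value ANOVA
#' and run-length rule are applied independently to each half over the delay.
#' Only units significant in both halves are kept. Peak-encoding bins (minimal
#' p among significant bins) and encoding durations are compared across halves
#' with Spearman correlations.
#'
#' @inheritParams encoding_profile
#' @param seed Seed for the split.
#' @return List: `units` (kept indices), `peak_train`, `peak_test` (delay bin
#'   indices), `dur_train`, `dur_test`, `R_peak`, `p_peak`, `R_dur`, `p_dur`,
#'   `order_train` (units sorted by training peak). Correlations are NA with
#'   fewer than 3 kept units.
#' @export
split_half_sequence_analysis <- function(X, labels, bins, task, alpha = 0.01,
                                         run_k = 7, seed = 1L) {
  if (inherits(X, "rate_matrix")) {
    bins <- attr(X, "bins"); labels <- attr(X, "labels")
    task <- attr(X, "task"); X <- unclass(X)
  }
  rng <- .local_seed(seed)
  on.exit(rng())
  cond <- interaction(labels$value, labels$type)
  half1 <- unlist(lapply(split(seq_len(nrow(labels)), cond), function(ix)
    sample(ix, floor(length(ix) / 2))))
  half2 <- setdiff(seq_len(nrow(labels)), half1)
  delay <- bins_in_window(bins, c(task$cue_off, task$reward))
  n_u <- dim(X)[2]

  half_stats <- function(rows) {
    pv <- fit_bin_anova(X[rows, , delay, drop = FALSE],
                        labels[rows, , drop = FALSE], "categorical")$value
    res <- lapply(seq_len(n_u), function(u)
      significance_runs(pv[u, ], alpha, run_k))
    list(sig = vapply(res, function(r) any(r$mask), logical(1)),
         peak = vapply(res, function(r)
           if (is.na(r$peak_bin)) NA_real_ else r$peak_bin, numeric(1)),
         dur = vapply(res, function(r) mean(r$mask), numeric(1)))
  }
  tr <- half_stats(half1)
  te <- half_stats(half2)
  keep <- which(tr$sig & te$sig)

  cor_or_na <- function(a, b) {
    if (length(keep) < 3) return(list(R = NA_real_, p = NA_real_))
    ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                           exact = FALSE))
    list(R = unname(ct$estimate), p = ct$p.value)
  }
  cp <- cor_or_na(tr$peak[keep], te$peak[keep])
  cd <- cor_or_na(tr$dur[keep], te$dur[keep])
  list(units = keep,
       peak_train = tr$peak[keep], peak_test = te$peak[keep],
       dur_train = tr$dur[keep], dur_test = te$dur[keep],
       R_peak = cp$R, p_peak = cp$p, R_dur = cd$R, p_dur = cd$p,
       order_train = keep[order(tr$peak[keep])],
       halves = list(train = half1, test = half2))
}

#' Reverse cumulative distribution of encoding durations
#'
#' Fraction of units whose encoding duration (fraction of delay bins
#' significant) is at least `x`, on a grid of coverage fractions.
#'
#' @param durations Durations in `[0, 1]`.
#' @param grid Coverage grid (default 0..1 by 0.01).
#' @return data.frame with `coverage` and `fraction`.
#' @export
coverage_distribution <- function(durations, grid = seq(0, 1, by = 0.01)) {
  stopifnot(all(durations >= 0 & durations <= 1))
  data.frame(coverage = grid,
             fraction = vapply(grid, function(x) mean(durations >= x),
                               numeric(1)))
}

#' Kolmogorov-Smirnov comparison of two regions' duration distributions
#'
#' @param dur_a,dur_b Encoding durations of the two regions.
#' @return List with `stat` and `p` from the two-sample KS test.
#' @export
ks_durations <- function(dur_a, dur_b) {
  kt <- suppressWarnings(stats::ks.test(dur_a, dur_b))
  list(stat = unname(kt$statistic), p = kt$p.value)
}

#' Identify non-linear value coders
#'
#' Flags units that are significant for value in the categorical ANOVA, not
#' significant for the value-by-type interaction, and not significant for value
#' in the linear-value model (the same run-length rule applied to each
#' criterion).
#'
#' @param profile An [encoding_profile()].
#' @return List: `flag` (logical per unit) and `proportion`.
#' @export
classify_nonlinear_value_units <- function(profile) {
  stopifnot(inherits(profile, "encoding_profile"))
  st <- profile$stats
  inter <- if (all(is.na(st$sig_interaction))) FALSE else st$sig_interaction
  flag <- st$sig_value & !inter & !st$sig_value_linear
  list(flag = flag, proportion = mean(flag))
}

#' Compare encoding between two regions
#'
#' Per-bin 2x2 chi-squared tests of encoding proportions (marked significant at
#' p <= 0.01; bins with an expected cell below 1 are skipped and flagged), an
#' overall chi-squared test on any-time encoding, and a Kruskal-Wallis test on
#' encoding latencies.
#'
#' @param profile_a,profile_b [encoding_profile()] objects for the two regions.
#' @param variable Variable to compare (default "value").
#' @param alpha Per-bin marking threshold (default 0.01).
#' @return List: `per_bin` (data.frame bin, chisq, p, significant, skipped),
#'   `overall` (chisq, p), `latency_kw` (stat, p).
#' @export
region_comparisons <- function(profile_a, profile_b, variable = "value",
                               alpha = 0.01) {
  ma <- profile_a$mask[[variable]]
  mb <- profile_b$mask[[variable]]
  stopifnot(ncol(ma) == ncol(mb))
  na <- nrow(ma); nb <- nrow(mb)
  per_bin <- do.call(rbind, lapply(seq_len(ncol(ma)), function(b) {
    ka <- sum(ma[, b]); kb <- sum(mb[, b])
    tab <- rbind(c(ka, na - ka), c(kb, nb - kb))
    exp_min <- min(outer(rowSums(tab), colSums(tab)) / sum(tab))
    if (exp_min < 1 || any(colSums(tab) == 0))
      return(data.frame(bin = b, chisq = NA_real_, p = NA_real_,
                        significant = FALSE, skipped = TRUE))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(bin = b, chisq = unname(ct$statistic), p = ct$p.value,
               significant = ct$p.value <= alpha, skipped = FALSE)
  }))
  any_a <- apply(ma, 1, any); any_b <- apply(mb, 1, any)
  tab <- rbind(c(sum(any_a), na - sum(any_a)), c(sum(any_b), nb - sum(any_b)))
  overall <- if (all(colSums(tab) > 0)) {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(chisq = unname(ct$statistic), p = ct$p.value)
  } else list(chisq = 0, p = 1)
  la <- profile_a$stats$latency_value[any_a]
  lb <- profile_b$stats$latency_value[any_b]
  latency_kw <- if (length(la) && length(lb)) {
    kw <- stats::kruskal.test(list(la, lb))
    list(stat = unname(kw$statistic), p = kw$p.value)
  } else list(stat = NA_real_, p = NA_real_)
  list(per_bin = per_bin, overall = overall, latency_kw = latency_kw)
}
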