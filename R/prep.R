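#' Continuous firing-rate estimate from a spike train
#'
#' Gaussian-kernel rate estimate: the sum of unit-area Gaussians of SD
#' `kernel_sd` centred on each spike. The integral of the returned function
#' over the recording equals the spike count (up to boundary truncation).
#'
#' @param spikes Sorted numeric vector of spike times (s).
#' @param kernel_sd Kernel standard deviation (s); 0.1 is used for encoding and
#'   decoding analyses, 0.05 for the trajectory-speed and time-regression
#'   analyses.
#' @return A vectorised function `rate(t)` in Hz.
#' @export
#' @examples
#' r <- smooth_rates(c(1, 2, 2.5), kernel_sd = 0.1)
#' r(2) # peak contribution 1/(0.1 * sqrt(2*pi)) plus neighbours
smooth_rates <- function(spikes, kernel_sd = 0.1) {
  if (kernel_sd <= 0) stop("kernel_sd must be positive", call. = FALSE)
  spikes <- as.numeric(spikes)
  function(t) {
    vapply(t, function(ti) sum(stats::dnorm(ti, mean = spikes, sd = kernel_sd)),
           numeric(1))
  }
}

#' Number of sliding bins covering an interval
#'
#' Bins of width `bin_width` start every `step` seconds at offsets
#' `0, step, ..., L - step`, so an interval of length `L` holds
#' `floor(L / step)` bins (40 bins per second of activity with 100 ms bins
#' every 25 ms, 20 with 50 ms steps, 1 bin for 0.1 s at 100 ms steps). The
#' last bins extend up to `bin_width - step` beyond the interval end, which is
#' well defined because rates are estimated by smoothing the whole recording
#' before epoching.
#'
#' @param L Interval length (s).
#' @param bin_width Bin width (s, unused by the count; kept for the geometry).
#' @param step Bin step (s).
#' @return Integer bin count.
#' @export
bin_count <- function(L, bin_width = 0.1, step = 0.025) {
  as.integer(floor(L / step + 1e-9))
}

#' Default analysis epochs
#'
#' Three concatenated epochs centred on the reward-predicting cue onset, the
#' response-instruction cue and reward delivery. With the default task timing
#' the windows abut without overlap: cue `[-0.5, 1.3]` s around cue onset,
#' response `[-0.8, 0.45]` s around the response cue, reward `[-0.45, 0.5]` s
#' around reward.
#'
#' @param task A [task_config()].
#' @return data.frame with columns epoch, ref (event column name), ref_time,
#'   start, end (relative to the reference event).
#' @export
default_epochs <- function(task = task_config()) {
  data.frame(epoch = c("cue", "response", "reward"),
             ref = c("t_cue_on", "t_resp_cue", "t_reward"),
             ref_time = c(task$cue_on, task$response_cue, task$reward),
             start = c(-0.5, -0.8, -0.45),
             end = c(1.3, 0.45, 0.5))
}

#' Bin grid over the analysis epochs
#'
#' @param task A [task_config()].
#' @param bin_width Bin width (s), default 0.1.
#' @param step Bin step (s): 0.025 for encoding analyses, 0.05 for decoding;
#'   `step = bin_width` gives non-overlapping bins (the coarse search grid).
#' @param epochs Epoch table as from [default_epochs()].
#' @return data.frame with one row per bin: epoch, t_rel (bin centre relative
#'   to the epoch's reference event), t_abs (bin centre relative to cue onset),
#'   abs_start, abs_end, width.
#' @export
bin_grid <- function(task = task_config(), bin_width = 0.1, step = 0.025,
                     epochs = default_epochs(task)) {
  rows <- lapply(seq_len(nrow(epochs)), function(i) {
    L <- epochs$end[i] - epochs$start[i]
    n <- bin_count(L, bin_width, step)
    if (n == 0L) return(NULL)
    rel_start <- epochs$start[i] + step * (seq_len(n) - 1) # may overhang `end`
    data.frame(epoch = epochs$epoch[i],
               t_rel = rel_start + bin_width / 2,
               t_abs = epochs$ref_time[i] + rel_start + bin_width / 2,
               abs_start = epochs$ref_time[i] + rel_start,
               abs_end = epochs$ref_time[i] + rel_start + bin_width,
               width = bin_width)
  })
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  grid
}

#' Indices of bins whose centres fall in a time window
#'
#' @param bins A bin grid from [bin_grid()].
#' @param window `c(lo, hi)` in seconds relative to cue onset; e.g.
#'   `c(task$cue_off, task$reward)` for the delay, `c(0, task$reward)` for the
#'   cue-to-reward window.
#' @return Integer vector of bin indices.
#' @export
bins_in_window <- function(bins, window) {
  which(bins$t_abs >= window[1] & bins$t_abs <= window[2])
}

#' Smooth, epoch and bin a session into a rate tensor
#'
#' The smoothed rate (Gaussian kernel over the whole trial's spike train) is
#' averaged within each bin of the grid; analytically, a spike at `s`
#' contributes `(pnorm(hi, s, sd) - pnorm(lo, s, sd)) / width` Hz to bin
#' `[lo, hi)`. Because smoothing runs over the whole recording before
#' epoching, bins just before an event can carry post-event information (a
#' property of the method, not removed). Trials with a missing event time are
#' dropped with a warning.
#'
#' @param session A `synth_session` (or data read by [read_session()]).
#' @param bin_width,step Bin geometry (s); see [bin_grid()].
#' @param kernel_sd Gaussian kernel SD (s).
#' @param epochs Epoch table; default [default_epochs()].
#' @return An object of class `rate_matrix`: 3-d array `[trial, unit, bin]` of
#'   rates (Hz) with attributes `bins` (the grid), `labels` (data.frame value,
#'   type per trial), `task`, `unit_ids`.
#' @export
epoch_and_bin <- function(session, bin_width = 0.1, step = 0.025,
                          kernel_sd = 0.1, epochs = default_epochs(session$task)) {
  stopifnot(inherits(session, "synth_session"))
  trials <- session$trials
  ev_cols <- unique(epochs$ref)
  ok <- stats::complete.cases(trials[, ev_cols, drop = FALSE])
  if (!all(ok)) {
    warning(sum(!ok), " trial(s) dropped: missing event time")
    trials <- trials[ok, , drop = FALSE]
  }
  # event times are required to be identical across trials (no jitter);
  # per-trial alignment would need a per-trial grid
  for (cc in ev_cols)
    if (length(unique(trials[[cc]])) != 1L)
      stop("per-trial event jitter is not supported by the shared bin grid",
           call. = FALSE)

  grid <- bin_grid(session$task, bin_width, step, epochs)
  n_bins <- nrow(grid)
  n_trials <- nrow(trials)
  n_units <- length(session$spikes)
  trial_rows <- match(trials$trial_id, session$trials$trial_id)

  X <- array(0, dim = c(n_trials, n_units, n_bins))
  half_supp <- 5 * kernel_sd
  for (u in seq_len(n_units)) {
    ul <- session$spikes[[u]][trial_rows]
    ns <- lengths(ul)
    if (sum(ns) == 0) next
    sp <- unlist(ul, use.names = FALSE)
    tid <- rep.int(seq_len(n_trials), ns)
    o <- order(sp)
    sp <- sp[o]; tid <- tid[o]
    for (b in seq_len(n_bins)) {
      lo <- grid$abs_start[b]; hi <- grid$abs_end[b]
      i1 <- findInterval(lo - half_supp, sp) + 1L
      i2 <- findInterval(hi + half_supp, sp)
      if (i2 < i1) next
      s <- sp[i1:i2]
      w <- stats::pnorm(hi, s, kernel_sd) - stats::pnorm(lo, s, kernel_sd)
      acc <- rowsum(w, tid[i1:i2])
      X[as.integer(rownames(acc)), u, b] <- acc / grid$width[b]
    }
  }
  ids <- if (!is.null(session$ground_truth)) names(session$ground_truth)
         else as.character(seq_len(n_units))
  structure(X, class = "rate_matrix",
            bins = grid,
            labels = data.frame(value = trials$value, type = trials$type),
            task = session$task, unit_ids = ids,
            kernel_sd = kernel_sd)
}

#' @export
print.rate_matrix <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("Rate tensor: %d trials x %d units x %d bins\n", d[1], d[2], d[3]))
  invisible(x)
}

#' Exclude units with low session-wide firing rate
#'
#' Units whose mean rate across the session (total spikes / total recorded
#' time) is strictly lower than `threshold` are removed; a unit at exactly the
#' threshold is retained.
#'
#' @param session A `synth_session`.
#' @param threshold Minimum mean rate (Hz), default 1.
#' @return The filtered session, with attributes `excluded` (unit ids removed)
#'   and `mean_rates` (named vector for all input units).
#' @export
filter_low_rate <- function(session, threshold = 1) {
  stopifnot(inherits(session, "synth_session"))
  tot_time <- nrow(session$trials) * diff(session$span)
  counts <- vapply(session$spikes, function(ul)
    sum(lengths(ul)), numeric(1))
  mean_rates <- counts / tot_time
  ids <- names(session$ground_truth)
  names(mean_rates) <- ids
  keep <- mean_rates >= threshold
  if (!any(keep))
    stop("all units fall below the ", threshold, " Hz exclusion threshold",
         call. = FALSE)
  out <- session
  out$spikes <- session$spikes[keep]
  out$ground_truth <- session$ground_truth[keep]
  if (!is.null(session$units)) out$units <- session$units[keep]
  attr(out, "excluded") <- ids[!keep]
  attr(out, "mean_rates") <- mean_rates
  out
}

#' Assemble pseudo-population datasets from binned sessions
#'
#' Units recorded in different sessions are combined as if simultaneous:
#' for every (value, type) condition, `trials_per_condition` trials are sampled
#' without replacement for each unit and stacked as pseudo-trials. The draw is
#' repeated `n_datasets` times (all population results downstream are reported
#' as the mean over datasets). By default trials are drawn and order-randomised
#' per unit, which removes within-session noise correlations; set
#' `per_unit = FALSE` to keep units of a session trial-aligned.
#'
#' @param rate_mats A `rate_matrix` or list of them (one per session), on the
#'   same bin grid.
#' @param n_datasets Number of independent draws (default 5).
#' @param trials_per_condition Trials drawn per condition per unit; defaults to
#'   the smallest condition count across sessions.
#' @param seed Integer seed for the draw sequence.
#' @param per_unit Randomise trial alignment per unit (default TRUE).
#' @return A list of `pseudopop` objects: each has `X` (array pseudo-trial x
#'   unit x bin), `labels`, `bins`, `task`, `unit_ids`, `dataset`, `seed`.
#' @export
build_pseudopopulation <- function(rate_mats, n_datasets = 5,
                                   trials_per_condition = NULL, seed = 1L,
                                   per_unit = TRUE) {
  if (inherits(rate_mats, "rate_matrix")) rate_mats <- list(rate_mats)
  bins <- attr(rate_mats[[1]], "bins")
  task <- attr(rate_mats[[1]], "task")
  for (rm in rate_mats)
    if (!isTRUE(all.equal(attr(rm, "bins")$t_abs, bins$t_abs)))
      stop("sessions must share the same bin grid", call. = FALSE)

  conds <- expand.grid(value = seq_len(task$n_values),
                       type = seq_len(task$n_types))
  avail <- sapply(rate_mats, function(rm) {
    lab <- attr(rm, "labels")
    apply(conds, 1, function(cd)
      sum(lab$value == cd["value"] & lab$type == cd["type"]))
  })
  avail <- matrix(avail, nrow = nrow(conds))
  if (is.null(trials_per_condition)) trials_per_condition <- min(avail)
  short <- which(avail < trials_per_condition, arr.ind = TRUE)
  if (nrow(short) > 0)
    stop(sprintf(
      "session %d has only %d trials for condition value=%d type=%d (need %d)",
      short[1, 2], avail[short[1, 1], short[1, 2]],
      conds$value[short[1, 1]], conds$type[short[1, 1]], trials_per_condition),
      call. = FALSE)

  m <- trials_per_condition
  n_units_tot <- sum(vapply(rate_mats, function(rm) dim(rm)[2], numeric(1)))
  n_bins <- nrow(bins)
  labels <- data.frame(
    value = rep(conds$value, each = m),
    type = rep(conds$type, each = m))
  unit_ids <- unlist(lapply(rate_mats, function(rm) attr(rm, "unit_ids")))

  lapply(seq_len(n_datasets), function(d) {
    rng <- .local_seed(.sub_seed(seed, d))
    on.exit(rng())
    X <- array(NA_real_, dim = c(nrow(labels), n_units_tot, n_bins))
    u0 <- 0L
    for (s in seq_along(rate_mats)) {
      rm <- rate_mats[[s]]
      lab <- attr(rm, "labels")
      nu <- dim(rm)[2]
      for (ci in seq_len(nrow(conds))) {
        rows_out <- (ci - 1L) * m + seq_len(m)
        idx_pool <- which(lab$value == conds$value[ci] &
                          lab$type == conds$type[ci])
        if (per_unit) {
          for (u in seq_len(nu)) {
            draw <- sample(idx_pool, m)
            X[rows_out, u0 + u, ] <- rm[draw, u, ]
          }
        } else {
          draw <- sample(idx_pool, m)
          X[rows_out, u0 + seq_len(nu), ] <- rm[draw, , , drop = FALSE]
        }
      }
      u0 <- u0 + nu
    }
    structure(list(X = X, labels = labels, bins = bins, task = task,
                   unit_ids = unit_ids, dataset = d,
                   seed = .sub_seed(seed, d)),
              class = "pseudopop")
  })
}

#' @export
print.pseudopop <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf("Pseudo-population dataset %d: %d pseudo-trials x %d units x %d bins\n",
              x$dataset, d[1], d[2], d[3]))
  invisible(x)
}

#' Restrict a pseudo-population to a subset of units and/or bins
#'
#' @param pop A `pseudopop`.
#' @param units Integer indices of units to keep (default all).
#' @param bins Integer indices of bins to keep (default all).
#' @return A `pseudopop` on the subset.
#' @export
subset_pop <- function(pop, units = NULL, bins = NULL) {
  stopifnot(inherits(pop, "pseudopop"))
  if (is.null(units)) units <- seq_len(dim(pop$X)[2])
  if (is.null(bins)) bins <- seq_len(dim(pop$X)[3])
  pop$X <- pop$X[, units, bins, drop = FALSE]
  pop$unit_ids <- pop$unit_ids[units]
  pop$bins <- pop$bins[bins, , drop = FALSE]
  pop
}
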