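#' Generate a synthetic recording session
#'
#' Draws spike trains for every unit on every trial as an inhomogeneous Poisson
#' process (thinning of a homogeneous process at the unit's rate bound). The
#' trial table is balanced: `task$trials_per_condition` trials for each
#' (value, type) condition, in randomised order. Spikes cover the window
#' `[-pre_window - margin, reward + post_window + margin]` so that kernel
#' smoothing at the analysis stage loses no spike mass at the epoch edges.
#'
#' @param specs List of [unit_spec()] objects.
#' @param task A [task_config()].
#' @param seed Integer seed; fully determines the session.
#' @param margin Extra spike-generation margin beyond the recording window (s).
#'
#' @return An object of class `synth_session`: list with `units` (specs),
#'   `trials` (data.frame: trial_id, value, type and the four event times),
#'   `spikes` (`spikes[[unit]][[trial]]`, spike times in s relative to cue
#'   onset), `ground_truth` (named character vector unit_id -> coding_class),
#'   `task`, `span` (spike-generation window) and `seed`.
#' @export
#' @examples
#' task <- task_config(trials_per_condition = 2)
#' s <- generate_session(sample_population(c(untuned = 3), task), task, seed = 1)
#' nrow(s$trials) # 2 trials x 4 values x 2 types
generate_session <- function(specs, task = task_config(), seed = 1L,
                             margin = 0.3) {
  if (length(specs) < 1) stop("need at least one unit spec", call. = FALSE)
  stopifnot(inherits(task, "task_config"))
  rng <- .local_seed(seed)
  on.exit(rng())

  conds <- expand.grid(value = seq_len(task$n_values),
                       type = seq_len(task$n_types))
  trials <- conds[rep(seq_len(nrow(conds)), each = task$trials_per_condition), ]
  trials <- trials[sample.int(nrow(trials)), , drop = FALSE]
  trials <- data.frame(trial_id = seq_len(nrow(trials)),
                       value = trials$value, type = trials$type,
                       t_cue_on = task$cue_on, t_cue_off = task$cue_off,
                       t_resp_cue = task$response_cue, t_reward = task$reward)

  span <- c(task$cue_on - task$pre_window - margin,
            task$reward + task$post_window + margin)
  span_len <- diff(span)

  n_units <- length(specs)
  spikes <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    sp <- specs[[u]]
    # one rate function per condition, reused across that condition's trials
    rfs <- vector("list", nrow(conds))
    for (ci in seq_len(nrow(conds)))
      rfs[[ci]] <- build_rate_function(sp, task, conds$value[ci], conds$type[ci])
    cond_of <- match(paste(trials$value, trials$type),
                     paste(conds$value, conds$type))
    ul <- vector("list", nrow(trials))
    for (tr in seq_len(nrow(trials))) {
      rf <- rfs[[cond_of[tr]]]
      rmax <- attr(rf, "rate_max")
      if (rmax <= 0) { ul[[tr]] <- numeric(0); next }
      n <- stats::rpois(1, rmax * span_len)
      if (n == 0) { ul[[tr]] <- numeric(0); next }
      cand <- sort(stats::runif(n, span[1], span[2]))
      keep <- stats::runif(n) < rf(cand) / rmax
      ul[[tr]] <- cand[keep]
    }
    spikes[[u]] <- ul
  }
  ids <- vapply(specs, function(s) as.character(s$unit_id), character(1))
  gt <- stats::setNames(vapply(specs, function(s) s$coding_class, character(1)),
                        ids)
  structure(list(units = specs, trials = trials, spikes = spikes,
                 ground_truth = gt, task = task, span = span, seed = seed),
            class = "synth_session")
}

#' @export
print.synth_session <- function(x, ...) {
  cat(sprintf("Synthetic session: %d units, %d trials (seed %d)\n",
              length(x$units), nrow(x$trials), x$seed))
  print(table(coding_class = x$ground_truth))
  invisible(x)
}

#' Write a session to a directory of plain-text files
#'
#' Layout: `spikes.csv` (unit_id, trial_id, spike_time_s), `trials.csv`
#' (trial_id, value, type, t_cue_on, t_cue_off, t_resp_cue, t_reward) and
#' `ground_truth.json`.
#'
#' @param session A `synth_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "synth_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(session$ground_truth)
  sp <- do.call(rbind, lapply(seq_along(session$spikes), function(u) {
    tr_list <- session$spikes[[u]]
    n <- lengths(tr_list)
    data.frame(unit_id = ids[u],
               trial_id = rep(session$trials$trial_id, n),
               spike_time_s = unlist(tr_list, use.names = FALSE))
  }))
  utils::write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(session$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  meta <- list(ground_truth = as.list(session$ground_truth),
               span = session$span, seed = session$seed,
               task = unclass(session$task))
  jsonlite::write_json(meta, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session from the plain-text layout written by [write_session()]
#'
#' Also reads externally produced data in the same layout: only `spikes.csv`
#' and `trials.csv` are required; `ground_truth.json` is optional (real
#' recordings have no planted labels).
#'
#' @param dir Directory containing the files.
#' @param task A [task_config()] used when `ground_truth.json` is absent.
#' @return A `synth_session` (with `units = NULL` and empty ground truth when
#'   not available).
#' @export
read_session <- function(dir, task = task_config()) {
  trials <- utils::read.csv(file.path(dir, "trials.csv"))
  sp <- utils::read.csv(file.path(dir, "spikes.csv"))
  gt <- character(0); span <- NULL; seed <- NA_integer_
  meta_path <- file.path(dir, "ground_truth.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    gt <- unlist(meta$ground_truth)
    span <- meta$span
    seed <- meta$seed
    tk <- meta$task
    task <- task_config(tk$cue_off, tk$response_cue, tk$reward, tk$pre_window,
                        tk$post_window, tk$n_values, tk$n_types,
                        tk$trials_per_condition)
  }
  ids <- unique(sp$unit_id)
  if (length(gt)) ids <- names(gt) # preserve generation order
  if (is.null(span))
    span <- c(min(trials$t_cue_on) - task$pre_window,
              max(trials$t_reward) + task$post_window)
  spikes <- lapply(ids, function(id) {
    su <- sp[sp$unit_id == id, ]
    lapply(trials$trial_id, function(tr)
      sort(su$spike_time_s[su$trial_id == tr]))
  })
  structure(list(units = NULL, trials = trials, spikes = spikes,
                 ground_truth = if (length(gt)) gt else
                   stats::setNames(rep(NA_character_, length(ids)),
                                   as.character(ids)),
                 task = task, span = span, seed = seed),
            class = "synth_session")
}
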