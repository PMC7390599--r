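#' Task configuration
#'
#' Temporal structure of a single trial of the cued-value task. All times are
#' in seconds relative to the onset of the reward-predicting cue (`cue_on` is
#' therefore always 0). A trial presents a value cue (one of `n_values` levels,
#' crossed with `n_types` reward types), followed by a delay that is
#' interrupted by a response-instruction cue, and ends with reward delivery.
#' With the defaults the cue-to-reward interval is 3 s and the post-cue-offset
#' delay is 2.4 s.
#'
#' @param cue_off Cue offset time (s).
#' @param response_cue Response-instruction cue time (s).
#' @param reward Reward delivery time (s).
#' @param pre_window Recording window before cue onset (s).
#' @param post_window Recording window after reward (s).
#' @param n_values Number of value levels (categorical, 1..n_values).
#' @param n_types Number of reward types (1 = juice, 2 = bar).
#' @param trials_per_condition Trials generated per (value, type) condition.
#'
#' @return An object of class `task_config`.
#' @export
#' @examples
#' task <- task_config()
#' task$reward - task$cue_off # delay length, 2.4 s
task_config <- function(cue_off = 0.6, response_cue = 2.1, reward = 3.0,
                        pre_window = 0.5, post_window = 0.5,
                        n_values = 4L, n_types = 2L,
                        trials_per_condition = 40L) {
  cue_on <- 0
  if (!(cue_on < cue_off && cue_off < response_cue && response_cue < reward))
    stop("event times must satisfy cue_on < cue_off < response_cue < reward",
         call. = FALSE)
  if (pre_window <= 0 || post_window <= 0)
    stop("pre_window and post_window must be positive", call. = FALSE)
  if (n_values < 2L || n_types < 1L || trials_per_condition < 1L)
    stop("invalid condition structure", call. = FALSE)
  structure(list(
    cue_on = cue_on, cue_off = cue_off, response_cue = response_cue,
    reward = reward, pre_window = pre_window, post_window = post_window,
    n_values = as.integer(n_values), n_types = as.integer(n_types),
    trials_per_condition = as.integer(trials_per_condition)
  ), class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("Task configuration (times in s, cue onset = 0)\n")
  cat(sprintf("  cue: 0 -> %.2f | response cue: %.2f | reward: %.2f\n",
              x$cue_off, x$response_cue, x$reward))
  cat(sprintf("  delay (cue offset -> reward): %.2f s\n", x$reward - x$cue_off))
  cat(sprintf("  %d values x %d types, %d trials/condition\n",
              x$n_values, x$n_types, x$trials_per_condition))
  invisible(x)
}

.coding_classes <- c("stable_linear", "stable_nonmonotonic", "sequential",
                     "reversing", "type_coder", "time_ramp", "untuned")

#' Specification of a simulated unit
#'
#' Describes one unit's tuning for the spike-train simulator. The
#' `coding_class` selects one of the planted coding regimes:
#' \describe{
#'   \item{stable_linear}{firing adds `value_gain * (value - mean value)` from
#'     cue onset to reward (a time-invariant monotonic value code).}
#'   \item{stable_nonmonotonic}{adds a per-value rate offset (`value_gain` must
#'     be a vector of length `n_values`, e.g. a peak at value 3) from cue onset
#'     to reward.}
#'   \item{sequential}{a Gaussian bump in time at `bump_center` (SD `bump_sd`)
#'     whose amplitude is `value_gain * value` (a transient value code).}
#'   \item{reversing}{like stable_linear, but the sign of the value slope flips
#'     at `reversal_time`.}
#'   \item{type_coder}{adds `value_gain` for type 2 and subtracts it for type 1,
#'     from cue onset to reward; ignores value.}
#'   \item{time_ramp}{a linear ramp from 0 to `value_gain` Hz between cue onset
#'     and reward; ignores value and type.}
#'   \item{untuned}{constant `baseline_rate`.}
#' }
#'
#' @param unit_id Unit identifier (integer or character).
#' @param coding_class One of the classes listed above.
#' @param baseline_rate Baseline firing rate (Hz, >= 0).
#' @param value_gain Tuning gain in Hz (see class descriptions); a length-4
#'   vector of per-value offsets for `stable_nonmonotonic`.
#' @param bump_center,bump_sd Gaussian bump centre and SD (s); sequential only.
#' @param reversal_time Time at which the value slope reverses (s); reversing
#'   only.
#'
#' @return An object of class `unit_spec`.
#' @export
unit_spec <- function(unit_id, coding_class, baseline_rate = 5,
                      value_gain = 2, bump_center = NA_real_,
                      bump_sd = NA_real_, reversal_time = NA_real_) {
  coding_class <- match.arg(coding_class, .coding_classes)
  if (baseline_rate < 0) stop("baseline_rate must be >= 0", call. = FALSE)
  if (coding_class == "sequential") {
    if (is.na(bump_center) || is.na(bump_sd) || bump_sd <= 0)
      stop("sequential units need bump_center and bump_sd > 0", call. = FALSE)
  }
  if (coding_class == "reversing" && is.na(reversal_time))
    stop("reversing units need a reversal_time", call. = FALSE)
  structure(list(
    unit_id = unit_id, coding_class = coding_class,
    baseline_rate = baseline_rate, value_gain = value_gain,
    bump_center = bump_center, bump_sd = bump_sd,
    reversal_time = reversal_time
  ), class = "unit_spec")
}

#' Draw a population of unit specifications
#'
#' Builds a list of [unit_spec()] objects from a composition (counts per coding
#' class). Sequential units' bump centres tile the cue-to-reward interval in
#' increasing order so that, as a population, their transients span the delay;
#' reversal times are drawn uniformly inside the delay (cue offset to reward).
#' Tuning parameters are drawn uniformly from `param_ranges`.
#'
#' @param composition Named integer vector or list, e.g.
#'   `c(stable_linear = 30, sequential = 40, untuned = 50)`.
#' @param task A [task_config()].
#' @param param_ranges Named list of `c(lo, hi)` ranges overriding the
#'   defaults for `baseline_rate`, `value_gain`, `bump_sd`, `type_gain`,
#'   `ramp_gain`, `nonmono_gain`.
#' @param seed Integer seed; fully determines the draw.
#'
#' @return A list of `unit_spec` objects.
#' @export
#' @examples
#' specs <- sample_population(c(sequential = 10), task_config(), seed = 1)
#' length(specs)
sample_population <- function(composition, task = task_config(),
                              param_ranges = list(), seed = 1L) {
  composition <- unlist(composition)
  if (length(composition) == 0 || sum(composition) == 0)
    stop("composition is empty", call. = FALSE)
  if (any(composition < 0)) stop("composition counts must be >= 0", call. = FALSE)
  bad <- setdiff(names(composition), .coding_classes)
  if (length(bad)) stop("unknown coding class: ", paste(bad, collapse = ", "),
                        call. = FALSE)

  rng <- .local_seed(seed)
  on.exit(rng())

  # gains calibrated so the simulated sensitivity index matches real
  # prefrontal value coding (population-mean d' of roughly 0.25, strongly
  # tuned units near 0.6); transient sequential responses are larger than the
  # sustained value offsets
  defaults <- list(baseline_rate = c(3, 8), value_gain = c(0.35, 0.6),
                   seq_gain = c(1, 2), bump_sd = c(0.10, 0.25),
                   type_gain = c(0.5, 1), ramp_gain = c(2, 4),
                   nonmono_gain = c(2, 4))
  rg <- utils::modifyList(defaults, param_ranges)
  runifr <- function(n, r) stats::runif(n, r[1], r[2])

  specs <- list()
  uid <- 0L
  for (cls in names(composition)) {
    n <- as.integer(composition[[cls]])
    if (n == 0L) next
    base <- runifr(n, rg$baseline_rate)
    extra <- switch(cls,
      sequential = {
        # centres tile cue onset -> reward, strictly increasing
        centers <- seq(task$cue_on + 0.1, task$reward - 0.1, length.out = n)
        list(center = centers, sd = runifr(n, rg$bump_sd),
             gain = runifr(n, rg$seq_gain))
      },
      reversing = list(rev = stats::runif(n, task$cue_off + 0.2,
                                          task$reward - 0.2),
                       gain = runifr(n, rg$value_gain)),
      stable_linear = list(gain = runifr(n, rg$value_gain)),
      stable_nonmonotonic = list(pref = sample.int(task$n_values, n, TRUE),
                                 gain = runifr(n, rg$nonmono_gain)),
      type_coder = list(gain = runifr(n, rg$type_gain)),
      time_ramp = list(gain = runifr(n, rg$ramp_gain)),
      untuned = list()
    )
    for (i in seq_len(n)) {
      uid <- uid + 1L
      specs[[uid]] <- switch(cls,
        stable_linear = unit_spec(uid, cls, base[i], extra$gain[i]),
        stable_nonmonotonic = {
          off <- numeric(task$n_values)
          off[extra$pref[i]] <- extra$gain[i]
          unit_spec(uid, cls, base[i], off)
        },
        sequential = unit_spec(uid, cls, base[i], extra$gain[i],
                               bump_center = extra$center[i],
                               bump_sd = extra$sd[i]),
        reversing = unit_spec(uid, cls, base[i], extra$gain[i],
                              reversal_time = extra$rev[i]),
        type_coder = unit_spec(uid, cls, base[i], extra$gain[i]),
        time_ramp = unit_spec(uid, cls, base[i], extra$gain[i]),
        untuned = unit_spec(uid, cls, base[i], 0)
      )
    }
  }
  specs
}

# Set the RNG to a given seed and return a restorer function.
.local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

# Derived sub-seed, kept within 32-bit integer range.
.sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}
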