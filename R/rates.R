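#' Deterministic firing-rate function of a simulated unit
#'
#' Builds the trial-time rate curve (Hz) of a unit for a given condition. The
#' returned function is vectorised over time and clipped at zero; its maximum
#' over the trial is attached as attribute `"rate_max"` (used as the thinning
#' bound by the Poisson simulator).
#'
#' @param spec A [unit_spec()].
#' @param task A [task_config()].
#' @param value Value level, integer in `1..task$n_values`.
#' @param type Reward type, integer in `1..task$n_types`.
#'
#' @return A function `rate(t)` (Hz), with attribute `rate_max`.
#' @export
#' @examples
#' task <- task_config()
#' r <- build_rate_function(unit_spec(1, "untuned", 5), task, 1, 1)
#' r(c(0, 1, 2)) # constant 5 Hz
build_rate_function <- function(spec, task, value, type) {
  stopifnot(inherits(spec, "unit_spec"), inherits(task, "task_config"))
  if (!(value %in% seq_len(task$n_values)) || !(type %in% seq_len(task$n_types)))
    stop("invalid value or type", call. = FALSE)
  b <- spec$baseline_rate
  vc <- value - (task$n_values + 1) / 2 # centred value
  on <- task$cue_on; off <- task$reward

  f <- switch(spec$coding_class,
    untuned = function(t) rep(b, length(t)),
    stable_linear = {
      d <- spec$value_gain * vc
      function(t) b + d * (t >= on & t <= off)
    },
    stable_nonmonotonic = {
      if (length(spec$value_gain) != task$n_values)
        stop("stable_nonmonotonic needs a per-value gain vector", call. = FALSE)
      d <- spec$value_gain[value]
      function(t) b + d * (t >= on & t <= off)
    },
    sequential = {
      amp <- spec$value_gain * value
      mu <- spec$bump_center; sd <- spec$bump_sd
      function(t) b + amp * exp(-(t - mu)^2 / (2 * sd^2))
    },
    reversing = {
      d <- spec$value_gain * vc; tr <- spec$reversal_time
      function(t) {
        s <- ifelse(t < tr, d, -d)
        b + s * (t >= on & t <= off)
      }
    },
    type_coder = {
      d <- spec$value_gain * (if (type == 2) 1 else -1)
      function(t) b + d * (t >= on & t <= off)
    },
    time_ramp = {
      ramp_gain <- spec$value_gain
      function(t) b + ramp_gain * pmin(pmax((t - on) / (off - on), 0), 1)
    },
    stop("unknown coding class: ", spec$coding_class, call. = FALSE)
  )
  g <- function(t) pmax(f(t), 0)
  # conservative analytic bound on the rate
  rmax <- switch(spec$coding_class,
    untuned = b,
    stable_linear = b + abs(spec$value_gain * vc),
    stable_nonmonotonic = b + max(abs(spec$value_gain)),
    sequential = b + abs(spec$value_gain) * task$n_values,
    reversing = b + abs(spec$value_gain * vc),
    type_coder = b + abs(spec$value_gain),
    time_ramp = b + max(spec$value_gain, 0)
  )
  attr(g, "rate_max") <- max(rmax, 0)
  g
}
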