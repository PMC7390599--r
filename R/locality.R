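# Temporal-locality measure: Gaussian fits to accuracy-versus-testing-time
# curves. f(t2) = a * exp(-(t2 - t1)^2 / (2 sigma^2)) + b with b fixed at
# chance and mu fixed at the training time; only a and sigma are free.

#' Fit the locality Gaussian to one accuracy row
#'
#' Nonlinear least squares with the amplitude profiled out: for a given sigma
#' the optimal `a` is closed-form, leaving a 1-D bounded minimisation over
#' sigma (Brent). The offset `b` is fixed to chance (0.25 for four classes)
#' and the mean to the training time `t1`.
#'
#' @param acc Accuracy at each testing time (one training bin's row).
#' @param t_test Testing-bin centres (s).
#' @param t1 Training-bin centre (s).
#' @param chance Fixed offset b (default 0.25).
#' @param sigma_bounds `c(lo, hi)` bounds for sigma (s); default half a bin
#'   step to the span of the testing window.
#' @return List: `a`, `sigma`, `fitted`, `sse`, `converged`.
#' @export
fit_locality_gaussian <- function(acc, t_test, t1, chance = 0.25,
                                  sigma_bounds = NULL) {
  stopifnot(length(acc) == length(t_test), length(acc) >= 3)
  if (is.null(sigma_bounds)) {
    step <- stats::median(diff(sort(t_test)))
    sigma_bounds <- c(step / 2, diff(range(t_test)))
  }
  yc <- acc - chance
  g_of <- function(sigma) exp(-(t_test - t1)^2 / (2 * sigma^2))
  prof <- function(sigma) {
    g <- g_of(sigma)
    a <- sum(g * yc) / sum(g * g)
    sum((yc - a * g)^2)
  }
  opt <- try(stats::optimize(prof, lower = sigma_bounds[1],
                             upper = sigma_bounds[2], tol = 1e-6),
             silent = TRUE)
  if (inherits(opt, "try-error"))
    return(list(a = 0, sigma = NA_real_, fitted = rep(chance, length(acc)),
                sse = sum(yc^2), converged = FALSE))
  sigma <- opt$minimum
  g <- g_of(sigma)
  a <- sum(g * yc) / sum(g * g)
  list(a = a, sigma = sigma, fitted = chance + a * g, sse = opt$objective,
       converged = TRUE)
}

#' Temporal locality measure of a cross-temporal accuracy matrix
#'
#' For each training bin, a Gaussian (offset fixed at chance, mean fixed at
#' the training time) is fitted to the accuracy over all testing bins; the
#' bin's locality term is `(max(fitted) - chance) / sigma`, i.e. the fitted
#' height above chance divided by its temporal spread. The locality measure is
#' the mean over training bins. Narrow, tall diagonal ridges score high; flat
#' or broad profiles score near 0. Failed fits contribute 0 and are flagged.
#'
#' @param x A `ctd_result` or accuracy matrix (train bins x test bins).
#' @param t_train,t_test Bin centres (s); taken from `x` when it is a
#'   `ctd_result`.
#' @param chance Chance level (default 0.25).
#' @param sigma_bounds Bounds for the Gaussian SD (s); see
#'   [fit_locality_gaussian()].
#' @return Locality measure (scalar, >= 0) with attributes `per_bin` (terms)
#'   and `fits` (list of per-row fits).
#' @export
locality_score <- function(x, t_train = NULL, t_test = NULL, chance = 0.25,
                           sigma_bounds = NULL) {
  if (inherits(x, "ctd_result")) {
    t_train <- x$bins$t_abs[x$train_bins]
    t_test <- x$bins$t_abs[x$test_bins]
    x <- x$accuracy
  }
  stopifnot(is.matrix(x), nrow(x) == length(t_train),
            ncol(x) == length(t_test))
  fits <- vector("list", nrow(x))
  terms <- numeric(nrow(x))
  n_failed <- 0L
  for (i in seq_len(nrow(x))) {
    ft <- fit_locality_gaussian(x[i, ], t_test, t_train[i], chance,
                                sigma_bounds)
    fits[[i]] <- ft
    if (!ft$converged || !is.finite(ft$sigma)) {
      n_failed <- n_failed + 1L
      terms[i] <- 0
    } else {
      # with mu inside the window, max(fitted) - chance = max(a, 0)
      terms[i] <- max(ft$a, 0) / ft$sigma
    }
  }
  if (n_failed == nrow(x)) stop("all locality fits failed", call. = FALSE)
  structure(mean(terms), per_bin = terms, fits = fits, n_failed = n_failed)
}
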