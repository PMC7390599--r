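# Shared fixtures: small simulated sessions and pseudo-populations, built in
# code at test time.

tiny_task <- function(trials_per_condition = 8L)
  task_config(trials_per_condition = trials_per_condition)

# Small mixed population on the coarse search grid.
tiny_pops <- function(seed = 1, n_datasets = 2, trials_per_condition = 8,
                      draw = 6, composition = c(stable_linear = 5,
                                                sequential = 5, untuned = 5),
                      param_ranges = list(), bin_width = 0.2, step = 0.2) {
  task <- tiny_task(trials_per_condition)
  specs <- sample_population(composition, task, param_ranges, seed = seed)
  s <- generate_session(specs, task, seed = seed + 1)
  rmat <- epoch_and_bin(s, bin_width = bin_width, step = step)
  pops <- build_pseudopopulation(rmat, n_datasets = n_datasets,
                                 trials_per_condition = draw,
                                 seed = seed + 2)
  attr(pops, "session") <- s
  pops
}

quick_config <- function(...) {
  decoder_config(n_outer_folds = 2, n_inner_folds = 2,
                 lambda_grid = 10^seq(-1, 3, 1), ...)
}

# Rate tensor with planted condition effects and Gaussian noise (no spiking),
# for encoding statistics where an analytic ground truth is wanted.
gaussian_tensor <- function(n_per_cond = 10, n_units = 4, n_bins = 20,
                            effect = function(v, ty, u, b) 0,
                            sd = 1, seed = 1) {
  set.seed(seed)
  labels <- expand.grid(value = 1:4, type = 1:2)
  labels <- labels[rep(seq_len(nrow(labels)), each = n_per_cond), ]
  rownames(labels) <- NULL
  X <- array(stats::rnorm(nrow(labels) * n_units * n_bins, sd = sd),
             dim = c(nrow(labels), n_units, n_bins))
  for (i in seq_len(nrow(labels)))
    for (u in seq_len(n_units))
      for (b in seq_len(n_bins))
        X[i, u, b] <- X[i, u, b] + effect(labels$value[i], labels$type[i], u, b)
  list(X = X, labels = labels)
}
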