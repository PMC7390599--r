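# End-to-end orchestration: simulate -> prep -> encoding -> decoding ->
# subspace/ensembles -> dynamics, with CSV/JSON outputs and a markdown report.

#' Default pipeline configuration
#'
#' A small, fast demonstration configuration; override any element via
#' [run_pipeline()]'s `config` (a list or a YAML file with the same names).
#'
#' @return Named list of configuration defaults.
#' @export
pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "valuedyn-run",
    composition = list(stable_linear = 8, sequential = 10, untuned = 10),
    trials_per_condition = 12,
    draw_per_condition = 10,
    n_datasets = 5,
    n_perm = 0,
    encoding_step = 0.025,
    decoding_step = 0.05,
    coarse_width = 0.2,
    n_search_folds = 1,
    stages = c("simulate", "prep", "encoding", "decoding",
               "subspace_ensembles", "dynamics", "report")
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order on a simulated session (or data in the
#' session CSV layout), writing figure-ready CSV tables, JSON metadata and a
#' markdown summary to `out_dir`. Stages absent from `config$stages` are
#' skipped with a notice; a failing stage halts with a stage-tagged error,
#' leaving earlier outputs in place.
#'
#' @param config A list, or path to a YAML file, overriding
#'   [pipeline_defaults()]. Set `config$session_dir` to read an existing
#'   session instead of simulating.
#' @return Invisibly, a list with the stage results.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  res <- list()
  timings <- list()
  stage <- function(name, expr) {
    if (!(name %in% cfg$stages)) {
      message("stage '", name, "' skipped (not in config$stages)")
      return(NULL)
    }
    ts <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), ts, units = "secs"))
    out
  }

  task <- task_config(trials_per_condition = cfg$trials_per_condition)

  res$session <- stage("simulate", {
    if (!is.null(cfg$session_dir)) {
      read_session(cfg$session_dir)
    } else {
      specs <- sample_population(cfg$composition, task,
                                 seed = .sub_seed(cfg$seed, 1))
      s <- generate_session(specs, task, seed = .sub_seed(cfg$seed, 2))
      s <- filter_low_rate(s)
      utils::write.csv(data.frame(unit = names(s$ground_truth),
                                  coding_class = unname(s$ground_truth)),
                       file.path(cfg$out_dir, "units.csv"), row.names = FALSE)
      s
    }
  })
  if (is.null(res$session)) return(invisible(res))
  session <- res$session

  res$prep <- stage("prep", {
    rm_enc <- epoch_and_bin(session, step = cfg$encoding_step)
    rm_dec <- epoch_and_bin(session, step = cfg$decoding_step)
    rm_coarse <- epoch_and_bin(session, bin_width = cfg$coarse_width,
                               step = cfg$coarse_width)
    pops <- build_pseudopopulation(rm_coarse, n_datasets = cfg$n_datasets,
                                   trials_per_condition = cfg$draw_per_condition,
                                   seed = .sub_seed(cfg$seed, 3))
    list(rate_enc = rm_enc, rate_dec = rm_dec, rate_coarse = rm_coarse,
         pops = pops)
  })
  prep <- res$prep

  res$encoding <- stage("encoding", {
    prof <- encoding_profile(prep$rate_enc)
    utils::write.csv(prof$stats, file.path(cfg$out_dir, "encoding_stats.csv"),
                     row.names = FALSE)
    sh <- split_half_sequence_analysis(prep$rate_enc,
                                       seed = .sub_seed(cfg$seed, 4))
    nl <- classify_nonlinear_value_units(prof)
    list(profile = prof, split_half = sh, nonlinear = nl)
  })

  res$decoding <- stage("decoding", {
    cfgd <- decoder_config(n_perm = cfg$n_perm)
    ctd <- ctd_datasets(prep$pops, cfgd, n_perm = cfg$n_perm,
                        seed = .sub_seed(cfg$seed, 5))
    tb <- ctd$train_bins
    utils::write.csv(
      data.frame(t = prep$pops[[1]]$bins$t_abs[tb],
                 accuracy = diag(ctd$accuracy)),
      file.path(cfg$out_dir, "decoding_diagonal.csv"), row.names = FALSE)
    utils::write.csv(ctd$accuracy, file.path(cfg$out_dir, "ctd_accuracy.csv"),
                     row.names = FALSE)
    ctd
  })

  res$subspace_ensembles <- stage("subspace_ensembles", {
    stab <- extract_stable_code(prep$pops, decoder_config(),
                                seed = .sub_seed(cfg$seed, 6),
                                n_search_folds = cfg$n_search_folds,
                                n_perm = cfg$n_perm)
    dyn <- extract_dynamic_code(prep$pops, decoder_config(),
                                seed = .sub_seed(cfg$seed, 7),
                                n_search_folds = cfg$n_search_folds,
                                n_perm = 0)
    ov <- ensemble_overlap_test(stab$ensembles, dyn$ensembles,
                                n_units = dim(prep$pops[[1]]$X)[2])
    utils::write.csv(stab$accuracy,
                     file.path(cfg$out_dir, "stable_ctd_accuracy.csv"),
                     row.names = FALSE)
    utils::write.csv(dyn$accuracy,
                     file.path(cfg$out_dir, "dynamic_ctd_accuracy.csv"),
                     row.names = FALSE)
    utils::write.csv(ov, file.path(cfg$out_dir, "ensemble_overlap.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(stable = stab$ensembles, dynamic = dyn$ensembles),
      file.path(cfg$out_dir, "ensembles.json"))
    list(stable = stab, dynamic = dyn, overlap = ov)
  })

  res$dynamics <- stage("dynamics", {
    rm_fast <- epoch_and_bin(session, step = cfg$decoding_step,
                             kernel_sd = 0.05)
    sp <- trajectory_speed(rm_fast)
    tr <- regress_time(prep$pops[[1]])
    utils::write.csv(sp, file.path(cfg$out_dir, "trajectory_speed.csv"),
                     row.names = FALSE)
    utils::write.csv(tr$per_bin, file.path(cfg$out_dir, "time_regression.csv"),
                     row.names = FALSE)
    battery <- NULL
    if (!is.null(res$encoding) && !is.null(res$subspace_ensembles)) {
      st <- res$encoding$profile$stats
      contr <- list(
        subspace_weight = subspace_weights(prep$pops),
        stable_ac = .mean_contribution(res$subspace_ensembles$stable),
        dynamic_contribution = .mean_contribution(res$subspace_ensembles$dynamic))
      battery <- correlation_battery(st[, c("es", "duration", "S")], contr)
      utils::write.csv(battery,
                       file.path(cfg$out_dir, "correlation_battery.csv"),
                       row.names = FALSE)
    }
    list(speed = sp, time_regression = tr, battery = battery)
  })

  if ("report" %in% cfg$stages) {
    .write_report(cfg, res, file.path(cfg$out_dir, "report.md"))
    jsonlite::write_json(
      list(config = cfg[setdiff(names(cfg), "stages")],
           stages_run = intersect(cfg$stages, names(res)),
           timings_s = timings,
           r_version = as.character(getRversion()),
           finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      file.path(cfg$out_dir, "run_metadata.json"), auto_unbox = TRUE)
  }
  invisible(res)
}

# Mean transformed contribution per unit across a code extraction's traces.
.mean_contribution <- function(code) {
  tr <- unlist(lapply(code$per_dataset, `[[`, "traces"), recursive = FALSE)
  m <- vapply(tr, function(t) t$contribution, numeric(tr[[1]]$n_units))
  contribution_transform(rowMeans(m, na.rm = TRUE))
}

.write_report <- function(cfg, res, path) {
  ln <- c("# valuedyn pipeline report", "",
          sprintf("Seed %d; %d units; %d trials/condition.",
                  cfg$seed,
                  if (!is.null(res$session)) length(res$session$spikes) else NA,
                  cfg$trials_per_condition), "")
  if (!is.null(res$encoding)) {
    st <- res$encoding$profile$stats
    ln <- c(ln, "## Unit encoding",
            sprintf("- value-encoding units (any time): %.1f%%",
                    100 * mean(st$sig_value)),
            sprintf("- mean encoding strength (es): %.2f", mean(st$es)),
            sprintf("- mean stability measure (S): %.2f", mean(st$S)),
            sprintf("- mean d': %.2f", mean(st$dprime, na.rm = TRUE)),
            sprintf("- non-linear value coders: %.1f%%",
                    100 * res$encoding$nonlinear$proportion),
            sprintf("- split-half peak-bin Spearman R: %.2f",
                    res$encoding$split_half$R_peak), "")
  }
  if (!is.null(res$decoding))
    ln <- c(ln, "## Decoding",
            sprintf("- mean diagonal accuracy: %.3f",
                    mean(diag(res$decoding$accuracy))),
            sprintf("- stability score (raw CTD): %.3f",
                    mean(res$decoding$accuracy)), "")
  if (!is.null(res$subspace_ensembles)) {
    se <- res$subspace_ensembles
    ln <- c(ln, "## Stable and dynamic extraction",
            sprintf("- stable (subspace+ensemble) stability score: %.3f",
                    mean(se$stable$accuracy)),
            sprintf("- dynamic ensemble diagonal - off-diagonal gap: %.3f",
                    diag_offdiag_gap(se$dynamic)),
            sprintf("- overlap instances significant after FDR: %d / %d",
                    sum(se$overlap$significant), nrow(se$overlap)), "")
  }
  if (!is.null(res$dynamics))
    ln <- c(ln, "## Dynamics",
            sprintf("- peak trajectory speed at t = %.2f s",
                    res$dynamics$speed$t[which.max(res$dynamics$speed$speed)]),
            sprintf("- time-regression LOO R2: %.3f",
                    res$dynamics$time_regression$r2_loo), "")
  writeLines(ln, path)
}

#' Diagonal minus far-off-diagonal accuracy gap
#'
#' Mean diagonal accuracy minus mean accuracy at time-bin pairs more than
#' `min_dt` apart; large values indicate a temporally local (dynamic) code.
#'
#' @param x A `code_extraction`, `ctd_result` or `ctd_agg`.
#' @param min_dt Minimum |train - test| time difference (s), default 0.5.
#' @return The gap (scalar).
#' @export
diag_offdiag_gap <- function(x, min_dt = 0.5) {
  acc <- x$accuracy
  t1 <- x$bins$t_abs[x$train_bins]
  t2 <- x$bins$t_abs[x$test_bins]
  dt <- abs(outer(t1, t2, `-`))
  mean(acc[dt < 1e-9]) - mean(acc[dt > min_dt])
}
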