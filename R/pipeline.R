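# End-to-end orchestration: generate -> extract -> detect -> summarise ->
# compare -> report, from a single seeded configuration.

#' Build (or load) a run configuration
#'
#' A run configuration bundles everything one experiment needs: arm, group
#' size, generator settings, detection parameters, calibration, PK
#' settings and the master seed. `config` may be a YAML file path or a
#' named list; missing entries take the package defaults.
#'
#' @param config NULL, a named list, or a YAML path.
#' @return an object of class `run_config`.
#' @export
run_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  defaults <- list(
    arm = "heroin_alone",
    n_subjects = 6L,
    seed = 1L,
    chain = "full",               # "full" or "concentration"
    baseline_rate = 10,
    amplitude_mean = 60,
    amplitude_cv = 0.4,
    noise_sd = 0.5,
    drift_coef_sd = 5,
    background_nA = 1000,
    session_noise_nA = 0.5,
    training_noise_nA = 0.5,
    pcr_k = 3L,
    multipliers = NULL,           # NULL -> default_effect_profile(arm)
    detection = list(),
    run_stats = TRUE,
    run_pk = FALSE,
    assay_cv = 0.15,
    out_dir = NULL)
  stop_if_not(all(names(config) %in% names(defaults)),
              paste("unknown config field(s):",
                    paste(setdiff(names(config), names(defaults)),
                          collapse = ", ")))
  cfg <- utils::modifyList(defaults, config)
  stop_if_not(cfg$chain %in% c("full", "concentration"),
              "`chain` must be 'full' or 'concentration'")
  stop_if_not(cfg$n_subjects >= 1, "need at least one subject")
  structure(cfg, class = "run_config")
}

#' Run one synthetic experiment end to end
#'
#' For each subject: draw ground-truth transients for the arm's dosing
#' schedule, render the 10 Hz concentration trace, (in the `"full"` chain)
#' render the raw voltammogram session and recover the trace through
#' background subtraction, PCR and molar calibration, then detect
#' transients and summarise them per dose epoch. Group results are
#' aggregated into a percent-change effect table and, optionally, the
#' gated statistical comparison and a plasma PK table. Identical
#' config + seed gives identical results; per-subject seeds are fanned out
#' with [child_seed()] so adding subjects does not perturb earlier ones.
#'
#' @param config a [run_config()], list, or YAML path.
#' @return an object of class `run_result`: `config`, per-subject
#'   `summaries`, `events`, `truths`, the `effect_table`, `stat_result`
#'   (or NULL), `plasma` (or NULL), and a `manifest` of written files when
#'   `out_dir` is set.
#' @export
run_experiment <- function(config = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  schedule <- if (cfg$arm == "vehicle_only") {
    make_dose_schedule("vehicle_only")
  } else {
    make_dose_schedule(cfg$arm)
  }
  profile <- if (is.null(cfg$multipliers)) {
    default_effect_profile(cfg$arm, baseline_rate = cfg$baseline_rate,
                           amplitude_mean = cfg$amplitude_mean,
                           amplitude_cv = cfg$amplitude_cv)
  } else {
    effect_profile(cfg$baseline_rate, cfg$multipliers,
                   cfg$amplitude_mean, cfg$amplitude_cv)
  }
  det <- do.call(detection_params, cfg$detection)
  calib <- calibration_model(background_ref = cfg$background_nA)
  wf <- waveform_params()
  templates <- analyte_templates(wf)

  truths <- list(); events <- list(); summaries <- list()
  for (s in seq_len(cfg$n_subjects)) {
    truth <- sample_transients(schedule, profile,
                               seed = child_seed(cfg$seed, s, 1L),
                               noise_sd = cfg$noise_sd,
                               drift_coef_sd = cfg$drift_coef_sd)
    conc <- render_concentration(truth)
    if (cfg$chain == "full") {
      session <- render_session(conc, calib = calib, templates = templates,
                                params = wf,
                                background_nA = cfg$background_nA,
                                noise_nA = cfg$session_noise_nA,
                                seed = child_seed(cfg$seed, s, 2L))
      training <- make_training_set(templates, calib,
                                    seed = child_seed(cfg$seed, s, 3L),
                                    noise_nA = cfg$training_noise_nA,
                                    params = wf)
      model <- build_pcr_model(training, k = cfg$pcr_k)
      bg_obs <- observed_background(session)
      sub <- background_subtract(session, window_s = det$window_s)
      traces <- apply_pcr(model, sub)
      conc_hat <- current_to_concentration(traces, calib, bg_obs)
    } else {
      conc_hat <- conc
    }
    ev <- detect_transients(conc_hat, det, schedule = schedule)
    truths[[s]] <- truth
    events[[s]] <- ev
    summaries[[s]] <- epoch_summary(ev, schedule)
  }
  effects <- percent_change(summaries)

  stat <- NULL
  if (isTRUE(cfg$run_stats) && cfg$n_subjects >= 2 &&
      n_epochs(schedule) >= 2) {
    design <- do.call(rbind, lapply(seq_along(summaries), function(s) {
      data.frame(subject = s, epoch = summaries[[s]]$epoch_index,
                 value = summaries[[s]]$frequency)
    }))
    cells <- split(design$value, design$epoch)
    gate <- withCallingHandlers(distribution_gate(cells),
      warning = function(w) invokeRestart("muffleWarning"))
    stat <- omnibus_and_posthoc(design, gate$branch)
    stat$gate <- gate
  }

  plasma <- NULL
  if (isTRUE(cfg$run_pk)) {
    times <- schedule$entries$time_s + schedule$epoch_length_s - 1
    plasma <- do.call(rbind, lapply(seq_len(cfg$n_subjects), function(s) {
      simulate_plasma(schedule, pk_params(), times,
                      seed = child_seed(cfg$seed, s, 4L),
                      assay_cv = cfg$assay_cv, subject = s)
    }))
  }

  result <- structure(list(config = cfg, schedule = schedule,
                           profile = profile, truths = truths,
                           events = events, summaries = summaries,
                           effect_table = effects, stat_result = stat,
                           plasma = plasma, manifest = NULL),
                      class = "run_result")
  if (!is.null(cfg$out_dir)) result$manifest <- write_run(result, cfg$out_dir)
  result
}

# Write the per-subject event tables, effect table, stats JSON and plasma
# CSV into `dir`; returns a manifest data frame with content hashes.
write_run <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (s in seq_along(result$events)) {
    p <- file.path(dir, sprintf("events_subject%02d.csv", s))
    write.csv(result$events[[s]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "effect_table.csv")
  write_effect_csv(result$effect_table, p)
  paths <- c(paths, p)
  if (!is.null(result$stat_result)) {
    p <- file.path(dir, "stats.json")
    write_stat_json(result$stat_result, p)
    paths <- c(paths, p)
  }
  if (!is.null(result$plasma)) {
    p <- file.path(dir, "plasma.csv")
    write.csv(result$plasma, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- data.frame(
    path = basename(paths),
    md5 = vapply(paths, function(f) unname(tools::md5sum(f)), character(1)))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result: %s, %d subjects, chain = %s, seed = %s>\n",
              x$config$arm, x$config$n_subjects, x$config$chain,
              x$config$seed))
  print(x$effect_table)
  if (!is.null(x$stat_result)) print(x$stat_result)
  invisible(x)
}

#' Maximal group-mean percent frequency change over drug epochs
#'
#' Convenience accessor for the headline effect size: the maximum, over
#' the epochs of `drug`, of the group-mean percent change in transient
#' frequency versus vehicle.
#'
#' @param result a [run_experiment()] result or an `effect_table`.
#' @param drug drug whose epochs are scanned.
#' @return scalar percent change.
#' @export
max_pct_change <- function(result, drug = "heroin") {
  grp <- if (inherits(result, "run_result")) {
    result$effect_table$group
  } else {
    result$group
  }
  rows <- grp$drug == drug
  stop_if_not(any(rows), sprintf("no '%s' epochs in the effect table", drug))
  max(grp$mean_pct_change_freq[rows])
}
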