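#' Full run configuration
#'
#' Bundles the task design, observer/simulation, analysis and fitting
#' settings for a reproducible batch run. Every stochastic stage takes an
#' explicit seed. The configuration round-trips through YAML unchanged.
#'
#' @param task A [task_config()].
#' @param observer A [bayes_params()] or [add_params()]; the generating
#'   observer for simulated cohorts.
#' @param variant Generating model variant.
#' @param detection A [detection_config()].
#' @param rt An [rt_config()].
#' @param qc A [qc_config()].
#' @param fit A [fit_settings()].
#' @param fit_variants Variants fitted by [run_fit_compare()].
#' @param n_observers Number of simulated observers.
#' @param seed Base seed; observer i uses seed + i.
#' @param n_bins Bins for the hallucination probability ratio.
#' @param window,window_step Learning-dynamics window length and step.
#' @return A `run_config` list.
#' @export
run_config <- function(task = task_config(), observer = bayes_params(),
                       variant = "BAYES_P", detection = detection_config(),
                       rt = rt_config(), qc = qc_config(),
                       fit = fit_settings(),
                       fit_variants = c("BAYES_P", "BAYES"),
                       n_observers = 5, seed = 1, n_bins = 11,
                       window = 110, window_step = 55) {
  structure(list(task = task, observer = observer, variant = variant,
                 detection = detection, rt = rt, qc = qc, fit = fit,
                 fit_variants = fit_variants, n_observers = n_observers,
                 seed = seed, n_bins = n_bins, window = window,
                 window_step = window_step),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param config A [run_config()].
#' @return A `run_config` (read); `path` invisibly (write).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(block, f) if (is.null(block)) f() else do.call(f, block)
  obs_block <- y$observer
  observer <- if (is.null(obs_block)) bayes_params()
              else if (!is.null(obs_block$w_prior)) do.call(add_params, obs_block)
              else do.call(bayes_params, obs_block)
  run_config(task = pick(y$task, task_config),
             observer = observer,
             variant = if (is.null(y$variant)) "BAYES_P" else y$variant,
             detection = pick(y$detection, detection_config),
             rt = pick(y$rt, rt_config),
             qc = pick(y$qc, qc_config),
             fit = pick(y$fit, fit_settings),
             fit_variants = if (is.null(y$fit_variants)) c("BAYES_P", "BAYES")
                            else y$fit_variants,
             n_observers = if (is.null(y$n_observers)) 5 else y$n_observers,
             seed = if (is.null(y$seed)) 1 else y$seed,
             n_bins = if (is.null(y$n_bins)) 11 else y$n_bins,
             window = if (is.null(y$window)) 110 else y$window,
             window_step = if (is.null(y$window_step)) 55 else y$window_step)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  yaml::write_yaml(strip(unclass(config)), path)
  invisible(path)
}

write_manifest <- function(out_dir, command, config, files) {
  manifest <- list(command = command, seed = config$seed,
                   n_observers = config$n_observers,
                   variant = config$variant, files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate a cohort of sessions to disk
#'
#' Generates one schedule per observer (seeded) and simulates a full
#' session from the configured observer; writes schedule and session CSVs
#' plus a manifest recording seeds and settings. Deterministic given the
#' configuration.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Character vector of written session file paths, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  files <- character(0)
  for (i in seq_len(config$n_observers)) {
    sched <- generate_schedule(config$task, seed = config$seed + i)
    sess <- simulate_session(sched, config$observer, config$detection,
                             seed = config$seed + i,
                             variant = config$variant, rt = config$rt,
                             observer_id = sprintf("obs%03d", i))
    sp <- file.path(out_dir, sprintf("schedule_obs%03d.csv", i))
    fp <- file.path(out_dir, sprintf("session_obs%03d.csv", i))
    write_schedule(sched, sp)
    write_session(sess, fp)
    files <- c(files, fp)
  }
  write_manifest(out_dir, "simulate", config, basename(files))
  invisible(files)
}

#' Behavioral analysis of a set of session files
#'
#' Applies the QC filter, per-direction summaries, the hallucination
#' probability ratio and windowed learning dynamics to each session, and
#' writes `session_summary.csv` (one row per session: QC values and flags,
#' p_ratio, hallucination count), `direction_stats.csv` (one row per
#' session x magnitude) and `learning_dynamics.csv`. Per-session failures
#' are recorded in the summary, not fatal.
#'
#' @param config A [run_config()].
#' @param session_files Paths to session CSVs.
#' @param out_dir Output directory.
#' @return List of the three result data.frames, invisibly.
#' @export
run_analyze <- function(config, session_files, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summaries <- list(); dstats <- list(); dyn <- list()
  for (f in session_files) {
    sess <- read_session(f)
    id <- sess$observer_id
    res <- try({
      qc <- qc_filter(sess, config$qc)
      zero <- sess$trials[sess$trials$condition == "zero" &
                            sess$trials$detected, ]
      pr <- p_ratio(zero$estimate_deg, config$n_bins)
      ds <- direction_stats(sess)
      ld <- learning_dynamics(sess, config$window, config$window_step)
      list(qc = qc, pr = pr, ds = ds, ld = ld)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      summaries[[id]] <- data.frame(observer_id = id, qc_pass = NA,
                                    p_ratio = NA_real_,
                                    n_hallucinations = NA_integer_,
                                    error = attr(res, "condition")$message,
                                    stringsAsFactors = FALSE)
      next
    }
    qcvals <- stats::setNames(res$qc$criteria$value, res$qc$criteria$name)
    summaries[[id]] <- data.frame(
      observer_id = id, qc_pass = res$qc$pass,
      high_detection = qcvals[["high_detection"]],
      high_rmse = qcvals[["high_rmse"]],
      low_detection = qcvals[["low_detection"]],
      p_ratio = res$pr$p_ratio, n_hallucinations = res$pr$n_hallucinations,
      error = "", stringsAsFactors = FALSE)
    if (res$qc$pass) {
      res$ds$observer_id <- id
      dstats[[id]] <- res$ds
      res$ld$observer_id <- id
      dyn[[id]] <- res$ld
    }
  }
  fill <- function(lst) if (length(lst)) do.call(rbind, lst) else NULL
  out <- list(session_summary = do.call(rbind, summaries),
              direction_stats = fill(dstats),
              learning_dynamics = fill(dyn))
  utils::write.csv(out$session_summary,
                   file.path(out_dir, "session_summary.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(out$direction_stats))
    utils::write.csv(out$direction_stats,
                     file.path(out_dir, "direction_stats.csv"),
                     row.names = FALSE, na = "")
  if (!is.null(out$learning_dynamics))
    utils::write.csv(out$learning_dynamics,
                     file.path(out_dir, "learning_dynamics.csv"),
                     row.names = FALSE, na = "")
  write_manifest(out_dir, "analyze", config, basename(session_files))
  invisible(out)
}

#' Fit configured model variants and compare them
#'
#' Estimates motor noise per session, fits every configured variant, and
#' runs both comparison methods (summed-BIC fixed effects and protected
#' exceedance probability). Sessions failing the configured QC filter are
#' excluded up front, mirroring the behavioral inclusion rule. Writes
#' `model_fits.csv` (one row per session x variant) and
#' `model_comparison.csv`. Sessions whose fits fail are reported and
#' excluded from the comparison.
#'
#' @param config A [run_config()].
#' @param session_files Paths to session CSVs.
#' @param out_dir Output directory.
#' @return List with `fits`, `fixed_effects`, `pxp`, invisibly.
#' @export
run_fit_compare <- function(config, session_files, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); failures <- character(0)
  for (f in session_files) {
    sess <- read_session(f)
    qc <- try(qc_filter(sess, config$qc), silent = TRUE)
    if (inherits(qc, "try-error") || !qc$pass) {
      failures <- c(failures, paste0(f, ": excluded by QC"))
      next
    }
    res <- try({
      sm <- estimate_motor_noise(sess)
      lapply(config$fit_variants, function(v) {
        ft <- fit_model(sess, v, sm, config$fit)
        data.frame(subject = sess$observer_id, variant = v,
                   nll = ft$nll, k = ft$k, n_trials = ft$n_trials,
                   bic = ft$bic, sigma_m = sm,
                   t(ft$par), stringsAsFactors = FALSE)
      })
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      failures <- c(failures,
                    paste0(f, ": ", attr(res, "condition")$message))
      next
    }
    rows <- c(rows, res)
  }
  if (!length(rows)) stop("no session could be fitted:\n",
                          paste(failures, collapse = "\n"))
  fits <- do.call(rbind, lapply(rows, function(r)
    r[intersect(c("subject", "variant", "nll", "k", "n_trials", "bic",
                  "sigma_m"), names(r))]))
  # column-union rbind: different variants carry different parameter sets
  allcols <- unique(unlist(lapply(rows, names)))
  full <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(allcols, names(r))
    for (m in miss) r[[m]] <- NA
    r[allcols]
  }))
  fe <- fixed_effects_compare(fits)
  px <- NULL
  subjects <- unique(fits$subject)
  if (length(subjects) >= 2 && length(config$fit_variants) >= 2) {
    bicmat <- sapply(sort(config$fit_variants), function(v)
      fits$bic[fits$variant == v][order(fits$subject[fits$variant == v])])
    px <- protected_exceedance_probability(as.matrix(bicmat),
                                           seed = config$seed)
  }
  utils::write.csv(full, file.path(out_dir, "model_fits.csv"),
                   row.names = FALSE, na = "")
  comp <- fe
  if (!is.null(px)) comp$pxp <- px$pxp[comp$variant]
  utils::write.csv(comp, file.path(out_dir, "model_comparison.csv"),
                   row.names = FALSE, na = "")
  if (length(failures))
    message("fit failures:\n", paste(failures, collapse = "\n"))
  write_manifest(out_dir, "fit_compare", config, basename(session_files))
  invisible(list(fits = fits, fixed_effects = fe, pxp = px))
}
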