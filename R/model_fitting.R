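#' Fit settings for observer-model likelihood maximization
#'
#' @param step Angular grid spacing in degrees used by the likelihood
#'   (default 1).
#' @param n_starts Number of points in the fixed Latin-square start grid.
#' @param n_optim Number of best start points (by initial likelihood) from
#'   which bounded quasi-Newton optimization is run.
#' @param maxit Maximum optimizer iterations per start.
#' @return A `fit_settings` list.
#' @export
fit_settings <- function(step = 1, n_starts = 12, n_optim = 4, maxit = 100) {
  stopifnot(n_starts >= 1, n_optim >= 1, n_optim <= n_starts)
  structure(list(step = step, n_starts = n_starts, n_optim = n_optim,
                 maxit = maxit), class = "fit_settings")
}

#' Motor-noise width from high-contrast trials
#'
#' Fits the von Mises + uniform mixture to high-contrast estimation errors;
#' the mixture's width is taken as the motor noise sigma_m (the uniform
#' lapse term absorbs outliers), which is then held fixed while fitting the
#' observer models.
#'
#' @param session A `session_data`.
#' @param min_n Minimum usable high-contrast estimation trials.
#' @return sigma_m in degrees.
#' @export
estimate_motor_noise <- function(session, min_n = 20) {
  tr <- session$trials
  hi <- tr[tr$condition == "high" & !is.na(tr$estimate_deg) &
             !is.na(tr$direction_deg), , drop = FALSE]
  if (nrow(hi) < min_n)
    stop("need at least ", min_n, " usable high-contrast estimation ",
         "trials, got ", nrow(hi))
  fit_vm_mixture(wrap_deg(hi$estimate_deg - hi$direction_deg))$sigma
}

# free parameters, bounds, and packing per variant
variant_par_info <- function(variant) {
  base_lo <- c(theta_p = 5, sigma_p = 2)
  base_hi <- c(theta_p = 80, sigma_p = 120)
  ss_lo <- 2; ss_hi <- 80
  if (variant %in% c("BAYES", "BAYES_P")) {
    lo <- c(base_lo, sigma_s = ss_lo, alpha_p = 0)
    hi <- c(base_hi, sigma_s = ss_hi, alpha_p = 0.5)
  } else if (variant == "BAYES_varmin") {
    lo <- c(base_lo, sigma_s_32 = ss_lo, sigma_s_other = ss_lo, alpha_p = 0)
    hi <- c(base_hi, sigma_s_32 = ss_hi, sigma_s_other = ss_hi, alpha_p = 0.5)
  } else if (variant == "BAYES_var") {
    ss <- stats::setNames(rep(ss_lo, 5),
                          paste0("sigma_s_", DIRECTION_MAGNITUDES))
    lo <- c(base_lo, ss, alpha_p = 0)
    hi <- c(base_hi, ss + (ss_hi - ss_lo), alpha_p = 0.5)
  } else if (variant %in% ADD_VARIANTS) {
    lo <- c(base_lo, sigma_s = ss_lo, alpha_p = 0, w_prior = 0)
    hi <- c(base_hi, sigma_s = ss_hi, alpha_p = 0.5, w_prior = 1)
  } else stop("unknown variant: ", variant)
  list(lower = lo, upper = hi, k = length(lo))
}

unpack_params <- function(par, variant, sigma_m) {
  if (variant %in% ADD_VARIANTS)
    return(add_params(par[["theta_p"]], par[["sigma_p"]], par[["sigma_s"]],
                      par[["alpha_p"]], sigma_m, par[["w_prior"]]))
  ss <- switch(variant,
               BAYES = par[["sigma_s"]], BAYES_P = par[["sigma_s"]],
               BAYES_varmin = c(par[["sigma_s_32"]], par[["sigma_s_other"]]),
               BAYES_var = unname(par[paste0("sigma_s_",
                                             DIRECTION_MAGNITUDES)]))
  bayes_params(par[["theta_p"]], par[["sigma_p"]], ss, par[["alpha_p"]],
               sigma_m)
}

# linear interpolation of a circular grid density at arbitrary angles
grid_interp <- function(density, step, x) {
  n <- length(density)
  pos <- (wrap_deg(x) + 180) / step
  i0 <- floor(pos)
  frac <- pos - i0
  i0 <- (i0 %% n) + 1
  i1 <- (i0 %% n) + 1
  density[i0] * (1 - frac) + density[i1] * frac
}

# negative log-likelihood of observed estimates under an observer model;
# trials are grouped by sensory width, and within a group all presented
# directions share one percept lookup and motor kernel
model_nll <- function(par, variant, sigma_m, theta_act, estimate, step) {
  params <- try(unpack_params(par, variant, sigma_m), silent = TRUE)
  if (inherits(params, "try-error")) return(1e10)
  is_add <- variant %in% ADD_VARIANTS
  grid <- angle_grid(step)
  ll <- 0
  if (is_add) {
    for (a in unique(theta_act)) {
      g <- add_response_distribution(a, params, variant, step)
      d <- grid_interp(g$density, g$step, estimate[theta_act == a])
      ll <- ll + sum(log(pmax(d, 1e-300)))
    }
    return(if (is.finite(ll)) -ll else 1e10)
  }
  lapse <- if (variant == "BAYES") uniform_density(length(grid))
           else prior_motor_density(grid, params$theta_p, params$sigma_p,
                                    sigma_m)
  ss <- sigma_s_for(params, variant, theta_act)
  for (s in unique(ss)) {
    sel <- ss == s
    acts <- sort(unique(theta_act[sel]))
    D <- response_density_matrix(acts, params$theta_p, params$sigma_p, s,
                                 params$alpha_p, sigma_m, lapse, step)
    col <- match(theta_act[sel], acts)
    n <- length(grid)
    pos <- (wrap_deg(estimate[sel]) + 180) / step
    i0 <- floor(pos); frac <- pos - i0
    i0 <- (i0 %% n) + 1; i1 <- (i0 %% n) + 1
    d <- D[cbind(i0, col)] * (1 - frac) + D[cbind(i1, col)] * frac
    ll <- ll + sum(log(pmax(d, 1e-300)))
  }
  if (!is.finite(ll)) return(1e10)
  -ll
}

# deterministic Latin-square start grid inside the box [lower, upper]
latin_starts <- function(lower, upper, n_starts) {
  d <- length(lower)
  strides <- c(1, 5, 7, 11, 1, 5, 7, 11)[seq_len(d)]
  q <- (seq_len(n_starts) - 0.5) / n_starts
  sapply(seq_len(d), function(k) {
    perm <- ((seq_len(n_starts) - 1) * strides[k] + (k - 1)) %% n_starts + 1
    lower[k] + q[perm] * (upper[k] - lower[k])
  })
}

#' Maximum-likelihood fit of an observer model to one session
#'
#' Maximizes the summed log density of the observed estimates given the
#' presented directions over the usable low-contrast trials (estimate made
#' and stimulus reported detected; the two staircases are pooled;
#' random-direction trials are included with their drawn direction). The
#' motor-noise width `sigma_m` is fixed. Optimization is bounded
#' quasi-Newton (L-BFGS-B) started from the best `n_optim` points of a
#' fixed Latin-square grid of `n_starts` points; deterministic given the
#' data and settings.
#'
#' @param session A `session_data`.
#' @param variant A Bayesian or ADD variant name.
#' @param sigma_m Motor-noise width in degrees (from
#'   [estimate_motor_noise()]).
#' @param settings A [fit_settings()].
#' @return A `model_fit_result` list: variant, par (named vector), params
#'   ([bayes_params()]/[add_params()]), sigma_m, nll, n_trials, k, bic,
#'   converged, best_start.
#' @export
fit_model <- function(session, variant = "BAYES_P", sigma_m,
                      settings = fit_settings()) {
  use <- usable_low_trials(session$trials)
  use <- use[!is.na(use$direction_deg), , drop = FALSE]
  if (nrow(use) < 20)
    stop("too few usable low-contrast trials to fit: ", nrow(use))
  info <- variant_par_info(variant)
  theta_act <- use$direction_deg
  estimate <- use$estimate_deg
  obj <- function(p) {
    names(p) <- names(info$lower)
    model_nll(p, variant, sigma_m, theta_act, estimate, settings$step)
  }
  starts <- latin_starts(info$lower, info$upper, settings$n_starts)
  vals <- apply(starts, 1, obj)
  order_idx <- order(vals)[seq_len(settings$n_optim)]
  best <- NULL; best_start <- NA_integer_; diags <- character(0)
  for (i in order_idx) {
    fit <- try(stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                            lower = info$lower, upper = info$upper,
                            control = list(maxit = settings$maxit,
                                           factr = 1e9)),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      diags <- c(diags, paste0("start ", i, ": ", attr(fit, "condition")$message))
      next
    }
    if (is.null(best) || fit$value < best$value) {
      best <- fit; best_start <- i
    }
  }
  if (is.null(best))
    stop("all optimization starts failed:\n", paste(diags, collapse = "\n"))
  par <- stats::setNames(best$par, names(info$lower))
  n <- nrow(use)
  structure(list(variant = variant, par = par,
                 params = unpack_params(par, variant, sigma_m),
                 sigma_m = sigma_m, nll = best$value, n_trials = n,
                 k = info$k, bic = bic(info$k, n, best$value),
                 converged = best$convergence == 0,
                 best_start = best_start),
            class = "model_fit_result")
}

#' Bayesian Information Criterion
#'
#' @param k Number of free parameters.
#' @param n Number of observations.
#' @param nll Negative log-likelihood at the maximum.
#' @return k*log(n) + 2*nll.
#' @export
bic <- function(k, n, nll) k * log(n) + 2 * nll

#' Fixed-effects model comparison by summed BIC
#'
#' Sums BIC over subjects per model and reports differences relative to the
#' best (minimum) model.
#'
#' @param fits Data.frame with columns `subject`, `variant`, `bic`, one row
#'   per subject x variant; every subject must have every variant.
#' @return Data.frame with columns variant, total_bic, delta_bic, sorted by
#'   total_bic.
#' @export
fixed_effects_compare <- function(fits) {
  stopifnot(all(c("subject", "variant", "bic") %in% names(fits)))
  if (any(!is.finite(fits$bic))) stop("non-finite BIC values")
  tab <- table(fits$subject, fits$variant)
  if (any(tab != 1))
    stop("every subject must have exactly one fit per variant")
  tot <- stats::aggregate(bic ~ variant, data = fits, FUN = sum)
  names(tot)[2] <- "total_bic"
  tot$delta_bic <- tot$total_bic - min(tot$total_bic)
  tot[order(tot$total_bic), ]
}

#' Random-effects model comparison: protected exceedance probability
#'
#' Variational Bayes over model frequencies with a Dirichlet(1) prior,
#' using log model evidence approximated as -BIC/2. Exceedance
#' probabilities are estimated by Monte-Carlo sampling from the posterior
#' Dirichlet (fixed seed), and protected by blending with the uniform 1/K
#' according to the Bayes omnibus risk — the posterior probability that all
#' models are equally frequent.
#'
#' @param bic_matrix Numeric matrix, subjects x models (column names are
#'   model labels).
#' @param n_samples Dirichlet Monte-Carlo draws (default 1e5).
#' @param seed Seed for the Monte-Carlo step.
#' @return List: `alpha` (posterior Dirichlet counts), `model_freq`
#'   (expected frequencies), `ep` (exceedance probabilities), `bor` (Bayes
#'   omnibus risk), `pxp` (protected exceedance probabilities, summing
#'   to 1).
#' @export
protected_exceedance_probability <- function(bic_matrix, n_samples = 1e5,
                                             seed = 1) {
  bic_matrix <- as.matrix(bic_matrix)
  if (nrow(bic_matrix) < 2 || ncol(bic_matrix) < 2)
    stop("need at least 2 subjects and 2 models")
  if (any(!is.finite(bic_matrix))) stop("non-finite BIC entries")
  lme <- -bic_matrix / 2
  n <- nrow(lme); K <- ncol(lme)
  alpha0 <- rep(1, K)
  alpha <- alpha0
  for (it in 1:200) {
    elog <- digamma(alpha) - digamma(sum(alpha))
    u <- sweep(lme, 2, elog, `+`)
    u <- u - apply(u, 1, max)
    g <- exp(u) / rowSums(exp(u))
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < 1e-9) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  elog <- digamma(alpha) - digamma(sum(alpha))
  # variational free energy of the frequency model (H1)
  f1 <- sum(g * (lme + rep(elog, each = n))) - sum(g * log(pmax(g, 1e-300))) +
    lgamma(sum(alpha0)) - sum(lgamma(alpha0)) -
    (lgamma(sum(alpha)) - sum(lgamma(alpha))) -
    sum((alpha - alpha0) * elog)
  # evidence under H0: all models equally frequent
  rowmax <- apply(lme, 1, max)
  f0 <- sum(log(rowMeans(exp(lme - rowmax))) + rowmax)
  bor <- 1 / (1 + exp(f1 - f0))
  # exceedance probabilities by Dirichlet Monte Carlo
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  draws <- matrix(stats::rgamma(n_samples * K, shape = rep(alpha, each =
                                                             n_samples)),
                  nrow = n_samples)
  ep <- tabulate(max.col(draws, ties.method = "first"), K) / n_samples
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  pxp <- (1 - bor) * ep + bor / K
  labels <- colnames(bic_matrix)
  if (is.null(labels)) labels <- paste0("model", seq_len(K))
  list(alpha = stats::setNames(alpha, labels),
       model_freq = stats::setNames(alpha / sum(alpha), labels),
       ep = stats::setNames(ep, labels), bor = bor,
       pxp = stats::setNames(pxp, labels))
}

#' Parameter-recovery harness
#'
#' Simulates one session per true parameter set, re-estimates motor noise
#' and refits the generating variant, and tabulates true versus recovered
#' parameters with per-parameter Spearman rank correlations and median
#' absolute errors. Fit failures are recorded per observer, not fatal.
#'
#' @param true_params_list List of [bayes_params()] objects.
#' @param schedule A `trial_schedule` shared by all simulated observers.
#' @param seed Base seed; observer i uses seed + i.
#' @param variant Generating and fitted variant (default "BAYES_P").
#' @param det A [detection_config()].
#' @param settings A [fit_settings()].
#' @return List: `table` (long data.frame observer x parameter with true
#'   and recovered values), `spearman`, `mae` (named per parameter),
#'   `failures` (character).
#' @export
parameter_recovery <- function(true_params_list, schedule, seed = 1,
                               variant = "BAYES_P",
                               det = detection_config(),
                               settings = fit_settings()) {
  rows <- list(); failures <- character(0)
  for (i in seq_along(true_params_list)) {
    tp <- true_params_list[[i]]
    sess <- simulate_session(schedule, tp, det, seed = seed + i,
                             variant = variant,
                             observer_id = sprintf("rec%02d", i))
    fit <- try({
      sm <- estimate_motor_noise(sess)
      fit_model(sess, variant, sm, settings)
    }, silent = TRUE)
    if (inherits(fit, "try-error")) {
      failures <- c(failures, sprintf("observer %d: %s", i,
                                      attr(fit, "condition")$message))
      next
    }
    truth <- c(theta_p = tp$theta_p, sigma_p = tp$sigma_p,
               sigma_s = unname(tp$sigma_s[1]), alpha_p = tp$alpha_p)
    rec <- fit$par[names(truth)]
    rows[[length(rows) + 1L]] <-
      data.frame(observer = i, parameter = names(truth),
                 true = unname(truth), recovered = unname(rec),
                 stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  pars <- unique(tab$parameter)
  sp <- vapply(pars, function(p) {
    d <- tab[tab$parameter == p, ]
    suppressWarnings(stats::cor(d$true, d$recovered, method = "spearman"))
  }, numeric(1))
  mae <- vapply(pars, function(p) {
    d <- tab[tab$parameter == p, ]
    stats::median(abs(d$recovered - d$true))
  }, numeric(1))
  list(table = tab, spearman = sp, mae = mae, failures = failures)
}

#' Draw plausible observer parameter sets for recovery studies
#'
#' Uniform draws over ranges that span the behaviorally plausible regime
#' while staying identifiable with a single session of data.
#'
#' @param n Number of parameter sets.
#' @param seed Seed.
#' @param sigma_m Motor-noise width given to every observer.
#' @param ranges Named list of c(min, max) for theta_p, sigma_p, sigma_s,
#'   alpha_p.
#' @return List of [bayes_params()].
#' @export
draw_observer_params <- function(n, seed = 1, sigma_m = 8,
                                 ranges = list(theta_p = c(20, 45),
                                               sigma_p = c(5, 40),
                                               sigma_s = c(10, 40),
                                               alpha_p = c(0.02, 0.25))) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    bayes_params(stats::runif(1, ranges$theta_p[1], ranges$theta_p[2]),
                 stats::runif(1, ranges$sigma_p[1], ranges$sigma_p[2]),
                 stats::runif(1, ranges$sigma_s[1], ranges$sigma_s[2]),
                 stats::runif(1, ranges$alpha_p[1], ranges$alpha_p[2]),
                 sigma_m)
  })
}

#' Model-recovery harness
#'
#' Simulates cohorts from a generating variant, fits each subject under all
#' candidate variants, and records which variant wins the fixed-effects
#' (summed BIC) and random-effects (protected exceedance probability)
#' comparisons in each cohort.
#'
#' @param generating Generating variant name.
#' @param candidates Candidate variant names fitted to every subject.
#' @param n_cohorts,n_subjects Cohort count and size.
#' @param schedule A `trial_schedule`.
#' @param seed Base seed.
#' @param det A [detection_config()].
#' @param settings A [fit_settings()].
#' @return List: `cohorts` data.frame (cohort, bic_winner, pxp_winner),
#'   `bic_win_rate`, `pxp_win_rate` for the generating variant.
#' @export
model_recovery <- function(generating = "BAYES_P",
                           candidates = c("BAYES_P", "BAYES"),
                           n_cohorts = 10, n_subjects = 10,
                           schedule = generate_schedule(),
                           seed = 1, det = detection_config(),
                           settings = fit_settings()) {
  rows <- list()
  for (co in seq_len(n_cohorts)) {
    pars <- draw_observer_params(n_subjects, seed = seed + 7919 * co)
    fits <- list()
    for (sub in seq_len(n_subjects)) {
      sess <- simulate_session(schedule, pars[[sub]], det,
                               seed = seed + 7919 * co + sub,
                               variant = generating,
                               observer_id = sprintf("c%02ds%02d", co, sub))
      sm <- estimate_motor_noise(sess)
      for (v in candidates) {
        f <- fit_model(sess, v, sm, settings)
        fits[[length(fits) + 1L]] <- data.frame(subject = sub, variant = v,
                                                bic = f$bic)
      }
    }
    fits <- do.call(rbind, fits)
    fe <- fixed_effects_compare(fits)
    bicmat <- matrix(fits$bic[order(fits$variant, fits$subject)],
                     nrow = n_subjects,
                     dimnames = list(NULL, sort(candidates)))
    px <- protected_exceedance_probability(bicmat, seed = seed + co)
    rows[[co]] <- data.frame(cohort = co,
                             bic_winner = fe$variant[1],
                             pxp_winner = names(which.max(px$pxp)),
                             stringsAsFactors = FALSE)
  }
  cohorts <- do.call(rbind, rows)
  list(cohorts = cohorts,
       bic_win_rate = mean(cohorts$bic_winner == generating),
       pxp_win_rate = mean(cohorts$pxp_winner == generating))
}
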