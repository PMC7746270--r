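#' Quality-control thresholds
#'
#' @param high_detection Minimum high-contrast detection fraction; a
#'   session fails when detection is at or below this value (default 0.70).
#' @param high_rmse Maximum circular RMS estimation error (degrees) on
#'   high-contrast trials; fails when at or above (default 30).
#' @param low_detection Minimum low-contrast detection fraction; fails when
#'   below (default 0.50).
#' @return A `qc_config` list.
#' @export
qc_config <- function(high_detection = 0.70, high_rmse = 30,
                      low_detection = 0.50) {
  structure(list(high_detection = high_detection, high_rmse = high_rmse,
                 low_detection = low_detection), class = "qc_config")
}

#' Session inclusion filter
#'
#' Benchmarks performance on high-contrast trials (detection fraction and
#' circular RMS estimation error) and detection on low-contrast trials, and
#' reports each criterion's value alongside the pass/fail decision.
#'
#' @param session A `session_data`.
#' @param thresholds A [qc_config()].
#' @return List with `pass` (logical) and `criteria` (data.frame with one
#'   row per criterion: name, value, threshold, pass).
#' @export
qc_filter <- function(session, thresholds = qc_config()) {
  tr <- session$trials
  hi <- tr[tr$condition == "high", ]
  lo <- tr[tr$condition %in% c("low_2_1", "low_4_1"), ]
  if (nrow(hi) == 0 || nrow(lo) == 0)
    stop("session must contain high- and low-contrast trials")
  hi_det <- mean(hi$detected)
  hi_est <- hi[!is.na(hi$estimate_deg) & !is.na(hi$direction_deg), ]
  hi_rmse <- circ_rmse_deg(hi_est$estimate_deg - hi_est$direction_deg)
  lo_det <- mean(lo$detected)
  crit <- data.frame(
    name = c("high_detection", "high_rmse", "low_detection"),
    value = c(hi_det, hi_rmse, lo_det),
    threshold = c(thresholds$high_detection, thresholds$high_rmse,
                  thresholds$low_detection),
    pass = c(hi_det > thresholds$high_detection,
             !is.na(hi_rmse) && hi_rmse < thresholds$high_rmse,
             lo_det >= thresholds$low_detection),
    stringsAsFactors = FALSE)
  list(pass = all(crit$pass), criteria = crit)
}

#' Fit a von Mises + uniform mixture to angular errors
#'
#' Maximum-likelihood fit of the estimation-error model
#' (1 - alpha) * V(mu, sigma) + alpha / (2*pi): `mu` is the estimation
#' bias location, `sigma` the estimation variability, `alpha` the lapse
#' proportion. Optimization is run from a fixed 9-point start grid over
#' (sigma, alpha) centered on the circular mean of the data, on a
#' transformed scale that enforces sigma in (0.5, 120] degrees and alpha in
#' [0, 1]; deterministic given the data.
#'
#' @param errors Wrapped estimation errors in degrees (>= 10 values).
#' @return A `vm_mixture_fit` list: mu, sigma, alpha (degrees / proportion),
#'   log_likelihood, n_trials, converged.
#' @export
fit_vm_mixture <- function(errors) {
  errors <- wrap_deg(errors[!is.na(errors)])
  n <- length(errors)
  if (n < 10) stop("need at least 10 observations to fit the mixture")
  sig_lo <- 0.5; sig_hi <- 120
  nll <- function(par) {
    mu <- par[1]
    sigma <- sig_lo + (sig_hi - sig_lo) * stats::plogis(par[2])
    alpha <- stats::plogis(par[3])
    d <- (1 - alpha) * vm_density(errors, mu, sigma) + alpha / (2 * pi)
    -sum(log(pmax(d, 1e-300)))
  }
  cm <- circ_mean_deg(errors)
  if (is.na(cm)) cm <- 0
  inv_sig <- function(s) stats::qlogis((s - sig_lo) / (sig_hi - sig_lo))
  starts <- expand.grid(sigma = c(10, 30, 60), alpha = c(0.05, 0.3, 0.7))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    p0 <- c(cm, inv_sig(starts$sigma[k]), stats::qlogis(starts$alpha[k]))
    fit <- try(stats::optim(p0, nll, method = "Nelder-Mead",
                            control = list(maxit = 500, reltol = 1e-10)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("von Mises mixture fit failed from every start point")
  structure(list(mu = wrap_deg(best$par[1]),
                 sigma = sig_lo + (sig_hi - sig_lo) *
                   stats::plogis(best$par[2]),
                 alpha = stats::plogis(best$par[3]),
                 log_likelihood = -best$value, n_trials = n,
                 converged = best$convergence == 0),
            class = "vm_mixture_fit")
}

# usable estimation trials per the inclusion rule: low contrast, estimate
# made within the window, and a "DOTS" detection report
usable_low_trials <- function(tr) {
  tr[tr$condition %in% c("low_2_1", "low_4_1") & !is.na(tr$estimate_deg) &
       tr$detected, , drop = FALSE]
}

#' Per-direction behavioral summaries
#'
#' Folds the predetermined directions onto their absolute magnitudes (0,
#' 16, 32, 48, 64 deg; errors at negative directions are mirrored), and for
#' each magnitude fits the von Mises + uniform mixture to the estimation
#' errors of usable low-contrast trials (estimate made and stimulus
#' reported detected), giving bias (mu), variability (sigma) and lapse
#' proportion (alpha). Detection fraction (all low-contrast trials at the
#' magnitude) and mean RT (usable trials) are summarized alongside.
#' `bias_toward_32` flips the error sign for magnitudes beyond 32 so that
#' positive values always mean displacement toward the expected +/-32
#' directions. Random-direction trials are excluded. Magnitudes with fewer
#' than `min_n` usable trials are flagged unfitted (NA estimates).
#'
#' @param session A `session_data`.
#' @param min_n Minimum usable trials per magnitude for a mixture fit.
#' @return A `direction_stats` data.frame, one row per magnitude: columns
#'   magnitude, n_usable, bias_deg, bias_toward_32, variability_deg, lapse,
#'   mean_rt_s, detection_rate, fitted.
#' @export
direction_stats <- function(session, min_n = 10) {
  tr <- session$trials
  lo <- tr[tr$condition %in% c("low_2_1", "low_4_1") & !tr$is_random &
             !is.na(tr$direction_deg), , drop = FALSE]
  use <- usable_low_trials(lo)
  mags <- DIRECTION_MAGNITUDES
  out <- lapply(mags, function(m) {
    at <- use[abs(use$direction_deg) == m, , drop = FALSE]
    err <- wrap_deg(at$estimate_deg - at$direction_deg)
    folded <- ifelse(at$direction_deg < 0, -err, err)
    det_at <- lo[abs(lo$direction_deg) == m, , drop = FALSE]
    fitted <- length(folded) >= min_n
    if (fitted) {
      f <- fit_vm_mixture(folded)
      bias <- f$mu; sigma <- f$sigma; alpha <- f$alpha
    } else bias <- sigma <- alpha <- NA_real_
    data.frame(magnitude = m, n_usable = length(folded),
               bias_deg = bias,
               bias_toward_32 = if (m > 32) -bias else bias,
               variability_deg = sigma, lapse = alpha,
               mean_rt_s = if (nrow(at)) mean(at$rt_s, na.rm = TRUE)
                           else NA_real_,
               detection_rate = if (nrow(det_at)) mean(det_at$detected)
                                else NA_real_,
               fitted = fitted)
  })
  structure(do.call(rbind, out), class = c("direction_stats", "data.frame"))
}

#' Hallucination probability ratio
#'
#' Quantifies how much hallucinated percepts (direction estimates on
#' detected zero-contrast trials) cluster within 16 deg of the expected
#' +/-32 deg directions. The response range is divided into `n_bins`
#' (default 11) bins of 32 deg centered on multiples of 32; estimates
#' falling outside the covered 352 deg span join the nearest bin. The
#' ratio is the average probability of the two target bins (centers at
#' +/-32) times `n_bins`, so it equals 1 when estimates are equally likely
#' in every bin and `n_bins`/2 when all estimates are within 16 deg of
#' +/-32.
#'
#' @param no_stim_estimates Estimates (degrees) from detected zero-contrast
#'   trials.
#' @param n_bins Odd number of 32-deg bins, at most 11 (default 11).
#' @return A `p_ratio_result` list: p_ratio, n_hallucinations, n_bins,
#'   bin_centers, bin_counts, undefined (TRUE when there were no estimates,
#'   in which case p_ratio is NA).
#' @export
p_ratio <- function(no_stim_estimates, n_bins = 11) {
  if (n_bins %% 2 != 1 || n_bins < 3 || n_bins * 32 > 360)
    stop("n_bins must be an odd number of 32-degree bins covering at most ",
         "the full circle (3..11)")
  est <- wrap_deg(no_stim_estimates[!is.na(no_stim_estimates)])
  centers <- (seq_len(n_bins) - (n_bins + 1) / 2) * 32
  if (length(est) == 0L)
    return(structure(list(p_ratio = NA_real_, n_hallucinations = 0L,
                          n_bins = n_bins, bin_centers = centers,
                          bin_counts = rep(0L, n_bins), undefined = TRUE),
                     class = "p_ratio_result"))
  d <- abs(outer(est, centers, function(a, b) wrap_deg(a - b)))
  bin <- apply(d, 1, which.min)
  counts <- tabulate(bin, n_bins)
  targets <- which(centers %in% c(-32, 32))
  p_target <- mean(counts[targets] / length(est))
  structure(list(p_ratio = p_target * n_bins,
                 n_hallucinations = length(est), n_bins = n_bins,
                 bin_centers = centers, bin_counts = counts,
                 undefined = FALSE),
            class = "p_ratio_result")
}

#' Windowed learning-dynamics summaries
#'
#' Slides overlapping windows over trial order and summarizes, per window:
#' the attraction bias toward the nearest +/-32 prior mode (mean signed
#' folded error at the non-expected predetermined magnitudes 16, 48 and 64;
#' 0 deg is equidistant from both modes and excluded), the detection
#' fraction at +/-32 versus the other directions, and the mean RT at
#' +/-32 versus the other directions. All quantities use usable
#' low-contrast trials (detection fractions use all low-contrast trials).
#' A cheap mean-error estimator is used instead of a mixture fit because
#' windows are small.
#'
#' @param session A `session_data`.
#' @param window Window length in trials (default 110).
#' @param step Window step in trials (default 55).
#' @return Data.frame with one row per window: window_start, window_end,
#'   n_bias_trials, attraction_bias, detection_32, detection_other, rt_32,
#'   rt_other. Windows with no usable trials give NA.
#' @export
learning_dynamics <- function(session, window = 110, step = 55) {
  tr <- session$trials
  n <- nrow(tr)
  if (window > n) stop("window exceeds session length")
  starts <- seq(1, n - window + 1, by = step)
  rows <- lapply(starts, function(s) {
    w <- tr[tr$trial_index >= s & tr$trial_index < s + window, , drop = FALSE]
    lo <- w[w$condition %in% c("low_2_1", "low_4_1") & !w$is_random &
              !is.na(w$direction_deg), , drop = FALSE]
    use <- usable_low_trials(lo)
    bias_tr <- use[abs(use$direction_deg) %in% c(16, 48, 64), , drop = FALSE]
    err <- wrap_deg(bias_tr$estimate_deg - bias_tr$direction_deg)
    folded <- ifelse(bias_tr$direction_deg < 0, -err, err)
    attract <- ifelse(abs(bias_tr$direction_deg) > 32, -folded, folded)
    is32 <- abs(lo$direction_deg) == 32
    use32 <- abs(use$direction_deg) == 32
    data.frame(
      window_start = s, window_end = s + window - 1,
      n_bias_trials = nrow(bias_tr),
      attraction_bias = if (nrow(bias_tr)) mean(attract) else NA_real_,
      detection_32 = if (any(is32)) mean(lo$detected[is32]) else NA_real_,
      detection_other = if (any(!is32)) mean(lo$detected[!is32]) else NA_real_,
      rt_32 = if (any(use32)) mean(use$rt_s[use32], na.rm = TRUE)
              else NA_real_,
      rt_other = if (any(!use32)) mean(use$rt_s[!use32], na.rm = TRUE)
                 else NA_real_)
  })
  do.call(rbind, rows)
}
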