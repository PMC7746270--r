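#' Detection model of the synthetic observer
#'
#' The task itself does not prescribe a detection mechanism, so the
#' simulator uses a standard psychometric emulation: detection probability
#' is a logistic function of log-luminance with a threshold (luminance at
#' 50% detection) and slope, multiplied on the odds scale by
#' `direction_boost` on trials at the expected +/-32 deg directions (to
#' emulate better detection at expected directions). On zero-contrast
#' trials the observer "detects" (hallucinates) with `false_alarm_rate`,
#' and a hallucinated direction is drawn from the acquired prior with
#' probability `hallucination_prior_weight`, otherwise uniformly.
#'
#' @param threshold Luminance (cd/m2) at 50% detection; > 0.
#' @param slope Logistic slope on the log-luminance scale; > 0.
#' @param direction_boost Multiplicative odds factor at +/-32 deg; >= 0.
#' @param false_alarm_rate Hallucination probability on zero-contrast
#'   trials, in [0, 1].
#' @param hallucination_prior_weight Probability a hallucinated direction
#'   comes from the prior rather than uniform, in [0, 1].
#' @return A `detection_config` list.
#' @export
detection_config <- function(threshold = 0.2, slope = 2,
                             direction_boost = 1.5,
                             false_alarm_rate = 0.1,
                             hallucination_prior_weight = 0.5) {
  stopifnot(threshold > 0, slope > 0, direction_boost >= 0,
            false_alarm_rate >= 0, false_alarm_rate <= 1,
            hallucination_prior_weight >= 0,
            hallucination_prior_weight <= 1)
  structure(list(threshold = threshold, slope = slope,
                 direction_boost = direction_boost,
                 false_alarm_rate = false_alarm_rate,
                 hallucination_prior_weight = hallucination_prior_weight),
            class = "detection_config")
}

#' Reaction-time and response-window emulation settings
#'
#' Reaction times are drawn from a lognormal, with an additive shift of the
#' log-mean at the expected +/-32 deg directions (default -0.1, i.e. faster
#' there). This is a descriptive emulation for exercising RT summaries, not
#' a fitted model. Estimates are omitted (no response within the 3000 ms
#' window) uniformly at random at `omission_rate`.
#'
#' @param rt_meanlog,rt_sdlog Lognormal parameters of RT in seconds.
#' @param rt_shift_expected Additive log-mean shift at +/-32 deg.
#' @param omission_rate Probability an estimation response is missing.
#' @return An `rt_config` list.
#' @export
rt_config <- function(rt_meanlog = -0.2, rt_sdlog = 0.25,
                      rt_shift_expected = -0.1, omission_rate = 0.02) {
  stopifnot(rt_sdlog > 0, omission_rate >= 0, omission_rate <= 1)
  structure(list(rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
                 rt_shift_expected = rt_shift_expected,
                 omission_rate = omission_rate),
            class = "rt_config")
}

detect_prob <- function(luminance, det, expected) {
  p <- stats::plogis(det$slope * (log(luminance) - log(det$threshold)))
  odds <- p / (1 - p) * ifelse(expected, det$direction_boost, 1)
  odds / (1 + odds)
}

# estimation responses for stimulus trials under a Bayesian observer:
# theta_s ~ V(theta_act, sigma_s); percept = posterior mean with prob
# (1 - alpha_p), else a lapse (a prior draw for BAYES_P and the
# direction-dependent variants, uniform for BAYES); response adds motor
# noise
bayes_estimates <- function(theta_act, sigma_s, params, step = 1,
                            lapse_uniform = FALSE) {
  n <- length(theta_act)
  if (n == 0L) return(numeric(0))
  theta_s <- numeric(n)
  for (s in unique(sigma_s)) {
    sel <- sigma_s == s
    theta_s[sel] <- wrap_deg(theta_act[sel] + rvm_deg(sum(sel), 0, s))
  }
  lapse <- stats::runif(n) < params$alpha_p
  perc <- numeric(n)
  if (any(!lapse)) {
    idx <- which(!lapse)
    for (s in unique(sigma_s[idx])) {
      sel <- idx[sigma_s[idx] == s]
      perc[sel] <- posterior_mean_vec(theta_s[sel], params$theta_p,
                                      params$sigma_p, s, step)
    }
  }
  if (any(lapse)) {
    perc[lapse] <- if (lapse_uniform) stats::runif(sum(lapse), -180, 180)
                   else rprior_deg(sum(lapse), params$theta_p,
                                   params$sigma_p)
  }
  wrap_deg(perc + rvm_deg(n, 0, params$sigma_m))
}

# estimation responses under the ADD strategy observer; w_prior may be a
# per-trial vector (0 on high-contrast trials, where the stimulus is clear
# enough that the likelihood is always used)
add_estimates <- function(theta_act, sigma_s, params, variant = "ADD",
                          w_prior = params$w_prior) {
  n <- length(theta_act)
  if (n == 0L) return(numeric(0))
  theta_s <- numeric(n)
  for (s in unique(sigma_s)) {
    sel <- sigma_s == s
    theta_s[sel] <- wrap_deg(theta_act[sel] + rvm_deg(sum(sel), 0, s))
  }
  u <- stats::runif(n)
  lapse <- u < params$alpha_p
  use_prior <- !lapse & (stats::runif(n) < w_prior)
  resp <- theta_s
  if (any(use_prior)) {
    k <- sum(use_prior)
    if (variant %in% c("ADD_MODE", "ADD_MODE_P")) {
      side <- ifelse(circ_dist_deg(theta_s[use_prior], params$theta_p) <=
                       circ_dist_deg(theta_s[use_prior], -params$theta_p),
                     1, -1)
      resp[use_prior] <- side * params$theta_p
    } else {
      resp[use_prior] <- rprior_deg(k, params$theta_p, params$sigma_p)
    }
  }
  if (any(lapse)) {
    k <- sum(lapse)
    resp[lapse] <- if (variant %in% c("ADD_P", "ADD_MODE_P"))
      rprior_deg(k, params$theta_p, params$sigma_p)
    else stats::runif(k, -180, 180)
  }
  wrap_deg(resp + rvm_deg(n, 0, params$sigma_m))
}

#' Simulate a complete session from a parameterized observer
#'
#' Walks the schedule trial by trial: staircase luminances are updated from
#' the simulated detection outcomes; random-direction trials draw their
#' direction uniformly over the circle; estimation responses follow the
#' generative observer model (Bayesian posterior-mean observer with
#' prior-based or uniform lapses, or the ADD response strategy when
#' `params` is an [add_params()]); zero-contrast trials hallucinate at the
#' configured false-alarm rate and, when hallucinated, the estimate is
#' drawn from a prior-or-uniform mixture (plus motor noise); undetected
#' zero-contrast trials respond uniformly. Reaction times and response
#' omissions follow [rt_config()]. Deterministic given `seed`.
#'
#' @param schedule A `trial_schedule` from [generate_schedule()].
#' @param params A [bayes_params()] or [add_params()] object.
#' @param det A [detection_config()].
#' @param seed Integer seed.
#' @param variant Model variant used generatively (a Bayesian variant for
#'   `bayes_params`, an ADD variant for `add_params`).
#' @param rt An [rt_config()].
#' @param observer_id Identifier stored with the session.
#' @param step Grid spacing (degrees) for exact posterior-mean computation.
#' @param sigma_s_high Sensory width (degrees) on high-contrast trials: the
#'   clearly visible stimulus is sensed far more precisely than the
#'   near-threshold low-contrast one, which is what justifies estimating
#'   motor noise from high-contrast errors. ADD observers respond from the
#'   likelihood alone on high-contrast trials.
#' @return A `session_data` object: list with `trials` data.frame (columns
#'   trial_index, condition, direction_deg, is_random, luminance, detected,
#'   estimate_deg, rt_s), `observer_id`, `seed`, `params`, `variant`.
#' @export
simulate_session <- function(schedule, params, det = detection_config(),
                             seed = 1, variant = NULL, rt = rt_config(),
                             observer_id = "obs1", step = 1,
                             sigma_s_high = 3) {
  stopifnot(inherits(schedule, "trial_schedule"),
            inherits(params, "bayes_params"))
  is_add <- inherits(params, "add_params")
  if (is.null(variant)) variant <- if (is_add) "ADD" else "BAYES_P"
  if (is_add && !variant %in% ADD_VARIANTS)
    stop("add_params require an ADD variant, got ", variant)
  if (!is_add && !variant %in% BAYES_VARIANTS)
    stop("bayes_params require a Bayesian variant, got ", variant)
  if (!is_add && length(params$sigma_s) != sigma_s_length(variant))
    stop("sigma_s length does not match variant ", variant)

  set.seed(seed)
  cfg <- schedule$config
  tr <- schedule$trials
  n <- nrow(tr)
  sc <- list(
    "2_1" = staircase_state("two_up_one_down", cfg$staircase_start,
                            cfg$staircase_factor, cfg$luminance_min,
                            cfg$luminance_max),
    "4_1" = staircase_state("four_up_one_down", cfg$staircase_start,
                            cfg$staircase_factor, cfg$luminance_min,
                            cfg$luminance_max))

  direction <- tr$direction_deg
  direction[tr$is_random] <- wrap_deg(stats::runif(sum(tr$is_random),
                                                   -180, 180))
  luminance <- numeric(n)
  detected <- logical(n)

  for (i in seq_len(n)) {
    cond <- tr$condition[i]
    if (cond == "zero") {
      luminance[i] <- 0
      detected[i] <- stats::runif(1) < det$false_alarm_rate
    } else {
      lum <- if (cond == "high") cfg$high_luminance
             else sc[[tr$staircase_id[i]]]$level
      luminance[i] <- lum
      expected <- !tr$is_random[i] && !is.na(direction[i]) &&
        abs(direction[i]) == 32
      detected[i] <- stats::runif(1) < detect_prob(lum, det, expected)
      if (cond %in% c("low_2_1", "low_4_1"))
        sc[[tr$staircase_id[i]]] <-
          staircase_update(sc[[tr$staircase_id[i]]], detected[i])
    }
  }

  estimate <- rep(NA_real_, n)
  stim <- tr$condition != "zero"
  ss <- if (is_add) rep(params$sigma_s, sum(stim))
        else sigma_s_for(params, variant, direction[stim])
  is_high <- tr$condition[stim] == "high"
  ss[is_high] <- sigma_s_high
  estimate[stim] <- if (is_add)
    add_estimates(direction[stim], ss, params, variant,
                  w_prior = ifelse(is_high, 0, params$w_prior))
  else bayes_estimates(direction[stim], ss, params, step,
                       lapse_uniform = variant == "BAYES")

  # hallucinated estimates on detected zero-contrast trials; undetected
  # zero-contrast trials give an uninformed (uniform) bar placement
  zi <- which(!stim)
  if (length(zi)) {
    hall <- detected[zi]
    nh <- sum(hall)
    if (nh) {
      from_prior <- stats::runif(nh) < det$hallucination_prior_weight
      base <- ifelse(from_prior,
                     rprior_deg(nh, params$theta_p, params$sigma_p),
                     stats::runif(nh, -180, 180))
      estimate[zi[hall]] <- wrap_deg(base + rvm_deg(nh, 0, params$sigma_m))
    }
    nu <- sum(!hall)
    if (nu) estimate[zi[!hall]] <- wrap_deg(stats::runif(nu, -180, 180))
  }

  expected32 <- !is.na(direction) & !tr$is_random & abs(direction) == 32
  rt_s <- stats::rlnorm(n, rt$rt_meanlog +
                          ifelse(expected32, rt$rt_shift_expected, 0),
                        rt$rt_sdlog)
  omit <- stats::runif(n) < rt$omission_rate
  estimate[omit] <- NA_real_
  rt_s[omit] <- NA_real_

  trials <- data.frame(
    trial_index = tr$trial_index, condition = tr$condition,
    direction_deg = direction, is_random = tr$is_random,
    luminance = luminance, detected = detected,
    estimate_deg = estimate, rt_s = rt_s, stringsAsFactors = FALSE)
  structure(list(trials = trials, observer_id = observer_id, seed = seed,
                 params = params, variant = variant),
            class = "session_data")
}

#' @export
print.session_data <- function(x, ...) {
  cat("session_data:", nrow(x$trials), "trials, observer", x$observer_id,
      ", variant", x$variant, ", seed", x$seed, "\n")
  invisible(x)
}

#' Write / read one session as CSV
#'
#' One row per trial; missing values (no stimulus direction, no estimate,
#' no RT) are written as empty strings. Columns: trial_index, condition,
#' direction_deg ("RANDOM"-drawn values are written as their numeric draw),
#' is_random, luminance, detected, estimate_deg, rt_s, observer_id, seed.
#'
#' @param session A `session_data`.
#' @param path CSV path.
#' @return `path` invisibly (write); a `session_data` (read; `params` and
#'   `variant` are not round-tripped).
#' @export
write_session <- function(session, path) {
  tr <- session$trials
  tr$observer_id <- session$observer_id
  tr$seed <- session$seed
  utils::write.csv(tr, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_index", "condition", "direction_deg", "is_random",
            "luminance", "detected", "estimate_deg", "rt_s")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("session file ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  obs <- if ("observer_id" %in% names(raw)) raw$observer_id[1] else basename(path)
  seed <- if ("seed" %in% names(raw)) raw$seed[1] else NA_integer_
  structure(list(trials = raw[need], observer_id = obs, seed = seed,
                 params = NULL, variant = NA_character_),
            class = "session_data")
}
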