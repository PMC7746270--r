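#' Task design configuration
#'
#' Defaults reproduce the motion-estimation task: 567 trials over four
#' randomly interleaved contrast conditions — 167 zero-contrast (no
#' stimulus), 90 low-contrast trials on a 2-up/1-down luminance staircase,
#' 243 low-contrast trials on a 4-up/1-down staircase, and 67 high-contrast
#' trials at 1.76 cd/m2 above background. Stimulus directions relative to a
#' central reference: +/-32 deg on 58% of stimulus trials, the other
#' predetermined directions (0, +/-16, +/-48, +/-64) on 36%, and fully
#' random directions on 6%.
#'
#' @param n_zero,n_low_2_1,n_low_4_1,n_high Trial counts per condition.
#' @param pct_32,pct_other,pct_random Direction allocation percentages over
#'   stimulus (non-zero-contrast) trials; must sum to 100.
#' @param reference_deg Central reference angle; directions are stored
#'   relative to it, so it only rotates the frame.
#' @param staircase_start Starting luminance of both staircases (cd/m2
#'   above background).
#' @param staircase_factor Multiplicative step on luminance (> 1).
#' @param luminance_min,luminance_max Staircase clamp bounds (cd/m2).
#' @param high_luminance Luminance of high-contrast trials (cd/m2).
#' @return A `task_config` list.
#' @export
task_config <- function(n_zero = 167, n_low_2_1 = 90, n_low_4_1 = 243,
                        n_high = 67, pct_32 = 58, pct_other = 36,
                        pct_random = 6, reference_deg = 0,
                        staircase_start = 1.0, staircase_factor = 1.2,
                        luminance_min = 0.01, luminance_max = 1.76,
                        high_luminance = 1.76) {
  cfg <- list(n_zero = n_zero, n_low_2_1 = n_low_2_1, n_low_4_1 = n_low_4_1,
              n_high = n_high, pct_32 = pct_32, pct_other = pct_other,
              pct_random = pct_random, reference_deg = reference_deg,
              staircase_start = staircase_start,
              staircase_factor = staircase_factor,
              luminance_min = luminance_min, luminance_max = luminance_max,
              high_luminance = high_luminance)
  validate_task_config(cfg)
  structure(cfg, class = "task_config")
}

validate_task_config <- function(cfg) {
  counts <- c(cfg$n_zero, cfg$n_low_2_1, cfg$n_low_4_1, cfg$n_high)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("trial counts must be nonnegative integers")
  if (cfg$n_low_2_1 + cfg$n_low_4_1 + cfg$n_high < 1)
    stop("at least one stimulus trial is required")
  pct <- c(cfg$pct_32, cfg$pct_other, cfg$pct_random)
  if (any(pct < 0) || abs(sum(pct) - 100) > 1e-9)
    stop("direction percentages must be nonnegative and sum to 100")
  if (cfg$staircase_factor <= 1) stop("staircase_factor must exceed 1")
  if (cfg$luminance_min <= 0 || cfg$luminance_max <= cfg$luminance_min)
    stop("luminance bounds must satisfy 0 < min < max")
  invisible(cfg)
}

# exact-count direction pool over the stimulus trials: +/-32 gets pct_32
# split evenly by sign, pct_random trials are marked random, and the
# remaining trials spread as evenly as possible over the 7 other
# predetermined directions, remainder assigned by seeded draw
direction_pool <- function(cfg, n_stim) {
  n32 <- round(cfg$pct_32 / 100 * n_stim)
  nrand <- round(cfg$pct_random / 100 * n_stim)
  nother <- n_stim - n32 - nrand
  if (nother < 0) stop("direction percentages inconsistent with trial counts")
  others <- c(0, 16, -16, 48, -48, 64, -64)
  base <- nother %/% length(others)
  rem <- nother %% length(others)
  counts <- rep(base, length(others))
  if (rem > 0) {
    extra <- sample(seq_along(others), rem)
    counts[extra] <- counts[extra] + 1L
  }
  dirs <- c(rep(32, ceiling(n32 / 2)), rep(-32, floor(n32 / 2)),
            rep(others, counts))
  is_rand <- c(rep(FALSE, length(dirs)), rep(TRUE, nrand))
  list(direction = c(dirs, rep(NA_real_, nrand)), random = is_rand)
}

#' Generate a trial schedule
#'
#' Builds the full randomized trial sequence for one session: contrast
#' conditions interleaved at random, directions allocated with exact counts
#' (58% at +/-32 split evenly by sign, 6% random-direction markers, the
#' rest spread as evenly as possible over the other predetermined
#' directions). Deterministic given `seed`.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; the same seed reproduces the schedule exactly.
#' @return A `trial_schedule`: list with `trials` (data.frame with columns
#'   trial_index, condition, direction_deg, is_random, staircase_id),
#'   `seed`, and `config`. `direction_deg` is NA on zero-contrast trials and
#'   on random-direction trials (drawn at simulation time).
#' @export
generate_schedule <- function(config = task_config(), seed = 1) {
  validate_task_config(config)
  set.seed(seed)
  cond <- c(rep("zero", config$n_zero),
            rep("low_2_1", config$n_low_2_1),
            rep("low_4_1", config$n_low_4_1),
            rep("high", config$n_high))
  cond <- sample(cond)
  n_stim <- sum(cond != "zero")
  pool <- direction_pool(config, n_stim)
  ord <- sample.int(n_stim)
  direction <- rep(NA_real_, length(cond))
  is_random <- rep(FALSE, length(cond))
  stim_idx <- which(cond != "zero")
  direction[stim_idx] <- pool$direction[ord]
  is_random[stim_idx] <- pool$random[ord]
  trials <- data.frame(
    trial_index = seq_along(cond),
    condition = cond,
    direction_deg = direction,
    is_random = is_random,
    staircase_id = ifelse(cond == "low_2_1", "2_1",
                          ifelse(cond == "low_4_1", "4_1", "")),
    stringsAsFactors = FALSE
  )
  structure(list(trials = trials, seed = seed, config = config),
            class = "trial_schedule")
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat("trial_schedule:", nrow(x$trials), "trials, seed", x$seed, "\n")
  print(table(x$trials$condition))
  invisible(x)
}

#' Write / read a schedule as CSV
#'
#' Columns: trial_index, condition, direction_deg (empty on zero-contrast
#' trials, the marker "RANDOM" on random-direction trials), staircase_id.
#'
#' @param schedule A `trial_schedule`.
#' @param path Output CSV path.
#' @return `path`, invisibly (for `write_schedule`); a trials data.frame as
#'   in [generate_schedule()] (for `read_schedule`).
#' @export
write_schedule <- function(schedule, path) {
  tr <- schedule$trials
  dir_col <- ifelse(tr$is_random, "RANDOM",
                    ifelse(is.na(tr$direction_deg), "",
                           format(tr$direction_deg, trim = TRUE)))
  out <- data.frame(trial_index = tr$trial_index, condition = tr$condition,
                    direction_deg = dir_col, staircase_id = tr$staircase_id,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(direction_deg = "character",
                                        staircase_id = "character"))
  need <- c("trial_index", "condition", "direction_deg", "staircase_id")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("schedule file ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  is_random <- raw$direction_deg == "RANDOM"
  direction <- suppressWarnings(as.numeric(raw$direction_deg))
  direction[is_random] <- NA_real_
  data.frame(trial_index = raw$trial_index, condition = raw$condition,
             direction_deg = direction, is_random = is_random,
             staircase_id = raw$staircase_id, stringsAsFactors = FALSE)
}

#' Adaptive luminance staircase
#'
#' n-up/1-down rule on a multiplicative luminance scale: the level is
#' divided by `factor` after `n_down` consecutive correct detections
#' (2 for the 2/1 rule, 4 for the 4/1 rule) and multiplied by `factor`
#' after any single incorrect detection. Levels are clamped to
#' `[lum_min, lum_max]`.
#'
#' @param rule "two_up_one_down" or "four_up_one_down".
#' @param level Starting luminance (> 0).
#' @param factor Multiplicative step (> 1).
#' @param lum_min,lum_max Clamp bounds.
#' @return A `staircase_state` list with fields `rule`, `level`, `factor`,
#'   `bounds`, `n_down`, `run` (current correct run length) and `history`
#'   (data.frame of level and outcome per update).
#' @export
staircase_state <- function(rule = c("two_up_one_down", "four_up_one_down"),
                            level = 1.0, factor = 1.2,
                            lum_min = 0.01, lum_max = 1.76) {
  rule <- match.arg(rule)
  stopifnot(level > 0, factor > 1, lum_min > 0, lum_max > lum_min)
  structure(list(rule = rule,
                 level = min(max(level, lum_min), lum_max),
                 factor = factor, bounds = c(lum_min, lum_max),
                 n_down = if (rule == "two_up_one_down") 2L else 4L,
                 run = 0L,
                 history = data.frame(level = numeric(0),
                                      correct = logical(0))),
            class = "staircase_state")
}

#' Update a staircase after one detection outcome
#'
#' @param state A [staircase_state()].
#' @param detected_correctly Logical: was the stimulus detected?
#' @return The updated `staircase_state`.
#' @export
staircase_update <- function(state, detected_correctly) {
  stopifnot(inherits(state, "staircase_state"),
            is.logical(detected_correctly), length(detected_correctly) == 1)
  state$history <- rbind(state$history,
                         data.frame(level = state$level,
                                    correct = detected_correctly))
  if (!detected_correctly) {
    state$level <- state$level * state$factor
    state$run <- 0L
  } else {
    state$run <- state$run + 1L
    if (state$run >= state$n_down) {
      state$level <- state$level / state$factor
      state$run <- 0L
    }
  }
  state$level <- min(max(state$level, state$bounds[1]), state$bounds[2])
  state
}
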