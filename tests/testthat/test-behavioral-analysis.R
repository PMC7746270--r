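test_that("QC filter applies the documented inclusion thresholds", {
  n <- 80
  perfect <- make_session(data.frame(
    condition = rep(c("high", "low_2_1"), each = n),
    direction_deg = rep(c(32, -16), each = n),
    estimate_deg = rep(c(32, -16), each = n),
    detected = TRUE))
  expect_true(qc_filter(perfect)$pass)

  bad_det <- perfect
  bad_det$trials$detected[seq_len(n)] <- rep(c(TRUE, TRUE, TRUE, FALSE),
                                             n / 4)  # 75%... then lower
  bad_det$trials$detected[1:32] <- FALSE  # 60% high-contrast detection
  r <- qc_filter(bad_det)
  expect_false(r$pass)
  expect_false(r$criteria$pass[r$criteria$name == "high_detection"])

  # RMSE computed identically to the direct formula on the same records
  set.seed(3)
  noisy <- make_session(data.frame(
    condition = rep(c("high", "low_2_1"), each = n),
    direction_deg = 0,
    estimate_deg = wrap_deg(c(rvm_deg(n, 0, 45) + rvm_deg(n, 0, 20),
                              rvm_deg(n, 0, 30))),
    detected = TRUE))
  r <- qc_filter(noisy)
  hi_err <- noisy$trials$estimate_deg[1:n]
  expect_equal(r$criteria$value[r$criteria$name == "high_rmse"],
               sqrt(mean(wrap_deg(hi_err)^2)))
  # low-contrast detection below half fails
  half <- perfect
  half$trials$detected[(n + 1):(2 * n)] <- rep(c(TRUE, FALSE, FALSE, FALSE),
                                               n / 4)
  expect_false(qc_filter(half)$pass)
})

test_that("mixture fit recovers location, width and lapse proportion", {
  set.seed(11)
  draws <- rvm_deg(5000, 5, 15)
  f <- fit_vm_mixture(draws)
  expect_lt(abs(f$mu - 5), 1)
  expect_lt(abs(f$sigma - 15) / 15, 0.1)
  expect_lt(f$alpha, 0.02)
  expect_true(f$converged)

  # pure-lapse data: the lapse component dominates, and the fitted density
  # is essentially flat (a near-maximal-width von Mises can absorb sample
  # anisotropy, so alpha itself converges to a large but not extreme value)
  u <- runif(5000, -180, 180)
  fu <- fit_vm_mixture(u)
  expect_gte(fu$alpha, 0.8)
  dens <- (1 - fu$alpha) * vm_density(angle_grid(1), fu$mu, fu$sigma) +
    fu$alpha / (2 * pi)
  expect_lt(max(dens) / min(dens), 1.25)

  # 80/20 mixture
  mix <- c(rvm_deg(4000, 0, 20), runif(1000, -180, 180))
  fm <- fit_vm_mixture(mix)
  expect_lt(abs(fm$alpha - 0.2), 0.05)
  expect_error(fit_vm_mixture(rvm_deg(5, 0, 10)), "at least 10")
})

test_that("mixture fit bias shrinks as n grows", {
  errs <- sapply(c(200, 1000, 5000), function(n) {
    reps <- vapply(1:6, function(r) {
      set.seed(1000 * n + r)
      d <- c(rvm_deg(round(0.9 * n), 3, 18), runif(round(0.1 * n), -180, 180))
      f <- fit_vm_mixture(d)
      abs(f$mu - 3) + abs(f$sigma - 18) / 18 * 10 + abs(f$alpha - 0.1) * 50
    }, numeric(1))
    mean(reps)
  })
  expect_lt(errs[3], errs[1])
})

test_that("direction stats fold, filter and order the magnitudes", {
  p <- bayes_params(32, 15, 25, 0.1, 8)
  sess <- simulate_session(default_schedule(), p, seed = 31)
  ds <- direction_stats(sess)
  expect_equal(ds$magnitude, c(0, 16, 32, 48, 64))
  expect_true(all(ds$detection_rate >= 0 & ds$detection_rate <= 1))
  # attraction stronger at 64 than at 48 in this regime
  expect_gt(ds$bias_toward_32[ds$magnitude == 64],
            ds$bias_toward_32[ds$magnitude == 48])
  expect_gt(ds$bias_toward_32[ds$magnitude == 64], 0)

  # mirrored session: negate all angles; stats at signed magnitudes are
  # identical (magnitude 0 flips its bias sign, as folding cannot orient it)
  mir <- sess
  mir$trials$direction_deg <- -mir$trials$direction_deg
  mir$trials$estimate_deg <- wrap_deg(-mir$trials$estimate_deg)
  dm <- direction_stats(mir)
  sel <- ds$magnitude > 0
  expect_equal(dm$bias_deg[sel], ds$bias_deg[sel], tolerance = 1e-4)
  expect_equal(dm$variability_deg, ds$variability_deg, tolerance = 1e-4)
  expect_equal(abs(dm$bias_deg[1]), abs(ds$bias_deg[1]), tolerance = 1e-3)

  # flat prior, no lapses: no attraction anywhere
  p0 <- bayes_params(32, 1e4, 10, 0, 5)
  s0 <- simulate_session(default_schedule(), p0, seed = 32)
  d0 <- direction_stats(s0)
  expect_true(all(abs(d0$bias_deg[d0$fitted]) < 3.5))

  # strata below the minimum count are flagged, not fitted
  small <- sess
  keep <- abs(small$trials$direction_deg) != 64 |
    is.na(small$trials$direction_deg) |
    seq_len(nrow(small$trials)) %in%
      which(abs(small$trials$direction_deg) == 64)[1:5]
  small$trials$estimate_deg[abs(small$trials$direction_deg) == 64 &
                              !is.na(small$trials$direction_deg)] <- NA
  dsm <- direction_stats(small)
  expect_false(dsm$fitted[dsm$magnitude == 64])
  expect_true(is.na(dsm$bias_deg[dsm$magnitude == 64]))
})

test_that("p_ratio implements the 11-bin probability ratio", {
  centers <- (seq_len(11) - 6) * 32
  uniform <- rep(centers, each = 7)
  r <- p_ratio(uniform)
  expect_equal(r$p_ratio, 1, tolerance = 1e-12)
  expect_equal(r$n_bins, 11)
  # all estimates within 16 degrees of +/-32
  allin <- c(rep(32, 10), rep(-32, 14), 20, -44)
  expect_equal(p_ratio(allin)$p_ratio, 5.5, tolerance = 1e-12)
  # none near the modes
  expect_equal(p_ratio(c(0, 80, -90, 150))$p_ratio, 0)
  # empty input flagged undefined, not zero
  e <- p_ratio(numeric(0))
  expect_true(e$undefined); expect_true(is.na(e$p_ratio))
  # estimates beyond the covered 352-degree span join the nearest bin
  expect_equal(sum(p_ratio(c(179, -178))$bin_counts), 2)
  expect_error(p_ratio(1:20, n_bins = 4), "odd")
})

test_that("analytic and sampled p_ratio agree for an arbitrary grid", {
  p <- bayes_params(32, 12, 18, 0.15, 8)
  g <- response_distribution(16, p, "BAYES_P")
  m <- grid_bin_masses(g, c(-48, -16, 16, 48))
  analytic <- mean(c(m[1], m[3])) * 11
  set.seed(44)
  n <- 40000
  draws <- sample_response_grid(n, g)
  mc <- p_ratio(draws)$p_ratio
  se <- sqrt(analytic / 11 * (1 - analytic / 11) / n) * 11
  expect_lt(abs(mc - analytic), 3 * se)
})

test_that("learning dynamics windows summarize stationarity faithfully", {
  p <- bayes_params()
  sess <- simulate_session(default_schedule(), p, seed = 55)
  ld <- learning_dynamics(sess, window = 110, step = 55)
  expect_equal(ld$window_start, seq(1, 567 - 110 + 1, by = 55))
  expect_true(all(ld$window_end - ld$window_start == 109))

  # single window equals the whole-session summary
  one <- learning_dynamics(sess, window = 567, step = 567)
  expect_equal(nrow(one), 1)
  tr <- sess$trials
  lo <- tr[tr$condition %in% c("low_2_1", "low_4_1") & !tr$is_random &
             !is.na(tr$direction_deg), ]
  is32 <- abs(lo$direction_deg) == 32
  expect_equal(one$detection_32, mean(lo$detected[is32]))
  expect_error(learning_dynamics(sess, window = 1000), "window exceeds")

  # flat-prior, lapse-free observer: attraction index near zero throughout
  p0 <- bayes_params(32, 1e4, 10, 0, 5)
  s0 <- simulate_session(default_schedule(), p0, seed = 56)
  ld0 <- learning_dynamics(s0)
  expect_lt(max(abs(ld0$attraction_bias), na.rm = TRUE), 6)
})

test_that("stationary observers show no trend in windowed bias", {
  # the generative prior is static, so the windowed attraction series must
  # be flat; pooled regression of bias on window index across sessions
  p <- bayes_params()
  rows <- list()
  for (r in 1:30) {
    sess <- simulate_session(default_schedule(seed = 101), p,
                             seed = 700 + r)
    ld <- learning_dynamics(sess)
    rows[[r]] <- data.frame(idx = seq_len(nrow(ld)),
                            bias = ld$attraction_bias)
  }
  d <- do.call(rbind, rows)
  fit <- stats::lm(bias ~ idx, data = d)
  expect_gt(summary(fit)$coefficients["idx", "Pr(>|t|)"], 0.05)
})
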