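test_that("von Mises density is unimodal, normalized and matches quadrature", {
  g <- angle_grid(1)
  expect_gt(vm_density(0, 0, 20), vm_density(180, 0, 20))
  expect_equal(sum(vm_density(g, 10, 20)) * pi / 180, 1, tolerance = 1e-6)
  expect_error(vm_density(0, 0, -1), "positive")
  # peak height against independent quadrature of the kappa-form kernel
  kappa <- 1 / (20 * pi / 180)^2
  z <- stats::integrate(function(t) exp(kappa * cos(t)), -pi, pi,
                        rel.tol = 1e-10)$value
  expect_equal(vm_density(0, 0, 20), exp(kappa) / z, tolerance = 1e-8)
  # symmetry about mu
  expect_equal(vm_density(37 + 13, 37, 25), vm_density(37 - 13, 37, 25))
})

test_that("von Mises sampler matches the density", {
  set.seed(5)
  n <- 2e5
  x <- rvm_deg(n, 40, 22)
  expect_true(all(x >= -180 & x < 180))
  # Kolmogorov-Smirnov against a quadrature CDF
  th <- seq(-180, 180, by = 0.01)
  cdf <- cumsum(vm_density(th, 40, 22)) * 0.01 * pi / 180
  cdf <- cdf / max(cdf)
  ks <- max(abs(stats::approx(th, cdf, sort(x))$y - seq_len(n) / n))
  expect_lt(ks, 1.95 / sqrt(n))  # 0.001-level critical value
  # mean resultant length against the Bessel ratio
  kap <- 1 / (22 * pi / 180)^2
  expect_equal(mean(cos((x - 40) * pi / 180)),
               besselI(kap, 1, TRUE) / besselI(kap, 0, TRUE),
               tolerance = 2e-3)
})

test_that("bimodal prior has the documented shape", {
  expect_equal(prior_density(32, 32, 10), prior_density(-32, 32, 10))
  th <- seq(-180, 179.5, by = 0.5)
  d <- prior_density(th, 32, 10)
  # mode locations by grid argmax
  ord <- order(d, decreasing = TRUE)
  top2 <- sort(th[ord[1:2]])
  expect_equal(top2, c(-32, 32))
  # flat-prior limit
  dflat <- prior_density(th, 32, 1e4)
  expect_lt(max(dflat) / min(dflat), 1 + 1e-3)
  # symmetry under reflection
  expect_equal(prior_density(th, 32, 10), rev(prior_density(-rev(th), 32, 10)))
})

test_that("posterior mean interpolates between likelihood and prior mode", {
  flat <- bayes_params(32, 1e4, 20, 0, 8)
  expect_equal(posterior_mean(17, flat), 17, tolerance = 0.1)
  # a sensed direction at a prior mode stays put when the widths are
  # narrow; with broader noise the bimodal prior skews the posterior mean
  # slightly toward the saddle at 0, so only approximate equality holds
  expect_equal(posterior_mean(32, bayes_params(32, 10, 10, 0, 8)), 32,
               tolerance = 0.3)
  expect_equal(posterior_mean(32, bayes_params(32, 15, 20, 0, 8)), 32,
               tolerance = 2.5)
  p <- bayes_params(32, 15, 20, 0, 8)
  pm <- posterior_mean(64, p)
  expect_gt(pm, 32); expect_lt(pm, 64)
  # brute-force fine-grid oracle
  th <- seq(-180, 180 - 0.1, by = 0.1)
  post <- vm_density(64, th, 20) * prior_density(th, 32, 15)
  oracle <- circ_mean_deg(th, post)
  expect_equal(posterior_mean(64, p, step = 0.1), oracle, tolerance = 1e-8)
  expect_equal(pm, oracle, tolerance = 0.05)
})

test_that("pure-lapse and noiseless limits of the response distribution", {
  # alpha_p = 1: distribution is prior (x) motor noise, independent of
  # the presented direction
  p1 <- bayes_params(32, 15, 25, 1, 8)
  g1 <- response_distribution(48, p1, "BAYES_P")
  g2 <- response_distribution(-16, p1, "BAYES_P")
  expect_equal(g1$density, g2$density, tolerance = 1e-10)
  conv <- motionprior:::prior_motor_density(g1$angles, 32, 15, 8)
  expect_equal(g1$density, conv / (sum(conv) * pi / 180), tolerance = 1e-8)
  # near-noiseless veridical limit: mass concentrates at theta_act
  p0 <- bayes_params(32, 2000, 0.5, 0, 0.5)
  g0 <- response_distribution(48, p0, "BAYES_P")
  expect_equal(grid_circ_mean(g0), 48, tolerance = 0.05)
  m <- sum(g0$density[abs(wrap_deg(g0$angles - 48)) <= 2]) * pi / 180
  expect_gt(m, 0.999)
})

test_that("response distribution equals the forward-simulation oracle", {
  p <- bayes_params(32, 15, 25, 0.1, 10)
  g <- response_distribution(48, p, "BAYES_P")
  expect_gt(wrap_deg(48 - grid_circ_mean(g)), 0)  # shifted toward 32
  set.seed(31)
  draws <- simulate_responses_mc(2e5, 48, p)
  expect_grid_matches_mc(g, draws, z = 4)
})

test_that("response grids normalize across a broad random parameter sweep", {
  set.seed(8)
  for (i in 1:25) {
    p <- bayes_params(runif(1, 5, 80), runif(1, 2, 120), runif(1, 2, 80),
                      runif(1, 0, 0.5), runif(1, 2, 20))
    v <- sample(c("BAYES", "BAYES_P"), 1)
    g <- response_distribution(runif(1, -180, 180), p, v)
    expect_equal(sum(g$density) * pi / 180, 1, tolerance = 1e-6)
    expect_true(all(g$density >= 0))
  }
})

test_that("responses are attracted toward the 32-degree prior mode", {
  # attraction is measured with the same statistic the behavioral analysis
  # uses: the location of a von Mises + uniform mixture fitted to the
  # response distribution. (The raw circular mean of the full distribution
  # is not a clean attraction measure: under broad sensory noise percepts
  # leak across the prior saddle at 0 to the contralateral mode, dragging
  # the mean outside the stimulus-to-mode interval.)
  # sigma_p is kept below ~25: with a near-flat prior the attraction at the
  # inner 16-degree direction is smaller than the residual contralateral
  # leakage and the effect direction is no longer defined
  set.seed(21)
  for (i in 1:6) {
    p <- bayes_params(32, runif(1, 4, 25), runif(1, 6, 14), 0,
                      runif(1, 4, 12))
    for (act in c(16, 48, 64)) {
      m <- grid_mixture_stats(response_distribution(act, p, "BAYES_P"))["mu"]
      lo <- min(act, 32); hi <- max(act, 32)
      expect_gt(m, lo - 1e-6); expect_lt(m, hi + 1e-6)
      expect_gt(abs(m - act), 1e-2)  # strictly pulled away from act
    }
    m32 <- grid_mixture_stats(response_distribution(32, p, "BAYES_P"))["mu"]
    expect_equal(unname(m32), 32, tolerance = 2)
  }
})

test_that("response distributions mirror under stimulus reflection", {
  p <- bayes_params(32, 15, 25, 0.12, 8)
  pv <- bayes_params(32, 15, c(20, 25, 18, 30, 35), 0.12, 8)
  pa <- add_params(32, 15, 25, 0.1, 8, 0.4)
  cases <- list(list(p, "BAYES"), list(p, "BAYES_P"), list(pv, "BAYES_var"))
  mirror <- function(g) {
    # density at -angle, respecting the half-open grid
    idx <- match(wrap_deg(-g$angles), g$angles)
    g$density[idx]
  }
  for (cs in cases) {
    gp <- response_distribution(48, cs[[1]], cs[[2]])
    gm <- response_distribution(-48, cs[[1]], cs[[2]])
    expect_equal(gm$density, mirror(gp), tolerance = 1e-9)
  }
  for (v in c("ADD", "ADD_P", "ADD_MODE", "ADD_MODE_P")) {
    gp <- add_response_distribution(48, pa, v)
    gm <- add_response_distribution(-48, pa, v)
    expect_equal(gm$density, mirror(gp), tolerance = 1e-9)
  }
})

test_that("halving the grid spacing barely moves the circular mean", {
  p <- bayes_params(32, 15, 25, 0.1, 8)
  m1 <- grid_circ_mean(response_distribution(48, p, "BAYES_P", step = 1))
  m2 <- grid_circ_mean(response_distribution(48, p, "BAYES_P", step = 0.5))
  expect_lt(abs(wrap_deg(m1 - m2)), 0.05)
})

test_that("BAYES_var with equal widths collapses to BAYES_P", {
  pv <- bayes_params(32, 15, rep(25, 5), 0.1, 8)
  ps <- bayes_params(32, 15, 25, 0.1, 8)
  for (act in c(0, 16, 48)) {
    gv <- response_distribution(act, pv, "BAYES_var")
    gs <- response_distribution(act, ps, "BAYES_P")
    expect_lt(max(abs(gv$density - gs$density)), 1e-9)
  }
  # varmin routes the expected-direction width only to +/-32
  pm <- bayes_params(32, 15, c(10, 40), 0.1, 8)
  g32 <- response_distribution(32, pm, "BAYES_varmin")
  gref <- response_distribution(32, bayes_params(32, 15, 10, 0.1, 8),
                                "BAYES_P")
  expect_lt(max(abs(g32$density - gref$density)), 1e-9)
})

test_that("variant/parameter dimensionality mismatches are errors", {
  p <- bayes_params(32, 15, 25, 0.1, 8)
  expect_error(response_distribution(48, p, "BAYES_var"), "length")
  expect_error(bayes_params(sigma_s = c(1, 2, 3)))
  expect_error(bayes_params(alpha_p = 1.2))
  expect_error(bayes_params(theta_p = 0))
})

test_that("ADD response distribution limits and MC equivalence", {
  grid <- angle_grid(1)
  # w_prior = 0: likelihood (x) motor noise
  p0 <- add_params(32, 15, 25, 0, 8, w_prior = 0)
  g0 <- add_response_distribution(48, p0, "ADD")
  idx <- motionprior:::circulant_idx_cached(length(grid))
  Km <- matrix(vm_density(grid, 0, 8)[idx], length(grid))
  ref <- as.vector(Km %*% (vm_density(grid, 48, 25) * pi / 180))
  expect_equal(g0$density, ref / (sum(ref) * pi / 180), tolerance = 1e-8)
  # w_prior = 1: bimodal with modes at +/-32
  p1 <- add_params(32, 10, 25, 0, 4, w_prior = 1)
  g1 <- add_response_distribution(10, p1, "ADD")
  d <- g1$density
  top2 <- sort(g1$angles[order(d, decreasing = TRUE)[1:2]])
  expect_equal(top2, c(-32, 32), tolerance = 2)
  # w_prior = 0.5 equals forward simulation
  ph <- add_params(32, 15, 25, 0.05, 8, w_prior = 0.5)
  gh <- add_response_distribution(20, ph, "ADD")
  set.seed(77)
  n <- 2e5
  ts <- rvm_deg(n, 20, 25)
  u <- runif(n); lap <- u < 0.05
  use_prior <- !lap & runif(n) < 0.5
  resp <- ts
  resp[use_prior] <- motionprior:::rprior_deg(sum(use_prior), 32, 15)
  resp[lap] <- runif(sum(lap), -180, 180)
  draws <- wrap_deg(resp + rvm_deg(n, 0, 8))
  expect_grid_matches_mc(gh, draws, z = 4)
})
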