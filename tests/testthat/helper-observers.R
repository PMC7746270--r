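# shared fixtures, built in code

# one default schedule reused across tests (schedules are deterministic)
default_schedule <- local({
  sched <- NULL
  function(seed = 101) {
    if (is.null(sched) || sched$seed != seed)
      sched <<- generate_schedule(task_config(), seed = seed)
    sched
  }
})

# the parameter regime the behavioral signatures are asserted in
regime_params <- function() bayes_params(theta_p = 32, sigma_p = 15,
                                         sigma_s = 25, alpha_p = 0.1,
                                         sigma_m = 8)

# minimal hand-built session around a trials data.frame
make_session <- function(trials, observer_id = "synthetic") {
  defaults <- list(is_random = FALSE, luminance = 1, detected = TRUE,
                   rt_s = 0.8)
  for (nm in names(defaults))
    if (is.null(trials[[nm]])) trials[[nm]] <- defaults[[nm]]
  if (is.null(trials$trial_index)) trials$trial_index <- seq_len(nrow(trials))
  structure(list(trials = trials, observer_id = observer_id, seed = NA,
                 params = NULL, variant = NA_character_),
            class = "session_data")
}

# forward Monte-Carlo simulation of the Bayesian observer's response
# process; the theta_s -> percept map is evaluated on a fine lookup grid so
# millions of draws stay cheap. Used as the sampling-based oracle for the
# grid-integration response distribution.
simulate_responses_mc <- function(n, theta_act, params, variant = "BAYES_P",
                                  lookup_step = 0.25) {
  ss <- motionprior:::sigma_s_for(params, variant, theta_act)
  theta_s <- rvm_deg(n, theta_act, ss)
  lap <- stats::runif(n) < params$alpha_p
  perc <- numeric(n)
  if (any(!lap)) {
    qs <- seq(-180, 180 - lookup_step, by = lookup_step)
    tab <- motionprior:::posterior_mean_vec(qs, params$theta_p,
                                            params$sigma_p, ss, step = 1)
    idx <- (round((theta_s[!lap] + 180) / lookup_step) %%
              length(qs)) + 1
    perc[!lap] <- tab[idx]
  }
  if (any(lap)) {
    k <- sum(lap)
    perc[lap] <- if (variant == "BAYES") stats::runif(k, -180, 180)
                 else motionprior:::rprior_deg(k, params$theta_p,
                                               params$sigma_p)
  }
  wrap_deg(perc + rvm_deg(n, 0, params$sigma_m))
}

# bin masses of a response grid over [break_i, break_{i+1}) windows, with a
# trapezoid edge correction so point densities at grid nodes line up with
# the half-open windows
grid_bin_masses <- function(g, breaks) {
  dth <- pi / 180 * g$step
  vapply(seq_len(length(breaks) - 1), function(i) {
    sel <- g$angles >= breaks[i] & g$angles < breaks[i + 1]
    ia <- match(wrap_deg(breaks[i]), g$angles)
    ib <- match(wrap_deg(breaks[i + 1]), g$angles)
    sum(g$density[sel]) * dth +
      0.5 * (g$density[ib] - g$density[ia]) * dth
  }, numeric(1))
}

# compare MC draws against a response_grid: circular mean and coarse-bin
# masses must agree within `z` binomial standard errors
expect_grid_matches_mc <- function(g, draws, z = 3) {
  n <- length(draws)
  width <- 24
  breaks <- seq(-180, 180, by = width)
  bins <- floor((wrap_deg(draws) + 180) / width) + 1
  mc_mass <- tabulate(bins, length(breaks) - 1) / n
  grid_mass <- grid_bin_masses(g, breaks)
  se <- sqrt(pmax(grid_mass * (1 - grid_mass), 1e-12) / n)
  expect_true(all(abs(mc_mass - grid_mass) <= z * se + 2e-4),
              label = paste0("binned mass within ", z, " SE of MC"))
  mc_mean <- circ_mean_deg(draws)
  # SE of the circular mean via the circular dispersion
  r <- draws * pi / 180
  R <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  se_mean <- (180 / pi) * sqrt((1 - R^2) / (n * R^2))
  expect_lt(abs(wrap_deg(mc_mean - grid_circ_mean(g))),
            max(z * se_mean, 0.2))
}

# von Mises + uniform mixture fitted to a response grid by weighted maximum
# likelihood: the deterministic analogue of the per-direction behavioral
# statistics (location = bias, width = variability, alpha = lapse mass)
grid_mixture_stats <- function(g) {
  mass <- g$density * pi / 180 * g$step
  nll <- function(par) {
    mu <- par[1]
    sigma <- 0.5 + 119.5 * stats::plogis(par[2])
    alpha <- stats::plogis(par[3])
    d <- (1 - alpha) * vm_density(g$angles, mu, sigma) + alpha / (2 * pi)
    -sum(mass * log(pmax(d, 1e-300)))
  }
  f <- stats::optim(c(grid_circ_mean(g), 0, stats::qlogis(0.1)), nll,
                    control = list(maxit = 800, reltol = 1e-12))
  c(mu = wrap_deg(f$par[1]), sigma = 0.5 + 119.5 * stats::plogis(f$par[2]),
    alpha = stats::plogis(f$par[3]))
}

# brute-force Monte-Carlo oracle for protected exceedance probabilities:
# samples model-frequency vectors from the Dirichlet(1) prior, weights them
# by the marginal likelihood of the log evidences, and mixes with the
# equal-frequency null by its posterior probability
pxp_mc_oracle <- function(bic_matrix, n_samples = 2e5, seed = 42) {
  lme <- -as.matrix(bic_matrix) / 2
  n <- nrow(lme); K <- ncol(lme)
  rowmax <- apply(lme, 1, max)
  m <- exp(lme - rowmax)                      # subjects x models
  set.seed(seed)
  r <- matrix(stats::rgamma(n_samples * K, 1), ncol = K)
  r <- r / rowSums(r)
  logw <- colSums(log(m %*% t(r)))           # sum over subjects per sample
  w <- exp(logw - max(logw))
  winner <- max.col(r, ties.method = "first")
  ep <- vapply(seq_len(K), function(k) sum(w[winner == k]) / sum(w),
               numeric(1))
  # evidence for H1 (frequencies vary) vs H0 (all equal)
  log_py_h1 <- log(mean(w)) + max(logw) + sum(rowmax)
  log_py_h0 <- sum(log(rowMeans(m))) + sum(rowmax)
  bor <- 1 / (1 + exp(log_py_h1 - log_py_h0))
  list(ep = ep, bor = bor, pxp = (1 - bor) * ep + bor / K)
}
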