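#' Observer-model parameter sets
#'
#' Parameters of the Bayesian observer: a bimodal learned prior with modes at
#' +/- `theta_p` and width `sigma_p`, a von Mises sensory likelihood of width
#' `sigma_s`, a lapse probability `alpha_p`, and a motor-noise width
#' `sigma_m` that is estimated separately and held fixed during fitting.
#'
#' `sigma_s` is a single width for the BAYES and BAYES_P variants, one width
#' per absolute stimulus direction magnitude (0, 16, 32, 48, 64 degrees; 5
#' values) for BAYES_var, and two widths (at the expected +/-32 directions
#' vs all others) for BAYES_varmin.
#'
#' @param theta_p Prior mode magnitude in degrees, in (0, 90].
#' @param sigma_p Prior width in degrees (> 0).
#' @param sigma_s Sensory width(s) in degrees (> 0); length 1, 2 or 5.
#' @param alpha_p Lapse probability in [0, 1].
#' @param sigma_m Motor-noise width in degrees (> 0).
#' @return An object of class `bayes_params`.
#' @export
bayes_params <- function(theta_p = 32, sigma_p = 15, sigma_s = 10,
                         alpha_p = 0.1, sigma_m = 8) {
  stopifnot(length(theta_p) == 1, theta_p > 0, theta_p <= 90,
            length(sigma_p) == 1, sigma_p > 0,
            length(sigma_s) %in% c(1L, 2L, 5L), all(sigma_s > 0),
            length(alpha_p) == 1, alpha_p >= 0, alpha_p <= 1,
            length(sigma_m) == 1, sigma_m > 0)
  structure(list(theta_p = theta_p, sigma_p = sigma_p, sigma_s = sigma_s,
                 alpha_p = alpha_p, sigma_m = sigma_m),
            class = "bayes_params")
}

#' Parameters of the non-integrative "ADD" response-strategy observer
#'
#' Same fields as [bayes_params()] plus `w_prior`, the per-trial probability
#' of responding from the prior alone rather than from the sensory
#' likelihood alone. The response distribution of this observer is a mixture
#' (a sum) of a prior-based component and a likelihood-based component, with
#' no Bayesian integration.
#'
#' @inheritParams bayes_params
#' @param w_prior Probability in [0, 1] of a prior-based response.
#' @return An object of class `add_params` (inherits `bayes_params`).
#' @export
add_params <- function(theta_p = 32, sigma_p = 15, sigma_s = 10,
                       alpha_p = 0.1, sigma_m = 8, w_prior = 0.3) {
  stopifnot(length(w_prior) == 1, w_prior >= 0, w_prior <= 1)
  p <- bayes_params(theta_p, sigma_p, sigma_s, alpha_p, sigma_m)
  p$w_prior <- w_prior
  class(p) <- c("add_params", "bayes_params")
  p
}

BAYES_VARIANTS <- c("BAYES", "BAYES_P", "BAYES_var", "BAYES_varmin")
ADD_VARIANTS <- c("ADD", "ADD_P", "ADD_MODE", "ADD_MODE_P")
DIRECTION_MAGNITUDES <- c(0, 16, 32, 48, 64)

# sigma_s dimensionality demanded by each Bayesian variant
sigma_s_length <- function(variant) {
  switch(variant,
         BAYES = 1L, BAYES_P = 1L, BAYES_varmin = 2L, BAYES_var = 5L,
         stop("unknown variant: ", variant))
}

# nearest predetermined direction magnitude for an arbitrary direction
nearest_magnitude <- function(theta_act) {
  m <- DIRECTION_MAGNITUDES
  m[apply(outer(abs(wrap_deg(theta_act)), m, function(a, b) abs(a - b)),
          1, which.min)]
}

# per-trial sensory width under a variant; random directions take the width
# of the nearest predetermined magnitude
sigma_s_for <- function(params, variant, theta_act) {
  ss <- params$sigma_s
  need <- sigma_s_length(variant)
  if (length(ss) != need)
    stop("variant ", variant, " needs sigma_s of length ", need,
         ", got ", length(ss))
  if (need == 1L) return(rep(ss, length(theta_act)))
  mag <- nearest_magnitude(theta_act)
  if (need == 2L) return(ifelse(mag == 32, ss[1], ss[2]))
  ss[match(mag, DIRECTION_MAGNITUDES)]
}

#' Bimodal learned prior over motion directions
#'
#' Equal-weight mixture of two von Mises densities centered at +theta_p and
#' -theta_p, each of width sigma_p. Density per radian.
#'
#' @param theta Angle(s) in degrees at which to evaluate.
#' @param theta_p Prior mode magnitude in degrees.
#' @param sigma_p Prior width in degrees (> 0).
#' @return Density values per radian.
#' @export
prior_density <- function(theta, theta_p, sigma_p) {
  0.5 * (vm_density(theta, -theta_p, sigma_p) +
           vm_density(theta, theta_p, sigma_p))
}

# draw directions from the bimodal prior
rprior_deg <- function(n, theta_p, sigma_p) {
  if (n == 0L) return(numeric(0))
  side <- sample(c(-1, 1), n, replace = TRUE)
  wrap_deg(side * theta_p + rvm_deg(n, 0, sigma_p))
}

# percept (posterior circular mean) for each sensed direction theta_s,
# vectorized; scalar sigma_s. Internal workhorse shared by posterior_mean(),
# response_distribution() and the session simulator.
posterior_mean_vec <- function(theta_s, theta_p, sigma_p, sigma_s, step = 1) {
  grid <- angle_grid(step)
  prior <- prior_density(grid, theta_p, sigma_p)
  # L[i, j] = likelihood of direction grid_i given sensed theta_s_j
  L <- vm_density(outer(grid, theta_s, "-"), 0, sigma_s)
  P <- prior * L
  tot <- colSums(P)
  if (any(!is.finite(tot)) || any(tot <= 0))
    stop("degenerate posterior: zero or non-finite mass on the grid ",
         "(theta_p=", theta_p, ", sigma_p=", sigma_p, ", sigma_s=", sigma_s, ")")
  gr <- deg2rad(grid)
  wrap_deg(rad2deg(atan2(colSums(P * sin(gr)), colSums(P * cos(gr)))))
}

#' Posterior-mean percept of the Bayesian observer
#'
#' Multiplies the sensory likelihood centered on the sensed direction
#' `theta_s` with the bimodal prior on a uniform angular grid, normalizes,
#' and returns the circular mean of the posterior: the modelled percept.
#'
#' @param theta_s Sensed direction(s) in degrees.
#' @param params A [bayes_params()] object with scalar `sigma_s`, unless
#'   `sigma_s` is supplied explicitly.
#' @param step Grid spacing in degrees (default 1).
#' @param sigma_s Optional scalar sensory width overriding `params$sigma_s`.
#' @return Percept direction(s) in degrees in [-180, 180).
#' @export
posterior_mean <- function(theta_s, params, step = 1, sigma_s = NULL) {
  if (is.null(sigma_s)) sigma_s <- params$sigma_s
  if (length(sigma_s) != 1L)
    stop("posterior_mean needs a scalar sigma_s; pass the per-direction ",
         "width explicitly for direction-dependent variants")
  posterior_mean_vec(theta_s, params$theta_p, params$sigma_p, sigma_s, step)
}

#' Discretized response distribution
#'
#' A density over a uniform angular grid covering [-180, 180). Densities are
#' per radian: `sum(density) * step_rad == 1`.
#'
#' @param angles Grid angles in degrees (from [angle_grid()]).
#' @param density Nonnegative densities per radian, normalized on creation.
#' @return An object of class `response_grid`.
#' @export
response_grid <- function(angles, density) {
  stopifnot(length(angles) == length(density), all(density >= -1e-12))
  step <- 360 / length(angles)
  density <- pmax(density, 0)
  density <- density / (sum(density) * deg2rad(step))
  structure(list(angles = angles, density = density, step = step),
            class = "response_grid")
}

#' @export
as.data.frame.response_grid <- function(x, ...) {
  data.frame(angle = x$angles, density = x$density)
}

#' @export
print.response_grid <- function(x, ...) {
  cat("response_grid:", length(x$angles), "angles, step", x$step,
      "deg, circular mean", round(grid_circ_mean(x), 2), "deg\n")
  invisible(x)
}

#' Circular mean of a response grid
#'
#' @param g A [response_grid()].
#' @return Mean direction in degrees.
#' @export
grid_circ_mean <- function(g) circ_mean_deg(g$angles, g$density)

#' Draw samples from a response grid
#'
#' Samples a grid bin by its probability mass and jitters uniformly within
#' the bin, giving continuous draws whose density is the piecewise-constant
#' grid density.
#'
#' @param n Number of draws.
#' @param g A [response_grid()].
#' @return `n` angles in degrees.
#' @export
sample_response_grid <- function(n, g) {
  idx <- sample.int(length(g$angles), n, replace = TRUE,
                    prob = g$density)
  wrap_deg(g$angles[idx] + stats::runif(n, -g$step / 2, g$step / 2))
}

# uniform circular density per radian
uniform_density <- function(n) rep(1 / (2 * pi), n)

# prior convolved with motor noise, as a density vector on the grid
# (circular convolution via FFT)
prior_motor_density <- function(grid, theta_p, sigma_p, sigma_m) {
  step <- 360 / length(grid)
  kern <- vm_density(grid, 0, sigma_m)
  mass <- prior_density(grid, theta_p, sigma_p) * deg2rad(step)
  n <- length(grid)
  # rotate the kernel so that index arithmetic in the cyclic convolution
  # lines up with the grid starting at -180
  kern <- kern[((seq_len(n) - 1 + n / 2) %% n) + 1]
  pmax(Re(stats::fft(stats::fft(mass) * stats::fft(kern),
                     inverse = TRUE)) / n, 0)
}

.mp_cache <- new.env(parent = emptyenv())

circulant_idx_cached <- function(n) {
  key <- as.character(n)
  if (is.null(.mp_cache[[key]])) .mp_cache[[key]] <- circulant_idx(n)
  .mp_cache[[key]]
}

# response densities for a batch of presented directions sharing one
# sensory width: matrix [grid angle, direction], columns normalized.
# Shares the percept lookup and motor kernel across directions, which is
# what makes likelihood evaluation affordable inside the fit loop.
response_density_matrix <- function(theta_acts, theta_p, sigma_p, sigma_s,
                                    alpha_p, sigma_m, lapse_dens, step = 1) {
  grid <- angle_grid(step)
  n <- length(grid)
  dth <- deg2rad(step)
  idx <- circulant_idx_cached(n)
  gr <- deg2rad(grid)
  # percept per sensed direction: posterior mean over the same grid,
  # exploiting that the likelihood kernel is circulant
  vml <- vm_density(grid, 0, sigma_s)
  L <- matrix(vml[idx], n)
  P <- prior_density(grid, theta_p, sigma_p) * L
  perc_rad <- atan2(crossprod(P, sin(gr)), crossprod(P, cos(gr)))[, 1]
  # motor kernel K[i, j] = vm(grid_i - perc_j, sigma_m) via the cosine
  # addition identity (avoids trig on an n x n matrix)
  kap <- kappa_from_sigma_deg(sigma_m)
  Cm <- cos(gr) %o% cos(perc_rad) + sin(gr) %o% sin(perc_rad)
  K <- exp(kap * (Cm - 1)) / (2 * pi * besselI(kap, 0, expon.scaled = TRUE))
  W <- vm_density(outer(grid, theta_acts, "-"), 0, sigma_s) * dth
  D <- (1 - alpha_p) * (K %*% W) + alpha_p * lapse_dens
  sweep(D, 2, colSums(D) * dth, "/")
}

#' Response distribution of a Bayesian observer variant
#'
#' Distribution of the estimation response given the presented direction
#' `theta_act`. On non-lapse trials the sensed direction is drawn from a von
#' Mises centered on `theta_act` with width sigma_s; the percept is the
#' posterior mean combining that sensed direction with the bimodal prior;
#' the response adds motor noise of width sigma_m. On lapse trials (rate
#' alpha_p) the response is drawn from the prior convolved with motor noise
#' (BAYES_P, BAYES_var, BAYES_varmin) or uniformly at random (BAYES).
#'
#' The direction-dependent variants pick the sensory width from the
#' magnitude of `theta_act`: one width per magnitude (BAYES_var) or one
#' width at +/-32 vs all others (BAYES_varmin).
#'
#' @param theta_act Presented direction in degrees (scalar).
#' @param params A [bayes_params()] with `sigma_s` length matching `variant`.
#' @param variant One of "BAYES", "BAYES_P", "BAYES_var", "BAYES_varmin".
#' @param step Grid spacing in degrees (default 1).
#' @return A [response_grid()].
#' @export
response_distribution <- function(theta_act, params,
                                  variant = c("BAYES_P", "BAYES",
                                              "BAYES_var", "BAYES_varmin"),
                                  step = 1) {
  variant <- match.arg(variant)
  stopifnot(length(theta_act) == 1)
  ss <- sigma_s_for(params, variant, theta_act)
  grid <- angle_grid(step)
  lapse <- if (variant == "BAYES") uniform_density(length(grid))
           else prior_motor_density(grid, params$theta_p, params$sigma_p,
                                    params$sigma_m)
  D <- response_density_matrix(theta_act, params$theta_p, params$sigma_p,
                               ss, params$alpha_p, params$sigma_m, lapse,
                               step)
  response_grid(grid, D[, 1])
}

#' Response distribution of an ADD-strategy observer
#'
#' Non-integrative strategy: on each (non-lapse) trial the observer responds
#' either from the prior (probability `w_prior`) or from the sensory
#' likelihood alone, each perturbed by motor noise, so the response
#' distribution is a weighted sum of a prior component and a likelihood
#' component. Four variants are implemented as canonical reconstructions of
#' this model class (the exact published forms are not fully specified):
#' the prior component is either a draw from the prior ("ADD", "ADD_P") or
#' the prior mode nearest the sensed direction ("ADD_MODE", "ADD_MODE_P");
#' lapses are uniform ("ADD", "ADD_MODE") or prior-based ("ADD_P",
#' "ADD_MODE_P").
#'
#' @param theta_act Presented direction in degrees (scalar).
#' @param params An [add_params()] object (scalar `sigma_s`).
#' @param variant One of "ADD", "ADD_P", "ADD_MODE", "ADD_MODE_P".
#' @param step Grid spacing in degrees.
#' @return A [response_grid()].
#' @export
add_response_distribution <- function(theta_act, params,
                                      variant = c("ADD", "ADD_P",
                                                  "ADD_MODE", "ADD_MODE_P"),
                                      step = 1) {
  variant <- match.arg(variant)
  stopifnot(inherits(params, "add_params"), length(theta_act) == 1,
            length(params$sigma_s) == 1)
  grid <- angle_grid(step)
  n <- length(grid)
  dth <- deg2rad(step)
  idx <- circulant_idx(n)
  motor <- matrix(vm_density(grid, 0, params$sigma_m)[idx], n)
  sens <- vm_density(grid, theta_act, params$sigma_s) * dth
  lik_comp <- as.vector(motor %*% sens)
  prior_smp <- prior_motor_density(grid, params$theta_p, params$sigma_p,
                                   params$sigma_m)
  prior_comp <- if (variant %in% c("ADD", "ADD_P")) {
    prior_smp
  } else {
    dplus <- circ_dist_deg(grid, params$theta_p)
    dminus <- circ_dist_deg(grid, -params$theta_p)
    wplus <- ifelse(dplus < dminus, 1, ifelse(dplus > dminus, 0, 0.5))
    qplus <- sum(sens * wplus)
    qplus * vm_density(grid, params$theta_p, params$sigma_m) +
      (1 - qplus) * vm_density(grid, -params$theta_p, params$sigma_m)
  }
  base <- params$w_prior * prior_comp + (1 - params$w_prior) * lik_comp
  lapse <- if (variant %in% c("ADD", "ADD_MODE")) uniform_density(n)
           else prior_smp
  response_grid(grid, (1 - params$alpha_p) * base + params$alpha_p * lapse)
}
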