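---
title: "Bayesian observer models of motion estimation under a learned bimodal prior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian observer models of motion estimation under a learned bimodal prior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motionprior)
```

## The task and the scientific question

`motionprior` implements the computational machinery of a visual
statistical-learning experiment. An observer watches a cloud of coherently
moving dots and (i) aligns a bar with the perceived motion direction
(estimation) and (ii) reports whether any dots were seen at all (detection).
Stimulus contrast is interleaved across four conditions — no stimulus at
all, two near-threshold levels controlled by adaptive luminance staircases,
and a clearly visible high-contrast level — and, unknown to the observer,
two directions (±32° around a reference) are presented far more often than
the rest. Observers implicitly learn this bimodal direction statistic and
acquire a *prior* that attracts their percepts toward ±32°, speeds their
reactions there, improves detection there, and even shapes what they report
on trials where nothing was shown ("hallucinations").

The package provides every stage needed to study this quantitatively on
synthetic data: the task design, generative observer models, a session
simulator, the behavioral summary statistics, maximum-likelihood model
fitting, and model comparison. No participant data ship with the package;
the session simulator is a first-class, tested module that plays the role
of the experiment.

## Generative observer models

On a trial with true direction $\theta_{act}$ the observer senses
$\theta_s \sim V(\theta_{act}, \sigma_s)$, a von Mises (circular normal)
draw. All widths $\sigma$ in the package are in degrees and map to the von
Mises concentration as $\kappa = 1/\sigma_{rad}^2$, the standard
Gaussian-approximation convention. The acquired prior is an equal mixture
of two von Mises densities at $\pm\theta_p$ with width $\sigma_p$:

$$p_{prior}(\theta) = \tfrac12\left[V(-\theta_p,\sigma_p) + V(\theta_p,\sigma_p)\right].$$

The percept is the circular mean of the posterior
$p(\theta\,|\,\theta_s) \propto V(\theta_s - \theta, \sigma_s)\,p_{prior}(\theta)$
(the arithmetic mean is ill-defined on the circle). On a fraction
$\alpha_p$ of trials the percept instead comes from a lapse — a draw from
the prior itself (model **BAYES_P**) or a uniform random direction
(**BAYES**). The response adds motor noise:
$\theta_{est} \sim V(\theta_{perc}, \sigma_m)$, with $\sigma_m$ estimated
from high-contrast trials and held fixed during fitting. Two further
variants let the sensory width depend on the stimulus: one width per
direction magnitude 0/16/32/48/64 (**BAYES_var**, 8 free parameters) or one
width at ±32 versus all others (**BAYES_varmin**, 5). BAYES_P and BAYES
have 4. The direction-dependent variants use prior-based lapses, so
BAYES_var with all widths equal collapses exactly onto BAYES_P (a tested
identity).

A non-integrative **ADD** class is included as a strategy control: with
probability `w_prior` the observer responds from the prior alone, otherwise
from the likelihood alone, so the response distribution is a weighted sum
of the two rather than their product. The published description of the four
ADD variations is not fully specified, so the four implemented forms
(prior-*sample* vs prior-*mode* response, crossed with uniform vs
prior-based lapses) are labeled canonical reconstructions and reported as
such.

### Numerical scheme

All densities live on a uniform 1° grid over $[-180°, 180°)$ (360 points);
the integral over the sensed direction is a discrete sum on the same grid
and convolutions are circular (FFT-based for the lapse term). Densities are
per radian, so `sum(density) * step_rad` is 1. The scheme is deterministic
and oracle-checkable: the test suite compares it against million-draw
forward simulation of the generative process (binned masses within 3
binomial standard errors) and halving the grid spacing moves the response
circular mean by less than 0.05°. Likelihood evaluation reads grid
densities at observed estimates by linear interpolation. Degenerate
posteriors (zero mass on the grid) raise an error rather than returning a
silent fallback.

A practical note on the circular mean: with broad sensory noise, sensed
directions occasionally fall on the far side of the prior's saddle at 0°
and are attracted to the *contralateral* mode. This drags the full
distribution's circular mean toward 0 and can push it outside the interval
between $\theta_{act}$ and 32°. Attraction is therefore quantified
throughout with the same statistic used for behavioral data — the location
parameter of a von Mises + uniform mixture fit — which tracks the
ipsilateral response lobe and is robust to the contralateral mass. For the
same reason the posterior mean at $\theta_s = \theta_p$ equals $\theta_p$
only in the narrow-noise limit.

## Task design and staircases

`generate_schedule()` reproduces the published design exactly: 567 trials
(167 zero-contrast, 90 on a 2-up/1-down staircase, 243 on a 4-up/1-down
staircase, 67 high-contrast at 1.76 cd/m² above background), randomly
interleaved under a seed. Direction allocation is exact-count rather than
Bernoulli, which makes the printed percentages exact and testable: 58% of
the 400 stimulus trials at ±32° (116 per sign), 6% (24 trials) at fully
random directions drawn at simulation time, and the remaining 144 spread as
evenly as possible over 0°, ±16°, ±48°, ±64° (20 each plus a seeded
4-trial remainder). The central reference angle only rotates the frame and
defaults to 0.

The staircases step multiplicatively on luminance (factor 1.2, clamped to
[0.01, 1.76] cd/m²): the level is divided by the factor after 2 (or 4)
consecutive detections and multiplied by it after any miss. The source
experiment does not state step sizes, starting levels or bounds; these
defaults are standard psychophysics practice and are explicit configuration
knobs, not inferred facts. Against an ideal observer whose detection is a
fixed logistic function of log-luminance, the simulated level series
stabilizes within roughly 100 trials (a tested property), matching the
reported behavior of the real staircases.

## The synthetic observer

`simulate_session()` walks a schedule trial by trial. Detection is a
logistic function of log-luminance (threshold 0.2 cd/m², slope 2) times a
1.5 odds factor at ±32°; this emulates the reported better detection at
expected directions without claiming the experiment specified such a
mechanism. Zero-contrast trials are "detected" (hallucinated) at a 10%
false-alarm rate, and a hallucinated estimate is drawn from the prior with
probability 0.5 (otherwise uniformly), plus motor noise. Reaction times
are lognormal with a −0.1 log-mean shift at ±32° — purely descriptive
machinery for exercising the RT summaries, explicitly not a fitted model.
2% of estimates are omitted at random to emulate the 3000 ms response
window. High-contrast trials are sensed with a separate small width
(default 3°), which is what justifies estimating motor noise from them.

The default generating parameters ($\theta_p = 32°$, $\sigma_p = 15°$,
$\sigma_s = 10°$, $\alpha_p = 0.1$, $\sigma_m = 8°$) were calibrated once
against the published effect pattern: they yield attraction biases toward
±32° of roughly +2.6° at 16°, +5° at 48° and +10° at 64°, estimation
variability lowest near the expected directions, and a hallucination
probability ratio around 2–3 — the same magnitudes the experiment reports.
At substantially larger sensory noise (e.g. $\sigma_s = 25°$, used in some
fitting examples because it stresses the estimator) the model's bias at
16° genuinely reverses sign, because percepts leak across the prior saddle;
this is a property of the model, not a bug, and is why the generator
default is the calibrated value.

What the simulator does *not* emulate: prior acquisition over time (the
generative prior is static, as the models are fitted), sequential effects,
fatigue, or any mechanistic account of hallucinations and reaction times.
Tests passing on synthetic sessions therefore validate the pipeline's
internal consistency and identifiability, not claims about human data.

## Behavioral statistics

Estimation errors on usable low-contrast trials (estimate made within the
window *and* stimulus reported seen; the two staircases pooled) are fitted
per folded direction magnitude with the mixture

$$(1-\alpha)\,V(\mu, \sigma) + \alpha/2\pi,$$

giving bias ($\mu$ relative to the true direction), variability ($\sigma$)
and lapse proportion ($\alpha$). Folding mirrors negative directions onto
positive magnitudes; `bias_toward_32` flips the sign beyond 32° so positive
always means attraction toward the expected directions. Strata with fewer
than 10 usable trials are flagged rather than fitted. The optimizer runs
Nelder-Mead on a transformed scale enforcing $\sigma \in (0.5, 120]$ and
$\alpha \in [0,1]$ from a fixed 9-point start grid over $(\sigma_0,
\alpha_0)$ centered on the circular mean — deterministic given the data.
One caveat found while validating: on exactly uniform data the maximum
likelihood solution is *not* $\alpha = 1$, because a near-maximal-width von
Mises can absorb sample anisotropy; the fitted density is still flat.

QC mirrors the published inclusion rule: fail if high-contrast detection
≤ 70%, high-contrast circular RMS estimation error ≥ 30°, or low-contrast
detection < 50%.

The hallucination probability ratio divides the response range into 11 bins
of 32° centered on multiples of 32° (a 352° span; estimates outside it join
the nearest bin) and reports the average probability of the two bins at
±32° times the number of bins, so equal counts in every bin give exactly 1
and all estimates within 16° of ±32° give 5.5. The published bin layout
(11 × 32° ≠ 360°) is geometrically ambiguous; centering bins on the
predetermined directions and averaging the two target bins is the only
reading under which the uniform case calibrates to 1, and it is flagged
here as an interpretation.

Learning dynamics are summarized in overlapping 110-trial windows stepped
by 55: attraction bias (mean signed folded error toward the nearest mode
at the 16/48/64 magnitudes — 0° is equidistant from both modes and
excluded), detection and RT at ±32° versus elsewhere. A cheap mean-error
estimator is used instead of per-window mixture fits because windows hold
only a few dozen usable trials; this is a deliberate deviation noted here.
Since the generative prior is static, the windowed series must be flat —
a tested null.

## Fitting and model comparison

`fit_model()` maximizes the summed log response density over usable
low-contrast trials (random-direction trials included with their drawn
direction), with $\sigma_m$ fixed from the high-contrast mixture fit.
Optimization is bounded L-BFGS-B ($\theta_p \in [5, 80]$,
$\sigma_p \in [2, 120]$, $\sigma_s \in [2, 80]$, $\alpha_p \in [0, 0.5]$)
started from the best points of a fixed 12-point Latin-square grid;
everything is deterministic given data and settings. The likelihood shares
one percept lookup and one motor kernel across all directions with a given
sensory width, which is what makes a fit take seconds rather than minutes.
Default settings use the 1° grid and polish the best 4 starts; the batch
harnesses (recovery, cohort comparisons) use a 2° grid and 1–2 polished
starts, which the grid-refinement property shows is inconsequential for
the estimates while keeping a 400-fit recovery study inside a coffee
break. Problem sizes used by the shipped studies: 20 observers for
parameter recovery, 20 cohorts × 10 subjects × 2 variants for model
recovery.

Comparison is by BIC $= k\ln n + 2\,\mathrm{NLL}$ summed over subjects
(fixed effects) and by protected exceedance probability (random effects):
a variational Dirichlet model over per-subject model frequencies with log
evidence approximated as $-\mathrm{BIC}/2$, exceedance probabilities by
Monte-Carlo Dirichlet sampling (10⁵ draws, seeded), and protection by
blending with the uniform $1/K$ according to the Bayes omnibus risk — the
posterior probability that all models are equally frequent. The
implementation is checked against a brute-force sampling oracle that
weights Dirichlet prior draws by their marginal likelihood. Whether
detection data should enter the model likelihood is unspecified in the
source; only estimation responses are used here.

## Reproducibility

Every stochastic stage takes an explicit integer seed; schedules, sessions
and whole pipeline runs are byte-identical under a repeated seed (tested).
The `analysis/` scripts run the cohort study end to end
(simulate → behavioral analysis → fit/compare → recovery) and write their
tables under `results/`; `scripts/acceptance.R` recomputes the structural
calibration quantities and writes them as JSON.

## Known limitations

* The four ADD forms are reconstructions; conclusions about that class are
  conditional on the reconstruction.
* Group-level inference (ANOVAs, Bayes factors, rank tests) is out of
  scope by design; the package stops at per-session statistics and
  cohort-level model comparison.
* Reaction times are carried and summarized descriptively, never modelled.
* The hallucination mechanism, detection model, staircase step sizes and
  RT parameters are emulation choices, stated as such above.
* With ≤ 567 trials per session, $\alpha_p$ is the least identifiable
  parameter (rank correlation ≈ 0.6–0.7 in recovery); $\theta_p$,
  $\sigma_p$ and $\sigma_s$ recover well.
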