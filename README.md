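# motionprior

Bayesian observer models of visual motion estimation under a learned
bimodal prior — task simulation, behavioral statistics, model fitting and
model comparison.

## The problem

In a classic visual statistical-learning paradigm, observers estimate the
direction of a cloud of coherently moving dots presented at interleaved
contrast levels (none, two staircased near-threshold levels, one clearly
visible), and report on every trial whether they saw dots at all. Two
directions, ±32° around a reference, are shown far more often than the
rest (58% of stimulus trials). Observers implicitly acquire this statistic
as a perceptual *prior*: their estimates are attracted toward ±32°, their
detection and reaction times improve there, and when nothing is shown they
preferentially "hallucinate" motion near ±32°. This package implements the
computational pipeline used to study that phenomenon — for computational
psychiatrists and psychophysicists who want to fit, compare, and
power-check these observer models without collecting (or having access to)
participant data. All data are synthetic, produced by a tested generative
simulator.

## The models

On each trial the observer senses $\theta_s \sim V(\theta_{act},
\sigma_s)$ (von Mises, width in degrees, $\kappa = 1/\sigma_{rad}^2$), and
combines it with an acquired prior

$$p_{prior}(\theta) = \tfrac12\left[V(-\theta_p, \sigma_p) + V(\theta_p, \sigma_p)\right]$$

into a posterior whose circular mean is the percept. With probability
$\alpha_p$ the percept is instead a lapse — a draw from the prior
(**BAYES_P**) or uniform (**BAYES**). Motor noise $V(0, \sigma_m)$
(estimated from high-contrast trials, fixed during fitting) corrupts the
response:

$$p(\theta_{est}\mid\theta_{act}) = (1-\alpha_p)\int V\!\big(\theta_{perc}(\theta_s), \sigma_m\big)\,p(\theta_s\mid\theta_{act})\,d\theta_s + \alpha_p\,\big[p_{prior} * V(0,\sigma_m)\big].$$

Variants **BAYES_var** / **BAYES_varmin** let $\sigma_s$ vary with the
stimulus direction (8 / 5 free parameters vs 4), and a non-integrative
**ADD** class responds from prior *or* likelihood alone. Models are fitted
by maximum likelihood per session and compared by summed BIC (fixed
effects) and protected exceedance probability (random effects,
variational Dirichlet with Monte-Carlo exceedance and Bayes-omnibus-risk
protection).

## Worked example

```r
library(motionprior)

sched <- generate_schedule(task_config(), seed = 1)   # 567-trial design
obs   <- bayes_params(theta_p = 32, sigma_p = 15, sigma_s = 10,
                      alpha_p = 0.1, sigma_m = 8)
sess  <- simulate_session(sched, obs, detection_config(), seed = 1)

qc_filter(sess)$criteria
direction_stats(sess)
p_ratio(subset(sess$trials, condition == "zero" & detected)$estimate_deg)

sm  <- estimate_motor_noise(sess)
fit <- fit_model(sess, "BAYES_P", sm,
                 fit_settings(step = 2, n_optim = 2, maxit = 80))
```

This prints (abridged):

```
            name      value threshold pass
1 high_detection  0.9850746       0.7 TRUE
2      high_rmse 17.9750876      30.0 TRUE
3  low_detection  0.8318318       0.5 TRUE

  magnitude n_usable bias_toward_32 variability_deg  lapse detection_rate
1         0       15           0.99           13.26  0.000          0.833
2        16       22           1.85           16.72  0.000          0.727
3        32      161          -0.56           11.20  0.063          0.856
4        48       27          15.98           29.18  0.000          0.844
5        64       29          13.67           10.78  0.000          0.806

p_ratio = 2.75 over 12 hallucinations
sigma_m = 8.59
theta_p sigma_p sigma_s alpha_p        NLL = 27.5, BIC = 77.5
  29.85   14.17   10.01    0.12
```

Reading the numbers: the session passes the inclusion QC (detection and
estimation benchmarks on high contrast, detection on low contrast). The
per-direction table shows the prior's fingerprints — positive
`bias_toward_32` at the 16/48/64° magnitudes (estimates pulled toward the
frequent ±32° directions) and the highest detection rate at 32°. The
hallucination probability ratio of 2.75 means zero-contrast "seen" trials
were reported moving within 16° of ±32° almost three times as often as a
uniform responder would (1.0 is the no-prior calibration). The BAYES_P fit
recovers the generating parameters (true values 32, 15, 10, 0.1) from one
session with motor noise estimated at 8.59° against a true 8°.

The `analysis/` directory runs the full cohort study as numbered scripts
(`01_simulate.R` → `04_recovery.R`): simulate 12 observers, compute
behavioral summaries (median p_ratio 2.14 across the cohort), fit and
compare BAYES_P vs BAYES (ΔBIC ≈ 457 and PXP ≈ 0.997 in favor of the
generating BAYES_P), and run parameter/model recovery. Outputs land in
`results/`.

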