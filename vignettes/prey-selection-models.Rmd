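---
title: "Reward-rate learning in serial prey selection: models, fitting and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reward-rate learning in serial prey selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preyselect)
```

## The task and the normative benchmark

`preyselect` studies serial prey selection: a forager encounters options one
at a time and either accepts (collecting a reward after a handling delay) or
rejects (moving on immediately). Four options cross two reward levels (20 or
80 points) with two handling delays (2 or 8 s, the final second of which is
the reward display): the best option LDHR (80 points / 2 s), the two equally
profitable intermediates LDLR and HDHR (both 10 points/s), and the worst
option HDLR (20 points / 8 s). A *rich* environment offers LDHR on four of
every seven trials, a *poor* environment offers HDLR on four of seven; a
degenerate worst-only environment is available as the middle block of the
three-block design (`exp3`). Sessions pair the two environments in
counterbalanced order (`RichPoor` / `PoorRich`), with 900-s blocks in `exp1`
and 600-s blocks in `exp2`/`exp3`, a 2-s response window per offer, 25%
forced-choice attention checks, and an 8-s timeout after a missed response.

The Marginal Value Theorem supplies the normative policy: accept option $i$
exactly when its reward exceeds the opportunity cost of handling it,
$r_i \ge \rho^* t_i$, where $\rho^*$ is the environment's long-run reward
rate under the optimal policy itself. `mvtOptimalPolicy()` finds this policy
by enumerating all acceptance sets: accept only LDHR in the rich environment
(14.5 points/s) but also both intermediates in the poor one (6.9 points/s).
The interesting behaviour is therefore environment-dependent acceptance of
the intermediates.

## The learning models

Foragers do not know $\rho^*$; the models track a running estimate $\rho_t$
(points/s) with a delta rule applied at **every elapsed second** of the
session — encounter seconds, handling seconds, timeout seconds:

$$\rho_{t+1} = \rho_t + \alpha\,\delta_t, \qquad \delta_t = r_t - \rho_t,$$

where $r_t$ is the reward delivered at second $t$ (zero on all seconds
except reward delivery). The *Symmetric* model has one learning rate
$\alpha$; the *Asymmetric* model applies $\alpha^+$ on seconds where reward
arrives ($r_t > 0$) and $\alpha^-$ otherwise. Because reward delivery shares
its second with the last tick of the handling delay, that second is modelled
as two consecutive updates: a reward-free update followed by a reward
update (`rewardSecondUpdate()`; the order is configurable and results are
robust to it). The estimate is initialised to the session's arithmetic
average reward rate assuming every offer is accepted — a simplifying
convention that avoids special-casing initial conditions — and carries
across blocks with no reset, so a block switch must be *unlearned*.

Choices follow a softmax on the accept-versus-reject value difference,
evaluated at the second (final) encounter second using the estimate after
that second's update:

$$P(\text{accept}) = \frac{1}{1 + \exp\!\big(\beta_0 - \beta_1 (r_i - \rho_t t_i)\big)},$$

with $\beta_0$ a response bias (positive = reject-prone) and $\beta_1$ the
sensitivity per point. Forced trials execute their mandated direction.

Why the asymmetry matters: with $\alpha^+ > \alpha^-$ the estimate rises
quickly when rewards arrive but decays slowly through reward-free seconds,
so $\rho_t$ is biased upward — an *optimistic* forager that is too selective
after an environment deteriorates. That predicts the order effect the
package's simulations reproduce: foragers moving poor→rich adjust readily,
foragers moving rich→poor cling to inflated estimates, so the poor-minus-rich
acceptance difference score is larger in the PoorRich order.

### Numerical conventions worth knowing

* Time is discretised to exact 1-s ticks; all design durations are integer
  seconds. A trial starts only while the session clock is inside its block's
  nominal window; the final trial may overrun the boundary, and the next
  block then begins at its end.
* The double update on the reward second means the delta rule's stationary
  point is the per-*update* average reward, not the per-second rate: a
  worst-only environment delivering 20 points per 10-s trial generates 11
  updates per trial, so $\rho_t$ settles near $20/11 \approx 1.82$, about
  9% below the 2.0 points/s per-second rate. The property suite asserts the
  rule's actual fixed point; the distinction is immaterial for choice
  because all comparisons are against the same biased scale.
* Softmax likelihoods are evaluated through `plogis`/`log1p` forms, stable
  for arbitrarily large arguments.
* The compiled likelihood/simulation core (Rcpp) and the pure-R reference
  engine consume R's RNG stream identically and are tested bit-identical;
  the R engine additionally records the per-second update trace.

## Synthetic cohorts: what they emulate and what they do not

`generateCohort()` replaces the study's human data. Per-subject parameters
are independent Gaussian draws in transformed space (logit for learning
rates, identity for $\beta_0$, $\beta_1$) around reference group means for
each experiment configuration (`preyDefaults()`). Group means reproduce the
reference fitted estimates; between-subject spreads are **calibration, not
ground truth**: the reported group tables give means and confidence
intervals only, so

* learning-rate logit spreads are set to 0.6, which keeps roughly 90% of
  asymmetric draws with $\alpha^+ > \alpha^-$, matching the reported 88–92%
  individual-level prevalence of the bias, and
* $\beta_0$/$\beta_1$ spreads are back-computed from the reported 95%
  confidence intervals as $\mathrm{SEM}\times\sqrt{N}$.

Forced directions are fair coin flips (the task does not constrain the
split; configurable), forced trials are placed by deterministic quota —
exactly one per consecutive four-trial window, uniformly within the window —
so the 25% fraction is exact over complete windows, and offer cycles are
whole shuffled seven-trial cycles that may straddle the block end.
Per-subject seeds are derived from the master seed by a fixed stride, so
cohorts are reproducible and subjects independent.

Synthetic subjects never miss responses, never abort handling, and have no
reaction times or attrition; the exclusion screens (`applyExclusions()`)
therefore normally pass everyone and exist to process real-format logs. The
cohort also inherits every modelling idealisation above, so green tests
certify the pipeline's internal consistency and the model's qualitative
predictions — not that human foragers behave this way.

One consequence of following the convention that forced trials stay in the
likelihood (they are part of the subject's experience): mandated responses
are coin flips no softmax can predict, so fitted $\beta_0$/$\beta_1$ are
systematically shrunk relative to the generating values, and the misfit
pressure also biases the fitted $\alpha^+ - \alpha^-$ contrast downward —
enough to break the null calibration of the learning-bias z-test on
symmetric-generated cohorts. The flag `include_forced = FALSE` (forced
trials still drive $\rho$ through their elapsed seconds and rewards, only
their mandated responses leave the likelihood) restores near-nominal
calibration and essentially unbiased recovery of the learning rates; the
recovery and calibration analyses in the test suite therefore use it, while
the package default keeps forced trials in.

## Hierarchical fitting

`emFit()` implements empirical-Bayes EM with Laplace approximations:
subject-level MAP estimation under the current Gaussian group prior
(E-step; BFGS with analytic gradients from forward sensitivities of
$\rho_t$, best of 5 starts on the first sweep, warm starts after), then a
closed-form update of the group mean and diagonal covariance in which each
parameter's group variance is the mean squared MAP deviation plus the mean
Laplace posterior variance (M-step), iterated until group means move less
than `tol` (default $10^{-3}$; finite-difference Hessian step $10^{-4}$;
`max_iter` 200). The initial prior is broad and fixed (learning-rate logits
centred at logit 0.05 with spread 2; $\beta_0 \sim N(0, 4)$;
$\beta_1 \sim N(0.05, 0.01)$). A cohort of identical subjects collapses the
group spread to the Laplace floor, which the suite checks.

Model comparison uses subject-level leave-one-out cross-validation
(`loocv()`): for each held-out subject the group prior is refit on the rest
(warm-started), and the subject is scored by the negative Laplace
log marginal likelihood of their choices under that prior — the default
estimator; warm starts affect only the optimizer path, never the objective.
Scores are compared across models with a paired two-tailed t-test
(`compareModels()`). The group-level learning bias is tested with a
contrast on the asymmetric group means in logit space
(`learningBiasZtest()`), using the full covariance of the group means
assembled from MAP dispersion plus Laplace covariances.

Problem sizes in the shipped test-suite runs are deliberate choices that
keep recovery informative while staying cheap: 40-subject cohorts on the
600-s-block configuration for recovery and LOOcv, 16-subject cohorts for
the null calibration of the bias z-test, and 50-replicate order-effect runs
(the full-scale experiments default to 1000 and 500 replicates as the
simulation functions document).

## Design choices that were genuinely open

* **Forced-trial direction split** — unstated by the task; set to 50/50 and
  exposed as `forced_accept_prob`.
* **Initial-rate policy** — "average reward rate" does not name a policy;
  accept-all is the default (`initialRate(policy=)` also offers the MVT
  policy's rate).
* **Block boundaries** — blocks are time-defined, so trial counts are
  policy-dependent; trials are atomic and the last one may overrun.
* **$\beta_1$ transform** — left unconstrained (reference estimates are
  positive but positivity is not imposed), preserving exact nesting of the
  symmetric model inside the asymmetric one at $\alpha^+ = \alpha^-$.
* **Ties at $r_i = \rho^* t_i$** — accepted, matching the $\ge$ in the MVT
  rule.
* **Previous-offer analysis** — forced trials count as history (their
  offers were experienced) but their mandated current responses are
  excluded by default (`include_forced_current` flag).

## Known limitations

* The Laplace approximation can be poor for near-boundary learning rates;
  the z-test's null calibration is checked empirically in the suite rather
  than assumed.
* Group covariance is diagonal in the prior; correlations between
  parameters enter only through the covariance of the group means.
* Reaction times, missed responses and within-trial aborts are not
  simulated (missed trials are still replayed correctly when present in
  real-format logs).
* Models that learn $r_i$ and $t_i$ from experience are a documented
  extension point, not implemented.
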