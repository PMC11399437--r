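---
title: "Modelling deliberate ignorance and evidence distortion in vaccination decisions"
author: "vaxcog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling deliberate ignorance and evidence distortion in vaccination decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxcog)
```

## The scientific problem

When people decide whether to accept a vaccine, they can inspect evidence
about it — its possible side effects, its benefits, and the probabilities
of both — or choose not to look. Process-tracing experiments make this
observable: each piece of evidence sits behind a labelled box that is
revealed only while the mouse cursor hovers over it, and every hover event
is logged. Two phenomena are of particular interest:

* **Deliberate ignorance** — making the decision without inspecting some
  or all of the evidence. A trial shows *full* ignorance when no evidence
  box was opened, *none* when every box was opened at least once, and
  *partial* otherwise.
* **Probability neglect** — inspecting an outcome (e.g. "blood clots")
  but never its probability. The strict definition is used: the outcome
  box was acquired at least once and the paired probability box never.

Even fully inspected evidence may be processed in a distorted way. The
package models two classic distortions from risky-choice research: **loss
aversion** (side effects weigh more than equally rated benefits) and
**nonlinear probability weighting** (small probabilities overweighted,
large ones underweighted).

`vaxcog` implements the full analysis path: a validated evidence table
for eight COVID-19 vaccines, preprocessing of hover logs into
ignorance/neglect indices, a hierarchical Bayesian prospect-theory model
of the accept/refuse decisions, supporting hierarchical regressions, and
a synthetic-cohort generator with known ground truth so that every stage
can be tested against planted truth.

## The choice model

For participant $i$ and vaccine $v$ the probability of acceptance is

$$P(\text{accept}) = \operatorname{logit}^{-1}\!\big(\beta_i + X_v \beta_j + \varphi V_{i,v}\big),$$

where $\beta_i$ is an individual decision bias (the baseline log-odds of
accepting any vaccine), $X_v$ is a row of sum-to-zero contrasts coding
the vaccine's country of origin (US / China / other) and technology
(mRNA / vector / other) with coefficients $\beta_j$, and $V_{i,v}$ is the
subjective valuation of the inspected evidence, scaled by
$\varphi \in (0,1)$.

The valuation sums value $\times$ decision weight over the vaccine's
three side effects and three benefits,

$$V_{i,v} = \sum_{se} v(a_{i,se})\, w(p_{se}) + \sum_{b} v(a_{i,b})\, w(p_b),$$

with affect ratings $a$ (side effects $-5\ldots-1$, benefits $1\ldots5$)
as the outcome values. The value function has three cases:

$$v(a) = \begin{cases}
  -\lambda_i |a|^{\alpha} & \text{side effect}\\
  (1-\lambda_i)\, a^{\alpha} & \text{benefit}\\
  0 & \text{ignored outcome,}
\end{cases}$$

so $\lambda_i \in (0,1)$ measures loss aversion: $\lambda_i = 0.5$ weighs
both sides equally, and the conventional loss-aversion multiplier is
$\Lambda = \lambda_i/(1-\lambda_i)$ (reported per draw, then summarized).
$\alpha > 0$ allows a nonlinear use of the rating scale; because
$\alpha = 3$ would map a rating of 5 to $125\times$ the multiplier, the
$\varphi$ scale keeps the $\varphi V$ term in a range the data support.

Probabilities enter through a two-case weighting function:

$$w(p) = \begin{cases}
  \exp\{-(-\ln p)^{\gamma_i}\} & p \text{ inspected}\\
  0.5 & p \text{ neglected,}
\end{cases}$$

the one-parameter Prelec form: $\gamma_i = 1$ is linear weighting,
$\gamma_i = 0$ collapses every weight to $e^{-1} \approx 0.37$, and all
curves cross at the fixed point $p = e^{-1}$. The fixed 0.5 weight for
neglected probabilities encodes that the decision maker registered the
outcome as probabilistic but has no information about how likely it is.
Benefits whose probability is not displayed at all (three vaccines do not
show a probability for protection against death) are treated the same
way when their outcome was inspected; they are excluded from the neglect
*indices*, which require a displayed probability that was not acquired.

### Hierarchy and priors

Individual parameters are displacements from group-level parameters,

$$\beta_i = \beta + \zeta_i^{\beta},\qquad
  \lambda_i = \Phi(\lambda^{\Phi} + \zeta_i^{\lambda}),\qquad
  \gamma_i = \Phi(\gamma^{\Phi} + \zeta_i^{\gamma}),$$

with $\zeta_i \sim \mathrm{MVN}(0, \Sigma)$,
$\Sigma = \mathrm{diag}(\sigma) R\, \mathrm{diag}(\sigma)$. $\Phi$ is the
standard normal CDF; together with standard-normal priors on the
probit-scale group parameters this induces uniform priors on the (0,1)
scale of $\lambda$, $\gamma$, and $\varphi$. (The source equations are
written once with $\Phi$ and once with $\Phi^{-1}$; only the CDF
direction yields the stated uniform implied priors, so the CDF is used
throughout.) Remaining priors: $\mathcal N(0,1)$ on $\beta$ and
$\beta_j$; $\mathcal N(0, 0.5)$ on $\log\alpha$ (mode at linear scale
use, mass on roughly 0–4); LKJ($\eta = 5$) on $R$ (most correlation mass
in $\pm 0.5$); gamma(2, 1) on $\sigma_\beta$; and $\mathcal N(0.5, 0.13)$
on $\sigma_\lambda, \sigma_\gamma$, truncated to (0, 1) — the truncation
makes the "SD within 0–1" support claim literal, and the narrow prior
avoids bimodal individual posteriors after the $\Phi$ transform.
$\alpha$ and $\varphi$ are group-level only: eight decisions per
participant cannot identify them individually.

Each attitude group (anti / neutral / pro) is fitted independently, so
group comparisons never share information through the hierarchy.

## Sampling and diagnostics

No external probabilistic-programming backend is assumed: the package
ships a multinomial No-U-Turn sampler (dual-averaging step-size
adaptation targeting 0.8 acceptance — 0.9 for the regressions — and
windowed diagonal mass-matrix estimation) with hand-derived analytic
gradients for all three model classes, implemented in C++. The sampler
works on an unconstrained parameterization: non-centered displacements
($z_i \sim \mathcal N(0, I)$, $\zeta_i = \mathrm{diag}(\sigma) L z_i$),
$\log \sigma_\beta$, logit-scale $\sigma_\lambda, \sigma_\gamma$, and
tanh-transformed canonical partial correlations for the Cholesky factor
$L$ of $R$. The exported `model_log_density()` is the centered
specification; a test verifies that the sampler's density equals it plus
the exact transform jacobians, and finite-difference tests pin the
gradients. The LKJ density is kept unnormalized (the normalizer is
constant in the parameters).

Defaults follow the study configuration: 4 chains, 2000 warm-up and 3000
sampling iterations, every second draw recorded — 6000 recorded draws;
the supporting regressions use 4 chains of 4000 iterations with the
first half as warm-up and thinning by two — 4000 recorded draws.
Convergence is monitored with split rank-normalized $\hat R$ (maximum of
the bulk and folded variants) against the 1.01 threshold, computed for
every parameter including the individual displacements.

Predictive performance is summarized as **balanced accuracy**: posterior
predictive $P(\text{accept})$ per trial, classified at 0.5, averaging
the accept-class and refuse-class accuracies. The leave-one-out variant
reweights draws per trial by the inverse Bernoulli likelihood (truncated
importance sampling, weights capped at $\sqrt{S}$ times their mean);
exact refits are out of reach at this scale, and the truncation bounds
the variance of the estimator at the cost of a small bias toward the
in-sample value.

## The synthetic-cohort generator

The generator is first-class, tested code: it draws participants from
the model hierarchy, affect ratings from attitude- and severity-specific
ordinal distributions, hover-event logs from an explicit inspection
policy, and decisions from the generative model itself, storing all
ground truth. Because the underlying study does not model inspection
behavior generatively, the **inspection policy is a descriptive
construct**: per trial it selects full ignorance, no ignorance, or a
partial pattern with planted probability neglect. In partial trials each
category (mild / severe / extreme / benefit) plants a neglect pattern
with its configured conditional probability; non-forced inspected
outcomes always carry their probability, so the planted conditional rate
is exactly the trial-level neglect rate among eligible partial trials —
which is what makes preprocessing testable against planted truth.

Default calibration (chosen once, analytically): full-ignorance shares
0.18/0.09/0.07 and no-ignorance shares 0.42/0.50/0.55 for
anti/neutral/pro; conditional neglect rates solved so the implied
overall trial-level side-effect-neglect rates are 0.15/0.13/0.09
(benefits 0.08/0.06/0.04), with a fixed 1.5 : 1.2 : 1.0 emphasis of
extreme : severe : mild neglect. Default group parameters follow the
qualitative fitted pattern: decision biases $-2.5 / -0.5 / +1.5$,
loss-aversion multipliers $\Lambda \approx 2.3 / 4 / 4$, probability
sensitivities $\gamma \approx 0.3 / 0.5 / 0.4$, $\alpha = 1$,
$\varphi = 0.3$, displacement SDs $(1.5, 0.45, 0.45)$. Inspection
durations are log-normal with median 800 ms; incidental events (rate
0.05 per box) are uniform on 50–199 ms, below the 200 ms retention
threshold — only that threshold matters downstream, since all indices
use inspection counts, never durations.

**What the generator does not emulate.** Ratings are independent across
outcomes given attitude and severity (no participant-level affect
traits); ignorance and neglect are independent across a participant's
eight trials, so participant-level aggregates ("at least one neglect
trial") run higher than in real data, where neglect is strongly
participant-clustered; and demographics are placeholders with no causal
role. Passing tests therefore demonstrate correctness of the machinery
and recoverability of planted parameters — not that real cohorts look
like the synthetic ones in every aggregate.

## Numerical choices and degenerate inputs

* Probabilities are clamped to $[10^{-8}, 1-10^{-8}]$ before the Prelec
  transform (the packaged table contains no 0/1, but user configs
  might).
* A rating of 0 is off the scale and rejected; ratings enter as
  magnitudes $1\ldots5$ for both outcome kinds.
* Exactly 200 ms hovers are retained (the filter removes strictly
  shorter events).
* The HDI is the minimal-width window over sorted draws and requires at
  least 50 draws; ordered-logit cutpoints are parameterized as a first
  cutpoint plus positive increments, so they are strictly increasing in
  every draw by construction.
* Sampler initial values are uniform on $(-1, 1)$ on the unconstrained
  scale; a non-finite density at initialization is an error, not a
  silent retry.

## Problem sizes used in the shipped checks

The full-scale recovery check fits one synthetic group of 200
participants $\times$ 8 trials under the default 4 $\times$ (2000 + 3000,
thin 2) configuration — about four minutes of sampling — and asks all
group-level 95% HDIs to cover the planted truth with every $\hat R$
below 1.01. The descriptive-recovery checks use cohorts of 120–150
participants per policy; the regression checks use 40–120 participants
with shorter chains. The acceptance script generates a full-size cohort
(365/373/462) for the descriptives and fits one 120-participant group
for recovery and accuracy.

## Known limitations

* The policy construct describes *that* information is ignored, not
  *why*; it cannot test explanations such as motivated reasoning.
* The LOO accuracy is an importance-sampling approximation without
  Pareto-smoothed tail modelling; with eight observations per
  participant it is mildly optimistic relative to exact refits.
* Separate per-group fits preclude direct posterior contrasts of group
  parameters; contrasts would require a joint model.
* Only the strict neglect definition is implemented as an index;
  weaker count-based definitions appear in the raw counts but are not
  surfaced as flags.
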