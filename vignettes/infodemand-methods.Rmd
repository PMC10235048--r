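---
title: "Models and methods for two-lottery information-demand analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for two-lottery information-demand analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infodemand)
```

## The task and the scientific question

On each trial a participant faces two two-prize lotteries whose expected
values sum to 500 points: a high-variance lottery (prizes at its EV ± 60,
range 120) and a low-variance lottery (EV ± 15, range 30). The relative
expected value ΔEV = EV(hiVar) − EV(loVar) is drawn uniformly from a fixed
21-element set spanning −110 to 110 (with −100 and 100 absent). One prize is
drawn from each lottery, independently and with probability 1/2, and the
payoff is the sum. The participant reveals exactly one draw before acting.

Revealing a draw removes that lottery's contribution to the uncertainty
about the sum, so the residual range always equals the *unrevealed*
lottery's range: 30 points after a hiVar reveal, 120 after a loVar reveal.
The uncertainty-minimizing policy is therefore to reveal the hiVar lottery
on every trial, whatever its EV. Because the total EV is pinned at 500, a
hiVar reveal also pins the sum to one side of 500 (the loVar spread of ± 15
cannot cross back over the ± 60 offset), which is what makes the Estimate
task's optimal guess 100% accurate after a hiVar reveal and only 50%
accurate after a loVar reveal, and what gives the Intervene task its 60 vs
15 point (4×) recuperation asymmetry. All of these quantities are computed
in the package by exact enumeration of the four equiprobable draw pairs —
no simulation is involved in the normative observer.

One tie-break convention matters for expected earnings: after a loVar
reveal the two possible sums straddle 500, so the guess is genuinely
indifferent. The package labels these cases `indifferent` and scores them
at accuracy 1/2 *regardless of the guess emitted*, which makes the
expected Estimate earnings of an always-loVar policy exactly 250
points/trial (half of the 500-point expected sum). A fixed "always above"
guesser would instead earn 280 by value-weighting; we use the
policy-independent convention because the accuracy, not the guess, is the
quantity of scientific interest.

## The psychometric models and their fitting

Reveal choices in a participant-block are modelled two ways:

* bivariate: $p(\text{reveal hiVar}) = \dfrac{1}{1+e^{-b(a + \Delta EV)}}$,
  with ΔEV standardized to $[-1, 1]$ by division by 110 (the set maximum —
  the only mapping that makes the stated range exact), $a$ the sensitivity
  to uncertainty and $b$ the sensitivity to EV;
* univariate: $p(\text{reveal hiVar}) = \dfrac{1}{1+e^{-c}}$, a constant
  rate.

Estimation is maximum a posteriori under independent Normal priors on $a$,
$b$ and $c$. We interpret the prior notation $\mathcal N(0, 5)$ as
**standard deviation 5** (the convention of MATLAB's `normpdf`, the
plausible origin of the notation); the prior scale is configurable and the
test suite demonstrates that on identified data the fit is insensitive to
reading it as variance 5 instead. The prior's role is purely regularizing:
it keeps the MAP finite for 0/126 or 126/126 reveal counts.

Only trials with reaction times inside the 0.5–10 s window are fit
(`valid = TRUE`); invalid trials are excluded rather than re-queued,
because exclusion is what the analysis stage sees.

**Optimization.** The likelihood has a structural pathology: at $b = 0$ the
bivariate curve is $p = 1/2$ *regardless of* $a$, so the posterior has a
flat ridge, and for strongly uncertainty-driven choice records the sign of
a near-zero $\hat b$ dictates the sign of a large $\hat a$ (the sign-flip
indeterminacy; `diagnose_sign_flip()` quantifies it and the model
comparison resolves it). We therefore use five starts — the prior mode and
± 2 on each axis — each optimized by quasi-Newton (`nlminb` with analytic
gradients), followed by a damped Newton polish to a gradient norm below
1e-8. The test suite verifies the optimizer against a dense grid search
(0.01 resolution) as an independent oracle: brute force never finds a
better posterior value, and away from flat ridges the optima coincide to
one grid step.

**Intervals.** 95% intervals are Wald intervals from the numerically
differentiated Hessian of the log-posterior at the MAP; $c$'s interval is
transformed through the logistic to the rate scale. A fit whose observed
information is not positive definite, or whose gradient fails the
tolerance, is flagged unconverged and its strategy label withheld. A
bootstrap interval could be substituted where the asymptotic approximation
is in doubt; we use Wald intervals throughout because they match the
asymptotic intervals of standard ML fitting tools.

**Model comparison and classification.** BIC(H) = −2 log L + k log n, with
L the *a posteriori* likelihood at the MAP — the full posterior density,
prior normalization constants included. (A flag-equivalent is available by
computing `compute_bic()` on the pure log-likelihood; the posterior
variant is the default because that is how the fitting objective is
stated.) Participants are EV-sensitive by default; only when
BIC(bivariate) − BIC(univariate) > 4.6 — a Bayes factor of 10 — is the
univariate model accepted. EV-insensitive fits are then `Random` when the
rate interval covers 1/2, `Uncertainty_only` when it lies above, and
`LoVar_preferring` when it lies below; the last label covers a case on
which the classification scheme is otherwise silent, and is counted
separately rather than folded into Random. Each fit also records whether
the EV-sensitivity verdict agrees under the mirrored criterion (univariate
by default, bivariate only at −4.6), the `robust` flag.

## The synthetic cohort

No behavioural data ship with the package: every analysis is exercised
against a generative cohort whose ground truth is known. The generator's
defaults are the study conditions; they were chosen once, as follows, and
are config-exposed but not tuned per analysis.

* **Classes and mixture.** EV-sensitive 70%, Random 10%, Uncertainty-only
  20% — the ordering observed in this paradigm (EV-sensitive strategies
  dominate; strictly uncertainty-driven sampling is a small minority;
  random responders are a contaminant class).
* **Parameters.** EV-sensitive: $a \sim N(0.2, 0.4)$ (placing reveal rates
  at ΔEV = 0 around 70%, i.e. clearly above chance but far from optimal)
  and $b \sim N(5, 1.5)$ truncated to $[3, 9]$ (slopes well away from the
  sign-flip regime). Random: $c \sim N(0, 0.2)$. Uncertainty-only:
  $c \sim N(3, 0.4)$ truncated at 2.5 (reveal rates above 92%, the
  distinct high mode). Recovery tests that need *separated* classes set
  the Random dispersion to zero.
* **Instrumentality.** Uncertainty sensitivity is shifted by +0.4 (on $a$,
  or on $c$) in the Estimate and Intervene blocks, the order of the
  empirically reported mean task differences, so task-comparison analyses
  have a known signal. Random agents are *not* shifted: a disengaged
  responder samples at chance in every block.
* **Post-sampling behaviour.** Estimate guesses are optimal after hiVar
  reveals; after loVar reveals they follow the observed prize's valence
  with per-class probability (0.90 / 0.60 / 0.95) — the Random class's low
  obey rate mirrors the low instrumental accuracy of disengaged
  participants. Intervene actions follow switch-iff-below-EV with
  per-class lapse rates (0.05 / 0.40 / 0.03). An optional coupling ties an
  agent's obey probability to its standardized reveal tendency, planting
  the negative %inspect-loVar/obey-rate correlation for that analysis.
* **Trial-by-trial mechanisms.** Both are off by default (agents are
  stationary and memoryless): a win-stay/lose-shift carry-over (the
  probability of repeating the previous reveal shifts by ± `win_stay`
  after a high/low observed prize) and a per-trial drift on uncertainty
  sensitivity within instrumental blocks. They exist so the sequential
  and within-block learning analyses can be power-tested against planted
  effects.
* **Reaction times** are log-normal placeholders (meanlog log 1.5, sdlog
  0.4, putting ~99% of draws inside the 0.5–10 s validity window); they
  feed the validity filter and nothing else. No reaction-time model is
  claimed.
* **Personality.** The 15 questionnaire scores are generated standardized;
  planted scores load on the *standardized long-run reveal probability*
  (extraversion −0.5, need for cognition +0.4, thrill seeking −0.3, stress
  tolerance +0.3), with unit variance preserved
  ($\lambda z + \sqrt{1-\lambda^2}\,\varepsilon$). All loadings on EV
  sensitivity are zero, and demographics are independent of behaviour.

What the generator does **not** emulate: realistic reaction-time structure,
item-level questionnaire responses, gradual strategy change, or the
overlap and heavy tails of real parameter distributions. Passing tests
therefore demonstrate that the pipeline recovers what it assumes — correct
implementations, calibrated tests, recoverable planted effects — not that
real cohorts satisfy those assumptions.

## The dip test

The multimodality analysis needs Hartigan's dip statistic — the minimal
sup-norm distance between the empirical CDF and the class of unimodal CDFs
(convex below the mode, concave above, an atom allowed at the mode). The
package computes it exactly from this definition: for a candidate distance
$d$ the existence of a unimodal fit reduces to band-constrained convex /
concave interpolation, decided by chord-bound closures computed in a
single pass per side (in C++), including the slope-ordering coupling
across the modal gap and modes placed exactly at data points; the minimal
$d$ is then located by bisection to 1e-9. The implementation is verified
in the test suite against an independent brute-force oracle that solves
the same feasibility problem by linear programming at small n, and against
structural identities (an equal two-point mass has dip 1/4, perfectly
unimodal configurations attain the 1/(2n) minimum). The test's p-value is
the fraction of uniform(0,1) null samples of the same size whose dip
reaches the observed one — the uniform being the least favourable unimodal
null; constant input is degenerate and reports p = 1 with a warning.

## Decoding

Behavioural targets are median-split (values strictly above the median are
"high"; class balance is logged), and over 100 bootstrap iterations a
random 50:50 train/test split is drawn, predictors are standardized on the
training half only (no leakage), and a linear-boundary classifier is fit —
a linear-kernel SVM at the library's default regularization (coefficients
must stay interpretable), or logistic regression as the replication
method. Excess accuracy is the *paired* difference against a classifier
retrained on label-shuffled data with the same split, not a fixed 50%
baseline. SVM boundary orientation depends on training-row order, so
coefficients are sign-canonicalized (positive decision value = "high")
before aggregation; a predictor is significant when the 2.5–97.5%
quantile range of its per-iteration coefficients excludes zero.

A design note on the selectivity analysis (decoding EV sensitivity as the
negative control): in a mixed-class cohort, %reveal hiEV is strongly
confounded with class membership — Uncertainty-only agents sit at
%hiEV = 50% *and* at extreme %reveal hiVar, on which the planted scores
load — so that target decodes above chance even though nothing was planted
on EV sensitivity. The package therefore uses the pooled fitted slope
($\hat b$, with 0 assigned to EV-insensitive labels, the same pooling used
for variance attribution) as the EV-sensitivity target in its selectivity
checks; it is unconfounded and decodes at chance. %reveal hiEV remains
available as a decoding target.

Variance attribution is leave-one-predictor-out ΔR² from a multiple linear
regression on all 18 predictors; rank-deficient designs warn, and
perfectly collinear duplicates correctly show ΔR² ≈ 0 each.

## Numerical conventions and degenerate inputs

* ΔEV = 0 trials are excluded from %reveal hiEV (no higher-EV lottery
  exists) and a missing ΔEV = 0 bin flags the decomposition as undefined.
* The efficiency decomposition identity
  (shortfall + EV cost = 100 − %reveal hiVar) holds exactly by
  construction and is asserted over simulated cohorts.
* Within-block learning uses the first-half vs second-half %reveal
  difference as the primary statistic (robust at 126 trials), with the
  per-block logistic slope reported alongside.
* The 2³ strategy-consistency grouping uses the first Observe block plus
  the two instrumental blocks in presentation order; the second Observe
  block is reported separately. The repetition test conditions on
  Uncertainty-only vs EV-sensitive starts and uses a df = 1 chi-square
  with Cramér's V.
* Seeding: one master seed per run; per-participant and per-stage child
  seeds are derived deterministically (all below 2³¹), so cohorts and
  pipeline outputs are byte-reproducible and stages can be re-run
  independently.

## Identifiability limits worth knowing

Two regimes deserve explicit caution. First, the sign-flip ridge at
$b \approx 0$ discussed above — the reason the univariate model and the
BIC comparison exist at all. Second, saturation: when $|a|$ approaches the
standardized design bound ($\pm 1$), the reveal probability is extreme at
*every* ΔEV level and both parameters are weakly identified; single fits
then scatter widely (at $a = 2$, $b = 5$ and 12,600 trials,
sd($\hat a$) ≈ 0.4, sd($\hat b$) ≈ 1.3) and carry a small finite-sample
bias that shrinks with the trial count. Parameter-recovery claims in the
test suite are therefore phrased about mean estimates over replicate
simulations in saturated regimes, and about single fits only on identified
curves.

## Problem sizes used by the test suite

The suite runs entirely from simulation: cohorts of 15–60 agents for
calibration loops (100 seeds per null suite), 265 EV-sensitive agents for
the planted task-comparison recovery, 300 separated-class agents for
classification recovery, 500 agents for decoding, 200 replicate fits for
saturated-regime recovery, and dip oracles at n ≤ 10 with null
distributions of 300–500 bootstrap samples. These sizes were chosen to
give each check clear statistical resolution while keeping a full run in
the minutes range on a single core.
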