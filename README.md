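# infodemand

Tools for studying *information demand*: how people decide which of several
observations to request when predicting the combined outcome of a
multi-attribute situation. The package implements a complete, simulation-backed
analysis pipeline for a two-lottery sampling task in which, on every trial, a
participant sees two two-prize lotteries — one with high prize variance
(hiVar, a 120-point spread) and one with low variance (loVar, 30 points) —
whose expected values always sum to 500 points. One prize is drawn from each
lottery and the payoff is the sum of the draws; the participant may reveal
exactly one draw before acting. Because the residual uncertainty about the sum
always equals the range of the *unrevealed* lottery, the normative strategy is
to reveal the hiVar lottery on every trial, regardless of the relative
expected value ΔEV = EV(hiVar) − EV(loVar). Three task variants differ only in
the post-sampling action: Observe (none), Estimate (guess whether the sum is
above or below 500; correct guess pays the sum, incorrect pays 0), and
Intervene (keep the revealed draw or exchange it for the lottery's mean).

## What the package computes

**Psychometric strategy models.** Each participant-block's reveal choices are
fit by maximum a posteriori estimation with two models,

- bivariate: p(reveal hiVar) = 1 / (1 + exp(−b(a + ΔEV))), with ΔEV
  standardized to [−1, 1] (division by 110), a the sensitivity to uncertainty
  and b the sensitivity to EV;
- univariate: p(reveal hiVar) = 1 / (1 + exp(−c)), a constant reveal rate;

both under independent Normal(0, sd 5) priors. Model comparison uses
BIC(H) = −2 log L + k log n with L the a posteriori likelihood at the MAP.
Participants are EV-sensitive by default and EV-insensitive only when the
univariate BIC wins by more than 4.6 (Bayes factor 10); EV-insensitive fits
split into Random (the 95% interval of sigmoid(c) covers 0.5),
Uncertainty-only (entirely above 0.5) or LoVar-preferring (entirely below).

**Normative observer.** Exact enumeration of post-reveal outcomes: possible
sums, residual ranges, the 100% vs 50% expected accuracy of the optimal
Estimate guess after hiVar vs loVar reveals, the 60 vs 15 point Intervene
recuperation (a 4× ratio), and expected earnings for arbitrary reveal
policies.

**Synthetic cohorts.** A labelled generator for EV-sensitive, Random, and
Uncertainty-only agents with configurable parameter distributions,
instrumentality shifts, trial-by-trial mechanisms, and personality profiles
(15 questionnaire scores + 3 demographic codes) with loadings planted on
uncertainty sensitivity only — the ground truth for every downstream check.

**Behavioural metrics.** Sampling efficiency (%reveal hiVar) and its
decomposition into an uncertainty shortfall and an EV cost, psychometric curve
bins, Hartigan's dip test of multimodality (the statistic is computed exactly
from its definition, with a uniform-null bootstrap p-value), paired task
comparisons, strategy-consistency tables, sequential-trial effects,
within-block learning, and obey-rate analyses.

**Personality decoding.** Bootstrap linear classification (linear-kernel SVM
or logistic) of median-split behavioural targets from the 18 predictors, with
paired label-shuffle baselines (excess accuracy), coefficient intervals,
leave-one-score-out variance attribution, and extraversion-quartile tables.

## Worked example

```r
library(infodemand)
sch    <- build_schedule("p01", "EstimateFirst", seed = 11)
agent  <- agent_spec("p01", "EV_sensitive", a = 0.4, b = 5,
                     shift_estimate = 0.4, shift_intervene = 0.4)
trials <- simulate_choices(agent, sch, seed = 12)
fit    <- fit_strategy(reveal ~ delta_ev, data = subset(trials, block == "Observe1"))
fit
#> Sampling-strategy fit (126 trials)
#>   bivariate : a = 0.407 [0.283, 0.531], b = 4.225 [2.684, 5.766], BIC = 111.69
#>   univariate: c = 0.876, p(reveal hiVar) = 0.706 [0.621, 0.779], BIC = 162.48
#>   delta BIC (biv - uni) = -50.79; strategy: EV_sensitive (robust to criterion sign)
```

The fit recovers the generating parameters (a = 0.4, b = 5) within their 95%
intervals and labels the agent EV-sensitive: the bivariate BIC wins by ~51
points, far beyond the 4.6 criterion, and the verdict agrees under both signs
of the criterion. The model-free summary tells the same story:

```r
efficiency_summary(subset(trials, block == "Observe1"))
#> %reveal hiVar 70.6%; at dEV=0 100.0%; uncertainty shortfall 0.0; EV cost 29.4
```

This agent reveals the (always optimal) hiVar lottery on only 70.6% of
trials; the decomposition attributes the 29.4-point shortfall to EV
sensitivity (the ΔEV = 0 bin — here a small bin of six trials — shows no
uncertainty shortfall). `plot(fit)` overlays the fitted psychometric curve on
the per-ΔEV reveal fractions, and `run_pipeline(run_config(seed = 1))` runs
the whole chain — simulate, fit, classify, metrics, decode — writing
`trials.csv`, `fits.csv`, `metrics.csv`, `comparisons.json` and
`decoding.json` to a directory, byte-identical under a fixed seed.

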