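---
title: "Group benefits in joint multiple object tracking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group benefits in joint multiple object tracking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(jointmot)
```

## The task and its scores

In a joint multiple object tracking (MOT) session, two people sit at
separate screens showing the same display: 19 moving objects, 6 of which
were briefly cued as targets. After 11 s of motion each member independently
selects the objects they believe are targets. Scoring is per trial:

* **Individual score** — correct selections count +1, incorrect −1:
  $s = |S \cap T| - |S \setminus T|$ for selection set $S$ and target set
  $T$. Scores can be negative.
* **Team score** — the two selection sets are pooled as a *union* before the
  same correct-minus-incorrect count, so a selection made by both members
  counts only once. Two members with three correct selections each and one
  shared selection score 3 + 3 individually but only 5 as a team.
* **Overlap** — the fraction of shared selections. "Number shared divided by
  the total number of selections" is ambiguous; the package defaults to the
  intersection-over-union convention, which maps identical selections to 1
  and disjoint selections to 0, and offers the sum-denominator convention
  (`method = "sum"`, maximum 1/2) for sensitivity checks. A trial with no
  selections at all has no defined overlap; it returns a configurable value
  (default 0) and signals an auditable message rather than guessing
  silently.

```{r}
score_session(generate_session(n_trials = 3, seed = 1))
```

## Two benefit criteria

Dyads are compared against two baselines, giving per-trial ratio series that
are smoothed with a 20-trial moving average whose maximum ("peak") is the
pair-level dependent variable.

**Collective benefit** divides the team score by the *better member's*
individual score, per trial. A ratio above 1 means the pair beat its best
individual. The better member is re-evaluated each trial by default; a
session-level variant (one better member per pair, by mean score) is
selectable because the per-trial reading is not the only defensible one.

**Collaborative benefit** divides the team score by the mean team score of a
Monte-Carlo *independence null*: keeping each member's per-trial counts of
correct and incorrect selections, the correct ones are re-placed uniformly
at random (without replacement) among the 6 targets and the incorrect ones
among the 13 distractors, independently per member, and the resulting union
is scored; the default is 1000 repetitions per trial. Ratios above 1
indicate coordination beyond *statistical facilitation* — the advantage two
independent selectors get merely because their selections do not fully
coincide.

The null has an exact expectation,

$$ E[\text{team}] = T\Big(1 - \big(1 - \tfrac{c_1}{T}\big)\big(1 -
\tfrac{c_2}{T}\big)\Big) - D\Big(1 - \big(1 - \tfrac{w_1}{D}\big)\big(1 -
\tfrac{w_2}{D}\big)\Big), $$

implemented as `expected_null_team_score()` and used as the analytic oracle
for the sampler. The default sampler draws the two members' overlap counts
directly from their exact hypergeometric law (the intersection of two
independent uniform fixed-size subsets is hypergeometric), which is
distributionally identical to placing the sets and much faster; a literal
set-placement sampler (`method = "sets"`) is retained as a cross-check.

```{r}
expected_null_team_score(3, 0, 3, 0, 6, 13)
null_team_score(3, 0, 3, 0, 6, 13, n_reps = 2000, seed = 1)
```

### Numerical choices

* **Non-positive denominators.** Individual scores and null means can be
  zero or negative, where a ratio loses meaning. The default policy excludes
  such trials from the raw series *before* smoothing and reports the count;
  whether to exclude before or after smoothing is genuinely open, and
  exclude-then-smooth was chosen so every window mean is a mean of defined
  ratios.
* **Valid windows only.** The moving average uses fully contained windows
  (length $n - w + 1$), no padding, so the peak is never biased by partially
  filled edge windows.
* **Per-trial null substreams.** Each trial's Monte-Carlo null derives its
  own seed substream, so single-trial nulls are reproducible independently
  of trial order.

## The synthetic-data generator

The package is exercised on synthetic cohorts whose structure mirrors the
study design it emulates: 8 information conditions (all combinations of
individual-score, team-score and selection feedback), 16 pairs per
condition, 100 trials per pair.

**Kinematics.** 19 objects of radius 0.56 visual degrees in a 30 × 17
degree field (an order-of-magnitude match for a 24-inch display at 90 cm;
the original display geometry is given in pixels, not degrees), constant
per-object speeds drawn uniformly from 0.90–1.21 deg/s, 11 s of
straight-line motion. At walls and at object–object contact the velocity is
reflected *specularly* (angle of incidence = angle of reflection), which
conserves each object's speed exactly — the property the invariant tests
check to 1e−9. Initial placement enforces a minimum separation of one
diameter so trials do not open mid-collision; spacing and collision handling
are config-exposed because the behavioral literature does not pin them down.

**Selection behavior.** Each simulated member has a `capacity` (expected
targets tracked, realized expectation-preservingly), an `accuracy`
(probability a tracked target is reported) and a `guess_rate` (Poisson count
of distractor clicks). Pairs either select independently or adopt a
*left–right labor division*: from an onset trial (default 5, since divisions
emerge within a few trials) each member draws tracked targets only from its
own side of the vertical screen midline, evaluated at cue offset, with a
per-trial `adherence` probability. Under independence with accuracies of 1,
the expected number of shared correct selections is $c_1 c_2 / T$ — the
product-rule oracle the tests check by enumeration.

**Cohorts.** `generate_cohort()` draws heterogeneous member abilities and
decides division adoption from a logistic model whose log-odds follow a
planted `effect_map` (defaults: +2.2 for team-score feedback and for
selection information over a 10% baseline, reproducing the qualitative
pattern that these two information types drive labor division). Ground truth
is attached to the output. `generate_feature_cohort()` instead plants exact
*standardized* regression effects at the feature-row level — the only level
at which "a standardized weight of 0.4" is well-defined — and is what the
parameter-recovery experiments use.

**Questionnaires.** The Interpersonal Reactivity Index generator uses one
latent level per factor per person plus independent item noise on the
five-point scale, with reverse-keyed items expressed at the opposite end of
the scale — the simplest model consistent with the Likert structure. The
default scoring key is the standard published one (reversed items 3, 4, 7,
12, 13, 14, 15, 18, 19), overridable per study; scores sum 7 items per
factor (range 7–35 on 1–5 scoring, with the classical 0–4 variant
available). Cronbach's alpha uses the $n-1$ variance denominator by default;
the convention is exposed because alpha shifts slightly under $n$.

**What the generator does not emulate.** Attention dynamics (crowding,
speed–capacity tradeoffs), learning within a session beyond the strategy
onset, response omissions correlated with difficulty, and any dependence of
questionnaire scores on behavior. Passing tests on this generator therefore
demonstrate that the *analysis machinery* is correct and calibrated, not
that real dyads behave like the generator.

## The regression stage

The pair-level feature table carries the three binary condition flags,
performance similarity (better member's mean score over worse member's,
$\ge 1$), pair mean and absolute difference per IRI factor, familiarity,
mean overlap, and the two benefit peaks as DVs. Pairs with incomplete
questionnaires are excluded once, before the first model, so every nested
comparison uses the same rows.

Everything (DV and binary flags included) is z-scored before fitting, so OLS
slopes are standardized weights and the intercept is 0. Interaction columns
are formed as products of the *raw* 0/1 flags before standardization,
because products of z-scores define a different design. Blocks are added in
a fixed order — experimental factors (plus interactions for the
collaborative model), similarity, questionnaire blocks, overlap last — with
each step reporting ΔR² and the nested F-test
$F = \frac{(RSS_s - RSS_l)/(p_l - p_s)}{RSS_l/(n - p_l - 1)}$.

Ridge regression minimizes $RSS + \lambda \lVert\beta\rVert^2$ with an
unpenalized intercept, solved in closed form; this keeps the λ ∈ [0.01,
100] sweep on the conventional scale. The sweep's selection criterion is
leave-one-out RMSE by default (the in-sample criterion is selectable); the
choice is open in the source analysis and LOOCV is consistent with how the
model's generalization is assessed. LOOCV refits with each pair held out
and — by default — re-estimates the z-scoring parameters inside each fold,
avoiding leakage from the held-out row; the simpler standardize-once
variant is selectable. Significance stars follow the conventional
.05/.01/.001 thresholds with no multiple-testing correction.

```{r}
f <- generate_feature_cohort(n_pairs = 128,
                             betas = c(team_score = 0.4, selections = 0.4),
                             seed = 1)
sp <- stepwise_pipeline(f, "dv",
  plan = list(c("individual_scores", "team_score", "selections"),
              "similarity"))
sp$steps[, c("step", "added", "r_squared", "delta_r_squared", "p_value")]
```

## Problem sizes and calibration checks

The test suite and `scripts/acceptance.R` run everything at the study's own
scale where that is cheap (128-pair cohorts, 100 trials, 1000-rep nulls) and
at reduced but statistically adequate scale elsewhere: the Monte-Carlo vs
closed-form sweep uses 2000 repetitions per count pair (errors bounded by
3 exact hypergeometric standard errors), independence calibration uses 16
pairs × 100 trials (mean collaborative ratio within ±0.02 of 1), parameter
recovery uses 100 replicate 128-pair cohorts, and the nested-F type-I rate
uses 1000 null simulations. These sizes are the package's choices, balancing
Monte-Carlo error against runtime.

## Known limitations

* The collaborative ratio is unstable when a trial's null expectation
  approaches zero from above (low-scoring members with high guess rates):
  such trials produce very large ratios that survive the non-positive
  exclusion rule and inflate the variance of the collaborative peak across
  pairs. This is a property of the ratio statistic itself; on synthetic
  cohorts it depresses the share of collaborative-peak variance the
  condition flags explain relative to the collective model.
* The peak of a smoothed series is a maximum statistic and sits above the
  series mean even for perfectly calibrated (ratio ≈ 1) pairs; peaks should
  be compared between conditions, not read as unbiased benefit levels.
* `performance_similarity()` is undefined when the worse member's mean score
  is not positive; the package raises an error and the pipeline records `NA`
  for such pairs rather than imputing.
* One violation of "every collaborative benefit implies a collective
  benefit" can occasionally appear near the peak-equals-1 boundary on
  synthetic cohorts; the analysis scripts count and report such pairs
  instead of suppressing them.
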