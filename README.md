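# jointmot

Simulation and group-benefit analysis for **joint multiple object tracking
(MOT)** — a task in which two people jointly track moving target objects
among identical distractors and try to maximize a shared team score.

The package is for researchers studying *group benefits* in joint action:
when does a dyad outperform its best member, how much of that advantage is
genuine coordination (labor division) rather than the statistical
facilitation two independent selectors get for free, and which pair-level
factors — task feedback, information about the partner's actions, ability
similarity, empathy traits — predict the benefit?

## What it computes

For a trial with target set $T$ and member selections $S_a$, $S_b$:

* individual score $s_i = |S_i \cap T| - |S_i \setminus T|$;
* team score on the pooled union,
  $s_{team} = |(S_a \cup S_b) \cap T| - |(S_a \cup S_b) \setminus T|$,
  so shared selections count once;
* overlap $|S_a \cap S_b| / |S_a \cup S_b|$ (low overlap = good labor
  division).

Two pair-level benefit criteria, each the peak of a 20-trial moving average
of a per-trial ratio series:

* **collective benefit** $= s_{team} / \max(s_a, s_b)$ — does the pair beat
  its better member?
* **collaborative benefit** $= s_{team} / \bar{s}_{null}$, where
  $\bar{s}_{null}$ is the mean team score over 1000 Monte-Carlo re-placements
  of each member's correct/incorrect selections uniformly among the
  targets/distractors — does the pair beat its own non-coordinating shadow?
  The null's exact expectation
  $T(1-(1-\frac{c_1}{T})(1-\frac{c_2}{T})) -
  D(1-(1-\frac{w_1}{D})(1-\frac{w_2}{D}))$
  is implemented as an analytic cross-check.

On top of that: a full synthetic-data generator (2D object kinematics with
specular reflections, capacity/accuracy/guess selection behavior, left-right
labor-division strategies, cohorts with planted effects and ground truth),
Interpersonal Reactivity Index scoring with Cronbach's alpha, and the staged
regression analysis — z-scored OLS with standardized weights, nested
F-tests, closed-form ridge with a lambda sweep, and leave-one-out
cross-validated RMSE.

## Worked example

```r
library(jointmot)

# one trial: members select {1,2,3} and {3,4,5}; targets are 1..6
individual_score(c(1, 2, 3), targets = 1:6)   # 3
individual_score(c(3, 4, 5), targets = 1:6)   # 3
team_score(c(1, 2, 3), c(3, 4, 5), 1:6)       # 5  (shared '3' counts once)
overlap_fraction(c(1, 2, 3), c(3, 4, 5))      # 0.2

# what would two *independent* members with 3 correct selections each score?
null_team_score(3, 0, 3, 0, 6, 13, n_reps = 1000, seed = 1)  # 4.478
expected_null_team_score(3, 0, 3, 0, 6, 13)                  # 4.5

# a full session for a pair that divides the screen left/right from trial 5
s <- generate_session(
  agents   = list(agent_profile(4, 0.95, 0.3), agent_profile(3, 0.9, 0.5)),
  strategy = strategy_spec("left_right_division", onset_trial = 5,
                           adherence = 0.95),
  n_trials = 100, seed = 42)
pair_benefits(score_session(s), 6, 13, window = 20, n_reps = 1000, seed = 42)
#  pair_id collective_peak collaborative_peak mean_overlap similarity
#        1           1.675           1.554706      0.05425   1.180905
```

The pair's best 20-trial stretch beats its better member by 67% (collective
peak 1.675) and its independence null by 55% (collaborative peak 1.555);
mean overlap near 0.05 shows the labor division, and the members' mean
scores differ by a factor of 1.18.

## The analysis workflow

`analysis/01_simulate.R` … `analysis/05_models.R` run the full synthetic
study (8 information conditions × 16 pairs × 100 trials, 4 pairs with
incomplete questionnaires excluded from all models): simulate, score,
benefit series, feature table, staged regressions of both benefit DVs plus
LOOCV and the ridge lambda sweep. Each script is a thin driver over the
package functions, prints what it found, and writes its tables under
`results/`:

```sh
Rscript analysis/01_simulate.R --seed 1
Rscript analysis/02_score.R    --seed 1
# ... through 05
```

`run_pipeline(run_config(...))` does the same end-to-end in one call, with a
manifest recording the seed and config fingerprint; the same seed reproduces
byte-identical outputs.

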