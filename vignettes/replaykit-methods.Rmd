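---
title: "Measuring replay and linking it to behavior: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring replay and linking it to behavior: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replaykit)
library(dplyr)
```

replaykit implements an analysis pipeline for studying time-compressed
sequential neural reactivation ("replay") in a dual-environment sequential
decision task, together with the behavioral models needed to interpret it.
This vignette explains the models, the tunable parameters, the synthetic
data generator that makes the pipeline testable end to end, and the
numerical and design choices we made where more than one reasonable option
existed.

## The task

Two independent environments ("worlds") each contain two three-state paths
ending in reward points between 0 and 9 that drift across trials. Each
trial starts, pseudorandomly, in one of two *equivalent* start states of
one world; the two options available at either start state lead
deterministically to the same two paths. Because reward learned from one
start state transfers to the other only through knowledge of the task
structure, choice behavior separates model-based from model-free control.
Reward points are multiplied by a per-trial stakes cue (1x or 5x). The
default session is 6 blocks of 24 trials (144 trials), and with the default
2 worlds x 2 paths x 3 states there are 12 decodable path states.

## Sequenceness: temporally delayed linear modeling

The neural substrate is a per-trial-period reactivation matrix: a
time-by-state matrix of decoded probabilities on a 10-ms grid (from
`apply_classifiers()` on real data, or `generate_reactivation_series()` on
synthetic data). Sequenceness is measured in two regression stages:

* **Stage 1** (`stage1_empirical()`). For each state *j*, the reactivation
  time course is regressed on the time courses of all 12 states lagged by
  $\Delta t$, entered jointly with an intercept. The coefficient matrix
  $B_{ij}$ is the empirical evidence that state *i* predicts state *j* at
  that lag.
* **Stage 2** (`stage2_sequenceness()`). $B$ is vectorized (all 144
  entries) and regressed on four structural matrices: the forward
  transition indicator $T_F$ (8 within-path transitions), its transpose
  $T_B$, an all-ones off-diagonal constant $T_{cons}$ absorbing background
  dynamics, and the identity $T_{auto}$ absorbing autocorrelation. The
  $T_F$ and $T_B$ coefficients are forward and backward sequenceness.

Repeating this over the lag grid $\Delta t = 10, 20, \ldots, 600$ ms
(`sequenceness_curve()`) yields lag profiles whose peaks localize the
state-to-state compression of replay. The analysis lags used for
trial-wise scoring default to 70 ms (forward) and 40 ms (backward,
feedback period); these are configuration, and the localization is
re-runnable on any dataset.

Stage-1 matrices are computed per trial and averaged within participant
before stage 2; the aggregation order is not uniquely determined by the
two-stage description, and per-trial estimation followed by averaging is
the variant that extends naturally to trial-wise scores. Reactivation
series can optionally be z-scored per state before stage 1 (`zscore`
argument, default off — decoded probabilities are already on a common
scale, and z-scoring amplifies near-silent states).

### Degenerate inputs and numerical choices

* A lag must be a positive multiple of the sampling step; windows must
  exceed the lag by at least two samples, and curve estimation additionally
  drops lags whose lagged design would have fewer rows than predictors.
* Constant (flat) reactivation series make the stage-1 design rank
  deficient; aliased coefficients are set to zero with a classed warning,
  and `trialwise_sequenceness()` flags such trials as degenerate with a
  score of 0.
* Stage 2 is solved by exact normal equations; on any matrix that is an
  exact linear combination of the four structural matrices the coefficients
  are recovered to machine precision (this is a tested invariant).

### Current- versus other-world scores

Trial-wise scores can be restricted to the paths of the trial's current
world or of the other world. We enter the directional matrices of *both*
subsets jointly in stage 2 and report the requested subset's coefficients.
With only one subset's matrices present, sequence structure on the
unselected paths inflates the constant control and biases the subset
coefficient negative — the joint design keeps the other-world score exactly
blind to current-world injections, which we verify by construction in the
test suite.

### Permutation significance threshold

`permutation_threshold()` draws random relabelings of the 12 states,
recomputes stage 2 at every lag under each relabeled $T_F$/$T_B$ (stage 1
is unaffected by relabeling of the structural matrices, which makes the
null cheap), and records the across-lag maximum of the absolute group-mean
curve per direction; the threshold is the 95th percentile of these maxima,
a familywise control over the lag grid. Relabelings that leave $T_F$
unchanged — the identity and whole-path swaps — are excluded, since they
would duplicate the observed statistic inside the null and inflate the
threshold. Per-lag uncorrected thresholds are also returned for curve
plots. The default of 500 draws resolves p to about 0.002; the calibration
(about 5% familywise exceedance on null data) is checked in the test suite
across 200 simulated null datasets.

## Decoding

State decoders are one-vs-rest L1-penalized (lasso) logistic regressions —
one per state — trained on the sensor pattern at a single post-stimulus
latency (default 200 ms), via glmnet. The penalty is selected by
stratified 5-fold cross-validation over a log-spaced grid spanning six
decades, scored by held-out multiclass accuracy; the descent to the target
penalty uses a warm-started path for stability on near-separable data.
Applied to a trial-period window (binned to 100 Hz with
`downsample_window()` so outputs live on the 10-ms lag grid),
`apply_classifiers()` returns per-time, per-state probabilities with no
renormalization across states — one-vs-rest outputs are left as is, since
renormalization would induce artificial anticorrelations across states that
stage 1 would then model. Overall reactivation is tested against
classifiers trained on permuted epoch labels
(`reactivation_significance()`); the summary statistic is the mean over
time of the across-state maximum probability, which drops when classifier
weights are misaligned with the true patterns. Training against an
additional null class is not implemented; the variants that matter here
(penalty, latency) are explicit configuration.

## Behavioral models

`nll_choices()` implements delta-rule Q-learning likelihoods with three
controllers: model-free (start-state action values $Q(s, a)$), model-based
(path values $V(p)$, looked up through the option-to-path map), and a
hybrid whose decision value is $w V + (1 - w) Q$. Parameters: learning
rate $\alpha \in [0,1]$ (shared across both stores; a single rate keeps
the hybrid nested exactly between the pure controllers), softmax inverse
temperature $\beta \ge 0$ on the 0-9 point scale, hybrid weight
$w \in [0,1]$, and an optional perseveration bonus (log-odds for repeating
the previous same-world path; default off). Values initialize at the
reward midpoint 4.5 to avoid first-trial optimism bias, and stakes do not
scale the learning update — learning tracks raw points.

Fitting (`fit_model()`) is bounded quasi-Newton (L-BFGS-B) from at least 5
random starts per participant, with AIC and BIC reported ($k$ counts free
parameters, $n$ observed choices). The likelihood nesting
(`nll(hybrid, w=1) = nll(mb)`) holds to machine precision and is tested.
Parameter recovery at the study scale (24 participants x 144 trials)
keeps the absolute bias of $w$ below 0.1 for $w \in \{0, 0.5, 1\}$.

The replay-modulated model (`fit_replay_modulated()`) adds two inverse
temperatures that apply only on world-change trials, split by whether the
preceding feedback-period backward replay of the upcoming world was high
or low. The split (`replay_split_labels()`) is a within-participant median
split over trials preceding a world change, ties assigned to "low", with
the label attached to the following (world-change) choice trial. The
across-participant comparison of $\beta_{high} > \beta_{low}$ uses a
one-tailed Wilcoxon signed-rank test. Note the identifiability caveat: on
the 0-9 value scale the softmax saturates for $\beta$ above roughly 10, so
contrasts between two large inverse temperatures are weakly identified at
realistic trial counts; recovery tests use contrasts in the identifiable
range.

## Rarity of experience

Experience of each world is tracked by the same delta rule applied to a
binary appearance indicator, $F \leftarrow F + \eta (I - F)$ with
$\eta = 0.10$ (a deliberately slow rate: the tracker integrates over
roughly the last 10-20 trials), initialized at 0.5. Rarity is $1 - F$.
With two worlds and complementary indicators the two frequencies sum to 1
on every trial, and the recurrence equals its closed form
$F_t = (1-\eta)^t F_0 + \eta \sum_k (1-\eta)^{t-k} I_k$ — both tested.
Regressor tables use the value after the current trial's update, i.e. the
rarity in effect at that trial's feedback.

## Linking replay to behavior

`build_regressor_table()` aligns, per trial: start-state change versus the
previous same-world trial (the benefit-of-generalization contrast), the
mean model-predicted value of the two options under the fitted controller,
current- and other-world rarity, reward, reward prediction error (reward
minus the fitted value of the chosen option), and world-change indicators.
`link_glm()` regresses trial-wise sequenceness — z-scored within
participant, so coefficients are comparable across periods and directions —
on these covariates with a random intercept and a random slope of the
first regressor per participant. On non-convergence or a singular fit it
falls back to a random-intercept model and then to ordinary regression,
each fallback reported. One-tailed p values are used only where a
directional prediction is declared, and every row records its sidedness.

Null predictions are tested by equivalence rather than by absence of
significance: `tost_equivalence()` runs two one-sided tests against
symmetric bounds, rejecting effects larger than the bound. For logistic
stay models the default bound maps a medium standardized effect
(d = 0.5) to log-odds via $d \, \pi / \sqrt{3}$ times the regressor SD
(about 0.907 for a z-scored regressor); for linking regressions on
standardized scores the default bound is 0.5 per unit regressor SD.
`dissociation_test()` compares two coefficients by
$z = (a - b) / \sqrt{se_a^2 + se_b^2}$, and
`across_participant_correlation()` relates per-participant effect sizes.

## The synthetic-data generator

Every stage is testable without any recording because the generator
produces each input with controlled ground truth:

* **Schedules** (`generate_task_schedule()`): worlds with equal marginal
  probability constrained to at most 3 consecutive repeats, uniform start
  states, i.i.d. equiprobable stakes, and per-path latent rewards following
  a Gaussian random walk (SD 2 points/trial) reflected at 0 and 9,
  initialized uniformly — drifty enough that model-free and model-based
  expectations frequently disagree, while never leaving the printed bounds.
  Observed rewards are the rounded latent values.
* **Choices** (`simulate_agent()`): any of the controllers above, plus
  synthetic log-normal reaction times (median 0.7 s, sdlog 0.25) with an
  additive 10-ms slowing on start-state-change trials as the default
  generative RT effect.
* **Epochs** (`generate_sensor_epochs()`): orthonormal spatial patterns
  (scaled; requires at least as many sensors as states) expressed at a
  nominal latency in Gaussian sensor noise.
* **Reactivation series** (`generate_reactivation_series()`,
  `simulate_cohort_reactivation()`): i.i.d. Beta(1, 10) baseline noise per
  state and sample — low, positive, bounded, mimicking one-vs-rest
  classifier probabilities on non-events — plus injected events that
  reactivate a path's three states in order (or reversed order, for
  backward events) at a controlled lag, rate, fidelity and per-trial
  amplitude, clipped to [0, 1]. Coupling the amplitude to a behavioral
  regressor (start-state change, rarity) builds cohorts with a known
  replay-behavior link.

What the generator deliberately does **not** emulate: sensor geometry and
field spread, temporally autocorrelated or state-correlated noise,
classifier cross-confusability between visually similar stimuli, eye
movements and artifacts, or any relationship between behavior and neural
noise. Passing tests therefore demonstrate that the estimators recover
what they are defined to recover under the stated noise model — not that
real MEG data satisfy that model.

## Problem sizes in the test suite

The validation suite runs the study-scale checks it can afford and scales
the rest down, as the package's own choice of test design: oracle
equivalence on 100 random instances; lag/direction recovery with 24
synthetic participants x 40 trials; permutation calibration over 200 null
datasets of 6 participants x 8 trials (lag grid 10-150 ms, 100 draws
each); parameter recovery at 24 participants x 144 trials; and the double
dissociation over 10 seeded cohorts of 12 participants x 48 trials,
requiring the qualitative 2x2 pattern (positive where coupled,
TOST-supported null where not) in at least 9.

## Known limitations

* Multilevel models use Wald inference; no parametric bootstrap or
  Satterthwaite correction for the logistic models.
* The replay-modulated model's inverse-temperature contrast is weakly
  identified when both betas saturate the softmax (see above).
* The permutation null relabels whole states; it does not test against
  temporally structured (autocorrelated) null dynamics beyond what
  $T_{auto}$ and $T_{cons}$ absorb.
* Fitting is per participant (no hierarchical shrinkage), matching the
  scale of the analyses the package targets.
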