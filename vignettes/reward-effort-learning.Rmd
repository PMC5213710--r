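---
title: "Modelling reward- and effort-guided learning and its neurochemical correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reward- and effort-guided learning and its neurochemical correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relmrs)
```

## The task and the scientific question

`relmrs` models behavior in a two-option reward/effort learning task.  On
every trial a participant chooses between two options.  Each option carries
three attributes: a reward probability displayed on screen (so it never has
to be learnt), a reward magnitude (0–20 pence) and an effort magnitude
(0–15 effort units), both of which drift slowly across trials and must be
learnt from the outcome feedback, which is shown for the chosen *and* the
unchosen option.  A session has 120 learning trials — 100 with the two
drifting options and 20 "special-option" trials pitting one drifting option
against a fixed, pre-trained option worth 7.5 pence at an effort of 4 or 12
units — plus 20 attention-check trials that carry no feedback and are
excluded from every analysis.  Participants complete two such sessions (240
learning trials).

The question the package is built around: how much does a decision-maker
*use* the information they have learnt, as opposed to the probability cue
that is handed to them on screen — and does that usage covary with the
balance of excitatory (glutamate) and inhibitory (GABA) neurotransmission
in dorsal anterior cingulate cortex, measured by MRS?

## The model family

Learning follows the Rescorla–Wagner rule.  For each option and attribute
the model keeps a prediction that is updated after every learning trial,

$$\hat{m}_{t} = \hat{m}_{t-1} + \alpha\,(m_{t-1} - \hat{m}_{t-1}),$$

with learning rate $\alpha \in [0,1]$.  Both options are updated every
trial because both outcomes are displayed.  Predictions live on a
normalised scale (reward / 20, effort / 15) so that probability, reward and
effort terms are commensurable inside one utility; this also makes
$\gamma$, $\lambda$ scale-free and $\beta$ comparable across models.  The
paper mixes pence, effort circles and probabilities in one sum without
stating units, so this normalisation is a design choice of the package;
initial predictions default to 0.5 (mid-range), also unstated in the
original.

Utilities take one of two forms.  The linear family (M1–M3) computes

$$U = (1-\gamma)\,P \;+\; \gamma\,\bigl(\lambda\,\hat{m}^{\text{rew}} -
(1-\lambda)\,\hat{m}^{\text{eff}}\bigr),$$

where $\gamma \in [0,1]$ — the *use of learnt information* — is the
parameter of scientific interest and $\lambda$ the reward-versus-effort
weight.  The multiplicative family (M4–M6) computes
$U = (1-\lambda)\,P\,\hat{m}^{\text{rew}} - \lambda\,\hat{m}^{\text{eff}}$.
Within each family the variants differ in learning: a single shared
$\alpha$ (M1, M4), separate $\alpha_{\text{rew}}, \alpha_{\text{eff}}$
(M2, M5), or no fitted learning rate at all, with predictions supplied by a
Bayesian mean-tracking observer (M3, M6).  Choices follow a softmax with
inverse temperature $\beta$:
$P(A) = e^{\beta U_A} / (e^{\beta U_A} + e^{\beta U_B})$.

On special-option trials the fixed option's values were learned before the
experiment, so its predictions are pinned to the known values (7.5 pence;
effort 4 or 12) rather than learned, and the hidden drifting option on that
side receives no update (its outcome is not shown).  Predictions reset
between sessions, which were run on different days.

### The Bayesian observer stand-in

The original study derived regressors from an optimal-observer model
published separately; this package provides its own documented stand-in: an
independent Gaussian random-walk filter (Kalman mean-tracker) per option
and attribute, with drift variance `q = 0.005` and observation variance
`r = 0.01` per trial on the normalised scale — values matched to the
schedule generator defaults (draw SD of 10% of range, i.e. observation SD
0.1, and infrequent level jumps).  Its steady-state gain behaves like a
fixed Rescorla–Wagner rate, and on data simulated from fitted-rate agents
its predictions correlate with the RW predictions above r = 0.95 (the test
suite checks this), which is the property the original analysis relied on.
It is a stand-in, not a reproduction of the original observer.

## Fitting

Two estimation paths are provided, mirroring the study:

* **Hierarchical Bayesian** (`fit_hierarchical()`): participant-level
  parameters are drawn from group normal distributions on an unconstrained
  scale — logit for $\alpha$, $\gamma$, $\lambda$; scaled logit onto
  $(0, \beta_{\max})$ for $\beta$ — and transformed back, so individual
  estimates are shrunk toward the group.  Group means have flat priors over
  the allowed range and group SDs half-normal(0, 10) priors.  The
  description of the inverse temperature as "sampled on a scale from 0 to
  1" is ambiguous for an unbounded positive parameter; the package reads it
  as a scaled-logit transform with configurable $\beta_{\max}$ (default 20,
  at which the softmax saturates for the largest normalised utility
  differences).  Sampling uses a purpose-built Metropolis-within-Gibbs
  scheme: coordinate-wise random-walk updates of each participant's
  parameters (all participants' proposals for one coordinate evaluated in a
  single vectorised likelihood call), conjugate Gibbs draws for group
  means, random-walk updates on log group SDs, and an interleaved
  *non-centred* joint update of (mean, SD) per parameter that moves the
  whole group block while holding the standardised participant deviates
  fixed — without it the chain cannot traverse the funnel that opens when a
  group SD collapses.  Step sizes adapt only during warm-up.  Defaults are
  three chains of 1000 kept samples after 1000 warm-up samples; convergence
  is judged by split-R-hat < 1.1 on every sampled quantity (the original
  reports checking convergence without a number) and a failing fit is
  returned flagged, never silently.

* **Maximum likelihood** (`fit_ml()`): Nelder–Mead on the unconstrained
  scale from 10 random restarts, ties broken by likelihood then smaller
  parameter norm.  A fit indistinguishable from random choice (likelihood-
  ratio test against $n\log 0.5$ at 5%) is flagged unidentifiable.  The
  test suite checks the optimum against an exhaustive grid search at step
  0.02 on a toy dataset.

Model comparison uses summed BIC over per-participant ML fits (with each
participant's own trial count in the $\log n$ penalty — whether the
original pooled $n$ is not stated) and half-split cross-validation: fit on
one session, score summed predictive log-likelihood on the other.  The
direction of the split is not specified beyond "one session as test set",
so both directions are computed and summed.

## The synthetic-data generator

The generator replaces the study's raw participant data and is first-class,
tested code.  It emulates:

* **Schedules** (`generate_schedule()`): per-trial probabilities drawn
  independently per option from {0.1, …, 0.9} (the displayed values
  "changed randomly" with no stated distribution; a discrete grid matches
  on-screen display practice); four magnitude means drifting among three
  levels as piecewise-constant blocks, boundaries staggered so exactly one
  mean changes at a time and each mean spends exactly one third of the
  learning trials at each level; draws around the means are normal,
  clipped to the legal ranges.  The paper does not print the real
  schedules' level values, draw SDs or block structure, so defaults are
  stand-ins chosen once: levels at 25/50/75% of each range, draw SD 10% of
  range ("slowly drifting" means must remain discriminable from draw
  noise), block length `n_trials/6` with offsets at quarters of a block.
* **Agents and cohorts** (`simulate_agent()`, `simulate_cohort()`):
  choices sampled trial-by-trial from the model's own softmax
  probabilities, with predictions updated from the displayed feedback.
  Cohort parameters are drawn on the unconstrained scale from group
  normals, exactly matching the fitting model's generative assumptions.
  Defaults (logit means/SDs): $\gamma$: 0.6/0.65, giving a median of about
  0.65 and a 95% population range of roughly 0.33–0.92 — anchored to the
  published illustration that used 0.33 and 0.92 as the extreme ends of the
  group confidence interval; $\alpha$: −1.0/1.0 (median ≈ 0.27, wide
  individual differences of the size hierarchical RL fits typically show,
  and consistent with the very strong parameter recovery the original
  study reports); $\lambda$: 0.2/0.5 (median ≈ 0.55, slight reward
  emphasis); $\beta$: median ≈ 7 on the (0, 20) scale — decisive but
  stochastic choices.
* **MRS cohorts** (`generate_mrs_cohort()`): glutamate and GABA creatine
  ratios built from a shared component plus a half-difference whose
  variance is solved from the target glutamate–GABA correlation (default
  0.47, the study's value); the difference mixes standardised $\gamma$
  with independent noise to hit the target contrast–behavior association
  (default 0.53).  Tissue fractions are drawn with SD 0.02 — voxel
  placement in the study was guided by sulcal morphology and highly
  consistent across participants, and at this realistic variability the
  four partial-volume correction variants give nearly identical
  associations, as the study found.  A configurable fraction of records
  receives a GABA CRLB above 20% to exercise the quality-control path.

What the generator does **not** emulate: reaction times, the motor
mechanics of the effort phase, failure-to-complete penalties, sequential
choice biases beyond the model (e.g. motor perseveration), non-stationary
learning rates, or any imaging signal.  Passing tests therefore show that
the pipeline recovers what this generative family produces — they cannot
certify behavior against model misspecification in real data.

## Behavioral validation and choice curves

`build_stay_switch_design()` codes the model-free check: a logistic
regression predicting whether the previous choice is repeated, from the
current probabilities and the last four trials' reward and effort outcomes,
each coded stay-minus-switch.  z-scoring is per participant (the
regression is per participant; the original does not say), and the first
four learning trials of each session are dropped because their lags are
undefined.  Group-level inference is a one-sample t-test for the
probability weight (df = n−1; the published df of 26 with 27 participants
implies no group covariate there) and, for each lag family, a test of the
per-participant mean lag weight against zero with the binary drug/placebo
group as a centred between-participant covariate — algebraically an F(1,
n−2) main effect, reproducing the published df structure.  Separated
logistic fits fall back to a ridge-penalised IRLS solution and are flagged.

`binned_choice_curves()` bins choices by the difference in learnt value
(observer predictions collapsed with a configurable $\lambda$, default 0.5)
and by the difference in displayed probability; the logistic slope on each
axis is the quantitative handle for "which curve is steeper" used in the
high/low-$\gamma$ illustration.

## Neurochemical statistics

`qc_filter()` drops records whose CRLB exceeds 20% (strictly; exactly 20%
is kept).  `correct_measures()` implements the four partial-volume
conventions: A exposes tissue composition as covariates instead of
dividing; B–D divide the creatine ratio by grey, by grey+white, or divide
metabolite and creatine by different tissue terms before taking the ratio.
`partial_spearman()` realises the nonparametric partial correlation as
Pearson correlation of rank residuals (the method is named but not
algorithmically specified in the original; this is the standard
construction and is oracle-tested), with a t-approximate two-sided p on
df = n − q − 2.  Because the variant-A covariates are exactly collinear
(total tissue = relative grey + relative white when fractions sum to one),
q counts the *rank* of the covariate matrix, not its columns.  A seeded
permutation p-value is available for small samples.  Two-sided p-values
are assumed throughout (the original does not say), and the plain
glutamate–GABA correlation is computed without covariates.

`neurochem_behavior_analysis()` runs the battery: contrast
(glutamate−GABA) versus $\gamma$ controlling for group, $\beta$ and tissue
composition; each neurotransmitter separately, additionally controlling
for the other; a specificity screen of the contrast against $\gamma$,
$\beta$, $\alpha$ and $\lambda$ at the Bonferroni threshold 0.0125 for
four tests (the $\beta$ screen drops $\beta$ from its own covariate set);
and the plain glutamate–GABA correlation.

## Numerical and design notes

* Softmax probabilities are computed in log-space and never overflow;
  likelihood contributions are floored at exp(−300) before logging.
* The schedule generator rejects trial counts that cannot satisfy exact
  level occupancy (`n_trials` must be a multiple of 6, and `n_trials/6`
  a multiple of 4 for the staggered boundaries).
* ML tie-breaks: highest likelihood, then smallest unconstrained norm.
* Every generator and fit is a pure function of (configuration, seed);
  stage seeds in the pipeline are derived from one master seed and logged
  in a manifest together with an md5 hash of the configuration.
* Reduced problem sizes used by the test suite, chosen as the smallest
  designs at which each property is stable: recovery at 2 sets x 27
  participants with 2 chains x 500 samples; model selection over 20
  cohorts of 12 participants comparing the shared-rate and observer
  members of each utility family (the separate-rate variants are nested
  near-duplicates of the shared-rate ones on shared-rate data and cannot
  change the family minimum); calibration loops at 200 seeds.  The
  acceptance script runs the full 10 x 27 recovery design.

## Known limitations

* The hierarchical sampler is a random-walk scheme: effective sample sizes
  per iteration are far below a gradient-based sampler's, compensated by
  cheap vectorised likelihood evaluations.  For much larger cohorts or
  models a Hamiltonian sampler would be preferable.
* The Bayesian observer is a stand-in (see above); M3/M6 results quantify
  the observer-prediction family, not the original observer.
* Real schedules, real group-level parameter values and the article's
  source data are not distributed; `reproduce_source_stats()` recomputes
  the published statistics when the source tables are supplied as CSV.
* Partial-correlation p-values use the t approximation; at n = 27 with
  several covariates the permutation option is the safer choice for
  borderline decisions.
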