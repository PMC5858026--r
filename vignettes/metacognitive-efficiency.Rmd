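---
title: "Estimating metacognitive efficiency from confidence ratings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating metacognitive efficiency from confidence ratings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In a two-choice task (S1 vs S2) followed by a confidence rating, a subject
performs two discriminations at once: the *type 1* task of classifying the
stimulus, and the *type 2* task of judging — via confidence — whether their
own response was correct. Raw confidence–accuracy associations (gamma or
phi correlations, or the area under the type 2 ROC) confound genuine
metacognitive insight with type 1 performance and response bias: two
subjects with identical introspective ability but different d′ will show
different confidence–accuracy coupling.

The meta-d′ framework removes this confound by asking a model-based
question: *what type 1 sensitivity would an SDT-ideal observer need in
order to produce the observed confidence data?* That value, expressed in
d′ units, is meta-d′. Its ratio to the subject's actual d′,
meta-d′/d′ (the **M-ratio**), is a measure of metacognitive *efficiency*:
1 for an observer whose confidence uses all the evidence available to the
decision, below 1 when confidence is noisier than the decision, above 1
when confidence draws on additional information.

## The type 2 observer model

All fitting in this package rests on one generative object. Under the
equal-variance Gaussian SDT model, evidence on S1-stimulus trials is
distributed Normal(−meta-d′/2, 1) and on S2 trials Normal(+meta-d′/2, 1)
(the symmetric placement makes c = 0 the unbiased point; the anchoring
convention is not empirically identified, only criterion positions relative
to the means are). The evidence axis is partitioned by the ordered
criteria

cS1(1) ≤ … ≤ cS1(k−1) ≤ meta-c ≤ cS2(1) ≤ … ≤ cS2(k−1)

where meta-c is the meta-level type 1 criterion and the cS1/cS2 are the
k−1 response-conditional type 2 criteria per side for a k-point confidence
scale. Confidence increases with distance from meta-c. For each
(stimulus, response) pair, `type2_probs()` returns
P(conf = y | stim, resp): the Gaussian mass of the corresponding cell
renormalised by the mass of the whole response region. The meta-level
criterion is tied to the observed type 1 bias through **meta-c′ = c′**,
i.e. meta-c = (c/d′) · meta-d′, so the meta-level model reproduces the
subject's response bias rather than fitting it.

Numerics: cells below meta-c are computed from lower Gaussian tails and
cells above from upper tails, so the cell/region-mass ratios remain well
defined far into the tails (relevant once meta-d′ exceeds ~15, which the
bivariate simulation's log-normal efficiency distribution does produce).
Tied (zero-width) criteria are permitted and yield zero-probability cells.

## Single-subject point estimation

`fit_metad_mle()` maximises the multinomial type 2 likelihood
Σ n(conf, stim, resp) · log P(conf | stim, resp) over meta-d′ and the
2(k−1) criteria; `fit_metad_sse()` minimises the unweighted sum of squared
differences between observed and model conditional probabilities over the
same space. Shared choices:

* **Constraints by construction.** Criteria are parameterised as meta-c
  plus cumulative positive (exponentiated) increments per side, and meta-c
  is tied to meta-d′ via c′, so every optimizer iterate satisfies the
  ordinal constraint and meta-c′ = c′ exactly. The increments make the
  problem unconstrained and quasi-Newton-friendly.
* **Optimizer.** BFGS from 5 deterministic starts (meta-d′ anchored at d′
  scaled by {1, 0.5, 1.5, 0.25, 1} with varied initial criterion
  spacings), objective tolerance 1e−8, best result returned with the
  optimizer's convergence flag. The multi-start count is pragmatic
  insurance against the rare flat/multi-modal likelihood at small n, not a
  statistical claim.
* **Edge correction.** Default padding of 0.25 added to all 4k cells
  before fitting (the multinomial generalisation of the log-linear
  correction). Padding is a bias–variance trade: it guarantees finite
  rates but systematically distorts estimates when trials are few — the
  package's false-positive experiment exists to quantify exactly that.
* **SSE weighting.** Observed conditional probabilities are computed on
  padded counts per (stimulus, response) cell; cells are *unweighted* —
  each contributes its squared probability error equally regardless of the
  response class's trial count. Whether the classical implementation
  weights by class frequency is not documented; unweighted was chosen and
  is stated here prominently because SSE values are not comparable across
  conventions.
* **Degenerate inputs.** If the padded hit and false-alarm rates coincide
  exactly (d′ = 0), c′ is undefined and the subject cannot be fit;
  `fit_metad_subjects()` returns an NA row with a warning so group
  pipelines continue. At 20 trials per subject and d′ = 0.5 this is a
  regular occurrence, not an edge case.

## Hierarchical Bayesian estimation

`fit_metad_group()` estimates the *group-level* efficiency directly.
Per subject, d′ and c are fixed at their point estimates (computed without
padding — the multinomial likelihood handles zero cells natively, which is
one of the main reasons to prefer this route at low trial counts; a
subject whose raw rates sit exactly at 0 or 1 gets rate-only padding
1/(2k), logged). Subjects whose d′ point estimate is not positive are
excluded with a warning: meta-d′ enters the model as exp(log M) · d′, so a
non-positive d′ forces meta-d′ ≤ 0 regardless of the confidence data — the
subject's log M likelihood then increases without bound toward −∞ and
would drag the group estimate down arbitrarily. Metacognitive efficiency
is simply not identifiable for a subject without measurable above-chance
type 1 performance. The subject's meta-level sensitivity enters as
meta-d′ₛ = exp(log Mₛ) · d′ₛ, with:

* log Mₛ = μ_M + ξ_M · δₛ, δₛ ~ Normal(0, σ_δ) — **parameter expansion**:
  the redundant multiplier ξ_M ~ Beta(1, 1) keeps the hierarchical scale
  from sticking near zero during sampling; the population SD is recovered
  per sample as σ_M = |ξ_M| · σ_δ.
* μ_M ~ Normal(0, 1), σ_δ ~ half-Normal(1): a log-normal prior on the
  M-ratio, symmetric about 1 on the ratio scale.
* Type 2 criteria: one group mean/SD pair *per criterion index*,
  mirrored across response sides — cS1ₛ(j) ~ Normal(−μ_c2(k−j), σ_c2(k−j)),
  cS2ₛ(j) ~ Normal(+μ_c2(j), σ_c2(j)), with μ_c2 ~ Normal(0, 10) and
  σ_c2 ~ half-Normal(10). A single scalar pair cannot represent several
  ordered criteria, so the compact one-pair notation is read as
  per-element. Ordering is enforced by truncating raw draws at meta-cₛ and
  sorting within each side.
* Each stimulus class's 2k counts are multinomial with cell probabilities
  P(resp | stim; d′, c) · P(conf | stim, resp; meta-d′, meta-c, criteria);
  the type 1 factor is a data constant, so this is equivalent to
  conditioning on response while keeping the full contingency table in one
  likelihood node.

Sampling uses JAGS (3 chains × 10 000 retained samples after 1 000
adaptation/burn-in iterations by default — enough for R-hat ≈ 1.00 on the
group mean in the canonical 20-subject study; all overridable). Chain RNGs
and initial values derive deterministically from `seed`, so results are
exactly reproducible within this backend. Inside the model every
multinomial cell probability is floored at 1e−5 (JAGS renormalises), which
guards against `phi()` saturation at extreme meta-d′ at the cost of a
slightly misspecified likelihood in a regime the data essentially never
occupy.

**Diagnostics.** `rhat()` is the classic potential scale reduction factor
√(((n−1)/n · W + B/n)/W); all-constant chains return 1 by convention, and
any monitored parameter at R-hat ≥ 1.1 triggers a warning, never an error.
`calc_ci()` is the central percentile interval (type 7 linear
interpolation); `calc_hdi()` the shortest window containing the stated
mass. DIC is computed from a deviance trace evaluated in R from the
monitored subject-level samples, with p_D = mean deviance − deviance at
the posterior mean (the plug-in convention, *not* half the deviance
variance — DIC values are comparable only within one convention). Using
the package's own likelihood for both terms keeps the two halves of DIC
consistent with each other and with the in-model probability floor.

**Group comparison.** `group_difference()` subtracts pooled μ_M samples
elementwise (random pairing under a fixed seed if lengths differ) and
reports whether the credible interval of the difference (in log units)
excludes zero. Subject-level posterior estimates from a hierarchical fit
must *not* be fed to a frequentist test — partial pooling violates the
independence assumption.

**Cross-domain correlation.** `fit_metad_correlation()` models the pair of
subject log-efficiencies in two tasks as bivariate Gaussian with
ρ ~ Uniform(−1, 1), per-task means ~ Normal(0, 1) and SDs via precision ~
Gamma(0.001, 0.001); no parameter expansion in this variant. Because each
subject's efficiency enters as a latent variable, the posterior on ρ is
automatically disattenuated for estimation noise — it estimates the
correlation of *true* efficiencies, and can therefore legitimately exceed
the sample correlation of point estimates.

## The simulator

`metad_sim()` decouples performance from metacognition in two stages:
the four type 1 response-class counts (hits, misses, false alarms, correct
rejections) are drawn from the binomials implied by d′ and c — binomial
rather than fixed-quota, matching a genuine SDT observer — and each
class's confidence counts are then drawn from the multinomial given by the
type 2 model at meta-d′ = mratio · d′. Trials split equally between
stimuli with an odd trial going to S2. `simulate_group()` adds per-subject
d′ ~ Normal(mean, SD), floored at 0.1 so the contract is total (at the
default Normal(2, 0.2) the floor is never hit in practice); each subject
consumes sub-seeds derived from (seed, subject index), so subject s's data
do not depend on how many subjects are requested.
`simulate_noisy_confidence()` is the trial-level observer whose rating —
but not decision — is corrupted by Gaussian noise: ratings are binned on
the chosen-response side of c, and noisy values that cross the decision
criterion clamp to the lowest-confidence bin because the decision is not
revisited.

What the generator does *not* emulate: criterion drift over trials,
unequal S1/S2 evidence variance, response-conditional metacognitive
asymmetries, lapses, or reaction-time structure. Passing recovery tests
therefore shows the estimators are correct *under the model's own
assumptions* — it does not certify them against real data that violate
those assumptions.

In the bivariate simulation the per-subject log-efficiencies are drawn
from a bivariate Gaussian with means 0.8 and SDs 0.5 on the *log* scale,
read literally from the generative description of the two-task validation
study. That puts the median M-ratio at e^0.8 ≈ 2.2 — metacognitively
super-ideal — and occasionally produces meta-d′ above 15; ρ-recovery is
location/scale-invariant, so this choice affects only numerical stress
(handled by the tail-stable probability code), not the estimand.

## Validation studies and problem sizes

The package ships its validation as runnable code:

* `run_example_fit()` — 20 subjects × 400 trials, 4 levels,
  c2 = ±(0.5, 1, 1.5), c = 0, d′ ~ N(2, 0.2), efficiency 0.8; the
  hierarchical posterior mean lands within ±0.1 of truth with
  R-hat ≈ 1.00.
* `run_recovery_grid()` — the same design across efficiencies 0.5–2.
* `run_fpr_experiment()` — the three estimation routes compared on
  null data (true M-ratio 1) across d′ × trial-count cells, with the
  decision rules: p < 0.05 one-sample t-test against 1 for MLE/SSE,
  95% CI excluding 1 for the hierarchical fit. The package's test suite
  runs the harshest cell (d′ = 0.5, 20 trials/subject, 10 replicates,
  3 000 retained samples per hierarchical fit) and records all three
  rates.

A candid note on that harshest cell. At 20 trials and d′ = 0.5 the
sampling SD of the per-subject d′ point estimate (~0.6) exceeds d′
itself: a fifth of subjects land at or below chance (excluded, see
above), and subjects with small positive d′ estimates need log M far in
the prior's tail to express an ordinary meta-d′, which partial pooling
shrinks away. The plug-in scheme treats these point estimates as known,
so the group posterior inherits a downward bias with an interval too
narrow for it, and its false-positive rate in this cell is high —
*higher*, in this implementation, than the t-test on single-subject fits,
whose per-subject ratio estimates are so heavy-tailed there (ratios of a
noisy meta-d′ to a near-zero padded d′) that the t statistic loses all
power. An oracle experiment confirms the mechanism: plugging the *true*
d′ and c into the hierarchical model recovers the same cell essentially
perfectly, with wide intervals covering truth. The practical
recommendations follow directly: below ~50 trials per subject, treat any
group-level efficiency inference with suspicion, and treat the per-subject
d′ estimates — not the MCMC — as the binding constraint.

The automated test suite and the acceptance script deliberately scale
sampler settings by what each claim needs: the canonical example fit runs
at full default settings; the grid endpoint uses 5 000 retained samples
per chain; the 100-subject bivariate fit 2 500 (posterior means of
well-mixed chains stabilise long before the default 10 000); these sizes
are stated here as the package's validation design.

## Known limitations

* Equal-variance type 1 model only; the unequal-variance extension is
  deliberately out of scope because response-specific efficiency and the
  variance ratio are not jointly identified from a single task.
* d′ and c enter the hierarchical model as plug-in point estimates, not
  jointly estimated latent variables.
* With near-empty data the group posterior is prior-dominated but not
  literally the prior: even single extreme-confidence trials inform the
  multinomial likelihood. (Subjects with *no* usable trials — undefined
  type 1 rates — are excluded with a warning.)
* DIC uses the plug-in p_D convention and the in-model probability floor;
  compare DICs only between fits produced by this package.
* The false-positive experiment's scaled-down replicate counts bound the
  Monte-Carlo resolution of rate estimates at 1/n_reps.
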