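---
title: "Composing behavior from action values: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composing behavior from action values: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(qcompose)
```

# The scientific question

Animals and artificial agents can assemble a new behavior from previously
learned pieces.  `qcompose` implements a complete computational testbed for
one specific account of how that happens: the action-value functions
(Q functions) of two pretrained subtasks are combined by simple arithmetic
-- elementwise averaging -- to initialize the value function of a novel
composite task, and maximum-entropy (stochastic) subtask policies make the
composed value transferable.  The package provides

* a continuous arena simulator with two subtasks and their composite,
* a soft actor-critic (SAC) trainer whose twin critics can be composed by
  averaging or by the elementwise maximum,
* behavioral estimators (state values, action values, policy fields,
  policy entropy, occupancy) that apply equally to agent episodes and
  mouse-like trajectories,
* an encoding-model (GLM) and classification stack that identifies
  Q-representing units from activity, with shuffle nulls and FDR control,
* a nearest-neighbor KL estimator for population-manifold overlap, and
* a synthetic session generator with planted ground truth so that every
  analysis stage can be validated end to end.

# Tasks and environment

The arena spans $[-1,1]^2$ (2.0 x 2.0 arbitrary units).  The state given
to an agent is $(x, y, v_x, v_y)$, where velocity is the last applied
movement.  Actions are $(\mathrm{d}x, \mathrm{d}y, \ell)$ with movement
components in $[-0.1, 0.1]$ and a lick magnitude in $[0, 0.1]$; a lick
event is counted when $\ell > 0.08$.  All three tasks share this action
space so that Q networks are composable over a common domain; the lick is
inert in Task 1, and movement in Task 2 is free, with licking rewarded
only within reach of the water spout (a small region around the
bottom-middle start).  These two Task 2 choices matter for composition.
If the agent cannot move, the critic is trained on a single state and
its spatial value profile is arbitrary network extrapolation; if licking
paid everywhere, the true $Q_{task2}$ would be uniformly high and carry
no spatial structure at all.  With free movement and a spout-gated
reward -- as for a mouse that must reach the spout to lick it --
$Q_{task2}$ acquires a genuine value peak at the bottom middle, which
becomes the second high-value region of the averaged composite Q and is
what steers composed agents toward the bottom center.

* **Task 1** rewards reaching a central 0.8 x 0.8 reward zone from a
  random start outside it.
* **Task 2** starts the agent at the bottom middle $(0, -0.98)$ and
  rewards a lick event within the spout region
  ($|x| \le 0.1$, within 0.1 of the start).
* **Composite** requires reaching a small target (0.1 wide, 0.0031 tall,
  centered at the bottom edge); the agent then becomes immovable and must
  lick to collect the reward.  The reward requires target entry at a
  strictly earlier step than the lick.

Episodes are capped at 300 steps and truncate with zero reward.

**Edge handling.**  A movement component that would cross an arena wall
is *rejected* (that coordinate stays put) rather than clipped to the
wall, but goal *contact* is judged on the wall-projected candidate
position: pushing into the wall within the target's x-range counts as
touching the spout.  This combination is load-bearing for the composite
task.  If positions were clipped onto the wall, the bottom edge $y = -1$
would lie inside the 0.0031-tall target band and any random policy would
slide along the wall into the target, making the composite task trivially
solvable from scratch.  If contact also required the position to land
inside the thin band, no policy -- composed or not -- could realistically
reach it.  With rejection plus wall contact, an untrained policy touches
the target in under a tenth of its episodes, too sparse to learn from at
the study's learning rate, while an agent whose value function
concentrates behavior near the bottom center touches it repeatedly --
the difficulty structure under which composition matters.

# Soft actor-critic and composition

The trainer maximizes expected return plus $\alpha$-weighted policy
entropy.  Actor and critics are multilayer perceptrons with ReLU hidden
layers; the policy is a tanh-squashed Gaussian with state-dependent mean
and log-standard-deviation (clamped to $[-20, 2]$).  Two critics are
trained independently against the soft Bellman target; their minimum
drives policy improvement; target networks track the online critics by
polyak averaging (0.995); the optimizer is Adam.  Default hyperparameters
follow the study conditions: 3 hidden layers of 256 units, discount 0.95,
learning rate $10^{-4}$, replay $10^6$, 300 steps/epoch for 200 epochs,
$\alpha = 0.02$ for subtasks (0 for the deterministic variant) and 0.005
for the composite task.  Batch size 256, one update per environment step
after 1000 warm-up steps of uniform random actions.

`compose_q()` builds a composite critic that evaluates both subtask
critic subnetworks on the shared input and combines the scalar outputs by
the mean (so the composite Q is exactly the arithmetic average of the
subtask Qs at initialization) or the elementwise maximum.  Both twin
critics are composed pairwise.  The composite *actor* is freshly
initialized and learns against the composed critic; whether the original
study warm-started the actor is unstated, so the fresh-actor choice is a
design decision of this package.  During fine-tuning, gradients flow into
both subnetworks through the combining operator (uniform 1/2 weights for
the mean; the per-sample argmax indicator for the maximum).

`control_init()` composes Task 1 with a Task 2 variant trained at the
*top* middle of the arena: the mean composite Q over uniformly sampled
states and actions stays comparable (checked on $10^5$ samples, warning
beyond 10%), but the useful value structure is destroyed.

`ablate()` forces chosen hidden units' activations to zero in both twin
critics (and their targets); masks persist through fine-tuning, and the
control mode draws an equal number of units from the complement of the
ablation set.

## Reduced-scale experiment profile

Training 6 agents for 200 epochs with 3 x 256 networks is a
multi-hour computation.  The package therefore defines two profiles
(`train_profile()`): `"full"` with the study conditions above, and
`"reduced"` -- the desk-scale profile used by the tests, examples and the
acceptance script -- with 2 x 48 hidden layers, short subtask pretraining
(30 epochs for Task 1, 6 for Task 2) at learning rate $10^{-3}$, and
composite fine-tuning for 50 epochs at the study's $10^{-4}$ with one
gradient update per two environment steps.  The fine-tuning rate matters
qualitatively: at higher rates a scratch agent can bootstrap from rare
chance rewards within a few epochs and the composition advantage washes
out; at $10^{-4}$ value propagation from sparse rewards is slow -- as in
the full-scale setting -- while a composed critic needs no value
learning, only policy improvement.  The "early stage" of composite
learning is summarized as the mean return over the 50 fine-tuning epochs
(the first quarter of the full 200-epoch schedule).

# Behavioral value estimation

Because the reward arrives only at the terminal state, the state value
simplifies to $V(s) = \mathbb{E}[\gamma^{T-t}]$ over visits to $s$ in
rewarded trials ($\gamma$ = 0.95 per step for agents, 0.99 per 10 ms for
mouse-like data).  Values live on a 10 x 10 binning of the arena; the
reward zone is pinned at $V = 1$; miss trials carry no terminal reward
and are excluded from V (they still contribute to occupancy and policy
fields; the value map records the hit/miss counts).  Action values follow
by one-step lookahead, $Q(s,a) = \gamma V(\mathrm{neighbor}(s,a))$ over
8 directions plus no movement, with the same bin's value used at the
arena edge and for no movement.  Policy fields are speed-weighted vector
sums of movement vectors per bin (100-ms windows for mouse-like data);
policy entropy is the Shannon entropy (natural log) of the 8-direction
distribution, averaged over visited bins.  Displacements below 0.05
arena units per window count as no movement.

# Encoding models

Task variables sampled at 2000 Hz enter a design matrix: events (trial
onset/offset, lick onsets) expand through 6 evenly spaced raised-cosine
bases over $\pm 2$ s; rewards through 9 bases over $-2$ to $+4$ s; object
and joystick velocity decompose into 8 direction channels carrying
movement amplitude, each expanded through the 6 temporal bases; object
position is one-hot on the 10 x 10 arena and expanded through a 10 x 10
grid of two-dimensional raised cosines with width 1.5x the grid spacing.
Predictors are convolved at the sampling rate and downsampled by
averaging within each imaging frame (~5.67 Hz).  The temporal bases are
$\cos^2$ bumps with width equal to twice the center spacing, so their
interior sum is exactly constant.

Fitting is Gaussian identity-link ridge regression.  The penalty is
selected **per unit** by nested cross-validation (5 contiguous-block
outer folds; the inner criterion is held-out SSE over the training
blocks; candidate penalties $10^{-1} \ldots 10^4$); pseudo-explained
variance is $1 - \mathrm{SSE(model)}/\mathrm{SSE(intercept)}$ on held-out
frames, averaged over folds.  All units share the design, so the
factorizations are computed once per fold and penalty and reused --
fitting thousands of units costs little more than one.

Response profiles marginalize the fitted model: the space map evaluates
the spatial bases at the 100 bin centers; direction tuning is the
predicted response to sustained movement at the session's mean amplitude
in each of 8 directions (channels are mutually exclusive: the other
channels are set to zero, which also defines the no-movement level); lick
tuning contrasts the reconstructed post-lick kernel (averaged over the
second after onset) with the no-lick baseline.

# Classifying Q-representing units

Two classes of Task 1 Q representation are identified, as in the study.
*V-like* units have space maps correlated with $V(s)$; the null shuffles
the unit's map relative to the value map.  For square maps this shuffle
is a random two-dimensional circular (torus) shift: GLM-derived maps are
spatially smooth, and a full bin permutation destroys that smoothness,
making the null miscalibrated (smooth noise maps would be flagged).  The
torus shift preserves local structure and calibrates correctly.

*Q-conjunctive* units have direction tuning matching the local Q
distribution: Q is averaged over the unit's top-5% space-map bins
(weighted by normalized activity; at least 2 bins; only bins with a
defined Q row participate), and compared with the unit's direction tuning
by Pearson correlation and by a dot product computed on the mean-centered
tuning.  Centering matters: the estimation noise of a GLM profile is
dominated by a common-mode component (the unit's overall level) that
would otherwise swamp the direction-specific signal.  The null
distribution recomputes tuning under the movement-direction time-series
shuffle.  Refitting the GLM per shuffle is infeasible, but the fitted
direction profile is a fixed linear functional of the activity trace, so
the package uses a Freedman-Lane scheme (`velocity_profile_null()`): each
unit's activity is split into its reduced-model prediction (all
predictors except object velocity) plus residuals, the residuals are
circularly shifted against the design, and the same profile functional is
applied.  This preserves the unit's relationship to position and events
and its autocorrelation while destroying direction dependence.  A naive
circular shift of the raw activity is *not* usable: slow position-driven
autocorrelations then produce spurious velocity weights an order of
magnitude larger than the observed profile.

The Q-conjunctive test runs only on conjunctively tuned units, as in the
study: a unit enters the pool when its direction-profile spread beats the
shuffle null (screen p < 0.2) and its position group EV exceeds 0.02 and
half the velocity group EV.  The EV-dominance screen removes
direction-only units whose ridge-leaked space maps would otherwise mimic
conjunctive coding (under a goal-directed policy, where a direction is
used is exactly where it is valuable -- a behavioral confound that no
shuffle can remove).  FDR (Benjamini-Hochberg, 5%) is applied within the
pool, separately per metric, and a unit is labeled when either metric
survives.  Permutation p-values use the add-one rule throughout.

*Lick-Q* units comodulate their lick tuning (mean activity in the second
after lick onsets versus elsewhere) with the Q(lick)/Q(no-lick) contrast;
the null circularly shifts the lick-onset series.  *Mixed-composite*
units (composite task only) have space maps correlated with the
action-averaged composite Q map -- the average of the Task 1 value map
and the spatial value map of the stationary Task 2 goal, i.e. the
composition prediction with two high-value regions -- tested against the
torus-shift null within space-encoding units.  The chance level assumes
uniformly distributed place fields shaped like the GLM spatial basis.

For network units the same classifiers run on probed tuning: hidden-unit
activations for $10^5$ uniformly random state-action inputs, binned into
40 x 40 spatial bins and 8 movement-direction sectors, with nulls built
by randomly relabeling the probe samples (the sampling analog of the
time-series shuffles).  Q references come from the critic itself,
evaluated on a grid of states and canonical actions.

# Manifold overlap

Population activity is embedded by PCA fit on the composite condition;
the subtask condition is projected with the composite coefficients.  The
retained dimensionality is the smallest number of components explaining
80% of composite variance, capped at 10 (recorded in the output; the
study does not state its choice).  Overlap is the nearest-neighbor KL
estimate $\widehat{KL} = (d/n) \sum_i \log(s_i / r_i) + \log(m/(n-1))$
with $r_i$ the distance of each subtask sample to its nearest neighbor
among the subtask samples and $s_i$ to its nearest neighbor among the
composite samples ($n = m$; 1000 samples for Task 1, 500 for Task 2 by
default).  The permutation null shuffles the composite unit index before
the PCA; because PCA is invariant to column order, this is algebraically
identical to projecting the subtask data with permuted unit order through
the fixed loadings, which is how the null is computed (1000
permutations, one-tailed p for the observed KL lying below the null).

# The synthetic-data generator

`generate_session()` produces mouse-like sessions on a 10 x 10 cm arena
at a 10-ms base rate: Task 1 trials from random starts to the central
4 x 4 cm reward zone, stationary Task 2 licking trials with a 2-s delay
before the response period, and composite trials that freeze at a
bottom-middle target before licking.  Movement follows smooth heading
dynamics -- the heading is pulled toward the goal and diffuses with
angular noise -- because direction persistence at the ~100-ms scale is
both physically realistic (a joystick-driven object) and necessary for
direction tuning to be identifiable at the 5.67-Hz frame rate.  The
expert policy keeps substantial angular spread (drift 0.7, angular noise
0.9), reflecting the study's central observation that trained behavior
remains stochastic; the naive policy is nearly undirected.  Hit trials
append a 4-s reward-consumption period and 2-s intertrial interval.
Sessions default to 150 trials (roughly a quarter hour of recording).

Planted unit classes mirror the classification targets: place cells
(2-D Gaussian fields, sigma 1.0-1.6 cm), direction cells (von Mises over
movement angle), V-like cells (proportional to the analytic
discounted-steps value), Q-conjunctive cells (broad fields, sigma
2.0-2.8 cm, gated by the local Q-matched direction profile; fields are
planted outside the reward zone, where the Q profile would be flat and
the class undefined), lick cells (lick-suppressed, so that the class is
distinguishable from lick-Q cells under the comodulation test), lick-Q
cells (lick-locked transients scaled by the momentary lick value),
mixed-composite cells (broad fields at the arena center and bottom
middle) and untuned cells.  Value-tuned classes carry the Task 1 value
structure in every task, reflecting the retention of subtask
representations in the composite task; composite-session classification
is accordingly referenced to Task 1 maps estimated from companion subtask
data.  Latent drives are convolved with an exponential transient kernel
(tau = 0.15 s, a deconvolved-trace surrogate), averaged within frames,
and corrupted with Gaussian noise at 1/SNR of the signal standard
deviation.  The default SNR of 5 emulates activity-thresholded
deconvolved traces: analyses of real recordings (including the study's)
keep only units whose activity passes a threshold, so the analyzable
population has clearly resolvable transients.

What the generator does *not* emulate: imaging noise structure (motion,
neuropil), biophysical calcium dynamics, cross-regional correlations, and
units with mixed selectivity outside the planted classes.  Passing
recovery tests on these sessions therefore demonstrates that the analysis
stack is correct and calibrated, not that real cortical data would yield
the same fractions.

## Recovery benchmarks and their limits

Per-class recovery is assessed in the session type whose behavior
identifies the class: V-like and Q-conjunctive in Task 1 sessions, lick-Q
in Task 2, mixed-composite (and V-like) in composite sessions.  Composite
movement is directionally homogeneous (down the middle of the arena),
which leaves direction tuning under-identified there -- a genuine
property of the task, not an implementation artifact; the study's own
composite-task conjunctive analysis rests on companion subtask sessions
of the same neurons.

# Numerical choices and degenerate inputs

* Permutation p-values: $(1 + \#\{null \ge obs\})/(1 + S)$.
* Pearson on constant vectors is undefined; the dot-product metric then
  decides alone.  Units with all-NA or constant maps are labeled none.
* Space-map peak ties resolve to the first bin in map order (x-major,
  counted and reported).
* Zero nearest-neighbor distances in the KL estimator are jittered by
  machine epsilon with a warning.
* All randomness flows through private, seed-derived streams that never
  touch the caller's RNG state; regenerating any object from the same
  seed is bit-identical.

# Problem sizes used by tests and the acceptance script

The shipped tests and `scripts/acceptance.R` run the reduced profile:
one to two seeds per experiment, 2 x 48 networks, 30/6-epoch subtask
pretraining, 50-epoch composite fine-tuning, synthetic sessions of
200-900 units (2000 planted units across the session types) at a 500-Hz
design rate, and 400-800 shuffles per null.  These sizes are the
package's own choices for desk-scale reproducibility; the full study
conditions remain available through `train_profile("full")` and the
generator defaults.
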