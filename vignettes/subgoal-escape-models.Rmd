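---
title: "Modeling obstacle-edge subgoal learning: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling obstacle-edge subgoal learning: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subgoalsim)
```

`subgoalsim` simulates how reinforcement-learning agents acquire — or fail
to acquire — obstacle-edge subgoals during shelter-directed escape, and
quantifies continuous escape trajectories the way the corresponding animal
experiments are analyzed. This vignette explains the models, the parameters
that matter, the places where the design was genuinely open and what we
chose, and what the package's passing tests do and do not establish.

## The arena as a Markov decision process

The environment is a deterministic MDP on a 13x13 grid discretizing a 92-cm
circular platform. The canonical layout (fixed in one place and written to
plain-text map files by `write_gridmap()`) uses row widths
5, 7, 9, 11, 11, 13, 13, 13, 11, 11, 9, 7, 5 — a 125-cell disc — minus a
7-cell obstacle row in the center, leaving exactly 118 accessible cells and,
with 8 compass actions, 944 state-action pairs. The shelter sits centered
below the obstacle at (6, 9), the threat cell centered above it at (6, 2).
Entry into the shelter pays +100 and ends the episode; every transition is
charged its step length (1 cardinal, sqrt(2) diagonal) scaled by a
per-agent constant; a blocked move leaves the agent in place and is charged
the attempted step. On the no-shelter training map (condition 2) there is no
reward and no step penalty. The exact cell coordinates of shelter, threat
zone, obstacle span and trip wires are not published anywhere in numeric
form; the layout here is a reconstruction constrained by the 118-cell
invariant and the arena's symmetry, which is why the package's quantitative
simulation checks carry a +/-10-percentage-point tolerance.

Two conditions add a one-way **trip wire**, the simulation analog of
closed-loop interruption of edge-directed runs:

* **Condition 3 (full wire).** Southward crossings of the row-4/row-5
  boundary landing in columns 1..11 are blocked; the two perimeter columns
  stay open. The wire spans both sides of the arena: if one approach stayed
  open, a value learner would simply learn the direct route to the other
  obstacle edge and the condition would not force detours at all. The open
  perimeter leaves a legal route whose deviation from the direct edge path
  is at least two cells — the signature of a "tortuous" escape.
* **Condition 4 (partial wire).** Edge-directed actions (W, E, SW, SE) out
  of the threat-zone cells (rows 1-4, columns 4-8) are blocked. Poleward
  moves (N, NW, NE) are not edge-directed runs and pass freely, as do all
  moves from neighboring non-zone cells. The zone spans rows 1-4 because a
  shallower zone leaves one-step-deviation staircases to the edge that
  would classify as edge vectors; the lateral moves between two zone cells
  are blocked in both directions for the same reason (this is the one place
  where the wire is not strictly one-way, and the audit test documents it).

## Agents

All agents share the published hyperparameters: Q-learning gamma 0.9,
trace decay lambda 0.5, alpha 0.1, step-penalty scale 0.01; SARSA gamma
0.99, scale 0.001; SR gamma 0.9, lambda 0.5, alpha 0.1; tiles 2x2 and 3x3;
gradual model buffer N = 15. Four numerical choices deserve explanation:

* **SR step penalty and value.** The hyperparameter table lists a step
  penalty only for Q-learning and SARSA, and the SR's value is stated to
  reduce to `M(S,A,shelter) R(shelter)` — which is only true when
  non-shelter rewards are zero. The SR therefore runs with step-penalty
  scale 0.
* **SR bootstrap.** The expectation over next actions is taken on policy:
  the realized next action samples it. A uniform average (available via
  `sr_onpolicy = FALSE`) has the random-walk SR as its fixed point, whose
  discounted shelter occupancy from the threat cell is essentially zero, so
  a uniform-expectation SR never expresses the practiced edge routes at
  test — incompatible with this SR's role as an on-policy learner whose
  action values depend on how often an action led to the shelter.
* **SR initialization.** The successor matrix is initialized with small
  zero-mean noise (sd 0.01, configurable via `init_sd_m`). With large init
  noise, rows of rarely-taken actions keep their noise for tens of
  thousands of steps (noise in a row contracts only when that pair is
  taken, at rate alpha), and residual noise of order 0.1-1 dominates the
  attainable occupancy signal at the threat cell (about 0.05-0.2 at the
  published training budgets), turning every condition into non-escape.
  Keeping the initialization random but negligible is the only reading
  under which the published budgets produce the published behavior.
* **Blocked attempts and traces.** A blocked attempt receives its own TD
  update (the agent learns the wall) but is removed from the eligibility
  trace: an accumulating trace would otherwise credit the wall-bump with
  the reward of the route the agent subsequently takes, and the inflated
  blocked action — replayed on the wire-free test map — cuts the learned
  detour back to a one-step deviation.

**Hierarchical state space.** The arena is partitioned into 10 named
regions (threat, shelter, the two obstacle-edge areas, two mid-field
pockets, above/below-obstacle centers, two back-perimeter strips),
reconstructed so that cell-level adjacency between regions yields exactly
40 directed region-action pairs and, critically, so that the threat region
touches the edge regions along the column-3/column-9 seams — practice runs
launched from those flank columns cross threat-to-edge directly, which in
condition 4 (where the wire silences all zone-origin edge-ward moves) is
what lets the region-level learner acquire a valuable
"threat area to obstacle edge area" action it has never executed from the
escape-trigger cell itself. Region actions are temporally extended, so
their discount and trace decay use `gamma^(centroid distance)` — the same
centroid distance that sets the step penalty. With plain per-crossing
discounting, the one-hop advantage of the direct threat-to-edge action over
a mid-field detour (a factor gamma = 0.9) is smaller than the stationary
noise of constant-step-size learning on +/-100 returns, and condition-4
route choice degenerates into a coin flip. The shelter bonus accumulated
inside a region is credited to the action that entered it, so each region
update is applied at the next boundary crossing (or flushed with a zero
bootstrap at shelter entry). The low-level controller walks the rasterized
straight line to the target region's anchor cell and slides 45 degrees
along walls; without sliding it deadlocks against the obstacle whenever a
region line crosses it.

## The three-phase protocol

Training is **episodic**: the agent is dropped at a uniformly random
accessible cell and explores with a uniform random policy until it enters
the shelter (absorbing), completes a scripted practice run, or reaches a
100-step episode cap; eligibility traces and pending on-policy updates do
not cross episode boundaries, and total steps are fixed by the published
budget table (e.g. tabular Q 30k with practice runs, SR 20k, model-based
3k, hierarchical 1.5k). A continuing-walk reading was rejected because the
practice runs transport the agent toward the shelter side on every trigger,
and the resulting stationary distribution oversamples the bottom of the
arena roughly five-fold — starving exactly the threat-side cells whose
values decide the escape.

**Practice runs** mimic the animals' rapid, direct exploratory runs: on
entering one of eight threat-area start cells per side (p = 0.2 per entry),
a scripted geodesic takes the agent to an obstacle edge *and on to the
shelter* in one compound trajectory; separate shelter-vector runs trigger
at the edge cells. Trip wires interrupt a script exactly as they interrupt
ordinary moves, which is the mechanistic heart of conditions 3 and 4: in
condition 3 every edge-bound script is cut at the wire; in condition 4 only
the scripts launched from outside the zone's columns complete.

Each of three trials then runs a **pre-test** (random walk from shelter to
the threat cell on the obstacle-free test map, learning on) and a **test**:
the frozen learned policy from the threat cell, at most 100 steps. Values
are frozen at test — with learning on, tabular Q-learning in condition 2
escapes about 40% of the time by surfing value gradients acquired during
the pre-test, instead of the published universal failure. The model-based
agents' world model does update during the test rollout: immediate updating
is their defining property and part of how they select actions. Routes are
classified homing-vector (within one step of the straight threat-shelter
line, passing the three middle cells above the obstacle location and
continuing shelter-ward), edge-vector (within one step of the direct
threat-to-edge line, touching the edge cells), tortuous (reached the
shelter with a deviation of two or more steps), or non-escape.

## Behavioral quantification

The continuous-trajectory module uses its own coordinate frame (origin at
the arena center, +y toward the threat zone, cm, 40 frames/s). Speeds are
finite differences smoothed with a Gaussian kernel (sigma 4 frames = 100
ms, reflected padding). The escape target score is computed on the transect
10 cm in front of the obstacle from unsigned crossing offsets; written this
way the score saturates at 0 and 1 beyond the reference paths, which is
what the printed formula implies even though prose descriptions sometimes
suggest values above 1. Spontaneous-run extraction follows the five
published steps; two implementation details are worth knowing: the
qualifying threshold (homing speed > 15 cm/s or turning toward a target at
more than 90 degrees/s) is evaluated on the sigma = 0.5 s smoothed signals,
but the frame-wise rejection of non-approaching frames uses raw signals —
otherwise the smoothing tails stretch a sub-second dash past the 1-s
minimum — and momentary dropouts shorter than 0.25 s (for instance the
single frame of the turn at an obstacle edge) are bridged rather than
allowed to split one run in two. Edge-entry rectangles are boundary
inclusive; midline ties in `escape_side()` go left.

The initiation-set statistics use `stats::glm.fit` for the unregularized
logistic fits (convergence 1e-8, 200 iterations, complete separation
flagged), McFadden pseudo-R2, permutation p-values that count ties and the
identity arrangement (so the smallest attainable p is 1/(n+1)), delta-AIC
with k counting the intercept and the reference model chosen by name, and
binned correlations whose range is the widest 2.5-cm-aligned interval whose
seven equal bins each hold at least six escapes (bin centers, not bin
means, carry the correlation). The group permutation test shuffles labels
at the animal level and enumerates all assignments exactly whenever there
are at most 10,000 of them. The Von Mises sampler is the Best-Fisher
rejection algorithm; in the bias simulation the mean direction is the
heading whose target score is 0.6 (score space mapped to angle per start
point), each square-centimeter bin of the 1652-cm2 threat zone contributes
100 trials, and the handful of bins from which the homing- and edge-vector
transect crossings coincide (degenerate score) are excluded with a note.

## The synthetic-data generator

`generate_session()` builds sessions sequentially — slow correlated random
walk (6 cm/s, gentle turning), a sub-threshold guided approach to each
planted start point, the planted 40 cm/s dash (homing, or through an
edge-entry rectangle and on to the shelter), a one-second shelter visit —
plus isotropic tracking noise (sd 0.25 cm). Sequential construction keeps
the trajectory continuous, so the planted events are the only segments that
satisfy the extraction thresholds, by margin: dash speed 40 cm/s against
the 15 and 20 cm/s thresholds, durations above 1.5 s against the 1-s
minimum. The generator emulates the geometry, sampling rate, kinematic
regimes and event structure of real tracking data; it does not emulate
body-axis dynamics during turns (the optional 13-point body-part template
is rigid), climbing, grooming bouts, or realistic tracking dropouts. Tests
that pass on these sessions therefore establish that the pipeline's
*computations* are correct and that planted structure is recovered exactly;
they do not establish robustness to every artifact of real video tracking.
`generate_escape_dataset()` plants a logistic dependence of edge-vector
probability on the spatial predictors (default effect sizes put McFadden
pseudo-R2 near 0.2, the conventional "excellent fit" regime) and is the
basis of the parameter-recovery acceptance check.

## Problem sizes and known limitations

The test suite and the acceptance script run every targeted agent x
condition cell at the study's full 100 seeds x 3 trials (minutes in total;
the per-step updates are compiled, and each compiled rule is pinned to its
plain-R reference implementation by replay tests). Budget calibration
re-runs use checkpoints of one incremental training run per seed on the
published rounding lattice. Survey cells for the non-targeted agent
families use 30 seeds in the analysis scripts.

Known limitations, all consequences of reconstructing figure-only
geometry: the immediate model-based agent's first-trial homing rate depends
on which former-obstacle crossing the pre-test walk happens to discover,
leaving its pooled homing proportions around 80% rather than the published
low 90s; the successor representation learns about 2.5x more slowly in the
wire conditions than the original (at 2.5x the pinned budget its
condition-3 outcome distribution matches the published 70/30 split); and
the bias simulation's axis-distance correlation has the published sign but
roughly two-thirds of the published magnitude, since the per-bin edge
probability surface depends on the exact threat-zone polygon. The
qualitative pattern — which agent family dominates which outcome class in
which condition — is reproduced everywhere.
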