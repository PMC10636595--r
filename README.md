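# subgoalsim

Mice escaping a threat do not always run straight for their shelter: after
exploring an arena with an obstacle between threat site and shelter, they
memorize the obstacle edges as *subgoals* and, even once the obstacle is
removed, launch direct runs at the remembered edge location. `subgoalsim`
re-implements, as a tested R pipeline, the computational core of a study of
how such subgoals are learned: a grid-world escape simulator comparing eight
reinforcement-learning agent families across four experimental conditions,
plus the behavioral quantification applied to continuous tracked
trajectories (escape target scoring, spontaneous-run extraction and the
initiation-set statistics), with a synthetic-data generator so that every
stage is testable without recorded animal data.

## The models

**Environment.** A 13x13 grid discretization of a 92-cm circular arena: 118
accessible cells, 8 compass actions (so 944 state-action pairs), a shelter
cell worth +100 on entry, a per-transition cost equal to the step length
d(s,s') (1 or sqrt(2)), a central 7-cell obstacle on training maps, and — in
two conditions — a one-way "trip wire" (directed blocked transitions
emulating closed-loop optogenetic interruption of edge-directed runs). The
four conditions differ only in the training map: (1) obstacle + shelter,
(2) obstacle without shelter, (3) full trip wire between the threat area and
the obstacle edges, (4) partial trip wire blocking edge-directed movement
out of the threat zone only. Every test map has the shelter and no obstacle.

**Agents.** Tabular Q-learning with accumulating eligibility traces
(`Q <- Q + alpha [r + gamma max_a Q(s',a) - Q(s,a)] e`), its on-policy
variant SARSA, an on-policy successor representation
(`M(s,a,:) <- M(s,a,:) + alpha [1_{s'} + gamma E_a M(s',a,:) - M(s,a,:)] e`,
valued as `Q = sum_x M(s,a,x) R(x)`), linear tile coding (2x2 and 3x3
receptive fields), model-based planners over a learned undirected graph
(A*/shortest-path; *immediate* = latest observation per edge, *gradual* =
majority vote over a 15-observation buffer), hierarchical state-space
learners over 10 arena regions and 40 region-level actions, and a dual
Q-learning/model-based system that falls back to planning when no learned
action value exceeds a threshold. Training is episodic (uniform random
drop-ins, shelter absorbing) with a random walk punctuated by scripted
*practice runs* — rapid threat-area-to-edge-to-shelter trajectories
triggered with p = 0.2 — followed per trial by a pre-test random walk from
the shelter to the threat cell on the test map and a frozen-policy test
rollout, classified four ways (homing vector / edge vector / tortuous /
non-escape).

**Behavior.** For continuous 40 Hz trajectories: Gaussian-smoothed
kinematics; the escape target score
`|offsetHV - offsetEV + offsetHV-EV| / (2 offsetHV-EV)` measured on the
transect 10 cm in front of the obstacle (0 = shelter-directed, 1 =
edge-directed; scores > 0.65 classify as edge vectors); the five-step
extraction of spontaneous homing and edge-vector runs; logistic regressions
of edge-vector probability on spatial predictors with McFadden pseudo-R2
(`1 - LLfull/LLnull`), permutation p-values (10,000 shuffles), delta-AIC
model comparison, binned correlations on a 2.5-cm grid; the
pooled-mean-difference permutation test (animal-level shuffling, exact by
enumeration when feasible); and the Von Mises classification-bias control
(kappa = 8 headings from every square centimeter of the 1652-cm2 threat
zone).

## Worked example

```r
library(subgoalsim)

# Successor-representation agent in condition 2 (obstacle, no shelter at
# training; shelter, no obstacle at test), 100 seeds x 3 trials:
res <- run_condition("sr", condition = 2, n_seeds = 100)
round(100 * res$proportions, 1)
#> homing_vector   edge_vector      tortuous    non_escape
#>           0.0          89.0           4.7           6.3
```

Even though the shelter was never rewarded during training, 89% of test
escapes run at the remembered obstacle edge: the SR's spatial representation
learned the practiced edge paths without reward, and the reward vector
filled in during the pre-test. Tabular Q-learning in the same condition is
96% non-escape (it cannot learn without reward), and the immediate
model-based planner takes the direct homing vector 80% of the time — the
qualitative triad the simulation study is built around.

```r
vm <- vonmises_bias_simulation(seed = 1)
vm$edge_fraction      #> 45.9   (% of 165,100 simulated escapes scored > 0.65)
vm$cor_axis           #> r = -0.105, p = 1.9e-05
```

The bias control: headings drawn from a fixed Von Mises distribution score
as edge vectors about half the time everywhere in the threat zone, and the
per-bin edge probability does *not* increase with distance from the central
axis — so the spatial trends measured in animals are not artifacts of the
scoring metric.

The `analysis/` directory holds the numbered workflow drivers
(`01_build_maps.R` ... `05_synthetic_behavior.R`) that write the study's
tables under `results/`.

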