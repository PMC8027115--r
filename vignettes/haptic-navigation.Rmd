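---
title: "Haptic exploration as navigation: the model behind hapticnav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haptic exploration as navigation: the model behind hapticnav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapticnav)
```

## The problem

When a hand explores an object by touch it receives only *egocentric*
signals: slip sensations that register how the hand just moved relative to
the surface, proprioception of the hand's shape, and contact.  Yet what the
brain ends up with is knowledge of the object in an *object-centred*
(allocentric) frame.  `hapticnav` implements a minimal computational account
of how that translation can happen: haptic exploration is treated as
navigation, with the hand as the agent and the object surface as its
environment, and the learning machinery is nothing more than an unsupervised
learner of frequently occurring percept *sequences*.  Because the geometry
of the object constrains which movement sequences are possible, a code for
common sequences implicitly becomes a code for place.

The package simulates the whole loop — object, articulated hand, sequence
learner, action proposal circuit, external decoding, and a goal-reaching
reinforcement learner — and reproduces the qualitative phenomena that
motivate the account: decoding above chance without any location input,
better decoding on asymmetric objects, with tactile landmarks, and with an
articulated hand, and usable goal-directed navigation from the learned
representation alone.

## Objects and the hand

Objects are cuboids of unit cells; the surface of a `Dx x Dy x Dz` cuboid
has `p = 2(DxDy + DyDz + DxDz)` cells (24 on the 2x2x2 cube, 22 on the
3x2x1 cuboid).  Faces are numbered 1 = top, 2 = front, 3 = bottom, 4 = back,
5 = left, 6 = right, each with a 1-based `(x, y)` grid.  The frames of the
top and bottom faces are oriented so that `(face 1, 1, 1)` and
`(face 3, 1, 2)` on the cube are diagonally opposite — the start/goal pair of
the navigation task.  Adjacency joins cells that share an edge segment in
3D, so every cell has exactly four neighbours, some across cuboid edges;
geodesic distances are shortest paths in this unit-weight graph (Dijkstra
via igraph, cross-checked against breadth-first search in the tests).

The hand is a palm plus one finger that is either straight or bent at 90
degrees.  Its state is the palm cell, a heading tangent to the face, and the
finger situation: `on` (straight, resting on the cell ahead), `over`
(straight, extended past the face edge into the air), or `bent` (wrapped
over the edge, touching the adjacent face).  Whether a straight finger is
`on` or `over` is fully determined by palm cell and heading, so the state
space is small and exhaustively enumerable (`state_graph()`), which the
tests exploit.

The repertoire has ten actions, each with a distinct slip signature:

* `fwd_on`, `fwd_over` — forward translation, ending with the finger on the
  surface or slipping over an edge;
* `back_on`, `back_over` — backward translation, with the finger dragging on
  the surface or pulling back over an edge onto it;
* `left`, `right` — translation along the heading's perpendicular;
* `rot_ccw`, `rot_cw` — rotation in place;
* `bend`, `unbend` — the finger over an edge bends onto the adjacent face;
  unbending pivots the palm over the edge, which is the only way to change
  faces.

The count of ten is normative for the repertoire; the exact split of the
translations is a package choice.  Splitting *both* translations by their
ending configuration would make a backward overhang-producing action
impossible from every state (the cell behind a just-moved palm is the old
palm cell, which exists), so backward translation is split by the current
finger situation instead.  All ten actions are then executable somewhere on
the 3x2x1 cuboid.  On the cube, faces are only two cells deep, so `fwd_on`
and `back_on` happen to be unaffordable everywhere — an honest property of
that object's affordance structure, which the action generator learns.

Feasibility is a signalled outcome, not an error: translations are blocked
while bent or off the leading edge, rotations are blocked while bent,
bending requires an overhanging finger, unbending a bent one.  From every
reachable state at least one action is feasible (tested exhaustively).

A percept (width `13 + L`) is emitted after each successful action: the
10-wide slip one-hot, a straight/bent bit, finger-contact and palm-contact
bits, and an `L`-wide one-hot for the unique tactile landmark under the
palm, if any.  Landmark sensing is palm-based; the percept never encodes
location.  A degenerate unarticulated mode (no finger, six actions, edges
crossed as plain translations) supports the articulation comparison; its
repertoire is so unconstrained that every action is feasible everywhere,
which is precisely why it learns less.

## The sequence learner

The merge self-organizing map (MSOM) is a SOM whose `n^2` units carry a
regular weight `w_i` (what the input looks like) and a context weight `c_i`
(when it occurs).  With map context `c(t)` the unit distance is

    d_i(t) = (1 - zeta) ||x(t) - w_i||^2 + zeta ||c(t) - c_i||^2

activity is `a_i = exp(-nu d_i)`, the activity pattern is the normalized
activity vector, the winner (BMU) minimizes `d_i`, and the context recurses
through the previous winner:

    c(t) = (1 - iota) w_bmu(t-1) + iota c_bmu(t-1),  c(0) = 0.

Training moves `w_i` toward `x(t)` and `c_i` toward `c(t)` under a
decreasing learning rate and a Gaussian grid neighbourhood of the winner.
Defaults: a 10x10 map, `zeta = 0.4`, `iota = 0.5`; learning rate decaying
exponentially 0.3 to 0.01 and neighbourhood width `n/2` to 0.5 over the
planned run length (only "decreasing" is essential; the exponential form is
a package choice).  Regular weights start uniform in `[0, 1]`, context
weights at zero.  Ties in winner selection break to the lowest unit index.
With `zeta = 0` the BMU trajectory reduces exactly to a plain SOM, which the
tests verify against an independent implementation over 10^4 random inputs.

**Choice of `nu` (default 20).**  The activity scaling is the one model
parameter with no stated value.  It does not affect the winner, but it
controls how sharply the activity pattern concentrates, and the decoding
posterior is a pattern-weighted mixture: with `nu = 1` the pattern over 100
units is nearly uniform (max probability about 0.028), the mixture averages
all units' conditionals, and decoding collapses to chance no matter what the
winners encode.  Distances between distinct slip one-hots are about 2, so
`nu = 20` separates units cleanly (activity ratios of e^40 across percept
clusters) while leaving graded similarity within a cluster.  The value was
fixed once from this scale argument.

## Exploration and the next action generator

The architecture explores unsupervised: a small feedforward network (100
logistic hidden units, one logistic output per action, online SGD with
learning rate 0.01 on the attempted action's binary cross-entropy) maps the
current activity pattern to per-action feasibility scores.  Actions are
sampled proportionally to the scores; a failed attempt trains the generator
(target 0), is excluded for the rest of the time step, and costs no time —
slip sensors register only actual movement, so failures never reach the
MSOM.  A successful attempt trains the generator (target 1), produces the
percept, and trains the MSOM.  Output weights start near zero so the first
predictions are uniform, as required of an agent with no prior knowledge of
the object.  Over training the mean number of failed attempts per step falls
— the generator learns the object's affordance structure.

**Episodic exploration (default 100 attempts per episode).**  Exploration
restarts from a fixed start cell: after every 100 attempts the hand returns
to the start and the map context is cleared, while all weights and the hit
map persist.  This mirrors the epoch structure of the goal-learning stage
and is not incidental — it is what makes absolute location learnable at all
on an unmarked symmetric object.  The automorphism group of the cube acts
transitively on its 24 cells and preserves the exploration dynamics, so in a
single never-reset walk the joint distribution of (recent percept history,
location) is symmetric: any decoder built on finite-memory percept history
is at chance by symmetry, and measured decoding indeed sits at chance.  The
known start breaks the symmetry; each restart re-anchors the context
recursion, and locations reachable within the context memory of the start
become identifiable.  Continuous exploration remains available
(`episode_attempts = Inf`) and is the right setting for studying the
symmetric-limit behaviour itself.

## External decoding

Decoding is evaluation machinery, never model input.  A hit map counts
winner/true-cell pairs `c(i; j)`.  Each unit's conditional location
distribution is its normalized row (units never yet observed contribute a
uniform `1/p` — total ignorance); the posterior for a step is the mixture of
conditionals weighted by the activity pattern.  Metrics over a sliding
window of `phi` steps (default 1000):

* reconstruction accuracy `P_max`: fraction of steps whose maximum-posterior
  cell equals the true cell (posterior ties break uniformly at random, which
  matters only early); the top-`h` generalization counts the true cell
  anywhere in the `h` highest-posterior cells;
* geodesic error `D_geodesic`: posterior-weighted mean surface distance to
  the true cell.

Chance baselines are the uniform-posterior expectations: `1/p` for
accuracy and the mean of the geodesic distance matrix for the error
(2.5 on the cube).  Decoding at step `t` uses the hit map accumulated over
steps `1..t-1`, so a step never decodes itself, and the hit map accumulates
for the whole run — metrics late in training therefore mix in early,
disorganized counts, which is a conservative choice.

## Goal-oriented learning

Stage 1 runs the exploration architecture for 50 episodes; all MSOM and
generator weights are then frozen (bit-identity is asserted in the tests).
Stage 2 is episodic actor-critic temporal-difference learning whose state is
the activity pattern of the frozen map: actor and critic are 100x100x10 and
100x100x1 feedforward networks with learning rates `1e-5` and `1e-4`, the
discount is `gamma = 0.9` (unstated in the source model; a standard value
for a 10-20-step horizon, fixed once), and the behaviour policy is

    a(t) ~ softmax( actor(s_r) * generator(s_r) )   (element-wise product)

The actor emits unbounded preference scores: the softmax above is the
policy's only normalization.  Squashing the actor to a probability vector
first would confine the product to `[0, 0.1]` and pin the policy within a
factor `e^0.1` of uniform for ten actions — no policy improvement would be
expressible (measured: the step median stays at the attempt cap
indefinitely).  A `renormalize = TRUE` variant instead uses the exactly
renormalized product of a softmax actor and the generator scores, which
assigns infeasible-looking actions vanishing rather than merely reduced
probability.

The attempt is the clock of stage 2.  Every attempt costs reward -1
(reaching the goal is worth +1), counts toward the 100-attempt epoch cap,
and drives one TD update `delta = r + gamma V(s') - V(s)` (bootstrap term
dropped at the goal): a failed attempt leaves the hand, the context and
hence the pattern unchanged and produces no percept, while a successful one
advances the frozen MSOM.  Within a time step, failed actions are excluded
until one succeeds.

The baseline is a random walk with memory under the *same attempt
accounting*: uniform over the full ten-action repertoire, infeasible
attempts burn budget in place, and each test remembers its shortest
goal-reaching trajectory, reporting the running minimum (a never-increasing
series).  A feasibility-clairvoyant walker (`feasible_only = TRUE`) is also
provided, but as a headline baseline it is degenerate: its remembered
minimum reaches the breadth-first-search lower bound (7 attempts from the
standard start/goal pair on the cube) within about a thousand epochs, which
no policy can beat and which contradicts the behaviour the baseline is meant
to model.  End-of-training step counts of model and baseline are compared
with a one-sided Mann-Whitney test (the step variable is censored at the
attempt cap, so a rank test is appropriate), pooling the final tenth of
epochs across tests.

Temporal-difference learning at these learning rates is slow by
construction: the reference setting for this task trains for 5x10^4 epochs per test.  At
that scale the policy consolidates; at strongly scaled-down epoch counts the
actor has moved too little to shorten the median episode, and the memory
baseline — whose "learning" is a running minimum, improving fastest
precisely at the start — is at its strongest.  The comparison is therefore
scale-sensitive, and results at reduced scale must be read with that in
mind.

## What the simulation shows — and what it cannot

The synthetic environment *is* the study system here (there is no external
data): cuboid objects, a one-finger hand, noise-free Boolean percepts,
uniformly placed unique landmarks.  Passing tests show that the
sequence-learning account works in this discrete, deterministic world; they
cannot show anything about graded skin sensors, curved or concave objects,
multi-finger hands, or noisy perception, all of which are outside the model
class.  Decoding accuracy also depends on the episode anchoring discussed
above; an agent that never returns to a known pose on a featureless
symmetric object cannot, even in principle, recover absolute location from
egocentric input.

## Problem sizes used by the test suite and acceptance script

The test suite uses: 10 seeds of 2x10^4 exploration steps for the
above-chance check; 10 seeds of 10^4 steps per condition for the landmark
(0, 4, 8), object (cube vs cuboid) and articulation orderings;
normalization and SOM-equivalence checks over 10^4-step streams; and for
goal learning 6 seeded tests of 5x10^3 stage-2 epochs against the matched
baseline, with the Mann-Whitney comparison over the final tenth.  The
acceptance script uses 5 seeds of 2x10^4 steps for the decoding medians and
5 per condition for the ordering medians, keeping the goal-learning scale.
These sizes are the package's desk-scale choices; full scale (30 tests,
5x10^4 epochs) is reached by raising `tests` and `epochs`.

## Known limitations

* The MSOM's context memory is a few steps deep (geometric decay with
  `iota = 0.5`), so only locations within that horizon of an anchor are
  individually identifiable; landmarks extend the horizon by re-anchoring.
* The 10x10 map sits near the capacity suggested by the 5-units-per-pattern
  rule of thumb for the articulated percept set; richer percepts (many
  landmarks) can crowd it, which is visible as the articulated model's
  smaller benefit from dense landmarks.
* Policy learning inherits the source setting's very small actor step size;
  see the scale note above.
* Geodesics, adjacency and state enumeration assume convex cuboids; there
  is no support for meshes, curvature or concavity.
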