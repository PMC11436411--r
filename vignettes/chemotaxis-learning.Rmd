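---
title: "Learning chemotaxis: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning chemotaxis: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemotaxRL)
```

## The navigation problem

A sperm cell searching for an egg cannot measure a concentration gradient
across its own body: it is far too small.  What it can do is swim along a
curved path, compare the chemoattractant signal it detects now with the
signal a moment ago, and adjust the curvature of its path accordingly.  With
the right temporal pairing between "signal went up / signal went down" and
"turn harder / straighten out", a circling swimmer drifts up the gradient --
a strategy known as klinotaxis.

`chemotaxRL` implements a minimal model of this process in which the
steering rule is not prescribed but *learned*, by tabular Q-learning, from
the reciprocal-concentration reward the cell accumulates while swimming.
The classical stimulus--response adaptation model of chemotactic steering is
included as a benchmark strategy.

## Swimmer kinematics

The beat-cycle-averaged head position $\mathbf{x}(t)$ moves at constant
speed $v$ along its unit tangent $\mathbf{t}$, and the orthonormal moving
frame $(\mathbf{t}, \mathbf{n}, \mathbf{b})$ evolves with the path curvature
$\kappa$ and torsion $\tau$:

$$\dot{\mathbf{x}} = v\,\mathbf{t},\qquad
  \dot{\mathbf{t}} = v\kappa\,\mathbf{n},\qquad
  \dot{\mathbf{n}} = -v\kappa\,\mathbf{t} + v\tau\,\mathbf{b},\qquad
  \dot{\mathbf{b}} = -v\tau\,\mathbf{n}.$$

Constant $\kappa$ in the plane gives a circle of radius $1/\kappa$; constant
$(\kappa, \tau)$ in space gives a helix of radius
$\kappa/(\kappa^2+\tau^2)$ and pitch $2\pi\tau/(\kappa^2+\tau^2)$.  Planar
motion is handled as the three-dimensional system confined to $z = 0$ with
$\tau = 0$, so a single code path covers both cases.

Because the agent holds $(\kappa, \tau)$ constant over each learning step,
the frame evolution within a step is a rigid rotation about the Darboux
vector $\boldsymbol{\omega} = v(\tau\,\mathbf{t} + \kappa\,\mathbf{b})$.
The integrator applies this rotation (and the corresponding arc/helix
displacement) in closed form per sub-step, followed by a modified
Gram--Schmidt re-orthonormalisation.  Two consequences matter in practice:

* positions at learning-step boundaries are independent of the sub-step
  count `n_sub` (to round-off), so heavy multi-trial experiments can run
  with `n_sub = 1` without changing results;
* orthonormality of the frame is preserved to $10^{-9}$ over millions of
  sub-steps.

The chemoattractant field of the egg (a point source at $\mathbf{x}_c$) is
$c(\mathbf{x}) = c_0 / |\mathbf{x}-\mathbf{x}_c|$, the steady-state profile
of diffusion from a point source.

## The learning agent

At each learning step of duration $\delta t$ the agent senses the local
concentration and observes two things: the sign of the change since the
previous step, and its own discrete curvature level.  Curvature is
discretised as $\kappa = \kappa_0 + k\,\delta\kappa$ with
$k \in [-X, X]$ ($L = 2X+1$ levels); in 3D the torsion level is tracked
likewise and the state space doubles over $L^2$ level pairs.  The three
actions -- increase, decrease, keep -- shift the level(s); in 3D the same
shift applies to curvature and torsion together, so the *signs* of
$\delta\kappa$ and $\delta\tau$ select in-phase or out-of-phase modulation.

The reward for a step from concentration $c_n$ to $c_{n+1}$ is

$$r_n = \beta\left(\frac{1}{c_n} - \frac{1}{c_{n+1}}\right),
  \qquad \beta = \frac{1}{c_0},$$

positive exactly when the signal increased.  The reciprocal form keeps
rewards finite as the swimmer closes in on the singular source, and rewards
telescope: the cumulative reward of any episode is
$\beta(1/c_\text{first} - 1/c_\text{last})$, a fact the tests exploit.
Action values follow the standard Q-learning backup
$Q(s,a) \leftarrow Q(s,a) + \alpha\,[\,r + \gamma \max_{a'} Q(s',a') -
Q(s,a)\,]$ with $\alpha = 1$ and $\gamma = 0.8$, and actions are selected
$\varepsilon$-greedily with $\varepsilon = 0.1$.

### Actuation latency and credit timing

Two timing conventions required a decision, and both turned out to matter
enormously.

**Actuation.**  The flagellar response to a steering decision is not
instantaneous.  In this implementation a decision made at step $n$ changes
the curvature *from the following step on*: during step $n$ the swimmer
still moves with the previously commanded curvature.  We also found that the
benchmark stimulus--response strategy reproduces its published approach
times only when run with the same one-step sensing-to-actuation lag on the
same decision cadence (see below), which corroborates this convention.
With instantaneous actuation the learned policies never stabilise into an
orbit around the source, and performance *degrades* with training -- the
opposite of the behaviour this model family is known for.

**Credit.**  The reward used in the backup for the decision at step $n$ is
the concentration change over step $n$ itself, i.e. over the interval
*preceding* the actuation of that decision (`credit = "prompt"`).  The
seemingly better-aligned alternative -- crediting each decision with the
interval its curvature actually drove (`credit = "actuated"`) -- collapses
learning in this environment and is kept only as an option.  The signal
change over step $n$ is informative about the *state* in which the decision
was taken, and with the bootstrap term carrying the action's consequences
this indirect credit turns out to be what makes the strategy learnable.

### Tie-breaking

Early in training most Q rows are all-zero, so greedy ties are common and
the tie rule effectively sets the exploration style.  Three rules are
provided.  The default, `"keep"`, prefers keeping the curvature unchanged
when indifferent: the swimmer keeps circling, changes course only on
informative experience or $\varepsilon$-kicks, and single-episode success
rates land close to the published values.  Uniform-random tie-breaking
(`"random"`) makes the curvature level random-walk, which explores far more
aggressively and overshoots the published single-episode success rate by a
factor of two; `"increase"` reproduces the scan order of array-argmax
implementations.

### Episodes

Training is episodic: the swimmer is reset to its initial position,
orientation, curvature and (empty) signal memory, while the Q-matrix carries
over.  Episodes terminate when the swimmer first comes within the success
radius (`stop = "threshold"`), the convention also used for the
cumulative-learning-steps comparisons; fixed-length episodes and a
stable-orbit termination are available.  A trial counts as successful when
its final episode reaches the egg within the time horizon
$t_p = 25\,000$ s.

## Noise models

Signal noise follows the coarse-grained receptor-binding picture: molecules
bind at total rate $q(t) = \lambda c(\mathbf{x}(t))$ and the detected
stimulus over a learning step is $q + \sqrt{q}\,\xi_c$ with $\xi_c$ standard
normal -- shot-noise statistics with mean and variance $\lambda c$.  The
reward weight becomes $\beta = 1/(c_0\lambda)$ so that reward magnitudes
keep their scale.  Rare non-positive draws are floored at $10^{-12}$ (the
reciprocal reward must stay defined) and counted.

Curvature noise adds a zero-mean Gaussian $\xi_\kappa$ to the *commanded*
curvature for the duration of one learning step; the agent's discrete state
is unaffected.  The parameter $\sigma_\kappa = 0.005$ is interpreted as the
**variance** of $\xi_\kappa$, following the wording that accompanies the
model; because $\sigma$ conventionally denotes a standard deviation, the
configuration exposes `sigma_is_sd = TRUE` to flip the reading.  Under the
default reading the robustness results hold: noisy training needs more
cumulative learning steps at every episode count, yet the majority of noisy
runs still converge by ten episodes.

Both noise sources draw from R's RNG (as does everything in the compiled
core), so a single `set.seed()` reproduces any run bit for bit.

## The stimulus-response benchmark

The adaptation model couples a response variable $a$ and an adaptation
variable $p$,

$$\eta\,\dot a = p\,c - a, \qquad \mu\,\dot p = 1 - a,$$

and steers through $\kappa(t) = \kappa_0 + \kappa_1 (a(t) - 1)$.  At
constant $c$ the unique fixed point is $(a^*, p^*) = (1, 1/c)$: the system
adapts perfectly and responds only to relative signal changes.  Simulations
start at the fixed point for the local concentration, avoiding a startup
transient.  The ODEs are advanced by classical Runge--Kutta on the same
sub-step grid as the frame.

Run as a continuous system with $\eta = 0.14$ s and $\mu = 0.725$, this
strategy is very efficient: it reaches the 50 um radius from 255 um away in
about 40--60 s.  The published benchmark time (about 134 s) is recovered --
within one standard error -- only when the response is run on the *decision
cadence* of the learning agent: the concentration is sampled once per
$\delta t = 0.5$ s window, $(a, p)$ relax over the window at that frozen
value, and the curvature applied during a window is the one computed in the
previous window.  `fj_chemotaxis(response_dt = , latency = )` exposes this
mode, and the timing benchmark uses it so that both strategies operate under
identical sensory and motor constraints.

## Success criteria and metrics

*Reaching the egg* is operationalised as $d \le 50$ um, the typical egg
radius.  *Stable orbiting* (used by `detect_success()` and the
`"stable_orbit"` termination) additionally requires the trailing 200
learning steps to average at or below the threshold, with the qualifying
entry -- the first crossing after the last excursion beyond twice the
threshold -- occurring within $t_p$.  The excursion-reset form was chosen
because the final stable orbit is what matters: a transient early dip that
the swimmer subsequently abandons should neither qualify a run nor
permanently disqualify it.  The window of 200 steps spans several orbital
periods at the converged orbit scale and is configurable.

`n_r` is the first learning step with $d$ below threshold; the time to
reach is $n_r\,\delta t$.  Multi-trial summaries report mean and standard
error of the mean.  For the timing comparison, training is continued (up to
ten extra episodes) until its final episode reaches the target -- i.e. a
*converged* strategy is evaluated -- and evaluation runs with
$\varepsilon = 0$: keeping exploration on during evaluation inflates the
mean time to target several-fold and does not describe the converged
strategy.

## Default parameters

| Parameter | Default | Meaning |
|---|---|---|
| `v` | 120 um/s | swimming speed (measured range 100--200) |
| `kappa0` | 0.03 1/um | base curvature (circle radius 33 um) |
| `tau0` | 0.006 1/um | base torsion (3D) |
| `d_kappa` | 0.006 1/um | curvature increment per action |
| `d_tau` | 0.004 1/um | torsion increment (sign sets the phase mode) |
| `dt_learn` | 0.5 s | learning-step duration |
| `X` | 50 | half-width of the level grid (clamping is counted and warned) |
| `alpha`, `gamma`, `epsilon` | 1, 0.8, 0.1 | learning rate, discount, exploration |
| `c0` | 10 pM | field strength |
| `beta` | `1/c0` (noiseless), `1/(c0*lambda)` (noisy) | reward weight |
| `lambda` | 10 1/(pM s) | receptor binding constant |
| `sigma_kappa` | 0.005 | curvature noise variance |
| `d_threshold` | 50 um | success radius |
| `t_p` | 25000 s | success horizon |

On the unit of $c_0$: with $c = c_0/|\mathbf{x}-\mathbf{x}_c|$ and $c$ in
pM, $c_0$ dimensionally carries pM um.  The package treats $c_0$ as the
scalar 10 in the formula as conventionally printed; only ratios of
concentrations enter the agent's behaviour, so the unit convention does not
affect any result.

## Problem sizes and what the simulations show

The test suite runs the deterministic geometry and algebra checks at full
precision, and the stochastic claims at reduced size: success-rate curves
with 20 trials per episode count, timing comparisons with 10 orientations,
noise comparisons with 6--10 seeds.  The acceptance script uses 50 trials
for the success-rate experiment and 10 simulations for the timing and
convergence experiments.  With the exact-rotation integrator at
`n_sub = 1` these sizes complete in well under a minute.

The simulated conditions are the model's own: a beat-averaged swimmer with
a perfectly reciprocal field, no hydrodynamic or steric interaction with
the egg, no fluid shear, and sensing reduced to one sign bit per decision.
Passing tests therefore demonstrate the internal consistency of the model
and the learnability of chemotaxis within it -- not that real sperm cells
implement Q-learning.

## Known limitations

* Under sustained live learning ($\alpha = 1$, $\varepsilon = 0.1$) a
  converged policy occasionally relapses within an episode: a burst of
  contradictory updates sends the curvature level ratcheting far from the
  useful band, and the episode fails even though neighbouring episodes
  succeed.  This keeps the ten-episode success rate in the 70--90% range
  rather than at certainty, and makes the tenth-episode `n_r` several times
  larger on average than its frozen-greedy optimum (about 380 steps from
  the standard start).
* The success-rate surface over $(\delta\kappa, \delta t)$ is noisy at
  small trial counts; its non-monotonic shape in $\delta\kappa$ is robust
  at some step durations and marginal at others.
* The stimulus--response benchmark is implemented in 2D only, matching the
  comparison it serves.
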