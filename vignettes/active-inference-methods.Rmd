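---
title: "Methods: planning as inference and saccadic search in actinf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: planning as inference and saccadic search in actinf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actinf)
```

This vignette is the package's own account of the models it simulates, the
parameters that matter, and the numerical decisions behind the
implementation. Both simulators instantiate the same idea — *active
inference* — in which an agent's perception and action jointly minimize a
variational free-energy bound on the surprise of its sensations, and goals
enter as prior beliefs rather than as reward functions.

## 1. The discrete scheme: planning as inference

### Generative model

The discrete agent entertains a generative model over sequences of hidden
states $x_{0:T}$, hidden control states $u_{1:T}$, and observations:

$$
P(\tilde s, \tilde x, \tilde u) \;=\;
\Big[\prod_{t \le k} P(s_t \mid x_t)\Big]\; P(x_T)\,
\prod_{t=1}^{T} P(x_{t-1} \mid x_t, u_t)\, P(u_t),
$$

with $P(s_t\mid x_t) = A x_t$, $P(x_{t-1}\mid x_t, u_t) = B_{u_t} x_t$,
$P(x_T) = c$ and $P(u_t) = d$. The transition priors are written *backwards
in time* (a pullback): the model says where the agent *came from*, anchored
on a prior $c$ over the *final* state. A desired goal is therefore nothing
but a terminal prior with mass on the goal state — costs never appear.
All matrices are column-stochastic: column $j$ of $A$ is the observation
distribution in state $j$, and column $j$ of $B_k$ the distribution over
predecessors of state $j$ under control $k$.

Hidden controls are *fictive* actions: internal explanations of state
transitions. The action actually emitted is selected separately, over a
*sampling kernel* $R_a$ that maps the current observation to a distribution
over next observations (`run_episode()` uses the renormalized transpose of
the pullback matrices).

### Mean-field inference

`variational_sweep()` optimizes a fully factorized posterior
$Q = \prod_t Q(x_t)\prod_t Q(u_t)$ with sufficient statistics
$\alpha_t$ (states) and $\beta_t$ (controls) by coordinate ascent on the
free energy $F = E_Q[-\ln P] - H[Q]$. Each update is the exponentiated
expectation of the log-joint in the coordinate's Markov blanket, followed by
renormalization; $F$ is therefore non-increasing across sweeps, which
`discrete_free_energy()` lets you verify directly.

Three boundary decisions matter:

* $\alpha_T$ is clamped to the terminal prior $c$: the goal constraint is
  hard, which is what makes the scheme plan rather than drift.
* $\alpha_t$ at observed times is clamped to the normalized likelihood
  column of the observation. With an identity likelihood this is the exact
  conditional. Leaving these coordinates free is numerically dangerous: two
  saturated transition terms can outweigh a log-floored likelihood term, and
  beliefs then drift off the data into self-consistent but counterfactual
  modes.
* Within a sweep the update order alternates between backward
  ($t = T-1 \dots 0$) and forward passes, so that information from both
  anchors (the observation prefix and the terminal prior) traverses the
  whole horizon within a handful of sweeps. Eight sweeps per acted step is
  the default protocol.

`select_control_action()` then picks the action whose sampled next
observation has the highest expected log-likelihood under the belief about
the next hidden state — with an identity likelihood, the action whose
outcome distribution overlaps the predicted next-state marginal most. On
deterministic problems with a Bellman-optimal transition prior, this is
provably the optimal action itself, which the test battery checks against
`value_iteration()` on 100 seeded toy problems.

### What mean-field inference does *not* give you

The factorized posterior is an approximation. Its fixed point differs from
the exact smoothing posterior (available from `exact_smoother()` by
enumeration) by a *structural* bias: geometric-mean messages cannot
represent "either path A or path B", so on problems whose posterior is
genuinely multimodal the marginals are over-concentrated or displaced, with
per-marginal Kullback–Leibler divergences typically in the $10^{-2}$–$10^0$
range on small random models. This is inherent to the method, not a
convergence failure — running the sweeps to numerical convergence does not
remove it. The free-energy *bound* $F \ge -\ln P(\tilde s)$, by contrast,
holds in every case. Users who need calibrated posteriors on small problems
should use the enumeration oracle; the mean-field scheme's role is to scale
planning to state spaces (e.g. $1024$ states) where enumeration is
impossible.

### Numerical choices

* **Log floor.** Probabilities are floored at $10^{-32}$ inside logarithms.
  The floor sets the implied cost of an "impossible" event at
  $-\ln 10^{-32} \approx 73.7$ nats. This must exceed the free energy of any
  feasible trajectory (tens of nats for 16-step plans); a larger floor such
  as $10^{-16}$ (36.8 nats) makes a single impossible jump cheaper than a
  feasible multi-step plan, and the variational optimum then "teleports".
* **Log-sum-exp.** All belief updates renormalize in log space.
* **Ties.** Every argmax breaks ties toward the lowest index.

## 2. The mountain-car problem

The car lives on a landscape $H(x)$ with a valley at $x = -0.5$ and a
parking *pocket* — a second, local minimum — near $x = 1$:

$$\dot x = v,\qquad
\dot v = \tanh(a)\,\gamma - H'(x) - \kappa v,$$

with engine gain $\gamma = 0.5$ and friction $\kappa = 0.15$. The slope at
the origin is 1, while the strongest engine force is
$\tanh(2)\,\gamma \approx 0.48$: the car cannot drive from the valley to the
parking place directly (the package verifies this by forward integration)
and must first swing left to gather momentum. The pocket's walls are steep
enough to capture a car that crests the barrier.

### Why the landscape looks the way it does

The landscape's slope is piecewise linear through fixed knots. Two of its
features are deliberate couplings between the *continuous* dynamics and the
*discrete* planner:

* **Resolvable parking.** The pocket's harmonic core has natural frequency
  $\omega = \pi/2$, so its half-period equals the 2-second planning
  interval: a car that has settled into the core alternates between mirror
  states within the parking bin's neighborhood instead of drifting through
  many bins. A much stiffer core (full period = one step) looks attractive
  but makes *every* orbit a fixed point of the per-step map — a constant
  engine force then integrates to zero net displacement over one orbit and
  the parked car becomes uncontrollable. The half-period choice leaves
  roughly one grid bin of control authority per step.
* **Settling friction.** $\kappa = 0.15$ is large enough that a captured
  orbit spirals into the core within a few steps, yet small enough that
  resonant pumping in the valley still builds the momentum needed to cross
  the barrier.

### Discretization

`build_pullback()` discretizes one step of the dynamics on a
$32 \times 32$ grid over position $[-2, 2]$ and velocity $[-3, 3]$ with
five control levels $a \in \{-2, -1, 0, 1, 2\}$. Each state's forward image
under the integrated flow (classical Runge–Kutta with substeps — a single
Euler step over 2 s is badly unstable for this system) is split bilinearly
over its four neighboring bins; collecting these assignments per destination
and normalizing columns yields the pullback $B_k$, whose column means
reproduce the linearized backward step $x_j - f(x_j, a_k)\,\Delta t$ to
first order. Columns are then blurred with a separable Gaussian
($\sigma = 0.5$ bins) — modeling the uncertainty about the previous state
that discretization induces — and renormalized. The sampling kernel
$R_k$ is the renormalized transpose: the smoothed forward kernel. States
that receive no forward mass are unreachable under that control and get a
maximum-entropy pullback column; piling their mass onto the grid boundary
instead would fabricate absorbing boundary dynamics that the planner
learns to exploit.

The demonstration episode (`run_episode()` on
`make_mountain_car_model()`, $T = 16$, eight sweeps per step, modal
propagation) pumps in the valley, swings once, is captured by the pocket,
and parks in the goal bin at the final step, in roughly half a minute of
CPU time.

## 3. The continuous scheme: generalized filtering

`level_spec()` describes a single-level dynamic generative model: hidden
states $x$ with flow $f(x, u)$, control states $u$ drawn to a static prior
expectation $\eta_u$, observations $g(x, u)$, and Gaussian fluctuations
with log-precisions per channel group. Expectations live in *generalized
coordinates of motion* (value, velocity, acceleration; three orders by
default) and evolve by a gradient flow on free energy,
$\dot{\tilde\mu} = D\tilde\mu - \partial_{\tilde\mu} F$, where $D$ shifts
orders (`gen_shift()`). Generalized model functions are evaluated with the
first-order chain rule (higher-order curvature omitted), and temporal
orders are treated as independent in the precisions.

* **Integrator.** The default is local linearization,
  $\Delta\mu = (e^{J\,dt} - I)\,J^{-1}\dot\mu$, with the Jacobian assembled
  *analytically* under the same local-linearity assumption as the gradient
  itself ($J = D - \sum_b M_b^\top \Pi_b M_b$, negative semidefinite apart
  from the shift). A numerically differenced Jacobian would pick up the
  indefinite second-order curvature of, e.g., interpolated images, and the
  matrix exponential then amplifies spurious unstable directions. A
  free-energy guard retries any step that raises $F$ (for the same input)
  by more than a few nats with substeps; an explicit Euler mode exists as a
  cross-check on mild models.
* **Action.** The reflex arc $\dot a = -(\partial \tilde s/\partial a)^\top
  \xi_v$ has gain equal to the proprioceptive precision, so its time
  constant is far below one time bin; `action_step()` therefore integrates
  the locally linear reflex dynamics exactly over the bin (relaxation
  toward the error-nulling action) rather than taking an explicit step.
* **Conditional precision.** `conditional_precision()` returns the
  Gauss–Newton curvature $J^\top \Pi_s J + \text{prior}$ over a designated
  subset of latent variables. At a zero-residual point this equals the true
  Hessian of the Gibbs energy, which the tests confirm against central
  finite differences.

The conjugate linear-Gaussian case (static observation $g = \lambda u$,
prior mean $\eta$) is recovered exactly: the filter's fixed point is the
precision-weighted posterior mean and the curvature is
$\lambda^2\pi_s + \pi_p$.

## 4. Saccadic visual search

### Generative process and model

The world (`process_step()`) moves the true center of gaze as
$\dot x_p = a - x_p/16$ per time bin and returns proprioception
$s_p = x_p$ plus 256 visual channels: a $16 \times 16$ grid of
center-surround (difference-of-Gaussians) receptive fields under a 2-D
Hamming window, sampling the scene at the gaze (`sample_retina()`). Process
noise uses log-precisions 16 (sensory) and 8 (motion): effectively
noiseless sensors over a weakly fluctuating world.

The agent's model (`saccade_model()`) explains vision as a *mixture of
hypotheses*: $N = 3$ internal images with weights $e^{x_{q,i}}$ given by
perceptual log-weight states, sampled at the believed gaze. The gaze
expectation relaxes toward a control state $u$ (time constant 4 bins)
whose prior is reset between saccades; the perceptual states follow

$$\dot x_q = \big(1 - \textstyle\sum_i e^{x_{q,i}}\big) - x_q/1024,$$

a dynamic softmax whose equilibrium pins $\sum_i e^{x_{q,i}}$ to one up to
the slow-decay residual (about $10^{-3}$; `perceptual_equilibrium()`
computes it). Model log-precisions are 8 for proprioception, state motion
and the control prior, and 4 for vision — the agent prefers revising its
percept over doubting where it is looking.

### Salience and inhibition of return

Between saccades the agent asks, for each of $32 \times 32$ candidate
fixations: *how confident would I be about the hypotheses if I looked
there?* `salience_map()` substitutes the candidate for the gaze, holds the
current perceptual expectations fixed, and evaluates half the
log-determinant of the conditional precision over the perceptual states
only — the negative entropy of the counterfactual posterior. The
proprioceptive block is location-independent and would only add a
constant, and restricting the determinant to the perceptual states keeps
it well conditioned. Salience is by construction a function of beliefs
alone: the true scene never enters.

`apply_inhibition_of_return()` then shifts the map to differential
salience, multiplies by one minus a decaying memory of recent fixations,
and refreshes the memory with a Gaussian bump (peak 1, s.d. 1/16 of the
image size) at the new argmax plus half the old memory. The location just
foveated therefore has exactly zero salience on the next saccade, and the
memory of older fixations halves per saccade. The fixation prior
$\eta_u$ is reset to the winning location and the loop repeats: 8 saccades
of 16 bins (one bin nominally 12 ms) by default.

### Synthetic stimuli, and what the tests do and do not show

The package generates its own stimuli (`make_glyph_hypotheses()`): an
asymmetric arrangement of 3–5 small Gaussian blobs plus one thin bar,
with its 180°-rotated and 90°-rotated variants as competing hypotheses —
exact pixel permutations of one another, so the categories differ only in
arrangement, not statistics. Blob and bar scales are chosen so most of
their energy falls in the retina's center-surround passband; smooth,
low-frequency stimuli drive the channels weakly, and evidence then
saturates before the posterior becomes decisive. The generator emulates a
category-discrimination search on cluttered, feature-rich stimuli; it does
not emulate natural-image statistics, occlusion, luminance gradients, or
photographic texture, so passing tests demonstrate the mechanics of
evidence accumulation and salience-guided sampling, not recognition
performance on real scenes.

On a matched scene (the upright glyph, noiseless), the standard search
drives the true hypothesis's posterior above 0.95 with per-saccade entropy
decreasing monotonically, while consecutive fixations never repeat — the
behavior the acceptance checks assert.

## 5. Problem sizes and runtimes

The standard demonstrations are sized to run comfortably on one CPU: the
mountain-car episode (1024 states, 16 steps, 8 sweeps each) takes about
half a minute; a full 8-saccade search (21 latent dimensions, 258 sensory
channels, 1024 salience candidates per saccade) about ten seconds; all
enumeration oracles are guarded to at most $10^6$ joint sequences.

## 6. Known limitations

* Mean-field bias on multimodal posteriors (section 1) — by design of the
  scheme, quantified by the enumeration oracle.
* The discrete planner's performance depends on the discretization
  respecting the continuous dynamics; the forward-assignment construction
  plus integrated flow is essential (section 2), and grids much coarser
  than the dynamics' natural scales will degrade planning.
* Generalized filtering is implemented for a single model level; the
  machinery (errors, flows, precisions) is structured per level but
  hierarchical composition is not exposed.
* Temporal smoothness of fluctuations is not modeled in the precisions
  (orders are independent), which is adequate for the effectively
  noiseless regimes simulated here.
* The salience map evaluates "beliefs now, gaze there": counterfactual
  expectations are not propagated forward in time before evaluation.
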