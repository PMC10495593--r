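---
title: "The worm-blob agent model: equations, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The worm-blob agent model: equations, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`wormblob` simulates collectives of tubificine-type aquatic worms — "worm
blobs" — as a two-dimensional swarm of deformable, self-propelled,
cross-shaped agents. A blob is a dense, entangled aggregate that behaves
as a single soft body: it forms spontaneously, flees aversive chemicals,
and, in confined two-room arenas, shuttles between rooms, exploiting pegs
it can entwine. This vignette describes the model equations as
implemented, the numerical schemes, and the design decisions taken where
the model is under-determined — including several places where we had to
make concrete choices that materially shape the emergent behaviour.

## The agent

Each worm is a cross: a variable *head arm* of length $l_i \in [a, l_a]$
along the heading $\theta_i$, and three fixed arms of length $a$ (tail and
two laterals). Elongation represents a stretched crawling worm, $l_i = a$
a coiled one. Three coupled equations drive each agent:

* **Deformation** — $\tau \dot l_i = \bar l_i - l_i$ with target
  $\bar l_i = \max(l_a - l_b N_i,\, a)$: crowded agents (contact count
  $N_i$) coil, isolated ones elongate. With the default constants the
  coiling threshold $(l_a - a)/l_b = 20$ contacts.
* **Translation** — $m \ddot{\mathbf r}_i + c \dot{\mathbf r}_i =
  \mathbf F_{prop} + \sum_{j \in C_i} \mathbf F_{ij} + \mathbf F_{env}$,
  with propulsion $\eta\, G_i\, l_i$ along the heading (times the
  `speed_scale` repair factor, below), pairwise entanglement forces, and
  peg/wall forces.
* **Rotation** — $\dot\theta_i$ sums a piecewise-constant random drive
  $d_R \zeta_i$ (refreshed at Uniform$(t_{min}, t_{max})$ intervals), a
  chemotactic torque $d_C G_i \sin(\bar\theta_i - \theta_i)$ toward
  decreasing stimulus, a nematic alignment torque
  $d_A G_i (l_i - a)(l_j - a)\sin 2(\theta_j - \theta_i)$, and nematic
  alignment to contacted pegs ($d_P$) and walls ($d_W$).

The *activity* $G_i = f(\alpha A(\mathbf r_i) - \beta N_i) \in [0, 1]$
(piecewise-linear saturation $f$) multiplies propulsion, chemotaxis and
nematic alignment: crowding paralyses, aversive stimulus excites. Note
the co-design with the deformation law: $1/\beta = (l_a - a)/l_b = 20$,
so without stimulus an agent freezes at exactly the contact count that
also fully coils it; the self-released repellent (below) shifts the
freezing threshold upward and is what keeps a blob's rim alive.

## The stimulus field

The aversive stimulus $A = a_s + a_m$ combines a self-released repellent
$a_s$ — the model's hypothesis for why resting blobs eventually move —
and an optional static "mustard" gradient $a_m(x) = D e^{E x'}$. The
repellent obeys $\dot a_s = -k_{A0} a_s + D_A \nabla^2 a_s + k_{A1}
\sum_i \delta(\mathbf r - \mathbf r_i)$, solved with explicit Euler on a
cell-centred grid (`grid_dx`) with zero-flux boundaries.

Three interpretation choices, all flagged as such because the constants
$k_{A0}, k_{A1}, D_A, D, E$ are published dimensionless:

* **Grid-native units.** The Laplacian is computed per cell² (no
  $1/\mathrm{d}x^2$), making the published values directly usable; the
  stability requirement is then $D_A\,\mathrm{d}t \le 0.25$ (0.014 at
  defaults). The Dirac source becomes a deposit of $k_{A1}\mathrm{d}t$
  into the emitter's cell. The mustard coordinate is likewise in grid
  units, $x' = x/\mathrm{grid\_dx}$.
* **Cell size is a physical dial, not just resolution.** Because the
  constants are grid-native, the steady repellent level under a blob
  scales as $\rho\, k_{A1}\, \mathrm{grid\_dx}^2 / k_{A0}$ — choosing
  the cell size fixes how strongly a blob stimulates itself. The default
  `grid_dx` = 2 mm is chosen once so that the activity budget closes:
  under a packed blob $\alpha a_s$ then reaches order 1–2, comparable to
  the crowding penalty $\beta N$ at realistic contact counts, which is
  the regime the model needs (a crowded blob whose rim stays excitable).
  At 1 mm cells $\alpha a_s$ tops out near 0.3 and every crowded
  collective freezes permanently; the mustard e-folding length is
  16 mm at the default.
* **Walls are impermeable.** The zero-flux condition is applied at the
  arena boundary, not only at the grid edge: an out-of-domain neighbour
  mirrors the centre cell. This matters: the repellent then accumulates
  in the occupied room of a two-room arena and between the blob and a
  nearby wall, which is precisely the asymmetry that pushes the blob off
  its own chemical footprint. Cells just outside the domain are
  ghost-filled with the mean of their inside neighbours so interpolation
  and gradients sampled near a wall see no artificial step.
* **Out-of-grid agents** (possible only in the open dish) experience
  $a_s = 0$ and deposit nothing; the mustard term remains analytic
  everywhere. The exported `sample_stimulus()` treats out-of-grid points
  as an error; the engine degrades gracefully instead, since escaping
  agents leaving the mapped dish is normal behaviour there.

## Two repairs the published constants require

**Propulsion scale.** Substituting the published constants naively gives
a free-agent speed $\eta G l / c \approx 1.3 \times 10^3$ m/s — ten
orders out of range for centimetre arenas, and $\approx 10^9$ times the
maximal pairwise attraction ($\rho_1 \approx 1.65\times10^{-7}$ N), which
would make aggregation impossible at *any* uniform rescaling of the
equations (a uniform force rescale is a pure change of time unit in the
overdamped regime and preserves this imbalance). All other constants are
mutually consistent in SI: the torques are fractions of rad/s, the
pair/peg force constants give µN-scale forces, the friction constants
balance them at µm/s speeds. We conclude the propulsion coefficient alone
is dimensionally broken, and repair it with a single factor
`speed_scale` applied to the propulsion term only. Its default,
$4\times10^{-8}$, is calibrated once so that a free, half-active, fully
elongated agent traverses the 0.05 m arena scale in $\sim 10^3$ s,
matching the hours-scale arena traversals the model is meant to produce.

**Contact criterion.** "Contact" enters three ways ($N_i$ in activity
and target length, and the pair-interaction set $C_i$) but is never
geometrically defined. Treating any two body segments within a small
threshold as contact turns out to be structurally unusable: elongation
lengthens arms, which manufactures contacts, which raises $N$; dense
blobs then run away to complete contact graphs ($N \approx n$), every
agent saturates at $G = 0$, and the collective freezes into a dead lump
— verified numerically under a wide threshold sweep. We instead count
contact as *body-core overlap*: two agents are in contact iff their axis
intersection points are within `d_contact` (default 3.25 mm, about 1.3
coil diameters). This bounds $N$ by packing geometry independently of
posture, and lands blobs in the regime the model's constants were
evidently designed around: interior agents near the coiling threshold,
rim agents active and able to elongate outward. Peg and wall contacts
remain arm-based (a head arm reaching a peg is exactly the entwining the
peg interaction models) and use a separate threshold `d_touch`
(default 1 mm, about a worm diameter): physical grazing of a thin
obstacle is a body-thickness question, not a core-overlap one, and
reusing the 3.25 mm core radius for pegs turns them into arena-wide
friction patches (most of the collective "touching" a peg at all times)
instead of discrete anchors.

The equilibrium pair separation is $r_0 \rho_2 = 1.9$ mm; the power-law
bracket of the pair and peg forces is capped at its value at $0.1 r_0$ so
coincident initial placements cannot blow up.

## Arenas

Five environments: the 0.183 m square box (blob formation), the open
dish (escape, grid mapped over a 0.15 m square), the 0.05 × 0.025 m oval
(128-gon ellipse), and the two-room dumbbell with and without pegs. The
published dumbbell description (two 0.025 m octagons inside a 0.05 m
major axis) is degenerate — the rooms touch and the stated passage has
zero length — so the implementation follows the *experimental* bench
geometry instead: octagonal rooms 0.02 m flat-to-flat centred at
±0.015 m, joined by a 0.01 m long, 0.008 m wide passage (total span
exactly 0.05 m, aisle-to-room ratio 0.4). The funnel length is what
makes the dumbbell genuinely harder to cross than the oval. Pegs default
to an equilateral triangle per room (ring radius 0.3 × room half-width,
radius 0.75 mm, half the experimental peg side), mirrored across x = 0;
explicit coordinates are accepted.

## Numerics

* **Integrator.** The friction eigenvalue $c/m = 100\,s^{-1}$ makes the
  velocity equation stiff at $\mathrm{d}t = 0.2$ s ($z = -20$), far
  outside the stability region of a plain two-stage Runge–Kutta, which
  diverges violently. We therefore use the integrating-factor
  (exponential) form of the two-stage scheme: each agent's linear drag
  $b_i = c + q_1 N_i + q_2 P_i$ is integrated exactly via
  $e^{-b_i \mathrm{d}t/m}$ and $\varphi$-functions, while all remaining
  forces enter through a predictor/corrector pair that is exact for
  linearly-varying force and reduces to classical Heun as
  $b\,\mathrm{d}t/m \to 0$. The neighbour-velocity coupling
  $q_1 \sum_j \mathbf v_j$ stays explicit; its update weight
  $q_1 N/(c + q_1 N) < 1$ guarantees stability at any crowding. Headings
  use plain Heun; the head length uses explicit Euler plus the wall
  clamp, as in the source scheme. Observed convergence order on a
  noiseless curved trajectory is ≥ 1.8 (second order), checked in the
  acceptance suite with the head arm pinned at $l_a$ so the first-order
  length update does not mask the positional order.
* **Step staging.** Contacts, wall records, the field and $G_i$ are
  frozen across the two stages; the random torque is frozen across its
  whole refresh window. Stage 2 re-evaluates pair/peg forces and torques
  at the predictor state.
* **Contact bookkeeping.** A spatial hash (cell = `d_contact` + 2 mm
  skin) builds candidate pairs; the list is rebuilt only when accumulated
  motion could invalidate it, and the per-step contact test over
  candidates is exact, so the graph equals a full recomputation.
* **Wall queries** are pruned by a precomputed clearance grid (lower
  bound on wall distance per field cell), so interior agents skip the
  wall scan entirely.
* **Determinism.** All randomness flows through R's RNG in a fixed
  order (refresh sweep in agent order, single-threaded reduction);
  identical seeds give identical trajectories. Trial $k$ of an
  experiment uses seed $\mathrm{base} + 7919(k-1)$, shared across
  conditions so conditions are compared on a common seed ladder.

## Study conditions and what the tests show

The packaged scenarios default to the source protocols: blob formation
(square box, 1000 agents, $10^4$ steps), collective escape (open dish,
250 agents in a 12.5 mm disc, mustard on, $10^5$ steps), and the
confined-arena trio (oval / dumbbell / dumbbell + pegs, 250 agents
placed in the left side, $4\times10^5$ steps, 50 trials per condition —
`scripts/full_experiment.R`). The acceptance suite runs desk-scale
versions chosen to finish in minutes on one core: blob formation with
200 agents in a 0.08 m box for $5\times10^3$ steps (10 seeds), escape
with 100 agents for $2\times10^4$ steps (10 seeds), and the confined
trio with 100 agents for $10^5$ steps and 15 trials per condition;
`scripts/acceptance.R` reports the same quantities with 9 trials per
condition. Scaling down is not innocuous: with fewer agents the
self-released repellent is weaker and per-trial trip counts are small
integers, so the scaled ordering comparison has far less statistical
power than the 50-trial full protocol.

Trip counting uses a hysteretic state machine on the blob-centre
trajectory (centroid of the largest contact-graph cluster, all agents as
fallback — the agent-space analogue of tracking the dominant pixel
mass): a one-way trip is scored only when the centre enters the
*opposite* room's core disc (radius 0.5 × room half-width), so jitter at
the passage mouth never counts. The rank-sum comparison is implemented
in-package (exact enumeration below 8 per group, tie-corrected normal
approximation otherwise) and cross-checked against `stats::wilcox.test`
in the tests; two-sided by default, one-sided where a direction is being
asserted.

## What the synthetic scenarios do and do not capture

The generator reproduces the *model's* world: rigid cross geometry, 2D
kinematics, a single well-mixed repellent, deterministic walls. Real
worm blobs are three-dimensional, entangle topologically, bend along
their bodies, and are behaviourally heterogeneous — none of which is in
the model (the source model explicitly lacks bending softness), so
passing tests validate the implementation and the model's internal
logic, not those aspects of the biology. Known limitations worth
flagging: the emergent blob is looser than the dense hemispherical
aggregates seen on the bench (a direct consequence of the published
force constants once the collapse pathology is avoided); absolute trip
counts depend on the unstated contact radius and trip criterion, so only
between-condition *orderings* should be interpreted; the oval/dumbbell
contrast at desk scale rides on few-trip integer counts per trial; and
the peg-assist effect is not detectable at desk scale at all — with 100
agents and $10^5$ steps neither dumbbell condition completes
core-to-core crossings, so separating pegs from no-pegs requires the
full 250-agent, $4\times10^5$-step, 50-trial protocol of
`scripts/full_experiment.R`.
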