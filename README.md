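# wormblob

Agent-based simulation of **worm-blob collective locomotion**: how dense,
entangled aggregates of aquatic tubificine worms form, flee aversive
chemicals, and shuttle between the rooms of confined arenas — exploiting
pegs they can entwine — modelled as a 2D swarm of deformable,
self-propelled cross-shaped agents coupled to a self-released repellent
field. The package is aimed at researchers in collective behaviour and
active matter who want a reproducible, scriptable implementation of the
model and of its trip-count statistics.

## The model in brief

Each agent is a cross with a variable head arm `l ∈ [a, l_a]` along its
heading θ and three fixed arms of length `a`. Per agent:

* deformation: `τ dl/dt = max(l_a − l_b·N, a) − l` (crowded agents coil),
* translation: `m r̈ + c ṙ = F_prop + Σ_{j∈C} F_pair + F_peg + F_wall`
  with propulsion `η·G·l` along the heading,
* rotation: `dθ/dt = d_R ζ + d_C G sin(θ̄ − θ) + Σ_j d_A G (l_i−a)(l_j−a)
  sin 2(θ_j − θ_i) + d_P sin 2(θ_ip − θ) + d_W sin 2(θ_u − θ)`,

where the activity `G = f(α·A − β·N) ∈ [0,1]` couples everything to the
aversive stimulus `A = a_s + a_m`: a reaction–diffusion repellent `a_s`
emitted by the agents themselves (`ȧ_s = −k_A0 a_s + D_A ∇²a_s + k_A1 Σ
δ(r − r_i)`, zero-flux at the arena walls) plus an optional static
mustard gradient `a_m = D e^{Ex'}`. Pairwise entanglement is a viscous
term plus the distance-keeping bracket
`ρ1[(d/r0)^−λ1 − ρ2 (d/r0)^−λ2]`; pegs drag with `ρ3 (l−a)` times the
same bracket. Time stepping is a stiffness-aware two-stage Runge–Kutta
(exact exponential treatment of the friction), Euler for `l`, `dt` =
0.2 s. See `vignette("worm-blob-model")` for units, the dimensional
repairs the published constants require, and all numerical choices.

## Worked example

```r
library(wormblob)

params <- wb_params()                      # published constants + defaults
spec   <- scenario_spec("dumbbell_pegs",   # two rooms, 3 pegs per room
                        seed = 11, n_agents = 100, n_steps = 100000)
trial  <- run_scenario(spec, params)
trial
#> <wb_trial> dumbbell_pegs | seed 11 | 100 agents x 100000 steps
#>   clusters: 1 -> 17 | one-way trips: 0

tail(trial$centers, 3)                     # blob-centre trajectory (m)
#>      time             x           y
#> 199 19800 -0.0008293491 0.000870738
#> 200 19900 -0.0010751663 0.001053179
#> 201 20000 -0.0004365621 0.001225164
```

The initial bolus (one packed cluster in the left room) relaxes into a
handful of blobs plus free rovers; over the 2e4 s of model time the blob
mass drifts toward the passage (centre x from -0.011 up to ~0) without
completing a crossing, so this trial records 0 one-way trips. The trial
record carries per-stride agent snapshots (`trial$frames`), the
blob-centre track, a cluster-count time series, and the trip count: the
number of times the blob centre crossed from one room's core region to
the other's. Batch comparisons:

```r
ex <- run_experiment(c("oval", "dumbbell", "dumbbell_pegs"),
                     n_trials = 15, base_seed = 101,
                     n_agents = 100, n_steps = 100000)
ex   # per-condition trip medians, histograms, Mann-Whitney tests
```

Shell entry points (thin wrappers over the same functions) live in
`inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/simulate.R", package="wormblob"))')" \
    --scenario oval --seed 1 --steps 100000 --agents 100 --out run1
```

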