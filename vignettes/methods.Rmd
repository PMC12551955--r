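---
title: "Methods: temperature-responsive vector dynamics and release-schedule optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temperature-responsive vector dynamics and release-schedule optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`vectoropt` answers an operational question: given a suppression goal for a
mosquito vector population, logistics constraints on release frequency, and
one or several daily temperature futures, what schedule of transgenic male
releases meets the goal at least cost? The package contains three coupled
pieces: a dynamic model (stage- and genotype-structured ODEs driven by
daily temperature), a decision model (a smooth nonlinear program over
release amounts whose dynamics are a discretization of the same equations),
and a synthetic daily-temperature scenario generator that stands in for
observed weather and downscaled climate projections.

# The population model and its assumptions

Each node holds eggs, larvae, pupae, adult males, and mated adult females,
each count further indexed by genotype; mated females are indexed by their
own genotype *and* their mate's, so paternal alleles propagate correctly
through the inheritance cube. Assumptions, chosen to match standard
suppression-model practice:

* **Single compartment per juvenile stage.** No Erlang substaging; this
  keeps the optimization problem small. Stage durations are exponentially
  distributed as a consequence.
* **Density dependence acts on larval mortality** as the multiplier
  `1 + L_tot/K`, genotype-blind in both the crowding term and its victims.
  `K` (units: larvae) is the single habitat-quality dial; the wildtype
  equilibrium scales linearly with it.
* **Sex ratio is ½ at emergence; mating is instantaneous and once per
  female.** A newly emerged female mates male genotype `g_m` with
  probability `η_gm M_gm / Σ η M`. When no males are present the mating
  fraction is defined as 0 (no new mated females), which is the only
  self-consistent convention at extinction.
* **RIDL lethality is late-acting**, applied at adult emergence with
  penetrance ε (default 1): emergence survival is `1 − ε` for any genotype
  carrying the construct allele, in both sexes by default; a
  female-specific variant (`female_only = TRUE`) spares emerging males.
  Acting at emergence (rather than at larval stages) is the conservative
  choice for suppression: doomed heterozygous larvae still compete for the
  density-dependent resource.
* **Releases are adult males only**, added as start-of-day impulses. The
  released genotype defaults to the homozygous construct genotype, so all
  first-generation offspring are carriers.
* **Migration is adult-only** (males and mated females), linear in the
  source state, with per-day rate matrix; juveniles do not move. Nodes are
  internally well-mixed.
* **Temperature is piecewise-constant within a day**, because inputs are
  daily series.
* **Counting convention:** the "vector competent" population tracked by
  the objective is the mated females whose *own* genotype is wildtype,
  summed over mate genotypes and nodes. A wild female mated to a released
  male is still competent to bite and transmit; she is counted.

Thermal responses support the standard repertoire — constant, linear,
quadratic `c(T−T_min)(T_max−T)`, and Brière `aT(T−T_min)√(T_max−T)` — each
clamped below at a configurable floor. Mortalities are additionally floored
at `mort_floor` (default 1e-6/day) so equilibrium computations never divide
by zero. The shipped `aedes_aegypti` and `anopheles_gambiae` presets are
simplified, editable transcriptions in the style of published thermal-trait
fits; they are starting points for local parameterization and no package
test asserts their numeric values.

# The decision model

The objective, over horizon `T = {1..T_end}` (default 365) with
intervention start `t0` (default 200) and suppression fraction ψ (default
0.20), is

$$\sum_{t} \alpha_c c_t \;+\; \sum_k p_k \sum_{t \in \mathrm{win}} \alpha_F
 \sum_{g \in \mathrm{wild}} \left(F^k_{g,t} - \psi F^k_{g,1}\right)^2,$$

with default weights `alpha_c = alpha_F = 1` (the printed form of the
objective, which adds organisms and squared organisms; the weights allow
rescaling without changing the default). Two tracking windows are
implemented: `"from_t0"` (the default; the suppression goal applies from
`t0` through the end of the horizon) and `"all"` (every day of the
horizon). Both appear in the literature this formulation descends from; the
text description of the goal — a reduction held *from a designated date
onward* — is taken as authoritative, hence the default.

**Transcription.** The canonical full-space form of this program has state
variables at every (day, stage, genotype) with explicit-Euler equality
constraints, solved by an interior-point NLP code. No such solver exists in
this R stack, so the package uses the mathematically equivalent
reduced-space *single shooting* transcription: the only decision variables
are the release amounts on mask days (box-bounded in `[0, c_max]`, fixed 0
elsewhere — mask compliance is structural, not a constraint to satisfy),
and the states in the objective are produced by running the Euler rollout
itself. Two consequences matter:

1. **Transcription consistency is exact by construction.** The rollout the
   optimizer differentiates is byte-for-byte the rollout
   `rollout_discrete()` performs, so re-simulating a returned schedule
   reproduces the optimizer's states to machine precision.
   `verify_consistency()` still measures this honestly on every solve.
2. **Gradients are discrete adjoints.** The compiled kernel stores every
   Euler substep state on the forward sweep and back-propagates the exact
   Jacobian-transpose of the update (including the dependence of the
   target ψF₁ on the day-1 state, and of day-1 on a day-1 release), so one
   gradient costs about two rollouts regardless of the number of release
   variables. Gradients were validated against central finite differences
   (relative error ~1e-9; see `test-decision.R`).

The bound-constrained problem is solved with `stats::optim`'s L-BFGS-B.
The initial guess is the no-release rollout: feasible by construction and
deterministic. The solver is local; for the specific comparison
"weekly mask vs bi-weekly mask", warm-starting the wider-mask solve from
the narrower-mask solution (supported via `init_schedule`) makes the
relaxation monotonicity `f*_weekly ≤ f*_biweekly` a guarantee rather than a
hope, because L-BFGS-B never accepts an increase from its starting point.

**Stochastic form.** One state copy per temperature scenario, one shared
(non-anticipative) release schedule, tracking terms weighted by scenario
probabilities `p_k` (validated to sum to 1). The release-cost term is not
scenario-weighted — the schedule is decided before weather is realized, so
its cost is scenario-independent. A single-scenario stochastic program
follows exactly the deterministic code path and reproduces its solution
bit-for-bit; a zero-weight scenario contributes exactly nothing.

**Budget.** An optional total-release budget is enforced as a smooth
quadratic penalty (`1e6 · max(0, Σc − B)²`), since L-BFGS-B takes no linear
constraints. The penalty scale admits roughly percent-level overshoot; the
reported totals make any violation visible.

**Trips.** The printed formulation has no integer variables, so field
deployments are derived post hoc: `count_deployments()` counts (day, node)
pairs whose summed release reaches `theta_trip` (default 1 organism).
Release variables are continuous; schedules are rounded to whole organisms
only in the CSV writer, never in the report.

# Initialization and equilibria

The default initial state is the wildtype equilibrium at the mean
temperature of the (first) scenario. It is computed analytically — the
stage-balance chain pins total larvae at
`L = K (A − θ_L − μ_L)/μ_L`, where `A` collects the through-pipeline
reproduction rate — and then polished by damped Newton iteration with a
finite-difference Jacobian to residual `‖rhs‖ ≤ 1e-8 ‖state‖`. Non-viable
parameterizations (net reproduction below replacement) return the zero
state with a warning rather than an error, since extinction is the correct
equilibrium there. Because the ODE right-hand side is exactly zero at this
state, it is also an exact fixed point of the Euler rollout, which is why
ψ = 1 problems are solved by releasing nothing.

# Numerical choices

* **ODE integration**: adaptive Dormand–Prince 5(4), `rtol = atol = 1e-8`,
  restarted each day at the temperature switch and release impulse. (No
  ODE-solver package is available in the target environment; the
  integrator is ~60 lines and tested against the Euler rollout.)
* **Euler discretization**: `n_sub = 4` substeps/day by default. Stability
  requires `Δt · max total rate < 1`; the binding rate is density-inflated
  larval mortality `μ_L(1 + L_tot/K)`, so very fecund parameterizations
  need larger `n_sub` — the rollout detects states below
  `−1e-6·max(1, |state|)` and says so. Discrete and ODE trajectories agree
  to within 2% at `n_sub = 24` on smooth test problems.
* **Solver defaults**: `maxit = 2000`, `factr = 1e8`,
  `parscale = c_max/100`. The objective spans ~6 orders of magnitude
  between a no-release start and the optimum; `factr = 1e8` stops when the
  relative improvement per iteration is ~2e-8.
* **Output clamping**: ODE trajectories are reported clamped at zero with a
  `−1e-9` tolerance; the discrete rollout is left unclamped so the
  consistency check sees raw states.

# The synthetic climate generator

`generate_scenario()` produces
`T_mean + δ + A·sin(2π(t − φ)/365) + e_t`, with AR(1) anomalies
`e_t = ρ e_{t−1} + N(0, σ²(1−ρ²))` (stationary sd exactly σ), seeded and
bit-reproducible, leaving the caller's RNG state untouched. It emulates
the structure of the case-study inputs this model family is used with:
a seasonal cycle, a warming offset δ separating "historic" from "future"
regimes, and tunable daily variability σ separating "median" from "high"
variability scenarios. The four presets encode exactly those contrasts for
a tropical coastal climate (`T_mean = 26.5` °C, `A = 3.5` °C, `ρ = 0.65`;
δ = 0 vs 1.5 °C; σ = 1.0/2.2 vs 1.2/2.6 °C). Preset numbers are
documentation-level defaults — tests always pass explicit parameters.

What the generator does **not** emulate: multi-day heatwave clustering
beyond what AR(1) persistence produces, skewed anomaly distributions,
precipitation or humidity, and bias-corrected downscaling of real
projections. A green test suite therefore establishes that the machinery —
dynamics, transcription, optimization, evaluation — is correct on inputs
with realistic first- and second-order temperature structure; it does not
certify any real location's schedule. For operational use, replace the
generator with observed/projected series via the scenario manifest.

# Design decisions taken where the design was open

* **Anticipatory release masks.** A goal that binds from `t0` cannot be
  met *at* `t0` if releases may only start at `t0`: adult female mortality
  bounds the decline rate, so the population needs ~6–8 weeks of
  suppression lead time. The toy instances used in the acceptance tests
  therefore open the weekly mask 50 days before `t0`. This mirrors
  operational reality (programs ramp up before their target date) and is a
  property of the instance, not of the method.
* **Deterministic-on-average workflow.** `mean_series()` provides the
  pointwise weighted scenario mean so the deterministic model can be run
  on an averaged future — the workflow whose smoothing-of-extremes
  weakness motivates the stochastic formulation.
* **Cube interface.** Inheritance is a cross-indexed distribution-valued
  lookup plus per-genotype fitness modifiers, so non-Mendelian mechanisms
  (cytoplasmic incompatibility, homing drives) can be added as new cube
  constructors without touching the dynamics. Only Mendelian + RIDL is
  implemented here.
* **Hashing and provenance.** Every CLI run writes a manifest with a
  config content hash, package version, and timestamp; scenario files are
  byte-reproducible from (preset, seed).

# Known limitations

* No epidemiological (human transmission) coupling; the objective proxy is
  the wildtype adult female population.
* Open-loop only: the schedule is fixed at solve time; no re-optimization
  from surveillance during the horizon.
* The NLP is nonconvex and the solver local: different initial guesses can
  land on different local optima (the mask-relaxation warm start above is
  the worked mitigation for ordered comparisons).
* Single-locus, two-allele genetics; no resistance evolution.
* Daily temperature is the only exogenous driver; no precipitation,
  carrying-capacity seasonality, or behavioral thermoregulation.
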