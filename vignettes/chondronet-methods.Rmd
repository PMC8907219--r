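---
title: "Methods: semiquantitative regulatory-network modeling of chondrocyte regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semiquantitative regulatory-network modeling of chondrocyte regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chondronet)
```

## The model and its assumptions

`chondronet` models the biochemical regulation of an articular chondrocyte
as a signed directed graph over secreted, measurable molecules, transformed
into a continuous dynamical system. The design assumptions are:

- **High-level regulation only.** Nodes are soluble regulators (cytokines,
  chemokines, growth factors, proteases, structural proteins) plus a few
  effector read-outs (NO, ROS, apoptosis markers). Intermediate signaling
  metabolites are deliberately absent, so model states can be compared
  directly with secretome measurements from cell or explant cultures.
- **Normalized activations.** Every node carries an activation
  $x_n \in [0,1]$ interpreted as a fraction of its maximal expression; no
  absolute concentrations or kinetic constants are required.
- **Qualitative-to-continuous transformation.** A node's activators and
  inhibitors combine into a total input $\omega_n \in [0,1]$ via saturating
  blocks (see `total_input()`): the activator block rises from 0 to 1 as
  weighted activator levels rise, the inhibitor block gates it
  multiplicatively, and one-sided nodes use the single block (inhibitor-only
  nodes see $1-I$, so an unopposed silent inhibitor leaves the node free to
  express). The normalization prefactors $(1+\Sigma w)/\Sigma w$ guarantee
  saturation identities — a single activator at full expression yields
  $\omega = 1$ regardless of its weight — which makes steady states
  insensitive to unknown reaction kinetics; only the topology matters.
- **Sigmoid-minus-decay dynamics.** $dx_n/dt = \Phi_{h}(\omega_n) - \gamma_n
  x_n$ with a gain-$h$ sigmoid anchored exactly at $\Phi(0)=0$,
  $\Phi(1/2)=1/2$, $\Phi(1)=1$ (the anchors are algebraic, and the
  implementation preserves them to machine precision — they are tested at
  `1e-12`). Steady states of this system are the model's phenotypes.
- **Steady states as phenotypes.** Attractors reached from given initial
  conditions are interpreted as long-term expression programs (anabolic,
  catabolic, mixed). Limit cycles are not analyzed: a non-converged
  integration is reported with `converged = FALSE`, never silently used.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `h` | sigmoid gain (dimensionless) | 10 | smooth but decisive switch; the standard choice for this transformation, giving biologically plausible graded responses |
| `gamma` | decay rate (per model-time unit) | 1 | sets the (dimensionless) time scale; with activations in [0,1] the steady state of an isolated stimulated node is $\Phi(\omega)/\gamma$ |
| edge `weight` | activator/inhibitor weight α, β | 1 | unweighted topology-only modeling; weights are per-edge fields for users who have dose information |
| solver `step` | RK4 step | 0.01 | conservative; fixture steady states agree with the independent adaptive solver within 1e-6 max-norm (tested) |
| solver `tol` | convergence on max \|dx/dt\| | 1e-6 | tight enough that the fixed-point contract \|Φ(ω)−γx\| ≤ 10·tol holds at every reported steady state |
| solver `t_max` | integration horizon | 100 | ~7 decay time constants past typical convergence (t ≈ 12–20) |
| `direction_threshold` | qualitative up/down classification | 0.1 | a 10% change of normalized range; sensitivity to {0.05, 0.1, 0.2} can be re-run by the user |
| GA defaults | population 50, generations 100, crossover 0.8, mutation 1/L, tournament 3, elitism 2, repeats 100 | — | conventional small-GA settings; every value is a `ga_config()` field and is logged in run manifests |

Baselines are computed from a random initial condition drawn i.i.d. uniform
on $[0,1]$ from a Mersenne–Twister stream with seed 0 by default; responses
are "perturbed steady state minus baseline steady state", which maps onto
the $[-1,1]$ normalization of the cytokine-release datasets the model is
scored against. An ensemble of baseline seeds can be run by calling
`baseline()` over a seed vector; single-seed is the default reading.

## Design choices where the design was open

- **Source nodes.** Nodes without regulators have no defined $\omega$. They
  are held constant at their initial value by default (they act as boundary
  inputs, matching the use of sustained stimulation), with a configurable
  pure-decay alternative (`node_params(..., source_policy = "decay")`) used
  by the synthetic recovery problems, where inputs should vanish unless
  explicitly stimulated.
- **Clamping** pins a node's value *and* zeroes its derivative at every
  integrator step, so clamp contracts hold exactly in reported steady
  states, robust to solver interpolation.
- **Initial conditions.** Only the baseline uses random initial conditions;
  perturbation runs start unnamed nodes at 0 (configurable
  `default_initial`). An empty perturbation is defined to return the
  baseline itself, so "no perturbation ⇒ zero response" holds exactly.
- **Scenario 3's "50% of their potential"** is read as a clamp value of 0.5
  on a [0,1] node.
- **The IL-1β antagonist in ACS** is modeled as clamping `IL1B` to 0; an
  explicit antagonist node is out of scope.
- **"Pro-catabolic nodes"** in treatment scenarios 2–3 are the six OA
  induction cytokines minus IL-1β.
- **Treatment initial state.** Scenario integrations start from the OA-like
  steady state (the joint is diseased when treated); this is logged and
  configurable by constructing perturbations directly.
- **AMD exactly as defined.** The calibration fitness wraps the *mean*
  log-difference in the absolute value, so opposite-signed node errors can
  cancel; this pathology is intentional, regression-tested, and the reason
  final-model selection never relies on training AMD alone. `amd_strict()`
  (mean of absolute log-differences) is offered separately.
- **t-test between steady states** is a two-sided *paired* test across
  nodes; pairing and sidedness were open, and the choice is recorded in
  every result (`method` field). Degenerate zero-variance differences
  return p = 1 (zero mean, not significant) or p = 0 (uniform nonzero
  shift, significant). A sign-permutation test is provided as a
  nonparametric alternative.
- **Genome semantics.** Calibration deletes edges only — no additions, no
  sign flips. Which edges are mutable is an edge-table field; synthetic
  templates default to all-mutable.
- **Final-model selection** ranks candidates lexicographically: qualitative
  accuracy, then validation NMAD, then training AMD, with a
  catabolic-baseline flag surfaced but not ranked on. The lexicographic
  order is this package's own concretization of "examine qualitative and
  quantitative results together"; it is documented as a design choice, not
  as a reproduction of any published selection procedure.
- **Config files are JSON** (via `jsonlite`), not YAML: no YAML parser is
  available in the supported dependency set, and JSON round-trips the
  nested solver/GA sections losslessly.

## Numerical choices

- The reference integrator is fixed-step classical RK4 in C++; an
  independent Cash–Karp RK45 adaptive solver (pure R) must agree within
  1e-6 max-norm on fixture steady states, which is tested. States are
  clipped to $[0,1]$ after each step; excursions beyond 100·tol raise an
  error instead of being hidden.
- Non-convergence by `t_max` is an honestly reported outcome. In
  calibration it poisons the genome with fitness $+\infty$ (and a counter)
  rather than being skipped, so pathological topologies are never rewarded.
- GA fitness values are memoised per `run_ga()` call (a genome's fitness is
  deterministic); this changes no numbers and makes 100-repeat runs and
  exhaustive enumerations affordable.
- Seed fan-out: one master seed generates per-repeat seeds by a single
  `sample.int` draw, so adding repeats never perturbs earlier repeats'
  streams. All RNG use saves and restores the caller's `.Random.seed`.

## The synthetic-data harness

`generate_network()` emulates the *structure* of the experimental inputs,
not their distributions: random signed topologies with designated inputs
and guaranteed reachability; `generate_dataset()` emulates multiplexed
stimulation panels — one or two nodes clamped at 1 (pairs at 20%
frequency), per-node responses in $[-1,1]$, additive Gaussian measurement
noise (clipped), and self-readout masking (a perturbed protein's own
readout is excluded from scoring, since the clamp trivially determines it).
Noise is additive Gaussian by declaration — the real assay's noise model is
unknown — and the noise draw is scaled *after* sampling standard normals so
noise-free and noisy datasets from one seed share the same stimulus
sequence.

A green synthetic test therefore establishes: correctness of the
transformation and solvers, metric algebra, GA mechanics, masking and
normalization conventions, and recoverability of topology *under the
harness's assumptions* (independent additive noise, single/paired clamp
designs, identifiable candidate edges). It does **not** establish fidelity
to real chondrocyte biology, to the published curated topologies (the
packaged 28-node network is illustrative), or to real assay noise.

The topology-recovery problems used in the tests add two design elements
worth naming: candidate edges are screened for *identifiability* (a
candidate whose lone inclusion/exclusion moves the pooled AMD by less than
2e-4 is replaced — an edge invisible in the data cannot be recovered by any
method), and recovery is assessed on the `select_final()` winner across GA
repeats re-ranked by validation NMAD, because pooled AMD's cancelation
makes single-run training fitness an unreliable model-choice criterion —
precisely the behavior the multi-criterion selection step exists to fix.

For the GA-versus-exhaustive-search equivalence check (12 candidate edges,
4096 genomes), the test runs the GA at population 100, 150 generations,
mutation 2/L and tournament size 2 rather than the package defaults: the
pooled-AMD landscape on an exact-fit problem is partition-like and
deceptive, and the default small-budget GA finds the global optimum in only
a fraction of repeats. The original calibration used a commercial toolbox
whose defaults for a 12-variable problem amount to roughly 240,000 fitness
evaluations per run; the test's configuration spends about 6% of that.
Package defaults are unchanged.

## Known limitations

- Steady-state analysis only: no limit-cycle detection, no transient
  read-outs, no delays, no stochastic dynamics.
- No mechanotransduction, pharmacokinetics, or tissue-level communication;
  scenarios are steady-state comparisons under sustained clamps.
- The GA explores deletions of a fixed candidate set; it cannot propose new
  interactions or sign changes.
- AMD-based calibration inherits the cancelation pathology by design;
  users fitting real data should inspect NRSE distributions and qualitative
  scores, not the fitness alone.
- The fixture network is a vocabulary-complete illustration, not a curated
  model; conclusions about real chondrocyte regulation require a
  user-supplied curated topology.
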