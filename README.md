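# chondronet

Semiquantitative regulatory-network modeling of chondrocyte biochemical
regulation in healthy and osteoarthritic (OA) environments.

In early idiopathic OA, secreted inflammatory mediators shift articular
chondrocytes from an anabolic phenotype (collagen II, aggrecan, TIMP,
growth-factor signaling) toward a catabolic one (matrix metalloproteinases,
aggrecanases, nociceptive mediators). `chondronet` models that switch at the
cell level: a signed directed graph over measurable soluble molecules
(cytokines, chemokines, growth factors, proteases, structural proteins) is
transformed into a bounded continuous dynamical system, and long-term cell
phenotypes are read off as steady states under sustained stimulation or
blockade ("clamping"). The package is aimed at systems biologists and
cartilage researchers who want to explore cytokine-driven regulation,
calibrate a network topology against perturbation-response measurements
(e.g. Luminex cytokine-release panels normalized to [−1, 1]), and simulate
candidate treatments in silico.

## The model

Each node *n* carries a normalized activation level x_n ∈ [0, 1]. Its
regulators combine into a total input ω_n ∈ [0, 1]: with activator weights
α and inhibitor weights β (default 1),

    A = ((1 + Σα) / Σα) · (Σα x^a / (1 + Σα x^a))      activator block
    I = ((1 + Σβ) / Σβ) · (Σβ x^i / (1 + Σβ x^i))      inhibitor block

    ω = A(1 − I)   (both present) | A (activators only) | 1 − I (inhibitors only)

and the dynamics are a gain-h sigmoid of ω minus first-order decay:

    dx_n/dt = Φ_h(ω_n) − γ_n x_n,
    Φ_h(ω) = (−e^{0.5h} + e^{−h(ω−0.5)}) / ((1 − e^{0.5h})(1 + e^{−h(ω−0.5)}))

with Φ(0) = 0, Φ(½) = ½, Φ(1) = 1 exactly and defaults h = 10, γ = 1.
Steady states are found by fixed-step RK4 integration (an adaptive RK45
cross-check is built in). Perturbation responses are reported as the
perturbed steady state minus a baseline steady state reached from a seeded
random initial condition, giving values in [−1, 1] directly comparable to
normalized assay data.

On top of the dynamics the package provides:

- **Evaluation** — NMAD (mean |x−y|/2), per-point NRSE, the log-shifted AMD
  fitness |mean(ln(x+2) − ln(y+2))| (implemented exactly as defined,
  including its sign-cancelation pathology; `amd_strict` is the
  cancelation-free variant), paired t-tests between steady states with a
  sign-permutation alternative, and qualitative scoring against
  "stimulus ⇒ target up/down" behavior rules.
- **Calibration** — a genetic algorithm over binary edge-inclusion genomes
  (edge deletion only) minimizing AMD against a perturbation dataset, with
  seeded repeats, an exhaustive-search oracle for small problems, and
  multi-criterion final-model selection (qualitative accuracy, then
  validation NMAD, then training AMD).
- **Scenarios** — OA induction (IL-1β, TNF-α, IL-6, IL-8, IL-17, IL-18
  clamped at 1) and three autologous-conditioned-serum (ACS) treatment
  scenarios with t-test significance gating.
- **Synthetic data** — seeded generators for ground-truth networks and
  Luminex-style stimulation datasets (self-readout masking, additive
  Gaussian noise), so everything is testable offline.
- **CLI** — `generate` / `simulate` / `evaluate` / `calibrate` / `scenarios`
  subcommands driven by a JSON config, with reproducibility manifests
  (see `system.file("cli", "chondronet.R", package = "chondronet")`).

The packaged 28-node chondrocyte network (`fixture_chondrocyte_network()`)
covers the standard OA vocabulary (IL1B … CASP8, with UniProt accessions)
and literature-motivated example edges. It is **illustrative only**: a vocabulary-complete example, not a curated
model from the primary literature. To build an enrichment edge file yourself, query STRING
with the fixture's UniProt accessions (Homo sapiens; text mining +
experiments + databases; minimum interaction score 0.400 "medium
confidence"), export the interactions, and merge them with
`merge_networks()`.

## Worked example

```r
library(chondronet)
net <- fixture_chondrocyte_network()
net
#> regnet: 28 nodes, 62 edges (42 activating, 20 inhibiting)

params <- node_params(net)      # h = 10, gamma = 1, alpha = beta = 1
bs <- baseline(net, params, seed = 0)
round(bs$x_star[c("COL2A", "ACAN", "MMP13", "IL1B", "TGFB")], 3)
#> COL2A  ACAN MMP13  IL1B  TGFB
#> 0.987 0.904 0.000 0.001 0.999
```

The unstimulated baseline is anabolic: structural proteins and TGF-β near
full expression, proteases and IL-1β silent — a healthy chondrocyte.
Sustained proinflammatory stimulation flips the phenotype:

```r
oa <- oa_induction(net, params)  # six cytokines clamped at 1
round(oa$x_star[c("COL2A", "ACAN", "MMP13", "IL1B", "TGFB")], 3)
#> COL2A  ACAN MMP13  IL1B  TGFB
#> 0.000 0.000 0.998 1.000 0.000
```

Treating that OA state with ACS (TGF-β, IGF-1, IL-4, IL-10 clamped high,
IL-1β blocked; scenario 1 assumes the synovium is silenced):

```r
s1 <- acs_scenario(net, params, scenario_id = 1)
round(s1$deltas[c("MMP13", "COL2A", "ACAN", "VEGF", "PGE2")], 3)
#>  MMP13  COL2A   ACAN   VEGF   PGE2
#> -0.998  0.986  0.986 -1.000 -1.000
s1$ttest$p_value
#> [1] 0.2071328
```

MMP13 and the pain mediators (VEGF, PGE2) shut down and the structural
proteins recover — a full phenotype rescue on this illustrative network,
though the whole-vector paired t-test is not significant here because many
nodes barely move.

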