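---
title: "Methods: models, numerics and design choices in gcosc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, numerics and design choices in gcosc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Germinal-center B cells are believed to migrate cyclically between the dark
zone (DZ) and light zone (LZ) during affinity maturation. The chemokines
CXCL12 and CXCL13 occupy complementary regions and are read by the GPCRs
CXCR4 and CXCR5. Ligand binding triggers receptor desensitization and
internalization, so a cell sitting in a zone progressively loses
responsiveness to that zone's chemokine. `gcosc` models the closed loop —
static chemokine fields, receptor down-regulation, receptor-weighted
chemotaxis — and asks when this loop alone produces sustained DZ↔LZ
oscillations.

## Model structure and assumptions

**Fields.** Each chemokine profile is a static Gaussian in the coordinate
`x` along the inter-zone axis, `f_i(x) = c_i exp(-(x ∓ k)²/(2 w_i²))`, with
peak concentration `c_i` (arbitrary units), width `w_i` (μm) and centers at
`∓k`. Staticness assumes secretion/diffusion/decay equilibrate much faster
than cell migration. The peak-height parameterization (value `c` at the
center rather than unit mass) is deliberate: `c` and `w` then control height
and width independently. The convention is isolated in the `gaussian_field`
type so it could be swapped without touching any model code.

**Receptors.** The toy model uses mass-action down-regulation
(`dr/dt = π − r f − δ r`), giving the closed-form steady state
`π/(δ + f)`. The biologically motivated model starts from mass-action GPCR
trafficking — unbound receptors `U` bind ligand (`k_on`, `k_off`), bound
receptors `B` internalize (`μ`), the internal pool `I` recycles (`β`) or
degrades (`δ`), with synthesis `π` and first-order loss `τ` of `U`. Fast
binding plus neglect of recycling into the surface pool (valid when
synthesis dominates, `π ≫ μB`) collapses this to a single saturable
equation per receptor, `dr/dt = π − r τ κ f/(1 + κ f) − δ r`, with
`κ = k_on/(k_off + μ)` a rescaled association constant.
`reduce_mass_action()` performs exactly this mapping, and the test suite
verifies the reduced trajectory tracks `U + B` of the full scheme.

**Chemotaxis.** The velocity follows a persistent-random-walk (Langevin)
process relaxing at rate `γ` towards a chemotactic target velocity,

```
dv = γ [ χ ζ (S1 + S2) − v ] dt + σ dW ,
S_i = r_i ε_i f_i'(x) / (1 + ε_i f_i(x))² .
```

`S_i` is the receptor density times the spatial derivative of the saturable
occupancy `ε f/(1+ε f)` — the classic receptor-occupancy-difference signal
of chemotaxis theory, depending on both ligand concentration and receptor
density. `ε` is kept distinct from the trafficking constant `κ` so that
signalling and internalization can couple to bound receptor differently.

The drift placement deserves a note, because it was a genuinely open design
choice. Two formulations are equally natural a priori: additive drift
(`dv = [χζ(S1+S2) − γv] dt`) and relaxation towards a target velocity
(`dv = γ[χζ(S1+S2) − v] dt`); they differ only by a factor `γ` on the
drift and coincide for `γ = 1` (the toy-model scenarios). We adopted the
relaxation form because, under the bundled reference parameter sets, it is
the only variant of the saturable signal family we examined (saturation
exponents 0–3, gain vs association-constant placements of `ε`,
receptor-saturated signals) that reproduces the documented phase-diagram
structure of the biologically motivated model: the three oscillatory and
three stationary reference `(k, π1)` points and the location of the upper
oscillation threshold near `k ≈ 52`. The signal function is a single
swappable definition (`chemotactic_signal()`) so alternative couplings can
be explored without touching the integrators or the continuation code.

**Noise** enters only the velocity equation (additive, intensity `σ`);
receptors and position are noise-free. The toy model keeps the historical
additive form `dv/dt = r1 f1' + r2 f2' − γ v`.

## Parameters

All rates are per abstract model time unit; the bundled scenarios put
oscillation periods in the hundreds of time units, consistent with
interzonal cycling over hours when one unit is of order a minute.

| symbol | meaning | typical value |
|---|---|---|
| `c`, `w` | field peak height, width (μm) | 10–20, 15–25 |
| `k` | zone half-separation (μm) | 30–50, the main bifurcation parameter |
| `pi_i` | receptor synthesis | 0.005–1 |
| `delta_i` | constitutive degradation | 0.001–0.006 |
| `tau_i` | bound-receptor removal | 0.005–0.06 |
| `kappa_i` | trafficking association constant (conc⁻¹) | 0.1–10 |
| `epsilon_i` | signalling association constant (conc⁻¹) | 0.1–6 |
| `chi` | chemotactic responsiveness | 3–28 |
| `zeta` | overall signal scale | 1 |
| `gamma` | velocity relaxation rate | 0.03–5 |
| `sigma` | velocity noise intensity | 0 (deterministic) or 2 (IBM) |

The scenario registry (`scenario_names()`) freezes the reference parameter
sets used by the examples, tests and the acceptance script; they are the
study conditions, not tuning knobs.

## Numerical methods

**Integration.** Deterministic runs use `deSolve::lsoda` with `rtol 1e-8`,
`atol 1e-10`; the suite checks that halving tolerances moves endpoints by
less than `1e-6` relative. Stochastic runs use fixed-step Euler–Maruyama
(default `dt = 0.01`), adequate because the noise is additive on a single
component; with `σ = 0` the scheme agrees with the adaptive solution to
`O(dt)` and is verified against it. Each simulated cell owns an RNG stream
seeded `base_seed + cell_id`, making multi-cell runs reproducible
independently of scheduling order.

**Equilibria and continuation.** Every model variant has equilibria with
`v = 0` and receptors on closed-form nullclines, so the equilibrium set at
fixed parameters is the root set of a scalar force balance in `x`. We scan
it on a 4001-point grid, refine roots with `uniroot` to `1e-13`, and
classify stability from finite-difference Jacobian eigenvalues (step
`1e-6·(1+|state|)`). This full-root-set scan was chosen over
natural-parameter branch following because the branches of interest fold,
and the upper (subcritical) Hopf point sits numerically on top of the fold
that creates the re-stabilized branch: following a single branch loses it.
`continuation()` therefore reports (i) the oscillatory window — the
parameter interval with no stable equilibrium — with boundaries bisected to
`1e-3` and labelled H1/H2, (ii) complex-pair real-part crossings matched
along branches by x-continuity, and (iii) fold points from root-count
changes. In the frozen-receptor variant the fixed receptor contributes a
structural zero eigenvalue, so stability is assessed on the active
`(x, v, r1)` subsystem.

**Trajectory phenotyping.** The classifier discards the first 25% of the
record, then applies a decision tree: near-zero displacement range (`< 1`
μm) is a fixed point; a consistently shrinking peak envelope (Spearman
ρ < −0.6 and last-quartile median under half the first) is damped;
otherwise the oscillation is phenotyped from prominence-filtered peaks
(prominence above 10% of the swing, which suppresses sampling jitter and
SDE noise). `chaotic` requires both irregular inter-peak intervals
(CV > 0.2) and a positive largest-Lyapunov estimate (> 0.01 per time unit,
from two-trajectory renormalization) — either alone can be a long
transient. `nested` requires substantially more prominent maxima than
midline cycles (ratio > 1.8) with heterogeneous heights; `intrazonal`
requires all extrema on one side of the midline; remaining cycles are
symmetric or asymmetric by cycle mean and zone-residence balance (10%
tolerance, dead band `k/4`). All thresholds are configuration values with
these defaults — the categories themselves are qualitative.

**Voxel grids.** The IBM stores concentrations at voxel centroids (default
5 μm) and interpolates trilinearly; gradients are precomputed per axis by
central differences (one-sided at boundaries) and interpolated with the
same stencil, keeping the force continuous across voxel boundaries. Grids
are padded two voxels beyond the confinement volume so every admissible
position has a full stencil. Interpolation error is bounded by
`(spacing²/8)·max|f''|` and the tests verify the quadratic convergence
under spacing halving. Boundaries are reflective (position mirrored,
normal velocity negated), which preserves the 1D comparison and avoids
absorbing artifacts; collisions, when enabled, use linear soft-sphere
repulsion along the center line (off by default — the reference
comparisons are single-cell).

## What the scenario suite does and does not show

The bundled scenarios exercise: the saddle-node structure of the reduced
undamped velocity model; Hopf-bounded oscillatory windows in `k` for both
models; the six-point oscillation/stationarity phase-diagram check; the
ODE↔IBM agreement with a discretization-dominated error that shrinks with
voxel spacing; and noise-robustness of the oscillatory phenotype.

Two limitations are documented deliberately. First, the
weak-drag (`gamma = 0.03`) oscillation-diversity scenarios
(`fig5_bottom*`) converge to a stable focus near one field peak under the
adopted equations: with any gradient-proportional signal the
receptor–velocity coupling vanishes at a field peak (where `f' = 0`), so
the focus there keeps linearized decay rate `−γ/2` regardless of the
receptor kinetics, and the nested/chaotic phenotypes those scenarios are
named for must live on large-amplitude attractors that our transcription
of the velocity coupling does not sustain from the reference initial
state. The corresponding taxonomy check in the test suite is left failing
rather than re-labelled, and the acceptance script reports the agreement
count as computed. Second, the single-receptor variant's oscillatory
window depends on the frozen receptor level, which is a free parameter;
the package scans a small grid of levels and compares the widest window
against the full model's.

The IBM emulates single cells and small groups in a static field; it does
not model division, death, activation, cell–cell signalling, or evolving
chemokine fields, so conclusions about collective germinal-center dynamics
are outside its scope.

## Problem sizes

The test suite and acceptance script use: continuation grids of 40–60
parameter values at scan resolution 0.25–1 with 3001–4001-point root scans;
deterministic trajectories of 2001–4001 samples over 4000–40000 time units;
Euler–Maruyama runs of 10⁵–2×10⁵ steps; IBM comparisons over 150 time
units (deterministic) and 1500 time units (noisy); and an OU variance check
over 2×10⁵ steps. These sizes were chosen so each check is comfortably
converged at its stated tolerance.
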