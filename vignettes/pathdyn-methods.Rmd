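---
title: "Simulating and comparing intervention regimes in signaling-network kinetic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and comparing intervention regimes in signaling-network kinetic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathdyn)
```

## The problem pathdyn addresses

Kinetic models of cell-signaling networks — PI3K/PTEN/AKT, RAF/MEK/ERK and
their relatives — are systems of coupled ODEs over species concentrations,
with mass-action or similar rate laws attached to every reaction. The
questions practitioners ask of such models are comparative: what changes in
the network when a drug is added at minute 0, when a resistance mutation
halves a phosphatase, or when a second inhibitor is layered on top? pathdyn
answers these questions headlessly: it imports the model from SBML,
integrates it under two named intervention regimes ("Control" and
"Experiment"), differences the two runs entity-by-entity over time, and
renders the result with the field's visual conventions — node radius
proportional to concentration, edge thickness proportional to reaction
velocity, and a white/red/blue coloring of differences.

## Model representation and ODE compilation

A `reaction_network` holds species (with initial concentrations in nM, and
an optional boundary flag), reactions (reactants/products with positive
stoichiometries, modifiers, and a kinetic-law expression over species,
parameters and time), global parameters, and constant-volume compartments.
The supported SBML subset is Level 2 (V4) and Level 3 (V1) core: events,
rules, function definitions and piecewise/delay math are rejected with an
explicit unsupported-feature error. This is a deliberate architectural
choice, not a shortcut: interventions enter through the regime machinery,
outside the model file, so a model plus a regime file is a complete,
auditable description of an experiment. Species declared as amounts are
divided by their compartment volume on load so that everything downstream
works in one unit (nM); reaction-local parameters are hoisted to global
scope under `<reaction>__<parameter>` names to give interventions a flat,
unambiguous target namespace.

`compile_odes()` assembles the net stoichiometry matrix $S$ (products minus
reactants, boundary rows zeroed) and returns the velocity map $v(t, c, p)$ —
each kinetic law evaluated at the state — together with the derivative
$\dot c = S\,v$. Velocities are first-class outputs, recomputed at every
grid point from the reported state, because edge thickness and edge
differences encode them directly.

## Intervention regimes and event handling

An `intervention` is one of five discontinuities: `dose` (add nM to a
species — a bolus), `set_concentration`, `scale_concentration` (the
mutation pattern; a 50% reduction is factor 0.5), `set_parameter`,
`scale_parameter`. A `regime` is a time-sorted list of interventions with a
label. Dose semantics are additive rather than assignment: a second bolus
stacks on whatever drug remains, which is what sequential-dosing protocols
mean; for a drug that starts at zero the two readings coincide. Simultaneous
interventions apply in declared order, so regimes are deterministic by
construction.

`simulate_network()` integrates piecewise between consecutive intervention
times with LSODA (stiff-capable, adaptive; deSolve), applying each
intervention as an exact state/parameter jump and restarting the
integrator. Defaults are `rtol = 1e-8`, `atol = 1e-10` nM, a 601-point
uniform grid over `[0, 10]` minutes (signaling transients in the models this
emulates play out in 1–60 min; the grid mirrors a time slider between 0 and
`maxTime`). At a grid point that coincides with an intervention, the
post-discontinuity state is reported — the trajectory shows the dose jump,
not the pre-dose value.

One numerical choice deserves a note: the maximum internal step `hmax`
defaults to the grid spacing rather than deSolve's default (the whole time
span). This makes the solver's step sequence a function of the grid and the
state alone, not of the integration horizon, with the useful consequence
that a dosed run is *bitwise* identical to the untreated run at every grid
point before the first intervention. Interventions that are algebraic
no-ops (scale by 1) still restart the integrator, so they reproduce the
untreated run only to global-error accuracy (~1e-6 relative), not bitwise;
the test suite distinguishes these two guarantees deliberately.

Concentrations are integrated unconstrained and clipped at zero in the
reported trajectory, with a warning if any value falls below `-100 * atol`
— the fixture networks are non-stiffly positive, so clipping is a guard,
not a crutch. `integrated_signal()` supplies the scalar readout used for
inset summaries (a trapezoidal window integral, e.g. integrated AKT-like
activity).

## Comparison encoding

`compare_trajectories()` requires identical grids (resampling is the
caller's job; the comparison itself stays exact) and computes signed
differences `experiment - control` for every species and reaction at every
time. Hue follows the sign (red above control, blue below, white equal);
intensity is `|diff| / M(e)` with `M(e)` the per-entity maximum |value|
across both runs. Per-entity normalization is the default because a
10-fold change in a low-abundance species should be as visible as one in an
abundant species; a `global` mode (single shared scale) is available when
absolute comparability matters. Entities never observed away from zero get
intensity 0 rather than 0/0.

## Layout

`compute_layout()` runs Fruchterman–Reingold on the bipartite
species–reaction graph: every reaction is a small auxiliary node joined to
its reactants, products and modifiers. This representation was chosen over
direct species–species edges because a two-substrate reaction has no single
species pair, and because per-reaction velocities need a drawable carrier.
Parameters: optimal distance $k = \sqrt{\text{area}/n}$ with unit area,
temperature cooled linearly from 0.1 to 0 over the iterations (default
500), seeded uniform initial positions in the unit box. Three modes:
`planar2d`, `free3d`, and `sphere`, which re-projects every position onto
the sphere surface after each iteration (norms are exact to within
floating-point rounding). Layouts are bit-deterministic for a fixed
`(seed, iterations, mode)`; the global RNG state is saved and restored
around the seeded draw. Edge crossings are reduced only incidentally, as
with any FR-family method; equal edge lengths are an emergent property the
test suite checks on a symmetric graph (coefficient of variation < 0.05 on
the triangle motif).

## Rendering

Node radius maps concentration linearly onto `[r_min, r_max]` using the
per-entity run maximum as ceiling (floor ensures zero-concentration species
remain visible); edge width maps |velocity| the same way — thickness cannot
carry sign, so direction information in single-run mode is deliberately not
displayed. A `log1p` mode exists for wide dynamic ranges. Frames are
rasterized into an in-memory RGB array (discs with alpha-blending over
thick segments, black background) and written with `png::writePNG`, which
makes PNG export byte-deterministic — the property that makes animation
outputs diffable and cacheable. JPEG export goes through the standard
graphics device and is not promised byte-stable. The animation timeline is
an exported frame sequence; frames-per-run is a config constant.

## The fixture generator: what it emulates and what it does not

`make_fixture()` builds five mass-action motifs with documented closed
forms and conservation laws; `write_fixture_tree()` emits them as SBML plus
regime/catalogue files. Two motifs emulate the biology that motivates the
package:

* `receptor_inhibitor` — ligand + receptor ⇌ complex, complex +
  co-receptor ⇌ active dimer, inhibitor + co-receptor ⇌ inert pair: the
  HER2/HER3-style dimerization block targeted by an antibody drug. The
  steady dimer level falls monotonically with inhibitor dose.
* `crosstalk_shared_phosphatase` — two cascades deactivated by one
  limiting phosphatase through explicit enzyme–substrate complexes, plus a
  drug sequestering the first cascade's inactive kinase. Inhibiting
  cascade X frees phosphatase and *raises* the phosphatase complex on
  cascade Y — the PP2A-style crosstalk signature. The motif carries its
  own inhibitor species so that "inhibit cascade X" is an ordinary dose
  intervention rather than a special case.

Rate constants are of order 0.01–1 in nM/min units — generic signaling
scales chosen once so every qualitative mechanism is comfortably expressed
within a 10-minute horizon. The fixtures are *structural* stand-ins: they
reproduce mechanisms (dose-response, conservation, crosstalk direction),
not the published parameterizations of any cell-line model, so passing
tests demonstrate that the machinery is correct, not that any particular
biological prediction is. Real SBML models bring features the fixtures do
not exercise — deep stiffness, rate laws with shared global parameters
across dozens of reactions, wide concentration ranges — which is why solver
tolerances and the encoding scales are exposed in the run configuration
rather than fixed.

The standard regime suite per motif is: empty Control; 30 nM inhibitor at
t = 0; a mutation halving a motif-specific species (the shared phosphatase
for the crosstalk motif — the phosphatase-loss pattern — and the receptor
for the dimerization motif); and their combination. Sequential dosing is
exercised with a second 100 nM bolus of the same inhibitor at t = 5 min,
since each motif carries one drug species.

## Numerical choices and degenerate inputs

* Solver: LSODA, `rtol 1e-8` / `atol 1e-10` nM, `hmax` = grid spacing (all
  configurable). Verification sizes: closed-form and conservation checks on
  601-point grids over 10 min; cross-checking against an independent
  fixed-step RK4 oracle uses step 1e-4 min over a 2-minute window, where
  agreement is ~4e-9 relative.
* Comparisons require bit-identical grids; off-grid queries
  (`diff_summary`, `encode_frame`) snap to the nearest grid point with a
  warning rather than erroring.
* Ties in `diff_summary` rankings break lexicographically by entity id.
* A network with no reactions simulates as constant; a single-species
  network lays out at the origin (sphere pole in sphere mode); disconnected
  graphs are laid out per component and offset, with a warning.
* Empty drug catalogues are valid; catalogue rows bind to an explicit
  target-species column because headless operation cannot resolve drug
  names inside the model the way a curated GUI model could.

## Limitations

No SBML events/rules/function definitions (by design — use regimes); no
stochastic simulation or steady-state solving; no pharmacokinetic clearance
beyond what the network's reactions encode; comparisons are two regimes at
a time; rendering is orthographic projection without interactive rotation.
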