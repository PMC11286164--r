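---
title: "The looped-thread model: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The looped-thread model: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The mechanical picture

Cribellate spiders such as *Kukulcania hibernalis* spin capture threads
whose extensibility (~4000%) far exceeds that of any constituent silk
fibre (≤ ~50%). The mechanism is structural, not material: thin fibres are
deposited as continuous series of loops along a straight axial fibre, and
each loop stores *hidden length*. Under tension a loop opens at a critical
strain, the force across its fibre collapses, and the released length must
be straightened before the fibre carries load again. Thousands of such
sacrificial openings delay catastrophic failure and produce a sawtooth
force–elongation curve.

`loopfbm` casts this as an extended equal-load-sharing fibre bundle model
(FBM) under displacement control. Because the external strain `x` is
imposed, every surviving element sees the same elongation and load
"redistribution" after a failure is simply the change of the force sum —
no per-fibre load transfer needs to be computed. The classic closed form
`F = N k x (1 − P(x))` is provided (`classic_fbm_force()`) and serves as an
analytic reference for the solver: a Monte-Carlo bundle of 10^4 linear
fibres with uniform thresholds must reproduce it within 2% of the bundle
force scale `N·k` in sup-norm (the finite-sample Kolmogorov fluctuation of
the empirical threshold CDF sets the attainable agreement at this `N`; the
peak `N·k/4` at `x = 0.5` is checked to the same 2%).

## Elements

**Straight elements** carry `σ(x_e) · d²` for effective elongation
`0 < x_e ≤ x_c` and fail permanently beyond `x_c`. `d` is the *relative*
diameter; forces scale with the relative cross-section `d²` (area scaling),
so all model forces are in arbitrary relative units — the composite
morphology does not admit a meaningful absolute cross-section, which is
also why no stress or toughness output is offered.

**Looped elements** hold loops `(t_i, ℓ_i)` (opening strain, hidden
length). Openings proceed in ascending threshold order: after every opening
the effective elongation resets below zero, so the smallest remaining
threshold is necessarily the next one reached. Each opening adds slack
`s_i = t_i + ℓ_i`, which makes the post-opening effective elongation
exactly `−ℓ_i`: the force across the structure resets and the element
re-engages only after the hidden length straightens. This *reset* rule is
the package's central modelling choice. A weaker convention that credits
only the hidden length (`s_i = ℓ_i`) is available as
`settings$slack_mode = "hidden_only"` for parametric study; it releases far
less length and cannot reach extreme elongations. Only the reset rule
reproduces the ~4000% headline with the stock parameters: the expected
total slack per looped fibre is `200 · (0.150 + 0.038) = 37.6`, and the
last surviving element fails near `max(slack) + 0.5 ≈ 39–40`.

A looped element cannot fail while unopened loops remain; once the last
loop is open it behaves as a bare fibre with a *post-loop critical strain*
(default 0.5, configurable). The stock looped fibres have no measured
failure strain of their own, so they are given the same terminal strain as
the axial component; some terminal criterion is required for the
simulation to end, and 0.5 keeps all elements under the same 50% material
bound.

**Hierarchical coupling.** Straight axial elements adhere to the looped
fibres and feel their released slack. At every step a coupled element
receives the *largest* accumulated slack among its coupling sources (the
most-elongating undulating fibre transmits its displacements), scaled by
the transmission coefficient `Cs`:
`x_e = x − Cs · max_j slack_j`. The stock `Cs = 0.999` means nearly
perfect transmission: the axial component rides along with the unravelling
bands and fails only near the very end of the run. An alternative reading
would pin each axial element to one specific undulating fibre; the
max-slack rule is used because it matches the adhesive, band-wide contact
of the cribellar mat, and with the stock parameters the two uf slack
histories are statistically exchangeable so the choice is immaterial to
the headline quantities.

## The stock configuration

| group  | count | rel. diameter | law (GPa)            | critical strain | loops/fibre | t (opening) | ℓ (hidden) | Cs |
|--------|------:|--------------:|----------------------|----------------:|------------:|------------------|----------------|-----|
| radial | 1     | 1             | linear, E = 7        | 0.2             | —           | —                | —              | —   |
| axial  | 2     | 0.2           | 0.1·ε + 5·ε³         | 0.5             | —           | —                | —              | 0.999 → uf |
| uf     | 2     | 0.175         | linear, E = 7        | (post-loop 0.5) | 200         | 0.150 ± 0.145    | 0.038 ± 0.002  | —   |
| pc     | 6     | 0.035         | linear, E = 7        | (post-loop 0.5) | 200         | 0.150 ± 0.145    | 0.038 ± 0.002  | —   |

Notes on the choices embedded here:

* `±` everywhere denotes the **halfwidth of a uniform distribution** —
  the uniform family is the one the loop-opening statistics are defined
  with, and we apply the same reading to every distribution-valued
  parameter. All supports must be non-negative (strain-like quantities).
* Loop counts are **per fibre**: 2 × 200 uf loops + 6 × 200 pc loops =
  1600 loops in the default bundle. Loops are a geometric feature of each
  fibre (a continuous series along the axial line), and this reading is
  what yields the ~4000% extensibility.
* The axial critical strain is fixed at exactly 0.5 in the default; a
  `list(mean = 0.5, pm = 0.05)` variant expresses the looser "0.50 ± 0.05"
  assumption if wanted.
* The opening-strain distribution `0.150 ± 0.145` is deliberately
  *decoupled* from the loop size. An alternative convention ties the
  opening strain range to 0–300% of the loop length (max ≈ 0.114 for
  ℓ ≈ 0.038); both are expressible through the config, but the decoupled,
  wider distribution is the default: uniformly distributed opening strains
  over a wide range are what give the structure its positive overall
  stiffness towards the end of the pull.
* The stated relative diameters contain a tension: the axial component
  (0.2) is described as five times thinner than the undulating fibres, yet
  uf is listed at 0.175. The defaults follow the listed numbers verbatim;
  the discrepancy is documented rather than resolved, and both values are
  plain config fields.
* Odd, non-negative polynomial laws through the origin cover every law
  used here (linear and linear+cubic) and guarantee a monotone
  stress–strain response. The cubic axial law provides the strain
  stiffening that makes the force grow again towards the end of the curve.

## What the sampling emulates — and what it does not

`build_bundle(config, seed)` draws every loop threshold, hidden length and
(where distribution-valued) critical strain from independent substreams
derived from `(seed, element id, quantity)`, so changing one quantity's
distribution never perturbs another's draws, and identical
`(config, seed)` pairs give bit-identical bundles. The generator emulates
the *statistical geometry* of a real thread: loop inventories with
stochastic opening strains and near-constant loop sizes.

It does **not** emulate: adhesion and peeling of the cribellar nanofibre
mat (thought to propagate stress even after radial failure), slip–stick
friction during axial fibre fracture (a source of peak-amplitude variance
in empirical curves), strain-rate or humidity effects, or absolute forces
in mN (relative units only — empirical peak forces around 20 mN for the
radial line and ~1–3 mN for the bands require real silk cross-sections and
are out of the model's reach). Passing tests therefore validate the
meta-structural mechanism, not a quantitative force prediction for any
particular thread.

## Numerical scheme

* **Grid stepping.** Strain runs from 0 to `x_max` (default 50) in steps
  `dx` (default 0.005, i.e. 0.5% strain). Events are resolved *at grid
  points*, not by bisection, so every event strain carries up to one `dx`
  of slop; tests and analyses compare event locations with a `± dx`
  band. Halving `dx` moves the default thread's final strain by well under
  1% (checked in the test suite), which bounds the discretization error at
  the scale that matters.
* **Event cascades.** At one grid point an opening changes the slack felt
  by coupled elements, which can trigger further events at the same
  strain. The solver iterates passes (open every reached loop, mark every
  failure, recompute effective elongations) until a pass changes nothing,
  with a hard iteration cap (total loop count + element count + margin) as
  a termination guarantee. Within one element at most one loop can open
  per pass, because the reset leaves the element below zero elongation.
* **Ties.** Loops are kept sorted by threshold; exact ties open in input
  order, one per pass.
* **Termination.** The run ends at the first grid point where every
  element has failed (the force is identically zero from there on), or at
  `x_max`.
* **Degenerate inputs.** Negative effective elongation is legal and
  carries zero force (straightening of released length); the stress law
  itself refuses negative strain so slack handling stays explicit. A
  looped element with zero loops is exactly a straight element (tested as
  a reduction property). An empty bundle carries zero force.
* **Curve summaries.** The "radial peak" is identified as the *global*
  force maximum, which in full axial tests dominates all later forces;
  for radial-free tests (vertical plucking of the band alone)
  `summarize_curve(radial = FALSE)` reports only the overall peak and
  break strain. "Strain at break" is the last strain with force above a
  noise floor of 1% of the global maximum (configurable); this is a
  declared convention for noisy tails, not an attempt to reconstruct any
  particular experimenter's reading.
* **Drop detection.** A drop event is a maximal strictly decreasing run
  with relative drop ≥ `min_rel_drop` (default 5%). In the stock thread
  the six paracribellar fibres are so thin (d² ≈ 0.1% of the radial) that
  their 1200 openings are invisible in the total force at that threshold —
  only the ~400 undulating-fibre teeth and the failures register. The
  event-log cross-check is therefore exercised on an equal-diameter bundle
  where every opening is a detectable tooth.

## Problem sizes and runtime

The default simulation (11 elements, 1600 loops, dx = 0.005, ~8000 grid
points) takes well under a second; the test suite runs ten of them for the
extensibility average, one 10^4-fibre Monte-Carlo bundle against the
classic closed form, and small hand-specified bundles (≤ 10 loops) against
the exact closed-form opening strains
`x_i = Σ_{j<i}(t_(j) + ℓ_j) + t_(i)`. These sizes were chosen to keep the
whole suite in the tens of seconds while leaving every statistical check
with comfortable margins.

## Known limitations

* Quasi-static only: no inertia, no rate dependence.
* Equal load sharing only: no local load-sharing FBM variants.
* Relative forces: no stress/toughness output, no fit to empirical mN
  values, and no parameter-fitting layer (configurations are forward
  models).
* The terminal criterion for looped fibres (post-loop critical strain) is
  an assumption; empirical threads may fail by mat/fibre adhesion loss
  instead.
* Statistics on empirical curves (e.g. mixed-model species comparisons)
  are out of scope; the package stops at per-curve summaries.
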