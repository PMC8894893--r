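---
title: "Models and methods: free-energy ladders, headspace mass balance and the synthetic incubation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methanoFe)
```

# The scientific problem

In anoxic sediments and soils, iron-reducing bacteria and acetoclastic
methanogens compete for acetate. The classical "thermodynamic ladder"
predicts that whichever terminal-electron-accepting process yields the most
energy per mole of donor should win, which makes the identity of the iron
oxide decisive: poorly crystalline ferrihydrite is a far better electron
acceptor than well-crystalline goethite or hematite. This package packages
the computational core needed to study that competition in batch
incubations: the free-energy engine, the headspace methane mass balance, the
iron speciation bookkeeping, and a synthetic forward model that makes the
whole pipeline testable against known truth.

# The free-energy engine

## Model

For each registry reaction, written per mole of acetate,

$$\Delta G_{rxn} = \Delta G^\circ_{rxn} + RT \ln Q, \qquad
\log_{10} Q = \sum_i \nu_i \log_{10} a_i,$$

with $\nu_i$ the signed stoichiometric coefficient (products positive) and
$a_i$ the activity. Solids and water take unit activity; the proton enters
as $a_{H^+} = 10^{-pH}$. Negative $\Delta G_{rxn}$ is exergonic.

Assumptions, each a deliberate design choice:

* **Activities are concentrations.** The incubations this models run in
  dilute artificial freshwater (ionic strength ~0.02), where activity
  coefficients are near one on a log scale. No Davies/Debye–Hückel model is
  applied; users wanting one can pre-correct their activity maps.
* **T = 298 K, R = 8.314×10⁻³ kJ mol⁻¹ K⁻¹ by default**, even though such
  incubations are often run slightly warmer; the tabulated standard
  energies are 298 K values and consistency matters more than the ~1%
  temperature effect. Both are fields of `chemical_conditions()`.
* **Tabulated ΔG°rxn, not recomputed.** The registry ships the standard
  reaction energies directly (−546.47, −510.83, −370.99, −347.87, −14.68
  kJ/mol acetate for magnetite, ferrihydrite, goethite, hematite reduction
  and methanogenesis). `standard_reaction_energy()` remains available for
  user-supplied formation-energy tables; it is not used for the registry
  because the registry's provenance is the tabulated constants themselves.
* **pH is not an activity-map entry.** A proton activity in the map would
  silently double-specify the same quantity; the constructor rejects it.
* **No kinetics.** Monod terms, growth yields, speciation equilibria
  (carbonate system, Fe²⁺ complexation) and mineral transformation dynamics
  are out of scope; the engine answers "who *can* win", not "how fast".

## Derived quantities and numerical choices

* `sensitivity()` is the exact per-decade derivative
  $\nu_i RT\ln 10$ — 45.64 kJ/mol per decade of Fe²⁺ for the 8-Fe oxide
  reductions, 5.70 kJ/mol per decade for any coefficient-1 species. The
  `per = "decrease"` switch flips the sign because "+5.7 per decade
  *decrease* in acetate" is the natural phrasing for a reactant. The 8:1
  ratio between the Fe²⁺ and CH₄ sensitivities is pure stoichiometry and is
  asserted as a test invariant.
* `ladder()` sorts by ΔG with ties defined at 10⁻⁹ kJ/mol and broken by
  registry insertion order; the sort key is quantized to that tolerance so
  the tie-break is deterministic across platforms. Because every registry
  reaction consumes exactly one acetate, acetate activity shifts all rungs
  equally and the ordering is provably acetate-invariant (property-tested).
* `crossover_activity()` brackets and bisects $\Delta G_A(x)-\Delta G_B(x)$
  to 10⁻⁶ log units. The difference is linear in $x$, so bisection is
  numerically boring — which is the point: it independently cross-checks
  the closed-form algebra used in the tests. A bracket without a sign
  change returns `NA`; an identically-zero difference (e.g. a reaction
  against itself) is flagged `degenerate`.
* `energy_landscape()` refuses an axis species that also has a fixed
  activity — the alternative (silent override) hides user error. Along any
  axis the grid is monotone with the sign of the species' coefficient,
  asserted as an invariant.
* Lepidocrocite is deliberately not a registry entry: its formation energy
  is nearly identical to goethite's, so a separate rung would suggest a
  distinction the thermodynamics cannot support. Users may register one.

# Headspace methane mass balance

## From ion currents to fractions

Each RGA sampling reads m/z {2, 15, 16, 18, 28, 32, 44} every ~18 s for
~3 min; signals stabilise late in the draw, so the sample's composition is
the mean of the last five readouts (`stable_average()`, `n_last`
configurable). CH₄ is quantified at m/z 15 only — m/z 16 is ambiguous with
O₂ — and CO₂ at 44; other channels are carried for QC. Calibrated ratios

$$R_{CH_4} = s\,\frac{I_{15}}{I_{28}} + b$$

feed the fraction equations

$$F_{CH_4} = \frac{R_{CH_4}}{R_{CH_4}+R_{CO_2}+1},\quad
F_{CO_2} = \frac{R_{CO_2}}{R_{CH_4}+R_{CO_2}+1},\quad
F_{N_2} = \frac{1}{R_{CH_4}+R_{CO_2}+1}.$$

One prominent flag: the second of these is sometimes printed with a CH₄
numerator, which would make it identical to the first; the CO₂ numerator
used here is the only reading under which $F_{CO_2}$ is the fraction of
CO₂ and the three fractions sum to one. A calibrated ratio that comes out
negative (negative intercept near the detection limit) is clamped to zero
with a warning rather than propagated.

## From fractions to cumulative production

Moles come from the ideal gas law at an assumed 1 atm total pressure
(`moles_in_headspace()`, R = 0.082057 L·atm·mol⁻¹·K⁻¹; a single code path
so every conversion is bit-identical). The 1 atm assumption slightly
underestimates once CH₄/CO₂ production builds pressure; the pressure is a
parameter, and no pressure-buildup model is applied by default.

Two bookkeeping subtleties, both resolved in favour of closing an explicit
mole inventory and both exposed as switches:

* **Headspace volume.** Each ~6 mL liquid withdrawal expands the headspace.
  `headspace_volume()` counts withdrawals at *strictly earlier* timepoints,
  so the first measurement sees exactly the initial 300 mL. The
  alternative (count the same-day withdrawal too) is
  `include_current = TRUE`.
* **Withdrawal correction.** The instrument consumes ~7 mL of headspace per
  measurement (1 mL per 26 s; `rga_gas_consumed()`), so methane present
  understates methane produced. `cumulative_methane()` adds back the
  methane in every *prior* draw, at the composition measured when that draw
  was taken:
  $n_{prod}(k) = n_{present}(k) + \sum_{j<k} F_{CH_4}(j)\,n(V_{rem}(j))$.
  At the first timepoint nothing has been withdrawn and production equals
  presence. Crediting the current draw to its own timepoint
  (`include_current = TRUE`) is a defensible alternative reading, but only
  the strict prior-removal form agrees with a step-by-step bottle
  inventory, which is why it is the default and the oracle-tested path.
  Withdrawn gas is assumed to have the headspace composition at that
  timepoint, and volumes are not subtracted from the headspace (the 1 atm
  assumption implies replacement at ambient pressure from the glovebag).

`production_rate()` differences the cumulative curve over a day window with
linear interpolation at off-grid endpoints; `max_rate_window()` slides a
fixed-width window anchored at measurement days, first window winning ties.

# Iron speciation and the acetate budget

HCl-extractable Fe(II) and total Fe are assayed after a 1:1 acid dilution
(`dilution_correct()`, factor 2 default) and split by difference
(`ferrozine_split()`). Assay noise can push Fe(II) marginally above total;
overshoot within 2% of total — typical colorimetric noise — clamps Fe(III)
to zero with a warning, larger overshoot errors. Aqueous Fe arrives
already on the in-bottle scale (its own 1:1 dilution is applied upstream of
the reported concentration).

Because the aqueous pool's valence is not measured, solid-phase Fe(II) is
reported as an interval: if all aqueous Fe is ferrous the solid holds
$Fe(II)_{HCl} - Fe_{aq}$, if all ferric it holds $Fe(II)_{HCl}$ (capped by
the solid total), and any intermediate split lands between
(`solid_phase_bounds()`). The interval-coverage property is tested against
the generator, which *does* know its valence split. For narrative
comparisons the aqueous pool is often treated as fully ferrous; the
interval output never assumes this.

`acetate_budget()` converts increments of Fe(II) and CH₄ into acetate
consumed by each pathway (8 mol Fe(III) per mol acetate; 1 mol CH₄ per
mol acetate); it is homogeneous of degree one and reports the Fe:CH₄
acetate ratio, `NA` when no methane was produced.

# The synthetic incubation generator

## The stated world

One parameter set (`condition_preset()`) encodes the incubation world the
package is designed around, chosen once:

| Quantity | Default | Why |
|---|---|---|
| Bottle | 200 mL liquid / 300 mL headspace | standard 500 mL serum bottle setup |
| CH₄ model | logistic, plateau 2 mmol, r = 0.5/day | S-shaped curves with ~0.25 mmol/day peak (plateau·r/4), in the observed 0.2–0.3 range |
| Midpoint | day 17.5 (ferrihydrite), 14.5 (others) | places maximum-rate windows at days 16–19 vs 13–16: the lag contrast |
| Fe(II) | 6 mM·(1−e^(−0.4 t)) for ferrihydrite | ~98% of the 6 mM plateau by day 10; <1 mM presets otherwise |
| Acetate | 10 mM + 5 mM·(1−e^(−1.5 t)) pulse | initial dose plus sediment fermentation reaching ~15 mM by day 3 |
| CO₂:CH₄ | 0.5 mol/mol to headspace | bicarbonate buffering keeps most produced carbon dissolved |
| Aqueous Fe | 1/3 of HCl-extractable Fe(II) | HCl-extractable Fe(II) ≈ 3× dissolved Fe (1:2 aqueous:sorbed) |
| Noise | 1% relative (RGA), 0.1 mM (Fe), 0.3 mM (acetate) | realistic instrument/assay scatter |

A logistic rather than Gompertz cumulative curve was chosen because the
data the world emulates are described only as S-shaped; the logistic's
symmetric inflection makes the max-rate-window arithmetic transparent.

The acetate ledger is *intensive*: concentrations on the nominal 200 mL
basis, with acetate drawn down by exactly
$CH_4 + Fe(II)/8$ (in moles on that basis). Withdrawn liquid carries the
same concentrations as what remains, so sampling does not move
concentrations; the carbon/electron balance therefore holds to machine
precision by construction and is asserted on every trajectory. The gas
side, in contrast, is fully volume-aware: an explicit CH₄/CO₂/N₂ mole
inventory at 1 atm, instrument draws removed at the prevailing composition,
liquid withdrawals expanding the headspace for subsequent timepoints. With
the ferrihydrite world (6 mM Fe(II) → 0.75 mM acetate-equivalent against
10 mM to methane), the ledger leaves a few mM of acetate unconsumed at day
30 — the generator does not force the drawdown to zero, and does not claim
to.

`forward_rga()` inverts the calibration to raw signal ratios and emits
11-readout scans with a deterministic warm-up drift that vanishes before
the final five readouts, so the stable-tail average round-trips exactly at
zero noise; relative Gaussian noise is applied per readout and channel.
`forward_wetchem()` halves concentrations (the acid dilution in reverse)
and adds additive noise. All randomness flows through explicit `seed`
arguments into R's default Mersenne-Twister generator; the latent truth
itself uses no randomness at all.

## What a green test does and does not establish

The generator world is self-consistent by construction, so end-to-end
recovery tests establish that the pipeline's bookkeeping is the exact
inverse of the stated forward model — no more. Real incubations break the
world's assumptions in known ways the generator deliberately omits:
headspace pressure above 1 atm, CH₄ partitioning into the liquid, CO₂
carbonate equilibria, replicate-to-replicate biology, non-logistic lags,
mineral transformation feedback on rates, and acetate produced by ongoing
fermentation after day 3. Recovering the synthetic truth to 10⁻⁶ says the
arithmetic is right, not that a field bottle obeys it.

# Known limitations

* The ladder engine is an equilibrium statement; it cannot express surface
  passivation, transformation of ferrihydrite to magnetite/goethite, or
  any kinetic reason why a favorable metabolism fails to dominate — the
  central observation such incubation studies turn on.
* The 1 atm assumption biases late-timepoint moles low; a pressure model
  would need total-pressure measurements the instrument does not provide.
* Solid-phase speciation is interval-valued by design; no point estimate is
  offered because none is identifiable from these assays.
* The CLI's config schema is strict (unknown keys are rejected); this is a
  feature, but it means new pipeline switches require a package update.
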