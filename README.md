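# methanoFe

Tools for batch-incubation studies of the competition between microbial
iron(III) oxide reduction and acetoclastic methanogenesis — the situation in
anoxic lake sediments, wetlands and water-saturated soils where iron
reducers and methanogens share acetate as the electron donor and the iron
oxide's mineralogy (ferrihydrite vs. goethite, hematite, magnetite) decides
who wins.

The package has four parts:

1. **Thermodynamic ladder engine.** In-situ Gibbs energies
   `ΔGrxn = ΔG°rxn + RT ln Q` for a built-in registry of five
   acetate-consuming metabolisms (magnetite, ferrihydrite, goethite and
   hematite reduction, and acetoclastic methanogenesis), all normalised per
   mole of acetate. Solids and water take unit activity, H⁺ enters as
   `10^(-pH)`, and activities follow the concentration-as-activity
   convention for dilute freshwater. On top of `delta_g()` sit per-decade
   sensitivities (`coeff · RT ln 10`), stable favorability ladders,
   bisection-solved crossover activities, and gridded energy landscapes.
2. **Headspace gas pipeline.** Converts multi-ion residual-gas-analyzer
   (RGA/MIMS) scans of sealed serum-bottle headspace into calibrated
   CH₄/CO₂/N₂ fractions (`F_CH4 = R_CH4/(R_CH4 + R_CO2 + 1)`), moles via
   the ideal gas law at 1 atm, and cumulative methane production corrected
   for the gas the instrument itself withdrew at earlier timepoints, plus
   windowed production rates and the maximum-rate window.
3. **Iron speciation and acetate budget.** Ferrozine-style Fe(II)/Fe(III)
   splits with dilution correction, interval bounds on solid-phase Fe(II)
   (honest about the unmeasured valence of the aqueous pool), and the
   8:1 electron budget linking iron reduction to methane production
   (8 mol Fe(III) per mol acetate vs. 1 mol CH₄ per mol acetate).
4. **Synthetic incubation generator.** A seed-deterministic forward model
   of a 500 mL bottle (200 mL liquid / 300 mL headspace, ~30 days) that
   emits the exact CSV dialects the pipeline consumes, so every stage is
   testable end-to-end with known ground truth.

## Worked example

```r
library(methanoFe)

reg <- reaction_registry()
cond <- reference_conditions(acetate = 1e-4)   # pH 7, reference activities

delta_g(reg$ferrihydrite, cond)
#> [1] -48.73955
delta_g(reg$methanogenesis, cond)
#> [1] -31.79446

ladder(reg, cond)$id
#> [1] "ferrihydrite" "methanogenesis" "goethite" "hematite" "magnetite"

sensitivity(reg$ferrihydrite, "Fe2+")          # kJ/mol per decade increase
#> [1] 45.63856
crossover_activity(reg$goethite, reg$methanogenesis, "Fe2+",
                   cond, bracket = c(-12, 0))
#> [1] -5.692787
```

Ferrihydrite reduction (−48.7 kJ/mol acetate) out-competes methanogenesis
(−31.8) at the reference condition, while goethite and hematite reduction
are endergonic there; each decade of Fe²⁺ accumulation costs iron reducers
45.6 kJ/mol acetate, so goethite reduction only overtakes methanogenesis
below an Fe²⁺ activity of about 10⁻⁵·⁷.

End-to-end on synthetic data:

```r
truth  <- simulate_incubation(condition_preset("ferrihydrite"))
scans  <- forward_rga(truth, noise_sd = 0.01, seed = 7)
events <- cbind(bottle = truth$bottle, truth$schedule)
series <- process_gas(scans, events)
max_rate_window(series, width_days = 3)
#> $window
#> [1] 16 19
#> $rate
#> [1] 0.0002387  # mol/day, i.e. ~0.24 mmol/day
```

The ferrihydrite preset peaks in days 16–19 versus 13–16 for the Fe-free
control — the lag imposed by early iron reduction.

## Command line

An installed `exec/methanoFe` script exposes the pipeline:

```sh
methanoFe thermo-table --acetate 1e-4,1e-2 --out table.tsv
methanoFe landscape --species Fe2+ --from -8 --to -2 --by 0.25 --out ls.tsv
methanoFe simulate --condition ferrihydrite --seed 1 --out-dir sim/
methanoFe gas-process --scans sim/scans.csv --events sim/events.csv \
    --calibration sim/calibration.csv --out gas.csv
methanoFe fe-process --in sim/fe.csv --out fe.csv
methanoFe budget --delta-fe 0.002 --delta-ch4 0.002
```

Column schemas (all long-format CSV, days as floats, concentrations mM,
moles mol): scans `(bottle, day, elapsed_s, mz, signal)`; events
`(bottle, day, liquid_mL, gas_mL)`; calibration
`(analyte, mz, slope, intercept)`; iron
`(bottle, day, fe2_raw_mM, fetot_raw_mM, aqueous_mM, dilution)`; acetate
`(bottle, day, acetate_mM)`.

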