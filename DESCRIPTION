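Package: methanoFe
Title: Thermodynamic Ladders and Headspace Mass Balance for Iron-Oxide
    vs. Methanogenesis Incubations
Version: 0.1.0
Authors@R:
    person("methanoFe", "Developers", email = "methanofe@example.org",
           role = c("aut", "cre"))
Description: Tools for batch incubation studies of competition between
    microbial iron(III) oxide reduction and acetoclastic methanogenesis.
    Provides a reaction free-energy engine (standard and in-situ Gibbs
    energies, per-decade sensitivities, favorability ladders, crossover
    activities and energy landscapes) for acetate-consuming metabolisms;
    a residual-gas-analyzer headspace pipeline converting multi-ion scans
    into calibrated CH4/CO2 fractions, moles and withdrawal-corrected
    cumulative methane production with windowed rates; Fe(II)/Fe(III)
    speciation bookkeeping with honest interval bounds on the solid phase
    and the acetate electron budget; and a seed-deterministic synthetic
    incubation generator for end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
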