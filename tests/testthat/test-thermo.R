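reg <- reaction_registry()
t1_lo <- reference_conditions(1e-4)   # 100 uM acetate
t1_hi <- reference_conditions(1e-2)   # 10 mM acetate

test_that("registry reactions are element- and charge-balanced", {
  for (r in reg) expect_silent(assert_balanced(r))
  bad <- reaction_spec("unbalanced", c("Fe2+" = 1, "H2O" = -1), 0)
  expect_error(assert_balanced(bad), "not balanced")
})

test_that("standard_reaction_energy is the signed-coefficient dot product", {
  toy_phases <- c(X = "aqueous", Y = "aqueous")
  toy <- reaction_spec("toy", c(X = -2, Y = 1), 0, phases = toy_phases)
  expect_equal(
    standard_reaction_energy(formation_energy_table(c(X = -10, Y = -50)), toy),
    -30)
  # null table and identity reaction give zero
  expect_equal(
    standard_reaction_energy(formation_energy_table(c(X = 0, Y = 0)), toy), 0)
  ident <- reaction_spec("ident", c(A = 0), 0, phases = c(A = "aqueous"))
  expect_equal(
    standard_reaction_energy(formation_energy_table(c(A = -123)), ident), 0)
  expect_error(
    standard_reaction_energy(formation_energy_table(c(X = -10)), toy),
    "missing formation energy.*Y")
})

test_that("log10 reaction quotient handles phases and errors", {
  expect_equal(log10_reaction_quotient(reg$ferrihydrite, standard_state()), 0)
  expect_equal(log10_reaction_quotient(reg$ferrihydrite, t1_lo), 81)
  expect_equal(log10_reaction_quotient(reg$methanogenesis, t1_lo), -3)
  # activity validation happens at condition construction
  expect_error(chemical_conditions(7, c("Fe2+" = 0)), "strictly positive")
  expect_error(chemical_conditions(7, c("Fe2+" = -1)), "strictly positive")
  # missing activity for a needed species
  cond <- chemical_conditions(7, c("HCO3-" = 0.01))
  expect_error(log10_reaction_quotient(reg$methanogenesis, cond),
               "no activity supplied")
  # H+ may not be double-specified
  expect_error(chemical_conditions(7, c("H+" = 1e-7)), "use pH")
})

test_that("delta_g reproduces the tabulated in-situ energies", {
  printed <- rbind(
    magnetite      = c(166.63, 155.22),
    ferrihydrite   = c(-48.74, -60.15),
    goethite       = c(91.10, 79.69),
    hematite       = c(114.22, 102.81),
    methanogenesis = c(-31.79, -43.20)
  )
  for (id in rownames(printed)) {
    expect_lt(abs(delta_g(reg[[id]], t1_lo) - printed[[id, 1]]), 0.05,
              label = id)
    expect_lt(abs(delta_g(reg[[id]], t1_hi) - printed[[id, 2]]), 0.05,
              label = id)
  }
  # Q = 1 recovers the standard energy exactly
  for (r in reg) expect_equal(delta_g(r, standard_state()),
                              r$delta_g_standard)
})

test_that("sensitivity: linearity oracle across all species and reactions", {
  # moving any species one decade up changes delta_g by exactly the
  # sensitivity; solids/water/absent species change nothing
  species <- c("Fe2+", "HCO3-", "CH4(aq)", "CH3COO-", "Fe(OH)3", "H2O")
  for (r in reg) {
    for (sp in species) {
      base <- if (sp %in% names(t1_lo$activities))
        t1_lo$activities[[sp]] else 1
      if (sp %in% c("Fe(OH)3", "H2O")) {
        expect_equal(sensitivity(r, sp), 0)
        next
      }
      shifted <- cond_with(t1_lo, sp, 10 * base)
      expect_equal(delta_g(r, shifted) - delta_g(r, t1_lo),
                   sensitivity(r, sp), tolerance = 1e-10,
                   label = paste(r$name, sp))
    }
  }
})

test_that("sensitivity magnitudes match the reported per-decade constants", {
  for (id in c("ferrihydrite", "goethite", "hematite")) {
    expect_equal(round(sensitivity(reg[[id]], "Fe2+"), 1), 45.6)
  }
  for (r in reg) {
    expect_equal(round(sensitivity(r, "CH3COO-", per = "decrease"), 1), 5.7)
  }
  expect_equal(round(sensitivity(reg$methanogenesis, "CH4(aq)"), 1), 5.7)
  expect_equal(sensitivity(reg$methanogenesis, "Fe2+"), 0)
  # 8:1 stoichiometric ratio between iron reduction and methanogenesis
  expect_equal(sensitivity(reg$ferrihydrite, "Fe2+"),
               8 * sensitivity(reg$methanogenesis, "CH4(aq)"))
})

test_that("ladder ordering at standard state and reference conditions", {
  expect_equal(ladder(reg, standard_state())$id,
               c("magnetite", "ferrihydrite", "goethite", "hematite",
                 "methanogenesis"))
  expect_equal(ladder(reg, t1_lo)$id,
               c("ferrihydrite", "methanogenesis", "goethite", "hematite",
                 "magnetite"))
  single <- ladder(reg["goethite"], t1_lo)
  expect_equal(nrow(single), 1L)
  expect_equal(single$id, "goethite")
})

test_that("ladder ties break by registry insertion order", {
  a <- reaction_spec("A", c("CH3COO-" = -1, "H2O" = -1,
                            "CH4(aq)" = 1, "HCO3-" = 1), -14.68)
  lad <- ladder(list(first = a, second = a), t1_lo)
  expect_equal(lad$id, c("first", "second"))
})

test_that("ladder ordering is invariant to acetate activity", {
  # acetate coefficient is -1 everywhere, so changing its activity shifts
  # all reactions equally
  set.seed(42)
  base <- ladder(reg, t1_lo)$id
  for (a in 10^stats::runif(20, -7, -1)) {
    expect_equal(ladder(reg, reference_conditions(a))$id, base,
                 label = sprintf("acetate %.3g", a))
  }
})

test_that("crossover_activity finds the goethite/methanogenesis crossing", {
  x <- crossover_activity(reg$goethite, reg$methanogenesis, "Fe2+",
                          t1_lo, bracket = c(-12, 0))
  # closed form: -370.99 + RTln10*(8x + 105) = dG(methanogenesis)
  rt <- 8.314e-3 * 298 * log(10)
  dg_met <- delta_g(reg$methanogenesis, t1_lo)
  closed <- (dg_met - (-370.99 + rt * 105)) / (8 * rt)
  expect_equal(x, closed, tolerance = 1e-5)
  expect_equal(round(x, 2), -5.69)
  # below the crossover goethite beats methanogenesis
  lo <- cond_with(t1_lo, "Fe2+", 1e-7)
  expect_lt(delta_g(reg$goethite, lo), delta_g(reg$methanogenesis, lo))
  # degenerate pair
  d <- crossover_activity(reg$goethite, reg$goethite, "Fe2+", t1_lo,
                          c(-12, 0))
  expect_true(is.na(d))
  expect_true(isTRUE(attr(d, "degenerate")))
  # no sign change in bracket
  expect_true(is.na(crossover_activity(reg$goethite, reg$methanogenesis,
                                       "Fe2+", t1_lo, c(-2, 0))))
  expect_error(crossover_activity(reg$goethite, reg$methanogenesis, "Fe2+",
                                  t1_lo, c(0, -2)), "invalid bracket")
  expect_error(crossover_activity(reg$goethite, reg$methanogenesis, "Xx",
                                  t1_lo, c(-2, 0)), "neither reaction")
})

test_that("energy_landscape grids obey the monotonicity invariant", {
  acts <- t1_lo$activities
  cond <- chemical_conditions(7, acts[setdiff(names(acts), "Fe2+")])
  axes <- list(list(species = "Fe2+", log10_grid = c(-6, -5, -4, -3)))
  ls <- energy_landscape(reg, axes, cond)
  df <- as.data.frame(ls)
  # ferrihydrite (Fe2+ a product): strictly increasing
  fer <- df$delta_g[df$reaction == "Ferrihydrite reduction"]
  expect_true(all(diff(fer) > 0))
  # methanogenesis has no Fe: constant
  met <- df$delta_g[df$reaction == "Methanogenesis"]
  expect_equal(diff(met), rep(0, 3))
  # 1-point grid equals delta_g at that point
  one <- energy_landscape(reg["goethite"],
                          list(list(species = "Fe2+", log10_grid = -4)),
                          cond)
  expect_equal(as.vector(one$delta_g),
               delta_g(reg$goethite, cond_with(cond, "Fe2+", 1e-4)))
  # axis species clashing with a fixed activity is an error
  expect_error(energy_landscape(reg, axes, t1_lo), "fixed activity")
  # 2-axis grid against direct evaluation
  axes2 <- list(list(species = "Fe2+", log10_grid = c(-5, -3)),
                list(species = "CH4(aq)", log10_grid = c(-6, -4)))
  acts2 <- acts[setdiff(names(acts), c("Fe2+", "CH4(aq)"))]
  cond2 <- chemical_conditions(7, acts2)
  ls2 <- energy_landscape(reg, axes2, cond2)
  direct <- delta_g(reg$hematite,
                    cond_with(cond_with(cond2, "Fe2+", 1e-3),
                              "CH4(aq)", 1e-4))
  expect_equal(ls2$delta_g[4, 2, 2], direct)
})
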