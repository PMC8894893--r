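#' Define a reaction
#'
#' A reaction is a named stoichiometry map (products positive, reactants
#' negative) plus a standard-state Gibbs energy for the reaction as written.
#' All built-in registry entries are normalised per mole of acetate
#' (acetate coefficient exactly -1), which makes in-situ energies directly
#' comparable across metabolisms competing for the same electron donor.
#'
#' @param name reaction label.
#' @param stoichiometry named numeric vector, species -> signed coefficient.
#' @param delta_g_standard standard Gibbs energy of reaction (kJ per mole of
#'   reaction as written).
#' @param phases optional named character vector declaring phases for species
#'   absent from [species_table()].
#' @param check_balance assert element (Fe, C, O, H) and charge balance using
#'   [species_table()] compositions; only possible when every species is known.
#' @return An object of class `reaction_spec`.
#' @export
#' @examples
#' methano <- reaction_spec(
#'   "Methanogenesis",
#'   c("CH3COO-" = -1, "H2O" = -1, "CH4(aq)" = 1, "HCO3-" = 1),
#'   delta_g_standard = -14.68
#' )
reaction_spec <- function(name, stoichiometry, delta_g_standard,
                          phases = NULL, check_balance = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(stoichiometry), length(stoichiometry) >= 1L,
            !is.null(names(stoichiometry)), all(nzchar(names(stoichiometry))),
            is.numeric(delta_g_standard), length(delta_g_standard) == 1L,
            is.finite(delta_g_standard))
  if (anyDuplicated(names(stoichiometry))) {
    stop("duplicated species in stoichiometry for '", name, "'", call. = FALSE)
  }
  rxn <- structure(
    list(name = name,
         stoichiometry = stoichiometry,
         delta_g_standard = delta_g_standard,
         phases = phases),
    class = "reaction_spec"
  )
  if (check_balance) assert_balanced(rxn)
  rxn
}

#' @export
print.reaction_spec <- function(x, ...) {
  s <- x$stoichiometry
  side <- function(coef) {
    paste(sprintf("%s %s", ifelse(abs(coef) == 1, "", format(abs(coef))),
                  names(coef)), collapse = " + ")
  }
  cat(sprintf("<reaction_spec> %s\n  %s -> %s\n  dG0_rxn = %.2f kJ/mol\n",
              x$name, side(s[s < 0]), side(s[s > 0]), x$delta_g_standard))
  invisible(x)
}

#' Assert element and charge balance of a reaction
#'
#' Checks Fe, C, O, H and charge conservation using the compositions in
#' [species_table()]. Errors if any species is unknown or any balance is
#' violated beyond 1e-9.
#'
#' @param rxn a [reaction_spec()].
#' @return `rxn`, invisibly.
#' @export
assert_balanced <- function(rxn) {
  tab <- species_table()
  sp <- names(rxn$stoichiometry)
  missing <- setdiff(sp, tab$species)
  if (length(missing)) {
    stop("cannot balance-check '", rxn$name, "': unknown composition for ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  idx <- match(sp, tab$species)
  for (el in c("Fe", "C", "O", "H", "charge")) {
    net <- sum(rxn$stoichiometry * tab[[el]][idx])
    if (abs(net) > 1e-9) {
      stop(sprintf("reaction '%s' is not balanced in %s (net %+g)",
                   rxn$name, el, net), call. = FALSE)
    }
  }
  invisible(rxn)
}

#' Built-in reaction registry
#'
#' The five acetate-consuming metabolisms of the iron-oxide /
#' methanogenesis competition: reduction of magnetite, ferrihydrite,
#' goethite and hematite, and acetoclastic methanogenesis. All are written
#' per mole of acetate and carry tabulated standard reaction energies
#' (kJ/mol acetate, 298 K, unit activities). Registry order records the
#' ranking at standard state (most to least favorable) and is the stable
#' tie-break order in [ladder()].
#'
#' Lepidocrocite is intentionally not an entry: it is thermodynamically
#' nearly indistinguishable from goethite, and users who need it can
#' register a goethite-like [reaction_spec()].
#'
#' @return Named list of [reaction_spec()] objects, in standard-state
#'   favorability order.
#' @export
#' @examples
#' names(reaction_registry())
reaction_registry <- function() {
  r <- list(
    magnetite = reaction_spec(
      "Magnetite reduction",
      c("Fe3O4" = -4, "CH3COO-" = -1, "H+" = -23,
        "Fe2+" = 12, "HCO3-" = 2, "H2O" = 12),
      delta_g_standard = -546.47),
    ferrihydrite = reaction_spec(
      "Ferrihydrite reduction",
      c("Fe(OH)3" = -8, "CH3COO-" = -1, "H+" = -15,
        "Fe2+" = 8, "HCO3-" = 2, "H2O" = 20),
      delta_g_standard = -510.83),
    goethite = reaction_spec(
      "Goethite reduction",
      c("FeOOH" = -8, "CH3COO-" = -1, "H+" = -15,
        "Fe2+" = 8, "HCO3-" = 2, "H2O" = 12),
      delta_g_standard = -370.99),
    hematite = reaction_spec(
      "Hematite reduction",
      c("Fe2O3" = -4, "CH3COO-" = -1, "H+" = -15,
        "Fe2+" = 8, "HCO3-" = 2, "H2O" = 8),
      delta_g_standard = -347.87),
    methanogenesis = reaction_spec(
      "Methanogenesis",
      c("CH3COO-" = -1, "H2O" = -1,
        "CH4(aq)" = 1, "HCO3-" = 1),
      delta_g_standard = -14.68)
  )
  r
}

#' Build a formation-energy table
#'
#' @param ... or a single named numeric vector: species -> standard Gibbs
#'   energy of formation (kJ/mol).
#' @return Named numeric vector of class `formation_energy_table`.
#' @export
#' @examples
#' tab <- formation_energy_table(c(X = -10, Y = -50))
formation_energy_table <- function(...) {
  vals <- c(...)
  stopifnot(is.numeric(vals), !is.null(names(vals)), all(nzchar(names(vals))))
  if (any(!is.finite(vals))) stop("non-finite formation energy", call. = FALSE)
  structure(vals, class = "formation_energy_table")
}

#' Standard reaction energy from formation energies
#'
#' Computes the standard Gibbs energy of reaction as the signed-coefficient
#' dot product of formation energies: products minus reactants.
#'
#' The built-in registry carries tabulated standard reaction energies
#' directly (the underlying formation-energy compilation is not shipped);
#' this function serves user-supplied tables.
#'
#' @param table a [formation_energy_table()].
#' @param rxn a [reaction_spec()].
#' @return Standard reaction energy, kJ per mole of reaction as written.
#' @export
#' @examples
#' tab <- formation_energy_table(c(X = -10, Y = -50))
#' rxn <- reaction_spec("toy", c(X = -2, Y = 1), delta_g_standard = 0,
#'                      phases = c(X = "aqueous", Y = "aqueous"))
#' standard_reaction_energy(tab, rxn)  # -30
standard_reaction_energy <- function(table, rxn) {
  stopifnot(inherits(rxn, "reaction_spec"))
  sp <- names(rxn$stoichiometry)
  missing <- setdiff(sp, names(table))
  if (length(missing)) {
    stop("missing formation energy for species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sum(rxn$stoichiometry * unclass(table)[sp])
}
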