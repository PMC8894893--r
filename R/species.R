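#' Species reference table
#'
#' Chemical species known to the built-in reaction registry, with elemental
#' composition, formal charge and phase. Phase controls activity handling in
#' reaction quotients: `solid` and `water` species always contribute unit
#' activity; `proton` activity is derived from pH; `aqueous` and
#' `dissolved-gas` species take their activity from the condition's activity
#' map.
#'
#' @return A data.frame with columns `species`, `phase`, `Fe`, `C`, `O`, `H`
#'   (atom counts) and `charge`.
#' @export
#' @examples
#' species_table()
species_table <- function() {
  tab <- rbind(
    #                 species        phase            Fe  C  O  H  charge
    list("CH3COO-",   "aqueous",       0, 2, 2, 3, -1),
    list("HCO3-",     "aqueous",       0, 1, 3, 1, -1),
    list("Fe2+",      "aqueous",       1, 0, 0, 0,  2),
    list("CH4(aq)",   "dissolved-gas", 0, 1, 0, 4,  0),
    list("H+",        "proton",        0, 0, 0, 1,  1),
    list("H2O",       "water",         0, 0, 1, 2,  0),
    list("Fe(OH)3",   "solid",         1, 0, 3, 3,  0),
    list("FeOOH",     "solid",         1, 0, 2, 1,  0),
    list("Fe2O3",     "solid",         2, 0, 3, 0,  0),
    list("Fe3O4",     "solid",         3, 0, 4, 0,  0)
  )
  data.frame(
    species = vapply(tab[, 1], identity, ""),
    phase   = vapply(tab[, 2], identity, ""),
    Fe      = vapply(tab[, 3], as.numeric, 0),
    C       = vapply(tab[, 4], as.numeric, 0),
    O       = vapply(tab[, 5], as.numeric, 0),
    H       = vapply(tab[, 6], as.numeric, 0),
    charge  = vapply(tab[, 7], as.numeric, 0),
    stringsAsFactors = FALSE
  )
}

#' Phases recognised for species
#' @keywords internal
.phases <- c("aqueous", "dissolved-gas", "water", "proton", "solid")

#' Look up the phase of one or more species
#'
#' Species not in [species_table()] must be declared through the `phases`
#' argument of [reaction_spec()]; there is no guessing.
#'
#' @param species character vector of species identifiers.
#' @param extra optional named character vector of additional phases.
#' @return character vector of phases.
#' @export
species_phase <- function(species, extra = NULL) {
  tab <- species_table()
  known <- stats::setNames(tab$phase, tab$species)
  if (!is.null(extra)) {
    stopifnot(all(extra %in% .phases))
    known[names(extra)] <- extra
  }
  out <- known[species]
  if (anyNA(out)) {
    stop("unknown phase for species: ",
         paste(species[is.na(out)], collapse = ", "),
         " (declare via `phases =`)", call. = FALSE)
  }
  unname(out)
}
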