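#' Chemical conditions for in-situ energy calculations
#'
#' Activities follow the concentration-as-activity convention appropriate to
#' dilute artificial freshwater (ionic strength ~0.02): no activity
#' coefficients are applied. Proton activity is derived from pH and must not
#' appear in the activity map (single source of truth). Solids and water take
#' unit activity and need no entries.
#'
#' @param pH dimensionless; proton activity is `10^(-pH)`.
#' @param activities named numeric vector of strictly positive activities for
#'   aqueous and dissolved-gas species.
#' @param temperature_K temperature, default 298 K.
#' @param R_kJ gas constant, kJ mol^-1 K^-1.
#' @return Object of class `chemical_conditions`.
#' @export
#' @examples
#' chemical_conditions(pH = 7,
#'   activities = c("HCO3-" = 0.01, "Fe2+" = 0.001,
#'                  "CH4(aq)" = 1e-5, "CH3COO-" = 1e-4))
chemical_conditions <- function(pH = 7, activities = numeric(),
                                temperature_K = 298, R_kJ = 8.314e-3) {
  stopifnot(is.numeric(pH), length(pH) == 1L, is.finite(pH),
            is.numeric(temperature_K), temperature_K > 0,
            is.numeric(R_kJ), R_kJ > 0)
  if (length(activities)) {
    stopifnot(is.numeric(activities), !is.null(names(activities)))
    if (any(!is.finite(activities)) || any(activities <= 0)) {
      stop("activities must be strictly positive and finite", call. = FALSE)
    }
    if ("H+" %in% names(activities)) {
      stop("do not set 'H+' in activities; use pH", call. = FALSE)
    }
  }
  structure(
    list(pH = pH, activities = activities,
         temperature_K = temperature_K, R_kJ = R_kJ),
    class = "chemical_conditions"
  )
}

#' @export
print.chemical_conditions <- function(x, ...) {
  cat(sprintf("<chemical_conditions> pH %.2f, T %.1f K\n", x$pH,
              x$temperature_K))
  if (length(x$activities)) {
    cat(paste(sprintf("  a(%s) = %g", names(x$activities), x$activities),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Reference incubation conditions
#'
#' pH 7, (HCO3-) = 0.01, (Fe2+) = 0.001, (CH4(aq)) = 1e-5, at a chosen
#' acetate activity, 298 K — the condition set under which the registry's
#' in-situ energies are tabulated.
#'
#' @param acetate acetate activity (1e-4 and 1e-2 are the tabulated levels).
#' @return A [chemical_conditions()] object.
#' @export
reference_conditions <- function(acetate = 1e-4) {
  chemical_conditions(
    pH = 7,
    activities = c("HCO3-" = 0.01, "Fe2+" = 0.001, "CH4(aq)" = 1e-5,
                   "CH3COO-" = acetate)
  )
}

#' RT ln(10) in kJ/mol per log10 unit
#' @keywords internal
rt_ln10 <- function(cond) cond$R_kJ * cond$temperature_K * log(10)

#' log10 reaction quotient
#'
#' Sum of `coefficient * log10(activity)` over aqueous, dissolved-gas and
#' proton species. Solids and water contribute unit activity and are
#' excluded. Protons enter as `-pH` per unit coefficient.
#'
#' @param rxn a [reaction_spec()].
#' @param cond a [chemical_conditions()].
#' @return log10 Q (dimensionless).
#' @export
#' @examples
#' log10_reaction_quotient(reaction_registry()$methanogenesis,
#'                         reference_conditions(1e-4))  # -3
log10_reaction_quotient <- function(rxn, cond) {
  stopifnot(inherits(rxn, "reaction_spec"),
            inherits(cond, "chemical_conditions"))
  sp <- names(rxn$stoichiometry)
  ph <- species_phase(sp, extra = rxn$phases)
  total <- 0
  for (i in seq_along(sp)) {
    coef <- rxn$stoichiometry[[i]]
    total <- total + switch(
      ph[i],
      "solid" = 0,
      "water" = 0,
      "proton" = coef * (-cond$pH),
      { # aqueous / dissolved-gas
        a <- cond$activities[sp[i]]
        if (is.na(a)) {
          stop("no activity supplied for species '", sp[i], "'",
               call. = FALSE)
        }
        if (a <= 0) {
          stop("activity for '", sp[i], "' must be positive", call. = FALSE)
        }
        coef * log10(a)
      }
    )
  }
  unname(total)
}

#' In-situ Gibbs energy of reaction
#'
#' `dG = dG0 + RT ln Q`, evaluated via log10: `dG0 + RT ln(10) log10(Q)`.
#' Negative values are exergonic (thermodynamically favorable).
#'
#' @inheritParams log10_reaction_quotient
#' @return kJ per mole of reaction as written (kJ/mol acetate for the
#'   built-in registry).
#' @export
#' @examples
#' delta_g(reaction_registry()$ferrihydrite, reference_conditions(1e-4))
delta_g <- function(rxn, cond) {
  rxn$delta_g_standard + rt_ln10(cond) * log10_reaction_quotient(rxn, cond)
}

#' Per-decade sensitivity of reaction energy to one species' activity
#'
#' The change in in-situ Gibbs energy per tenfold *increase* in a species'
#' activity is `coefficient * RT ln(10)` — positive for products (less
#' favorable as they accumulate), negative for reactants. With
#' `per = "decrease"` the sign is flipped, which is the natural reading for
#' reactants ("+5.7 kJ/mol per decade decrease in acetate"). Species absent
#' from the reaction, and solids/water (unit activity), give 0.
#'
#' @param rxn a [reaction_spec()].
#' @param species species identifier.
#' @param cond a [chemical_conditions()] supplying T and R (default 298 K).
#' @param per report per decade `"increase"` (default) or `"decrease"` of
#'   the species' activity.
#' @return kJ/mol per decade.
#' @export
#' @examples
#' sensitivity(reaction_registry()$ferrihydrite, "Fe2+")       # +45.6
#' sensitivity(reaction_registry()$ferrihydrite, "CH3COO-",
#'             per = "decrease")                               # +5.7
sensitivity <- function(rxn, species, cond = chemical_conditions(),
                        per = c("increase", "decrease")) {
  stopifnot(inherits(rxn, "reaction_spec"), length(species) == 1L)
  per <- match.arg(per)
  coef <- rxn$stoichiometry[species]
  if (is.na(coef)) return(0)
  ph <- species_phase(species, extra = rxn$phases)
  if (ph %in% c("solid", "water")) return(0)
  s <- unname(coef) * rt_ln10(cond)
  if (per == "decrease") -s else s
}

#' Favorability ladder
#'
#' Orders reactions by in-situ Gibbs energy, most favorable (most negative)
#' first. Energies within `tol` of each other are ties, broken by input
#' (registry insertion) order; the sort is stable.
#'
#' @param rxns list of [reaction_spec()] (a registry or subset).
#' @param cond a [chemical_conditions()].
#' @param tol tie tolerance in kJ/mol.
#' @return data.frame with columns `reaction`, `delta_g0`, `delta_g`, in
#'   ladder order; row order is the ladder.
#' @export
#' @examples
#' ladder(reaction_registry(), reference_conditions(1e-4))
ladder <- function(rxns, cond, tol = 1e-9) {
  stopifnot(length(rxns) >= 1L)
  dg <- vapply(rxns, delta_g, 0, cond = cond)
  # quantize to tol so near-equal energies fall back to input order
  key <- round(dg / tol)
  ord <- order(key, seq_along(key))  # explicit secondary key: stable ties
  out <- data.frame(
    reaction = vapply(rxns, function(r) r$name, ""),
    delta_g0 = vapply(rxns, function(r) r$delta_g_standard, 0),
    delta_g = dg,
    stringsAsFactors = FALSE
  )
  if (!is.null(names(rxns))) out$id <- names(rxns)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Crossover activity between two reactions
#'
#' Finds the log10 activity of `variable` at which two reactions have equal
#' in-situ Gibbs energy, all other activities held fixed. Solved by bisection
#' on `dG_A(x) - dG_B(x)` to 1e-6 log-unit tolerance (the difference is
#' linear in x, so bisection is also an independent check on the closed
#' form). Returns `NA` if the difference does not change sign in the
#' bracket; a degenerate pair (identical energy difference everywhere, e.g.
#' rxnA = rxnB) is flagged with attribute `degenerate = TRUE`.
#'
#' @param rxnA,rxnB [reaction_spec()] objects.
#' @param variable species whose activity is varied.
#' @param cond a [chemical_conditions()]; must fix every other activity. Any
#'   entry for `variable` is ignored during the scan.
#' @param bracket length-2 numeric, log10 activity search interval.
#' @param tol bisection tolerance in log10 units.
#' @return log10 activity of the crossover, or `NA_real_`.
#' @export
#' @examples
#' reg <- reaction_registry()
#' crossover_activity(reg$goethite, reg$methanogenesis, "Fe2+",
#'                    reference_conditions(1e-4), bracket = c(-12, 0))
crossover_activity <- function(rxnA, rxnB, variable, cond,
                               bracket = c(-12, 0), tol = 1e-6) {
  stopifnot(inherits(rxnA, "reaction_spec"), inherits(rxnB, "reaction_spec"))
  if (!is.numeric(bracket) || length(bracket) != 2L ||
      !all(is.finite(bracket)) || bracket[1] >= bracket[2]) {
    stop("invalid bracket: need finite (lo, hi) with lo < hi", call. = FALSE)
  }
  inA <- variable %in% names(rxnA$stoichiometry)
  inB <- variable %in% names(rxnB$stoichiometry)
  if (!inA && !inB) {
    stop("variable '", variable, "' appears in neither reaction",
         call. = FALSE)
  }
  at <- function(x) {
    acts <- cond$activities
    acts[variable] <- 10^x
    c2 <- chemical_conditions(cond$pH, acts, cond$temperature_K, cond$R_kJ)
    delta_g(rxnA, c2) - delta_g(rxnB, c2)
  }
  flo <- at(bracket[1]); fhi <- at(bracket[2])
  if (abs(flo) < 1e-12 && abs(fhi) < 1e-12) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  if (sign(flo) == sign(fhi)) return(NA_real_)
  lo <- bracket[1]; hi <- bracket[2]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- at(mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

#' Gibbs-energy landscape over activity grids
#'
#' Evaluates in-situ reaction energies over a 1- or 2-axis grid of log10
#' activities, the standard way to display how the favorability ladder
#' rearranges across environmental conditions.
#'
#' @param rxns list of [reaction_spec()].
#' @param axes list of 1 or 2 specs, each `list(species =, log10_grid =)`
#'   with a finite numeric grid.
#' @param cond fixed activities for everything not on an axis; an axis
#'   species must not also appear in `cond$activities`.
#' @return Object of class `energy_landscape`: list with `axes`, `reactions`
#'   and `delta_g` (array reactions x grid1 [x grid2]). `as.data.frame()`
#'   gives the long format (reaction, axis columns, delta_g).
#' @export
#' @examples
#' grid <- list(list(species = "Fe2+", log10_grid = -6:-3))
#' cond <- chemical_conditions(7, c("HCO3-" = 0.01, "CH4(aq)" = 1e-5,
#'                                  "CH3COO-" = 1e-4))
#' energy_landscape(reaction_registry(), grid, cond)
energy_landscape <- function(rxns, axes, cond) {
  stopifnot(is.list(axes), length(axes) %in% 1:2)
  for (ax in axes) {
    stopifnot(is.character(ax$species), is.numeric(ax$log10_grid),
              length(ax$log10_grid) >= 1L, all(is.finite(ax$log10_grid)))
    if (ax$species %in% names(cond$activities)) {
      stop("axis species '", ax$species,
           "' also has a fixed activity; remove it from the conditions",
           call. = FALSE)
    }
  }
  if (length(axes) == 2L && axes[[1]]$species == axes[[2]]$species) {
    stop("both axes vary the same species", call. = FALSE)
  }
  rnames <- vapply(rxns, function(r) r$name, "")
  g1 <- axes[[1]]$log10_grid
  g2 <- if (length(axes) == 2L) axes[[2]]$log10_grid else NA_real_
  dims <- c(length(rxns), length(g1), if (length(axes) == 2L) length(g2))
  arr <- array(NA_real_, dim = dims)
  for (i in seq_along(g1)) {
    for (j in seq_len(if (length(axes) == 2L) length(g2) else 1L)) {
      acts <- cond$activities
      acts[axes[[1]]$species] <- 10^g1[i]
      if (length(axes) == 2L) acts[axes[[2]]$species] <- 10^g2[j]
      c2 <- chemical_conditions(cond$pH, acts, cond$temperature_K, cond$R_kJ)
      dg <- vapply(rxns, delta_g, 0, cond = c2)
      if (length(axes) == 2L) arr[, i, j] <- dg else arr[, i] <- dg
    }
  }
  structure(list(axes = axes, reactions = rnames, delta_g = arr),
            class = "energy_landscape")
}

#' @export
as.data.frame.energy_landscape <- function(x, ...) {
  ax <- x$axes
  if (length(ax) == 1L) {
    grid <- expand.grid(reaction = x$reactions,
                        a1 = ax[[1]]$log10_grid,
                        stringsAsFactors = FALSE)
    grid$delta_g <- as.vector(x$delta_g)
    names(grid)[2] <- paste0("log10_", ax[[1]]$species)
  } else {
    grid <- expand.grid(reaction = x$reactions,
                        a1 = ax[[1]]$log10_grid,
                        a2 = ax[[2]]$log10_grid,
                        stringsAsFactors = FALSE)
    grid$delta_g <- as.vector(x$delta_g)
    names(grid)[2:3] <- paste0("log10_", c(ax[[1]]$species, ax[[2]]$species))
  }
  grid
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf("<energy_landscape> %d reactions x %s grid\n",
              length(x$reactions),
              paste(vapply(x$axes, function(a)
                sprintf("%s[%d]", a$species, length(a$log10_grid)), ""),
                collapse = " x ")))
  invisible(x)
}
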