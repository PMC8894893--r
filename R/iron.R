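#' Correct a measured concentration for sample dilution
#'
#' Liquid samples are dispensed 1:1 into acid (1.5 mL sample into 1.5 mL of
#' 2 M HCl, or 4% nitric), a twofold dilution undone here.
#'
#' @param measured_mM assay-side concentration, mM.
#' @param factor dilution factor, >= 1 (default 2).
#' @return In-bottle concentration, mM.
#' @export
dilution_correct <- function(measured_mM, factor = 2) {
  stopifnot(all(factor >= 1))
  measured_mM * factor
}

#' Split ferrozine readings into Fe(II) and Fe(III)
#'
#' Total HCl-extractable Fe is assayed with the reductant hydroxylamine
#' hydrochloride, Fe(II) without it; Fe(III) is the difference. Assay noise
#' can push Fe(II) slightly above total: overshoot within `tol` (default 2%
#' of total, typical colorimetric noise) clamps Fe(III) to zero with a
#' warning; larger overshoot is an inconsistency error.
#'
#' @param fe2_mM,total_mM dilution-corrected concentrations, mM, >= 0.
#' @param tol absolute tolerance in mM; default `0.02 * total_mM`.
#' @return Named numeric `c(FeII, FeIII)` with `FeII + FeIII = total` exactly
#'   (or `= fe2` after a clamp).
#' @export
#' @examples
#' ferrozine_split(6, 10)  # FeII 6, FeIII 4
ferrozine_split <- function(fe2_mM, total_mM, tol = 0.02 * total_mM) {
  stopifnot(fe2_mM >= 0, total_mM >= 0)
  fe3 <- total_mM - fe2_mM
  if (fe3 < 0) {
    if (-fe3 <= tol) {
      warning(sprintf(
        "Fe(II) %.4g mM exceeds total %.4g mM within tolerance; Fe(III) clamped to 0",
        fe2_mM, total_mM))
      fe3 <- 0
    } else {
      stop(sprintf("Fe(II) %.4g mM exceeds total %.4g mM beyond tolerance %.3g mM",
                   fe2_mM, total_mM, tol), call. = FALSE)
    }
  }
  c(FeII = fe2_mM, FeIII = fe3)
}

#' Solid-phase iron speciation with honest interval bounds
#'
#' The HCl extraction dissolves aqueous, sorbed and poorly crystalline solid
#' Fe together, and the aqueous pool's valence split is not measured. The
#' solid-phase Fe(II) therefore cannot be a point estimate: if all aqueous Fe
#' were ferrous, solid Fe(II) = fe2_HCl - aqueous; if all ferric,
#' solid Fe(II) = fe2_HCl (capped by the solid total). The truth lies in
#' between for any valence split, so the interval is reported rather than an
#' assumption.
#'
#' @param fe2_HCl,total_HCl HCl-extractable Fe(II) and total Fe,
#'   dilution-corrected, mM.
#' @param aqueous aqueous (filtered/acidified) Fe, mM; must not exceed
#'   `total_HCl` (+ `tol`).
#' @param tol consistency tolerance, mM (default 2% of total).
#' @return List of class `fe_speciation` with fields `fe2_HCl`, `fe3_HCl`,
#'   `aqueous`, `solid_total`, `solid_fe2` (length-2 interval, mM) and
#'   `solid_fe2_frac` (interval within \[0, 1\], `NA` when there is no solid
#'   phase).
#' @export
#' @examples
#' solid_phase_bounds(6, 10, 2)  # solid total 8, Fe(II) in [4, 6]
solid_phase_bounds <- function(fe2_HCl, total_HCl, aqueous,
                               tol = 0.02 * total_HCl) {
  stopifnot(fe2_HCl >= 0, total_HCl >= 0, aqueous >= 0)
  if (aqueous > total_HCl + tol) {
    stop(sprintf("aqueous Fe %.4g mM exceeds HCl-extractable total %.4g mM",
                 aqueous, total_HCl), call. = FALSE)
  }
  aqueous <- min(aqueous, total_HCl)
  split <- ferrozine_split(fe2_HCl, total_HCl, tol)
  solid_total <- total_HCl - aqueous
  lo <- max(0, fe2_HCl - aqueous)
  hi <- min(fe2_HCl, solid_total)
  frac <- if (solid_total > 0) c(lo, hi) / solid_total else c(NA_real_, NA_real_)
  structure(list(
    fe2_HCl = fe2_HCl,
    fe3_HCl = unname(split["FeIII"]),
    aqueous = aqueous,
    solid_total = solid_total,
    solid_fe2 = c(lo = lo, hi = hi),
    solid_fe2_frac = c(lo = frac[1], hi = frac[2])
  ), class = "fe_speciation")
}

#' @export
print.fe_speciation <- function(x, ...) {
  cat(sprintf(
    "<fe_speciation> HCl Fe(II) %.3g, Fe(III) %.3g, aqueous %.3g mM\n",
    x$fe2_HCl, x$fe3_HCl, x$aqueous))
  cat(sprintf("  solid total %.3g mM; solid Fe(II) in [%.3g, %.3g] mM (frac [%.3g, %.3g])\n",
              x$solid_total, x$solid_fe2[1], x$solid_fe2[2],
              x$solid_fe2_frac[1], x$solid_fe2_frac[2]))
  invisible(x)
}

#' Acetate electron budget between iron reduction and methanogenesis
#'
#' Reaction stoichiometry ties both sinks to the shared donor: oxidising one
#' mole of acetate reduces eight moles of Fe(III), while one mole of methane
#' consumes one mole of acetate. Given observed increments of Fe(II) and CH4
#' the acetate routed to each pathway is therefore `dFe/8` and `dCH4`, and
#' their ratio summarises which metabolism dominated donor consumption.
#'
#' @param delta_FeII_mol increase in Fe(II), mol (>= 0).
#' @param delta_CH4_mol methane produced, mol (>= 0).
#' @return list with `acetate_to_Fe`, `acetate_to_CH4` (mol) and `ratio`
#'   (`acetate_to_Fe / acetate_to_CH4`; `NA` when no methane was produced).
#' @export
#' @examples
#' acetate_budget(2e-3, 2e-3)  # ratio 1/8
acetate_budget <- function(delta_FeII_mol, delta_CH4_mol) {
  stopifnot(delta_FeII_mol >= 0, delta_CH4_mol >= 0)
  a_fe <- delta_FeII_mol / 8
  a_ch4 <- delta_CH4_mol
  ratio <- if (a_ch4 > 0) a_fe / a_ch4 else NA_real_
  list(acetate_to_Fe = a_fe, acetate_to_CH4 = a_ch4, ratio = ratio)
}
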