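#' Process RGA scans into a cumulative-methane time series
#'
#' The full headspace pipeline for one or more bottles: stable-tail
#' averaging of each scan, calibration of the CH4:N2 and CO2:N2 signal
#' ratios, headspace fractions, withdrawal-aware headspace volumes, ideal
#' gas conversion and the prior-removal correction for cumulative
#' production.
#'
#' @param scans long-format data.frame (`bottle`, `day`, `elapsed_s`, `mz`,
#'   `signal`).
#' @param events data.frame (`bottle`, `day`, `liquid_mL`, `gas_mL`).
#' @param calibration list with `CH4` and `CO2` [calibration_curve()]s.
#' @param n_last readouts averaged per scan.
#' @param initial_mL initial headspace volume.
#' @param T_K,P_atm gas-law conditions.
#' @param include_current_removal see [cumulative_methane()].
#' @return data.frame per bottle/day: `bottle`, `day`, `V_mL`, `F_CH4`,
#'   `F_CO2`, `F_N2`, `gas_removed_mL`, `n_present`, `n_removed_cum`,
#'   `n_produced`.
#' @export
#' @examples
#' tr <- simulate_incubation(condition_preset("control"))
#' scans <- forward_rga(tr)
#' ev <- cbind(bottle = tr$bottle, tr$schedule)
#' names(ev)[names(ev) == "gas_mL"] <- "gas_mL"
#' res <- process_gas(scans, ev)
process_gas <- function(scans, events, calibration = default_calibration(),
                        n_last = 5L, initial_mL = 300, T_K = 298,
                        P_atm = 1, include_current_removal = FALSE) {
  stopifnot(all(c("bottle", "day", "elapsed_s", "mz", "signal") %in%
                  names(scans)),
            all(c("bottle", "day", "liquid_mL", "gas_mL") %in%
                  names(events)))
  mz_ch4 <- calibration$CH4$mz
  mz_co2 <- calibration$CO2$mz
  out <- lapply(split(scans, scans$bottle), function(sb) {
    bot <- sb$bottle[1]
    ev <- events[events$bottle == bot, , drop = FALSE]
    ev <- ev[order(ev$day), , drop = FALSE]
    days <- sort(unique(sb$day))
    rows <- lapply(days, function(d) {
      sig <- stable_average(sb[sb$day == d, , drop = FALSE], n_last,
                            id = sprintf("%s day %g", bot, d))
      for (mz in c(mz_ch4, mz_co2, 28)) {
        if (!as.character(mz) %in% names(sig)) {
          stop(sprintf("%s day %g: no m/z %s channel", bot, d, mz),
               call. = FALSE)
        }
      }
      r_ch4 <- calibrated_ratio(sig[[as.character(mz_ch4)]], sig[["28"]],
                                calibration$CH4)
      r_co2 <- calibrated_ratio(sig[[as.character(mz_co2)]], sig[["28"]],
                                calibration$CO2)
      f <- headspace_fractions(r_ch4, r_co2)
      gas_mL <- ev$gas_mL[abs(ev$day - d) < 1e-9]
      data.frame(bottle = bot, day = d,
                 V_mL = headspace_volume(ev, d, initial_mL),
                 F_CH4 = f[["F_CH4"]], F_CO2 = f[["F_CO2"]],
                 F_N2 = f[["F_N2"]],
                 gas_removed_mL = if (length(gas_mL)) gas_mL[1] else 0)
    })
    cumulative_methane(do.call(rbind, rows), T_K, P_atm,
                       include_current = include_current_removal)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Process iron assay readings into speciation with interval bounds
#'
#' Dilution-corrects the HCl-extract readings, splits Fe(II)/Fe(III), and
#' bounds the solid-phase Fe(II) given that the aqueous pool's valence is
#' unknown.
#'
#' @param samples data.frame (`bottle`, `day`, `fe2_raw_mM`, `fetot_raw_mM`,
#'   `aqueous_mM`, `dilution`). `aqueous_mM` is already in-bottle scale.
#' @param tol_frac clamping tolerance as a fraction of total (default 0.02).
#' @return data.frame with dilution-corrected pools, the solid-phase Fe(II)
#'   interval and its fraction interval.
#' @export
process_fe <- function(samples, tol_frac = 0.02) {
  stopifnot(all(c("bottle", "day", "fe2_raw_mM", "fetot_raw_mM",
                  "aqueous_mM", "dilution") %in% names(samples)))
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    s <- samples[i, ]
    fe2 <- dilution_correct(s$fe2_raw_mM, s$dilution)
    tot <- dilution_correct(s$fetot_raw_mM, s$dilution)
    sp <- solid_phase_bounds(fe2, tot, s$aqueous_mM, tol = tol_frac * tot)
    data.frame(bottle = s$bottle, day = s$day,
               fe2_hcl_mM = sp$fe2_HCl, fe3_hcl_mM = sp$fe3_HCl,
               fetot_hcl_mM = tot, aqueous_mM = sp$aqueous,
               solid_fetot_mM = sp$solid_total,
               solid_fe2_lo_mM = sp$solid_fe2[["lo"]],
               solid_fe2_hi_mM = sp$solid_fe2[["hi"]],
               solid_fe2_frac_lo = sp$solid_fe2_frac[["lo"]],
               solid_fe2_frac_hi = sp$solid_fe2_frac[["hi"]])
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
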