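#' Incubation generator parameters
#'
#' A stated world for a sealed 500 mL bottle incubation (200 mL liquid /
#' 300 mL initial headspace, ~30 days): cumulative methane follows a
#' logistic curve; HCl-extractable Fe(II) follows a saturating exponential;
#' acetate starts at 10 mM, receives a fermentation pulse to ~15 mM by day
#' 3, and is then drawn down by the stoichiometric ledger
#' (1 mol acetate per mol CH4, 1/8 mol per mol Fe(II)).
#'
#' The stoichiometric ledger is intensive (mM on the nominal 200 mL liquid
#' basis): withdrawn liquid has the same composition as what remains, so
#' concentrations are unaffected by sampling; conversions to moles use the
#' nominal volume. Gas bookkeeping (headspace growth, instrument draws) is,
#' in contrast, fully volume-aware.
#'
#' @param condition one of `"ferrihydrite"`, `"hematite"`, `"goethite"`,
#'   `"control"` (label only; defaults come from [condition_preset()]).
#' @param ch4_plateau_mol logistic plateau of cumulative CH4, mol.
#' @param ch4_rate_per_day logistic steepness r, /day (max rate =
#'   plateau * r / 4).
#' @param ch4_midpoint_day logistic midpoint, day.
#' @param fe2_plateau_mM,fe2_k_per_day saturating Fe(II) curve
#'   `plateau * (1 - exp(-k t))`.
#' @param fetot_hcl_mM total HCl-extractable Fe (held constant).
#' @param acetate_initial_mM,acetate_pulse_mM,acetate_pulse_k acetate model.
#' @param co2_per_ch4 headspace CO2 produced per CH4 (mol/mol).
#' @param aqueous_frac aqueous share of HCl-extractable Fe(II) (default 1/3:
#'   HCl-extractable Fe(II) about three times total dissolved Fe, i.e. a
#'   1:2 aqueous:sorbed partition).
#' @param aqueous_fe2_frac ferrous fraction of the aqueous pool (the latent
#'   valence split the assays cannot see; default 1).
#' @param liquid_mL,headspace_mL bottle geometry.
#' @param noise list of per-channel noise scales: `rga_rel` (relative signal
#'   noise), `fe_mM`, `acetate_mM` (additive assay-side sd).
#' @return Object of class `incubation_params`.
#' @export
incubation_params <- function(condition = "ferrihydrite",
                              ch4_plateau_mol = 2e-3,
                              ch4_rate_per_day = 0.5,
                              ch4_midpoint_day = 17.5,
                              fe2_plateau_mM = 6,
                              fe2_k_per_day = 0.4,
                              fetot_hcl_mM = 10,
                              acetate_initial_mM = 10,
                              acetate_pulse_mM = 5,
                              acetate_pulse_k = 1.5,
                              co2_per_ch4 = 0.5,
                              aqueous_frac = 1 / 3,
                              aqueous_fe2_frac = 1,
                              liquid_mL = 200,
                              headspace_mL = 300,
                              noise = list(rga_rel = 0.01, fe_mM = 0.1,
                                           acetate_mM = 0.3)) {
  stopifnot(ch4_plateau_mol >= 0, ch4_rate_per_day >= 0,
            fe2_plateau_mM >= 0, fe2_k_per_day >= 0,
            fetot_hcl_mM >= fe2_plateau_mM * 1,
            acetate_initial_mM >= 0, acetate_pulse_mM >= 0,
            co2_per_ch4 >= 0,
            aqueous_frac >= 0, aqueous_frac <= 1,
            aqueous_fe2_frac >= 0, aqueous_fe2_frac <= 1,
            liquid_mL > 0, headspace_mL > 0)
  structure(as.list(environment()), class = "incubation_params")
}

#' Condition presets for the generator
#'
#' Defaults emulate the observed contrasts: ~2 mmol total methane with a
#' 0.25 mmol/day peak rate in every condition; a later logistic midpoint
#' (day 17.5 vs 14.5) for ferrihydrite, whose iron reduction delays the
#' onset of peak methanogenesis; an Fe(II) plateau of ~6 mM reached by ~day
#' 10 with ferrihydrite against <1 mM for crystalline oxides and the
#' Fe-free control.
#'
#' @param condition `"ferrihydrite"`, `"hematite"`, `"goethite"` or
#'   `"control"`.
#' @param ... overrides passed to [incubation_params()].
#' @return An [incubation_params()] object.
#' @export
#' @examples
#' condition_preset("control")
condition_preset <- function(condition = c("ferrihydrite", "hematite",
                                           "goethite", "control"), ...) {
  condition <- match.arg(condition)
  base <- switch(condition,
    ferrihydrite = list(ch4_midpoint_day = 17.5, fe2_plateau_mM = 6,
                        fe2_k_per_day = 0.4, fetot_hcl_mM = 10),
    goethite     = list(ch4_midpoint_day = 14.5, fe2_plateau_mM = 0.8,
                        fe2_k_per_day = 0.3, fetot_hcl_mM = 1.5),
    hematite     = list(ch4_midpoint_day = 14.5, fe2_plateau_mM = 0.6,
                        fe2_k_per_day = 0.3, fetot_hcl_mM = 1.5),
    control      = list(ch4_midpoint_day = 14.5, fe2_plateau_mM = 0.3,
                        fe2_k_per_day = 0.3, fetot_hcl_mM = 0.5)
  )
  args <- utils::modifyList(c(list(condition = condition), base), list(...))
  do.call(incubation_params, args)
}

#' Default sampling schedule
#'
#' Roughly twice-weekly early, daily through the expected peak-rate window
#' (days 13-20), then tapering to day 30; each event withdraws 6 mL of
#' liquid and the RGA consumes a nominal 7 mL of headspace.
#'
#' @param days measurement days.
#' @param liquid_mL,gas_mL per-event withdrawals.
#' @return data.frame with columns `day`, `liquid_mL`, `gas_mL`.
#' @export
sampling_schedule <- function(days = c(0, 3, 6, 9, 11, 13, 15, 16, 17, 18,
                                       19, 20, 22, 25, 28, 30),
                              liquid_mL = 6, gas_mL = 7) {
  stopifnot(!is.unsorted(days), all(liquid_mL >= 0), all(gas_mL >= 0))
  data.frame(day = days, liquid_mL = liquid_mL, gas_mL = gas_mL)
}

#' Logistic cumulative production, zeroed at t = 0
#' @keywords internal
.logistic_prod <- function(t, K, r, m) {
  K / (1 + exp(-r * (t - m))) - K / (1 + exp(r * m))
}

#' Simulate a noise-free incubation (latent truth)
#'
#' Forward-models the latent state of one bottle at each scheduled sampling:
#' cumulative methane, an explicit headspace mole inventory (CH4/CO2/N2 at 1
#' atm, with instrument draws removed at the prevailing composition and
#' liquid withdrawals expanding the headspace for subsequent timepoints),
#' iron speciation with a known aqueous valence split, and the acetate
#' ledger. Deterministic: the same params and schedule always give the same
#' truth; noise enters only in [forward_rga()] / [forward_wetchem()].
#'
#' @param params an [incubation_params()].
#' @param schedule a [sampling_schedule()]-style data.frame.
#' @param bottle bottle identifier.
#' @param T_K,P_atm headspace gas-law conditions.
#' @return Object of class `synthetic_truth`: list with `params`, `schedule`,
#'   `bottle` and `state`, a per-event data.frame holding day, headspace
#'   volume and fractions, the mole inventory, cumulative production and
#'   removals, wet-chemistry concentrations and the acetate ledger.
#' @export
#' @examples
#' tr <- simulate_incubation(condition_preset("ferrihydrite"),
#'                           sampling_schedule())
#' tail(tr$state$ch4_cum_mol, 1)  # ~2e-3 mol
simulate_incubation <- function(params, schedule = sampling_schedule(),
                                bottle = params$condition,
                                T_K = 298, P_atm = 1) {
  stopifnot(inherits(params, "incubation_params"),
            all(c("day", "liquid_mL", "gas_mL") %in% names(schedule)))
  if (is.unsorted(schedule$day)) {
    stop("schedule not time-ordered", call. = FALSE)
  }
  p <- params
  prod_ch4 <- function(t) .logistic_prod(t, p$ch4_plateau_mol,
                                         p$ch4_rate_per_day,
                                         p$ch4_midpoint_day)
  fe2_mM <- function(t) p$fe2_plateau_mM * (1 - exp(-p$fe2_k_per_day * t))
  pulse <- function(t) p$acetate_pulse_mM * (1 - exp(-p$acetate_pulse_k * t))

  n_ev <- nrow(schedule)
  ch4_hs <- 0; co2_hs <- 0
  removed_ch4 <- 0; removed_co2 <- 0
  V <- p$headspace_mL
  prev_prod <- 0
  rows <- vector("list", n_ev)
  for (k in seq_len(n_ev)) {
    t_k <- schedule$day[k]
    prod_k <- prod_ch4(t_k)
    ch4_hs <- ch4_hs + (prod_k - prev_prod)
    co2_hs <- co2_hs + p$co2_per_ch4 * (prod_k - prev_prod)
    prev_prod <- prod_k

    n_tot <- moles_in_headspace(1, V, T_K, P_atm)
    n_n2 <- n_tot - ch4_hs - co2_hs
    if (n_n2 < 0) {
      stop("headspace over-filled: CH4+CO2 exceed 1 atm inventory",
           call. = FALSE)
    }
    f_ch4 <- ch4_hs / n_tot; f_co2 <- co2_hs / n_tot; f_n2 <- n_n2 / n_tot

    fe2_k <- fe2_mM(t_k)
    fe2_mol <- fe2_k / 1000 * (p$liquid_mL / 1000)
    consumed_mM <- (prod_k + fe2_mol / 8) * 1000 / (p$liquid_mL / 1000)
    acet <- p$acetate_initial_mM + pulse(t_k) - consumed_mM
    if (acet < -1e-12) {
      stop(sprintf("infeasible params: acetate over-consumed at day %.3g (%.3g mM)",
                   t_k, acet), call. = FALSE)
    }
    aq <- p$aqueous_frac * fe2_k

    # instrument draw at measured composition (replaced by glovebag N2)
    gas_mL <- schedule$gas_mL[k]
    r_ch4 <- if (gas_mL > 0) moles_in_headspace(f_ch4, gas_mL, T_K, P_atm) else 0
    r_co2 <- if (gas_mL > 0) moles_in_headspace(f_co2, gas_mL, T_K, P_atm) else 0
    removed_ch4 <- removed_ch4 + r_ch4
    removed_co2 <- removed_co2 + r_co2

    rows[[k]] <- data.frame(
      day = t_k, V_mL = V,
      F_CH4 = f_ch4, F_CO2 = f_co2, F_N2 = f_n2,
      n_ch4_headspace = ch4_hs, n_co2_headspace = co2_hs, n_n2 = n_n2,
      ch4_cum_mol = prod_k,
      n_ch4_removed_cum = removed_ch4,
      gas_removed_mL = gas_mL, liquid_mL = schedule$liquid_mL[k],
      fe2_hcl_mM = fe2_k, fetot_hcl_mM = p$fetot_hcl_mM,
      aqueous_fe_mM = aq, aqueous_fe2_frac = p$aqueous_fe2_frac,
      acetate_mM = acet
    )
    ch4_hs <- ch4_hs - r_ch4
    co2_hs <- co2_hs - r_co2
    V <- V + schedule$liquid_mL[k]  # takes effect for later timepoints
  }
  structure(list(params = p, schedule = schedule, bottle = bottle,
                 state = do.call(rbind, rows), T_K = T_K, P_atm = P_atm),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> '%s' (%s), %d timepoints over days %g-%g\n",
              x$bottle, x$params$condition, nrow(x$state),
              min(x$state$day), max(x$state$day)))
  cat(sprintf("  cumulative CH4 %.3g mol; Fe(II) plateau %.3g mM\n",
              max(x$state$ch4_cum_mol), x$params$fe2_plateau_mM))
  invisible(x)
}

#' Default RGA calibration pair used by the generator
#'
#' @return list of two [calibration_curve()]s, `CH4` and `CO2`.
#' @export
default_calibration <- function() {
  list(CH4 = calibration_curve("CH4", slope = 1.25, intercept = 0),
       CO2 = calibration_curve("CO2", slope = 0.80, intercept = 0))
}

#' Forward-model RGA scans from a synthetic truth
#'
#' Inverts the measurement pipeline: per event, the true headspace ratios
#' CH4:N2 and CO2:N2 are pushed back through the calibration to raw-signal
#' ratios and emitted as an 11-readout scan (180 s at 18 s cadence). The
#' first readouts carry a deterministic warm-up drift that decays to zero
#' before the final five, so the stable-tail average recovers the target
#' exactly at zero noise. Relative Gaussian noise of sd `noise_sd` is then
#' applied per readout and channel. QC channels (m/z 2, 16, 18, 32) are
#' carried at plausible minor levels.
#'
#' @param truth a [simulate_incubation()] result.
#' @param calibration list with `CH4` and `CO2` [calibration_curve()]s.
#' @param noise_sd relative signal noise (0 = noise-free).
#' @param seed integer seed (noise reproducibility).
#' @param n2_signal arbitrary instrument signal level for the N2 channel.
#' @return data.frame in the scans CSV dialect: `bottle`, `day`,
#'   `elapsed_s`, `mz`, `signal`.
#' @export
forward_rga <- function(truth, calibration = default_calibration(),
                        noise_sd = 0, seed = NULL, n2_signal = 100) {
  stopifnot(inherits(truth, "synthetic_truth"), noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  st <- truth$state
  elapsed <- seq(0, 180, by = 18)  # 11 readouts
  n_read <- length(elapsed)
  # warm-up drift, zero from readout 6 on (last 5 exact at zero noise)
  drift <- c(0.5 * exp(-1.2 * (1:5)), rep(0, n_read - 5))
  inv <- function(r_true, curve) {
    m <- (r_true - curve$intercept) / curve$slope
    if (any(m < 0)) {
      stop("calibration not invertible at these fractions", call. = FALSE)
    }
    m
  }
  out <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    m_ch4 <- inv(st$F_CH4[i] / st$F_N2[i], calibration$CH4)
    m_co2 <- inv(st$F_CO2[i] / st$F_N2[i], calibration$CO2)
    targets <- c(`2` = 0.02, `15` = m_ch4, `16` = 1.05 * m_ch4,
                 `18` = 0.03, `28` = 1, `32` = 0.001,
                 `44` = m_co2) * n2_signal
    sig <- outer(targets, 1 + drift)          # channels x readouts
    if (noise_sd > 0) {
      sig <- sig * (1 + matrix(stats::rnorm(length(sig), 0, noise_sd),
                               nrow(sig)))
      sig <- pmax(sig, 0)
    }
    out[[i]] <- data.frame(
      bottle = truth$bottle, day = st$day[i],
      elapsed_s = rep(elapsed, each = length(targets)),
      mz = rep(as.numeric(names(targets)), times = n_read),
      signal = as.vector(sig)
    )
  }
  do.call(rbind, out)
}

#' Forward-model wet-chemistry readings from a synthetic truth
#'
#' Applies the 1:1 acid dilution in reverse (assay-side concentrations are
#' half the in-bottle truth) and adds additive Gaussian assay noise; at zero
#' noise the speciation pipeline recovers the truth exactly.
#'
#' @param truth a [simulate_incubation()] result.
#' @param fe_sd,acetate_sd assay-side additive noise, mM.
#' @param seed integer seed.
#' @param dilution dilution factor written into the Fe table.
#' @return list of data.frames: `fe` (bottle, day, fe2_raw_mM, fetot_raw_mM,
#'   aqueous_mM, dilution) and `acetate` (bottle, day, acetate_mM).
#' @export
forward_wetchem <- function(truth, fe_sd = 0, acetate_sd = 0, seed = NULL,
                            dilution = 2) {
  stopifnot(inherits(truth, "synthetic_truth"), fe_sd >= 0, acetate_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  st <- truth$state
  n <- nrow(st)
  noisy <- function(x, sd) {
    if (sd > 0) pmax(x + stats::rnorm(n, 0, sd), 0) else x
  }
  fe <- data.frame(
    bottle = truth$bottle, day = st$day,
    fe2_raw_mM = noisy(st$fe2_hcl_mM / dilution, fe_sd),
    fetot_raw_mM = noisy(st$fetot_hcl_mM / dilution, fe_sd),
    aqueous_mM = noisy(st$aqueous_fe_mM, fe_sd),
    dilution = dilution
  )
  acetate <- data.frame(
    bottle = truth$bottle, day = st$day,
    acetate_mM = noisy(st$acetate_mM, acetate_sd)
  )
  list(fe = fe, acetate = acetate)
}
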