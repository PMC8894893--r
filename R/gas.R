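#' @name gas-constants
#' @title Gas-law constants
#' @description The headspace pipeline works in L, atm, K and mol with
#'   `R = 0.082057 L atm mol^-1 K^-1`; every conversion in the package goes
#'   through [moles_in_headspace()] so the route is bit-consistent.
#' @keywords internal
NULL

R_GAS_L_ATM <- 0.082057  # L atm mol^-1 K^-1

#' Average the stable tail of an RGA scan
#'
#' A residual gas analyzer reads each m/z channel every 15-20 s over a ~3 min
#' sampling; signals stabilise after the first minute, so the composition of a
#' sample is taken as the per-channel arithmetic mean of the final `n_last`
#' readouts.
#'
#' @param scan data.frame in long format with columns `elapsed_s`, `mz`,
#'   `signal` (one scan: single bottle/day). Readouts must be time-ordered
#'   within channel.
#' @param n_last number of final readouts to average (default 5).
#' @param id label used in error messages.
#' @return Named numeric vector: `mz` value -> mean signal.
#' @export
stable_average <- function(scan, n_last = 5L, id = "scan") {
  stopifnot(is.data.frame(scan),
            all(c("elapsed_s", "mz", "signal") %in% names(scan)),
            n_last >= 1L)
  if (any(scan$signal < 0)) {
    stop("negative signal in ", id, call. = FALSE)
  }
  channels <- split(scan, scan$mz)
  out <- vapply(channels, function(ch) {
    if (is.unsorted(ch$elapsed_s)) {
      stop("readouts not time-ordered in ", id, call. = FALSE)
    }
    n <- nrow(ch)
    if (n < n_last) {
      stop(sprintf("%s: %d readouts at m/z %s, need >= %d",
                   id, n, ch$mz[1], n_last), call. = FALSE)
    }
    mean(ch$signal[(n - n_last + 1L):n])
  }, 0)
  out
}

#' Calibration curve for an RGA signal ratio
#'
#' Linear map from a measured analyte:N2 signal ratio to the true molar
#' ratio, replacing manufacturer sensitivity factors. Quantitation channels
#' are m/z 15 for CH4 (unambiguous, unlike 16) and 44 for CO2.
#'
#' @param analyte `"CH4"` or `"CO2"`.
#' @param slope,intercept linear coefficients; `slope` must be positive.
#' @param mz quantitation channel; defaults to 15 (CH4) / 44 (CO2).
#' @return Object of class `calibration_curve`.
#' @export
calibration_curve <- function(analyte = c("CH4", "CO2"), slope = 1,
                              intercept = 0, mz = NULL) {
  analyte <- match.arg(analyte)
  stopifnot(is.numeric(slope), slope > 0, is.numeric(intercept))
  if (is.null(mz)) mz <- if (analyte == "CH4") 15 else 44
  structure(list(analyte = analyte, mz = mz, slope = slope,
                 intercept = intercept),
            class = "calibration_curve")
}

#' Apply a calibration curve to a signal ratio
#'
#' `R = slope * (signal_analyte / signal_N2) + intercept`. A negative result
#' (possible near the detection limit with a negative intercept) is clamped
#' to 0 with a warning.
#'
#' @param signal_analyte,signal_N2 raw signals; `signal_N2` must be > 0.
#' @param curve a [calibration_curve()].
#' @return True molar ratio analyte:N2 (dimensionless, >= 0).
#' @export
calibrated_ratio <- function(signal_analyte, signal_N2, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(signal_N2 <= 0)) stop("N2 signal must be positive", call. = FALSE)
  r <- curve$slope * (signal_analyte / signal_N2) + curve$intercept
  if (any(r < 0)) {
    warning(sprintf("calibrated %s ratio below 0 (min %.3g); clamped",
                    curve$analyte, min(r)))
    r <- pmax(r, 0)
  }
  r
}

#' Headspace fractions from calibrated ratios
#'
#' With CH4, CO2 and N2 making up (essentially all of) the headspace,
#' `F_CH4 = R_CH4 / (R_CH4 + R_CO2 + 1)`, `F_CO2 = R_CO2 / (...)` and
#' `F_N2 = 1 / (...)`; the three sum to one by construction.
#'
#' Note: the second fraction equation is printed elsewhere with a CH4
#' numerator; the CO2 numerator used here is the only reading consistent
#' with F_CO2 being the fraction of CO2.
#'
#' @param R_CH4,R_CO2 calibrated molar ratios to N2, >= 0.
#' @return Named numeric vector `c(F_CH4, F_CO2, F_N2)` (vectorised inputs
#'   give a 3-column matrix).
#' @export
#' @examples
#' headspace_fractions(2, 1)  # 0.50 0.25 0.25
headspace_fractions <- function(R_CH4, R_CO2) {
  if (any(R_CH4 < 0) || any(R_CO2 < 0)) {
    stop("ratios must be non-negative", call. = FALSE)
  }
  denom <- R_CH4 + R_CO2 + 1
  out <- cbind(F_CH4 = R_CH4 / denom, F_CO2 = R_CO2 / denom,
               F_N2 = 1 / denom)
  if (nrow(out) == 1L) out[1, ] else out
}

#' Headspace volume accounting for liquid withdrawals
#'
#' Each liquid sampling expands the sealed bottle's headspace by the volume
#' withdrawn. The headspace in effect at time `t` is the initial volume plus
#' all liquid withdrawn at strictly earlier timepoints (the withdrawal made
#' at `t` itself takes effect for subsequent measurements; set
#' `include_current = TRUE` for the other convention).
#'
#' @param events data.frame with columns `day`, `liquid_mL` (time-ordered).
#' @param t day of measurement.
#' @param initial_mL initial headspace, default 300.
#' @param include_current count a withdrawal made exactly at `t`.
#' @return Headspace volume in mL.
#' @export
#' @examples
#' ev <- data.frame(day = c(0, 2, 4), liquid_mL = 6)
#' headspace_volume(ev, t = 5)  # 318
headspace_volume <- function(events, t, initial_mL = 300,
                             include_current = FALSE) {
  if (is.null(events) || !nrow(events)) return(initial_mL)
  stopifnot(all(c("day", "liquid_mL") %in% names(events)),
            all(events$liquid_mL >= 0))
  if (is.unsorted(events$day)) stop("events not time-ordered", call. = FALSE)
  keep <- if (include_current) events$day <= t else events$day < t
  initial_mL + sum(events$liquid_mL[keep])
}

#' Moles of a gas in the headspace (ideal gas law)
#'
#' `n = F * P * V / (R T)` with V in litres and
#' `R = 0.082057 L atm mol^-1 K^-1`. Total pressure is assumed 1 atm unless
#' stated (an assumption that slightly underestimates moles once CH4/CO2
#' production builds pressure).
#'
#' @param F_gas mole fraction in \[0, 1\].
#' @param V_mL headspace volume, mL (> 0).
#' @param T_K temperature, K.
#' @param P_atm total pressure, atm.
#' @return mol.
#' @export
#' @examples
#' moles_in_headspace(0.1, 300)  # 1.227e-3
moles_in_headspace <- function(F_gas, V_mL, T_K = 298, P_atm = 1) {
  if (any(F_gas < 0 | F_gas > 1)) {
    stop("fraction must be within [0, 1]", call. = FALSE)
  }
  if (any(V_mL <= 0) || T_K <= 0 || P_atm <= 0) {
    stop("V, T and P must be positive", call. = FALSE)
  }
  F_gas * P_atm * (V_mL / 1000) / (R_GAS_L_ATM * T_K)
}

#' Gas volume consumed by an RGA sampling
#'
#' The instrument draws headspace continuously; the draw rate was estimated
#' at 1 mL per 26 s, so a 3 min sampling consumes ~6.9 mL (nominally
#' reported as 7 mL).
#'
#' @param duration_s sampling duration, seconds (>= 0).
#' @param rate_mL_per_s draw rate, default `1/26`.
#' @param nominal if TRUE, round the result to the nearest mL (the nominal
#'   bookkeeping figure).
#' @return mL.
#' @export
#' @examples
#' rga_gas_consumed(180)                  # 6.923
#' rga_gas_consumed(180, nominal = TRUE)  # 7
rga_gas_consumed <- function(duration_s, rate_mL_per_s = 1 / 26,
                             nominal = FALSE) {
  stopifnot(all(duration_s >= 0), rate_mL_per_s >= 0)
  v <- duration_s * rate_mL_per_s
  if (nominal) round(v) else v
}

#' Withdrawal-corrected cumulative methane production
#'
#' Each RGA measurement removes several mL of headspace, and each liquid
#' sampling changes the headspace volume, so the methane present at a
#' timepoint understates cumulative production. The correction adds back the
#' methane carried away by all *prior* gas withdrawals (at the composition
#' measured when each was taken):
#'
#' `n_produced(k) = n_present(k) + sum_{j<k} F_CH4(j) * n(V_removed(j))`
#'
#' At the first timepoint no gas has been withdrawn, so production equals
#' the methane present. `include_current = TRUE` additionally credits the
#' current timepoint's own draw to its own production (an alternative
#' reading of the bookkeeping; off by default because only the strict
#' prior-removal form closes an explicit mole inventory).
#'
#' @param series data.frame, time-ordered, with columns `day`, `F_CH4`,
#'   `V_mL` (headspace at measurement) and `gas_removed_mL` (volume drawn by
#'   the instrument at that timepoint).
#' @param T_K,P_atm gas-law conditions.
#' @param include_current see Details.
#' @return `series` with columns `n_present`, `n_removed_cum` (running total
#'   of methane carried away, including the current draw) and `n_produced`
#'   (mol) appended.
#' @export
cumulative_methane <- function(series, T_K = 298, P_atm = 1,
                               include_current = FALSE) {
  stopifnot(is.data.frame(series),
            all(c("day", "F_CH4", "V_mL", "gas_removed_mL") %in%
                  names(series)))
  if (is.unsorted(series$day)) {
    stop("series not time-ordered", call. = FALSE)
  }
  n <- nrow(series)
  n_present <- moles_in_headspace(series$F_CH4, series$V_mL, T_K, P_atm)
  removed <- ifelse(series$gas_removed_mL > 0,
                    moles_in_headspace(series$F_CH4,
                                       pmax(series$gas_removed_mL, 1e-12),
                                       T_K, P_atm),
                    0)
  removed_cum <- cumsum(removed)
  prior_removed <- c(0, removed_cum[-n])[seq_len(n)]
  credit <- if (include_current) removed_cum else prior_removed
  series$n_present <- n_present
  series$n_removed_cum <- removed_cum
  series$n_produced <- n_present + credit
  series
}

#' Interpolated cumulative production at an arbitrary day
#' @keywords internal
.n_produced_at <- function(series, day) {
  if (day < min(series$day) - 1e-9 || day > max(series$day) + 1e-9) {
    stop(sprintf("day %.3g outside measured span [%.3g, %.3g]",
                 day, min(series$day), max(series$day)), call. = FALSE)
  }
  stats::approx(series$day, series$n_produced, xout = day, rule = 1)$y
}

#' Average methane production rate over a day window
#'
#' `(n_produced(b) - n_produced(a)) / (b - a)`, with linear interpolation
#' between measurements for off-grid endpoints.
#'
#' @param series output of [cumulative_methane()].
#' @param window numeric length-2, `(day_a, day_b)` with `day_a < day_b`,
#'   both inside the measured span.
#' @return Rate in mol/day (multiply by 1e3 for mmol/day).
#' @export
production_rate <- function(series, window) {
  stopifnot(is.numeric(window), length(window) == 2L)
  if (!"n_produced" %in% names(series)) {
    stop("series lacks n_produced; run cumulative_methane() first",
         call. = FALSE)
  }
  if (window[2] <= window[1]) stop("window must have day_a < day_b",
                                   call. = FALSE)
  (.n_produced_at(series, window[2]) - .n_produced_at(series, window[1])) /
    (window[2] - window[1])
}

#' Window of maximum methane production rate
#'
#' Slides a fixed-width window anchored at each measurement day and reports
#' the first window (tie-break) achieving the maximal average rate — the
#' quantity used to compare lag between incubation conditions.
#'
#' @param series output of [cumulative_methane()].
#' @param width_days window width in days.
#' @return list with `window` (c(day_a, day_b)) and `rate` (mol/day).
#' @export
max_rate_window <- function(series, width_days) {
  stopifnot(width_days > 0)
  days <- series$day
  starts <- days[days + width_days <= max(days) + 1e-9]
  if (!length(starts)) {
    stop("series span shorter than window width", call. = FALSE)
  }
  rates <- vapply(starts, function(a)
    production_rate(series, c(a, a + width_days)), 0)
  best <- which.max(rates)  # which.max returns the first maximum
  list(window = c(starts[best], starts[best] + width_days),
       rate = rates[best])
}
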