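# Independent oracles used across tests. These deliberately avoid the
# package's own code paths (separate gas-law arithmetic, explicit loops).

# Explicit mole-inventory bottle: given per-interval CH4 production (mol),
# sampling days and withdrawal volumes, walk the inventory step by step and
# emit both the measurement series the pipeline would see and the true
# cumulative production.
oracle_bottle <- function(prod_increments, days,
                          liquid_mL = rep(6, length(days)),
                          gas_mL = rep(7, length(days)),
                          T_K = 298, P_atm = 1, V0 = 300) {
  R <- 0.082057
  V <- V0
  ch4 <- 0
  rows <- vector("list", length(days))
  for (k in seq_along(days)) {
    ch4 <- ch4 + prod_increments[k]
    n_tot <- P_atm * (V / 1000) / (R * T_K)
    f <- ch4 / n_tot
    rows[[k]] <- data.frame(
      day = days[k], F_CH4 = f, V_mL = V, gas_removed_mL = gas_mL[k],
      true_cum = sum(prod_increments[seq_len(k)])
    )
    ch4 <- ch4 - f * P_atm * (gas_mL[k] / 1000) / (R * T_K)
    V <- V + liquid_mL[k]
  }
  do.call(rbind, rows)
}

# Unit-activity conditions: Q = 1 for every registry reaction (pH 0 puts
# the proton at unit activity too), so delta_g == delta_g_standard.
standard_state <- function() {
  chemical_conditions(pH = 0,
                      activities = c("HCO3-" = 1, "Fe2+" = 1,
                                     "CH4(aq)" = 1, "CH3COO-" = 1))
}

# Reference conditions with one activity replaced.
cond_with <- function(cond, species, activity) {
  acts <- cond$activities
  acts[species] <- activity
  chemical_conditions(cond$pH, acts, cond$temperature_K, cond$R_kJ)
}

# One full synthetic round trip: truth -> scans -> pipeline series.
round_trip <- function(condition = "ferrihydrite", noise_sd = 0,
                       seed = NULL, ...) {
  truth <- simulate_incubation(condition_preset(condition, ...))
  scans <- forward_rga(truth, noise_sd = noise_sd, seed = seed)
  events <- cbind(bottle = truth$bottle, truth$schedule)
  list(truth = truth, series = process_gas(scans, events))
}
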