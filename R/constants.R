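# Physical constants used throughout. Energies are handled in kcal/mol
# internally; potentials in mV at the user interface.

#' @keywords internal
.FARADAY_KCAL <- 23.061   # kcal mol^-1 V^-1
#' @keywords internal
.FARADAY_KJ <- 96.485     # kJ mol^-1 V^-1
#' @keywords internal
.KCAL_PER_KJ <- 1 / 4.184
#' @keywords internal
.MEV_PER_KCAL <- 1000 / 23.061  # meV (per elementary charge) per kcal/mol
#' @keywords internal
.R_KCAL <- 1.987204259e-3 # gas constant, kcal mol^-1 K^-1
#' @keywords internal
.KB_OVER_H <- 1.380649e-23 / 6.62607015e-34  # k_B/h, s^-1 K^-1

#' @keywords internal
.DEFAULT_T_K <- 310  # simulation-ensemble temperature, K

.energy_units <- c("kcal/mol", "kJ/mol", "meV")

# value in `units` -> kcal/mol
.to_kcal <- function(value, units) {
  switch(units,
    "kcal/mol" = value,
    "kJ/mol"   = value * .KCAL_PER_KJ,
    "meV"      = value / .MEV_PER_KCAL,
    stop("unknown energy unit: '", units, "' (use one of ",
         paste(.energy_units, collapse = ", "), ")", call. = FALSE)
  )
}

.from_kcal <- function(value, units) {
  switch(units,
    "kcal/mol" = value,
    "kJ/mol"   = value / .KCAL_PER_KJ,
    "meV"      = value * .MEV_PER_KCAL,
    stop("unknown energy unit: '", units, "' (use one of ",
         paste(.energy_units, collapse = ", "), ")", call. = FALSE)
  )
}

# thermal energy RT in kcal/mol
.rt_kcal <- function(temperature_K) .R_KCAL * temperature_K
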