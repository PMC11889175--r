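#' Empirical electron-tunneling rate (distance ruler)
#'
#' Non-adiabatic electron tunneling between protein cofactors follows, to a
#' good approximation, the empirical ruler
#' \deqn{\log_{10} k = A - B\,R - C\,(\Delta G + \lambda)^2/\lambda}
#' with R the edge-to-edge donor-acceptor distance in Angstrom and the
#' energies in eV. Defaults A = 15, B = 0.6, C = 3.1 are the standard
#' exergonic-regime coefficients; the reorganization energy defaults to
#' 0.7 eV, typical for buried protein cofactors.
#'
#' @param distance_A Edge-to-edge distance in Angstrom (> 0).
#' @param dG_eV Reaction free energy in eV (negative = exergonic).
#' @param lambda_eV Reorganization energy in eV (> 0, default 0.7).
#' @param coef Numeric vector `c(A, B, C)` of ruler coefficients.
#' @return Rate in s^-1 (strictly positive).
#' @examples
#' tunneling_rate(16, -0.13)   # ~9e3 s^-1
#' tunneling_rate(20, -0.13)   # ~36 s^-1
#' @export
tunneling_rate <- function(distance_A, dG_eV, lambda_eV = 0.7,
                           coef = c(15, 0.6, 3.1)) {
  if (!all(is.finite(distance_A)) || any(distance_A <= 0)) {
    stop("distance_A must be positive and finite", call. = FALSE)
  }
  if (!all(is.finite(lambda_eV)) || any(lambda_eV <= 0)) {
    stop("lambda_eV must be > 0", call. = FALSE)
  }
  stopifnot(length(coef) == 3L, all(is.finite(coef)))
  log10k <- coef[1] - coef[2] * distance_A -
    coef[3] * (dG_eV + lambda_eV)^2 / lambda_eV
  10^log10k
}

#' Transition-state (Eyring) rate from an activation free energy
#'
#' \deqn{k = \kappa \frac{k_B T}{h} e^{-\Delta G^\ddagger / RT}}
#' Used for conformational transitions and ion binding/release steps whose
#' barriers come from free-energy calculations: +4 kcal/mol for the
#' inward/outward transition with the AE1 cluster reduced, +10 kcal/mol
#' with it oxidised.
#'
#' @param dG_barrier_kcal Activation free energy in kcal/mol (>= 0).
#' @param temperature_K Absolute temperature (default 310 K).
#' @param transmission Dimensionless prefactor scale in (0, 1], default 1.
#' @return Rate in s^-1.
#' @examples
#' eyring_rate(4)    # ~1e10 s^-1
#' eyring_rate(10)   # ~6e5 s^-1
#' @export
eyring_rate <- function(dG_barrier_kcal, temperature_K = .DEFAULT_T_K,
                        transmission = 1) {
  if (any(dG_barrier_kcal < 0)) {
    stop("dG_barrier_kcal must be >= 0", call. = FALSE)
  }
  if (temperature_K <= 0) stop("temperature_K must be > 0", call. = FALSE)
  if (transmission <= 0 || transmission > 1) {
    stop("transmission must lie in (0, 1]", call. = FALSE)
  }
  transmission * .KB_OVER_H * temperature_K *
    exp(-dG_barrier_kcal / .rt_kcal(temperature_K))
}

#' Reverse rate by detailed balance
#'
#' Given a forward rate and the step free energy, returns the reverse rate
#' \eqn{k_{rev} = k_{fwd}\, e^{+\Delta G/RT}} so that
#' \eqn{k_{fwd}/k_{rev} = e^{-\Delta G/RT}}. This guarantees the kinetic
#' model is thermodynamically consistent: at equilibrium every edge flux
#' vanishes.
#'
#' @param k_forward Forward rate in s^-1 (> 0).
#' @param dG_kcal Step free energy in kcal/mol (negative = forward
#'   exergonic).
#' @param temperature_K Absolute temperature (default 310 K).
#' @return Reverse rate in s^-1.
#' @export
reverse_rate_detailed_balance <- function(k_forward, dG_kcal,
                                          temperature_K = .DEFAULT_T_K) {
  if (any(k_forward <= 0)) stop("k_forward must be > 0", call. = FALSE)
  k_forward * exp(dG_kcal / .rt_kcal(temperature_K))
}

#' Overall time of a sequential reaction chain
#'
#' Mean first-passage approximation for a chain of effectively irreversible
#' steps: the total time is the sum of the per-step dwell times,
#' \eqn{\sum_i 1/k_i}, dominated by the slowest step. Applied to the
#' six-step cofactor chain of the complex at 15-20 Angstrom spacings this
#' lands in the millisecond regime.
#'
#' @param rates Numeric vector of per-step forward rates in s^-1 (all > 0).
#' @return Total chain time in seconds.
#' @export
chain_overall_time <- function(rates) {
  if (length(rates) == 0L) stop("rates must be non-empty", call. = FALSE)
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("all rates must be positive and finite", call. = FALSE)
  }
  sum(1 / rates)
}
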