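# Two-state empirical valence bond (EVB) energy model: diabatic energies,
# gas-phase-shifted product state, adiabatic ground-state surface, mapping
# potential and the energy-gap reaction coordinate.

#' EVB Hamiltonian parameters
#'
#' The two constants that calibrate a two-state EVB model: the gas-phase
#' shift \eqn{\Delta\alpha} added once to the product diabatic state, and the
#' off-diagonal coupling element \eqn{H_{12}}. Defaults are the published
#' values for the elastase acylation step (\eqn{\Delta\alpha = 195.0},
#' \eqn{H_{12} = 113.0} kcal/mol).
#'
#' @param gas_shift Gas-phase shift added to the raw product diabatic energy,
#'   kcal/mol.
#' @param coupling Off-diagonal coupling element, kcal/mol; must be
#'   non-negative.
#' @return An object of class `evb_params`.
#' @examples
#' p <- evb_params()
#' shifted_state2(-195, p)
#' @export
evb_params <- function(gas_shift = 195.0, coupling = 113.0) {
  if (!is.finite(gas_shift) || !is.finite(coupling))
    stop_coldevb("EVB parameters must be finite", "coldevb_invalid_value")
  if (coupling < 0)
    stop_coldevb("coupling H12 must be non-negative", "coldevb_invalid_value")
  structure(list(gas_shift_alpha = gas_shift, coupling_h12 = coupling),
            class = "evb_params")
}

#' @export
print.evb_params <- function(x, ...) {
  cat(sprintf("EVB parameters: gas shift = %.1f, H12 = %.1f kcal/mol\n",
              x$gas_shift_alpha, x$coupling_h12))
  invisible(x)
}

#' Apply the gas-phase shift to the product diabatic state
#'
#' @param eps2_raw Raw diabatic energy of the product state, kcal/mol.
#' @param params An [evb_params()] object.
#' @return `eps2_raw + gas_shift_alpha`, kcal/mol. Vectorised.
#' @export
shifted_state2 <- function(eps2_raw, params) {
  stopifnot(inherits(params, "evb_params"))
  if (any(!is.finite(eps2_raw)))
    stop_coldevb("eps2_raw must be finite", "coldevb_invalid_value")
  eps2_raw + params$gas_shift_alpha
}

#' Adiabatic ground-state energy of the two-state EVB Hamiltonian
#'
#' Lower eigenvalue of the 2x2 Hamiltonian with diabatic energies on the
#' diagonal and `coupling_h12` off-diagonal:
#' \deqn{E_g = \tfrac12(\epsilon_1 + \epsilon_2') -
#'   \tfrac12\sqrt{(\epsilon_1-\epsilon_2')^2 + 4 H_{12}^2}.}
#' The product state energy must already include the gas-phase shift.
#'
#' @param eps1 Diabatic energy of the reactant state, kcal/mol.
#' @param eps2_shifted Gas-shifted diabatic energy of the product
#'   (tetrahedral-intermediate) state, kcal/mol.
#' @param params An [evb_params()] object.
#' @return Ground-state energy, kcal/mol; never exceeds either diabat and
#'   equals their minimum when the coupling is zero. Vectorised.
#' @export
adiabatic_ground <- function(eps1, eps2_shifted, params) {
  stopifnot(inherits(params, "evb_params"))
  if (any(!is.finite(eps1)) || any(!is.finite(eps2_shifted)))
    stop_coldevb("diabatic energies must be finite", "coldevb_invalid_value")
  d <- eps1 - eps2_shifted
  0.5 * (eps1 + eps2_shifted) - 0.5 * sqrt(d * d + 4 * params$coupling_h12^2)
}

#' Hellmann-Feynman weights of the ground state
#'
#' Derivatives of the ground-state energy with respect to each diabatic
#' energy; the ground-state gradient along any coordinate is
#' `w1 * d(eps1) + w2 * d(eps2')`. The weights sum to one.
#'
#' @inheritParams adiabatic_ground
#' @return Two-column matrix with columns `w1`, `w2`.
#' @export
ground_weights <- function(eps1, eps2_shifted, params) {
  stopifnot(inherits(params, "evb_params"))
  d <- eps1 - eps2_shifted
  den <- sqrt(d * d + 4 * params$coupling_h12^2)
  w1 <- ifelse(den == 0, 0.5, 0.5 * (1 - d / den))
  cbind(w1 = w1, w2 = 1 - w1)
}

#' Mapping potential of an FEP window
#'
#' \eqn{\epsilon_m = (1-\lambda)\epsilon_1 + \lambda\epsilon_2'}: the mixed
#' potential used to drive sampling from the reactant state to the
#' tetrahedral intermediate.
#'
#' @inheritParams adiabatic_ground
#' @param lambda Mixing parameter in \eqn{[0, 1]}.
#' @return Mapping energy, kcal/mol. Vectorised over energies.
#' @export
mapping_energy <- function(eps1, eps2_shifted, lambda) {
  if (any(lambda < 0 | lambda > 1))
    stop_coldevb("lambda must lie in [0, 1]", "coldevb_range_error")
  (1 - lambda) * eps1 + lambda * eps2_shifted
}

#' Energy-gap reaction coordinate
#'
#' \eqn{X = \epsilon_1 - \epsilon_2'}. Reactant-dominated configurations give
#' negative X under this convention (the product diabat lies far above the
#' reactant diabat there).
#'
#' @inheritParams adiabatic_ground
#' @return Energy gap, kcal/mol. Vectorised.
#' @export
energy_gap <- function(eps1, eps2_shifted) {
  eps1 - eps2_shifted
}

#' Evenly spaced FEP mapping windows
#'
#' @param n_windows Number of windows; default 51, the protocol value.
#' @return Data frame with integer `index` (0-based) and `lambda`
#'   (\eqn{\lambda_m = m/(n-1)}).
#' @examples
#' head(make_windows(51))
#' @export
make_windows <- function(n_windows = 51) {
  if (length(n_windows) != 1 || !is.finite(n_windows) || n_windows < 2)
    stop_coldevb("n_windows must be an integer >= 2", "coldevb_config_error")
  m <- seq_len(n_windows) - 1L
  data.frame(index = m, lambda = m / (n_windows - 1))
}
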