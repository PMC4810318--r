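# Relativistic kinematics per nucleon. Energies are kinetic, MeV/nuc;
# momenta are MeV/c per nucleon unless stated otherwise.

#' Velocity (beta) from kinetic energy per nucleon
#'
#' beta = v/c for a nucleus with kinetic energy T per nucleon, using the
#' nucleon rest energy m = 938.272 MeV: gamma = 1 + T/m, beta = sqrt(1 -
#' 1/gamma^2). Independent of the ion species because T is per nucleon.
#'
#' @param energy_per_nucleon Kinetic energy, MeV/nuc (vectorised, >= 0).
#' @return beta in [0, 1).
#' @export
#' @examples
#' beta_from_energy(938.272)  # gamma = 2, beta = sqrt(3)/2
beta_from_energy <- function(energy_per_nucleon) {
  if (any(energy_per_nucleon < 0)) stop("energy must be >= 0")
  g <- 1 + energy_per_nucleon / .M_NUCLEON
  sqrt(1 - 1 / g^2)
}

#' Momentum per nucleon from kinetic energy per nucleon
#'
#' p = sqrt(T (T + 2m)) per nucleon. The total momentum of a fragment of mass
#' number A travelling at the same velocity is A times this value.
#'
#' @inheritParams beta_from_energy
#' @return Momentum, MeV/c per nucleon.
#' @export
#' @examples
#' momentum_per_nucleon(250)       # ~729 MeV/c; x4 nucleons ~ 2.9 GeV/c for 4He
momentum_per_nucleon <- function(energy_per_nucleon) {
  if (any(energy_per_nucleon < 0)) stop("energy must be >= 0")
  sqrt(energy_per_nucleon * (energy_per_nucleon + 2 * .M_NUCLEON))
}

#' Kinetic energy per nucleon from momentum per nucleon
#'
#' Inverse of [momentum_per_nucleon()]: T = sqrt(p^2 + m^2) - m.
#'
#' @param p Momentum, MeV/c per nucleon (>= 0).
#' @return Kinetic energy, MeV/nuc.
#' @export
energy_from_momentum <- function(p) {
  if (any(p < 0)) stop("momentum must be >= 0")
  sqrt(p^2 + .M_NUCLEON^2) - .M_NUCLEON
}
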