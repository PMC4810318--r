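# Physical constants used throughout. Values are CODATA-rounded; the Bethe
# prefactor k = 4 pi N_A r_e^2 m_e c^2 is in MeV cm^2 / mol, so that
# k * (Z/A)_mat has units MeV cm^2 / g.

.M_ELECTRON <- 0.51099895    # MeV
.M_NUCLEON  <- 938.272       # MeV per nucleon (proton mass; bare-nucleus approx)
.K_BETHE    <- 0.307075      # MeV cm^2 mol^-1
.AVOGADRO   <- 6.02214076e23 # mol^-1
.LET_DOSE   <- 1.602e-9      # Gy per (keV/um * cm^-2) at unit density
.MB_PER_FM2 <- 10            # 1 fm^2 = 10 mb
.E_FLOOR    <- 1             # MeV/nuc, validity floor of the stopping model
.R_RESIDUAL <- 0.01          # g cm^-2 proton residual range below the floor

#' Physical constants of the transport model
#'
#' Returns the constants used by the stopping-power, range and dosimetry
#' routines: the Bethe prefactor `k` (MeV cm^2/g per unit Z/A of the medium),
#' the electron and nucleon rest energies (MeV), Avogadro's number, and the
#' LET-fluence-to-dose conversion (Gy per keV/um per cm^-2 at unit density).
#'
#' @return Named list of constants.
#' @export
#' @examples
#' physics_constants()$let_dose_conversion
physics_constants <- function() {
  list(
    k = .K_BETHE,
    electron_rest_energy = .M_ELECTRON,
    nucleon_rest_energy = .M_NUCLEON,
    avogadro = .AVOGADRO,
    let_dose_conversion = .LET_DOSE
  )
}
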