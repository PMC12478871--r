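# Internal unit system is atomic units (hbar = 1, mass in m_e, length in
# bohr, energy in hartree); user-facing quantities are Angstrom, amu,
# kcal/mol and cm^-1.

.BOHR_A <- 0.529177210903        # Angstrom per bohr
.HARTREE_KCAL <- 627.509474063   # kcal/mol per hartree
.HARTREE_CM <- 219474.6313632    # cm^-1 per hartree
.AMU_ME <- 1822.888486209        # electron masses per amu
.KB_KCAL <- 0.0019872041         # kcal/mol/K

#' Unit conversion constants
#'
#' Conversion factors between the package's internal atomic units and the
#' units used for input and output.
#'
#' @return Named list with `bohr_A` (Angstrom per bohr), `hartree_kcal`
#'   (kcal/mol per hartree), `hartree_cm` (cm^-1 per hartree) and `amu_me`
#'   (electron masses per amu).
#' @export
unit_constants <- function() {
  list(bohr_A = .BOHR_A, hartree_kcal = .HARTREE_KCAL,
       hartree_cm = .HARTREE_CM, amu_me = .AMU_ME)
}
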