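# Bridge between R-side objects (Angstrom/amu/kcal) and the compiled
# atomic-unit surface.

.model_spec <- function(conf, params, guided = FALSE, intermolecular = TRUE) {
  mols <- sort(unique(conf$mol_index))
  iO <- iH1 <- iH2 <- integer(length(mols))
  for (k in seq_along(mols)) {
    idx <- which(conf$mol_index == mols[k])
    iO[k] <- idx[conf$elements[idx] == "O"] - 1L
    hh <- idx[conf$elements[idx] == "H"]
    iH1[k] <- hh[1] - 1L
    iH2[k] <- hh[2] - 1L
  }
  g <- reduced_masses(params)
  k_oh <- params$k_oh / .HARTREE_KCAL * .BOHR_A^2
  k_a <- params$k_a / .HARTREE_KCAL
  mu_oh <- g$mu_oh * .AMU_ME
  mu_a <- g$mu_a * .AMU_ME / .BOHR_A^2
  list(type = 0L,
       mass = conf$masses * .AMU_ME,
       iO = iO, iH1 = iH1, iH2 = iH2,
       kOH = k_oh, leq = params$l_eq / .BOHR_A,
       kA = k_a, theq = params$theta_eq,
       eps = params$epsilon / .HARTREE_KCAL,
       sig = params$sigma / .BOHR_A,
       charge = ifelse(conf$elements == "O", params$q_o, params$q_h),
       intermolecular = isTRUE(intermolecular),
       rmin = 0.1 / .BOHR_A,
       guided = isTRUE(guided),
       a_l = sqrt(k_oh * mu_oh),
       a_th = sqrt(k_a * mu_a))
}

.check_not_degenerate <- function(conf, cutoff = 0.1) {
  d <- stats::dist(conf$coords)
  if (any(d < cutoff))
    stop("degenerate geometry: interatomic distance below ", cutoff, " A")
}

#' q-SPC/Fw potential energy
#'
#' Sum of harmonic intramolecular stretch/bend terms, O-O Lennard-Jones, and
#' intermolecular Coulomb interactions.  There are no intramolecular
#' nonbonded terms; the energy zero is the isolated-monomer equilibrium.
#'
#' @param conf `wc_configuration`.
#' @param params `qspcfw_params`.
#' @param intermolecular Include intermolecular terms (disable to study the
#'   decoupled intramolecular problem).
#' @return Energy in kcal/mol.
#' @export
potential_energy <- function(conf, params = qspcfw_params(), intermolecular = TRUE) {
  .check_not_degenerate(conf)
  spec <- .model_spec(conf, params, intermolecular = intermolecular)
  potential_cpp(spec, .coords_au(conf)) * .HARTREE_KCAL
}

#' Analytic gradient of the q-SPC/Fw potential
#'
#' @inheritParams potential_energy
#' @return n x 3 matrix, kcal/mol/Angstrom.
#' @export
pes_gradient <- function(conf, params = qspcfw_params(), intermolecular = TRUE) {
  .check_not_degenerate(conf)
  spec <- .model_spec(conf, params, intermolecular = intermolecular)
  g <- gradient_cpp(spec, .coords_au(conf))
  matrix(g, ncol = 3, byrow = TRUE) * .HARTREE_KCAL / .BOHR_A
}

#' Dipole moment from the fixed point charges
#'
#' `mu = sum_i q_i x_i` with the q-SPC/Fw partial charges.
#'
#' @inheritParams potential_energy
#' @return Length-3 vector in e*Angstrom.
#' @export
dipole_moment <- function(conf, params = qspcfw_params()) {
  spec <- .model_spec(conf, params)
  dipole_cpp(spec, .coords_au(conf)) * .BOHR_A
}

#' Intramolecular guiding function
#'
#' Product over monomers of Gaussians in the bond-length and angle
#' displacements, `psi_guide = prod_k exp(-[sqrt(k_OH mu_OH)(dl1^2 + dl2^2)
#' + sqrt(k_A mu_A) dtheta^2] / (2 hbar))` -- the exact ground state of the
#' decoupled intramolecular harmonic problem.
#'
#' @param conf `wc_configuration`.
#' @param params `qspcfw_params`.
#' @param log Return the logarithm (default) or the value itself.
#' @return Scalar (dimensionless).
#' @export
guiding_value <- function(conf, params = qspcfw_params(), log = FALSE) {
  spec <- .model_spec(conf, params, guided = TRUE)
  lv <- guiding_log_cpp(spec, .coords_au(conf))
  if (log) lv else exp(lv)
}

#' Gradient of the log guiding function
#'
#' `grad log psi_guide` per atom, used as the drift field in importance
#' sampling.
#'
#' @inheritParams guiding_value
#' @return n x 3 matrix in 1/Angstrom.
#' @export
guiding_log_gradient <- function(conf, params = qspcfw_params()) {
  spec <- .model_spec(conf, params, guided = TRUE)
  g <- guiding_grad_cpp(spec, .coords_au(conf))
  matrix(g, ncol = 3, byrow = TRUE) / .BOHR_A
}

#' Local energy of the guided walk
#'
#' `E_L = V - sum_i (hbar^2 / 2 m_i) (lap_i psi_g)/psi_g`, the branching
#' energy of importance-sampled DMC.  With intermolecular terms switched off
#' and the monomer at any geometry it equals the intramolecular zero-point
#' energy exactly (zero variance).
#'
#' @inheritParams potential_energy
#' @return Energy in kcal/mol.
#' @export
local_energy <- function(conf, params = qspcfw_params(), intermolecular = TRUE) {
  spec <- .model_spec(conf, params, guided = TRUE, intermolecular = intermolecular)
  local_energy_cpp(spec, .coords_au(conf)) * .HARTREE_KCAL
}
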