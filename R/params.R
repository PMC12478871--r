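#' q-SPC/Fw potential parameters
#'
#' Reads the flexible point-charge water parameters from a flat key/value
#' text file.  The bundled default (`inst/extdata/qspcfw.par`) holds the
#' q-SPC/Fw parametrization used throughout the package: harmonic
#' intramolecular stretch and bend (convention `V = (k/2) x^2`), O-O
#' Lennard-Jones, intermolecular Coulomb from fixed partial charges.
#'
#' @param file Path to a parameter file; default is the bundled set.
#' @return Object of class `qspcfw_params`: a list with `k_oh`
#'   (kcal/mol/A^2), `l_eq` (A), `k_a` (kcal/mol/rad^2), `theta_eq` (rad),
#'   `q_o`, `q_h` (e), `epsilon` (kcal/mol), `sigma` (A), `m_h`, `m_o` (amu).
#' @export
qspcfw_params <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "qspcfw.par", package = "dmcvib", mustWork = TRUE)
  lines <- readLines(file)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "[[:space:]]+")
  kv <- stats::setNames(
    vapply(toks, function(t) as.numeric(t[2]), numeric(1)),
    vapply(toks, `[[`, character(1), 1))
  need <- c("k_oh", "l_eq", "k_a", "theta_eq", "q_o", "q_h",
            "epsilon", "sigma", "m_h", "m_o")
  miss <- setdiff(need, names(kv))
  if (length(miss)) stop("parameter file misses keys: ", paste(miss, collapse = ", "))
  p <- as.list(kv[need])
  p$theta_eq <- p$theta_eq * pi / 180
  if (abs(p$q_o + 2 * p$q_h) > 1e-10)
    stop("monomer is not charge neutral: q_o + 2 q_h = ", p$q_o + 2 * p$q_h)
  if (p$k_oh <= 0 || p$k_a <= 0 || p$epsilon < 0 || p$sigma <= 0)
    stop("force-field constants must be positive")
  class(p) <- "qspcfw_params"
  p
}

#' @export
print.qspcfw_params <- function(x, ...) {
  cat("q-SPC/Fw parameters\n")
  cat(sprintf("  k_OH  %10.4f kcal/mol/A^2   l_eq     %6.3f A\n", x$k_oh, x$l_eq))
  cat(sprintf("  k_A   %10.4f kcal/mol/rad^2 theta_eq %6.2f deg\n",
              x$k_a, x$theta_eq * 180 / pi))
  cat(sprintf("  q_O %6.3f e  q_H %6.3f e  eps %8.5f kcal/mol  sigma %7.4f A\n",
              x$q_o, x$q_h, x$epsilon, x$sigma))
  h <- local_mode_harmonics(x)
  cat(sprintf("  local-mode harmonics: stretch %.1f cm^-1, bend %.1f cm^-1\n",
              h[["stretch"]], h[["bend"]]))
  invisible(x)
}

#' Reduced masses of the intramolecular guiding coordinates
#'
#' The OH-stretch reduced mass is `mu_OH = m_O m_H / (m_O + m_H)`; the HOH
#' bend reduced mass is `mu_A = (l_eq^2/2) / (1/m_H + (1 - cos theta_eq)/m_O)`,
#' the inverse of the Wilson G-matrix element of the bend at equilibrium.
#'
#' @param params `qspcfw_params` object.
#' @return Object of class `guiding_params`: list with `mu_oh` (amu),
#'   `mu_a` (amu A^2) and the parameters used.
#' @export
reduced_masses <- function(params) {
  stopifnot(inherits(params, "qspcfw_params"))
  mu_oh <- params$m_o * params$m_h / (params$m_o + params$m_h)
  mu_a <- params$l_eq^2 / 2 /
    (1 / params$m_h + (1 - cos(params$theta_eq)) / params$m_o)
  structure(list(mu_oh = mu_oh, mu_a = mu_a, params = params),
            class = "guiding_params")
}

#' Local-mode harmonic frequencies of the intramolecular motions
#'
#' Frequencies `nu = sqrt(k/mu)/(2 pi c)` of the decoupled OH stretch
#' (`k_OH`, `mu_OH`) and HOH bend (`k_A`, `mu_A`) oscillators, i.e. the
#' harmonics the intramolecular guiding function is built from.
#'
#' @param params `qspcfw_params` object.
#' @return Named numeric vector `c(stretch =, bend =)` in cm^-1.
#' @export
local_mode_harmonics <- function(params) {
  g <- reduced_masses(params)
  # in atomic units: omega = sqrt(k/mu), nu~ = omega * hartree_cm
  k_oh <- params$k_oh / .HARTREE_KCAL * .BOHR_A^2
  k_a <- params$k_a / .HARTREE_KCAL
  mu_oh <- g$mu_oh * .AMU_ME
  mu_a <- g$mu_a * .AMU_ME / .BOHR_A^2
  c(stretch = sqrt(k_oh / mu_oh) * .HARTREE_CM,
    bend = sqrt(k_a / mu_a) * .HARTREE_CM)
}

#' Harmonic normal-mode frequencies of an isolated monomer
#'
#' Diagonalizes the mass-weighted finite-difference Hessian of the
#' intramolecular potential at equilibrium and returns the three vibrational
#' frequencies.  Used as an independent cross-check of the local-mode
#' estimates.
#'
#' @param params `qspcfw_params` object.
#' @param h Finite-difference step in Angstrom.
#' @return Numeric vector of 3 frequencies (cm^-1), ascending.
#' @export
monomer_normal_modes <- function(params, h = 1e-4) {
  conf <- water_monomer(params)
  x0 <- as.vector(t(conf$coords)) / .BOHR_A
  spec <- .model_spec(conf, params, guided = FALSE, intermolecular = FALSE)
  n <- length(x0)
  hb <- h / .BOHR_A
  H <- matrix(0, n, n)
  for (c in seq_len(n)) {
    xp <- x0; xp[c] <- xp[c] + hb
    xm <- x0; xm[c] <- xm[c] - hb
    H[, c] <- (gradient_cpp(spec, xp) - gradient_cpp(spec, xm)) / (2 * hb)
  }
  H <- (H + t(H)) / 2
  m <- rep(conf$masses * .AMU_ME, each = 3)
  Hmw <- H / sqrt(outer(m, m))
  ev <- sort(eigen(Hmw, symmetric = TRUE, only.values = TRUE)$values)
  ev <- tail(ev, 3 * length(unique(conf$mol_index)) * 3 - 6)  # drop rigid modes
  sqrt(ev) * .HARTREE_CM
}
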