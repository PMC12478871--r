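#' Water-cluster configuration
#'
#' A configuration holds Cartesian coordinates (Angstrom), element symbols,
#' atomic masses (amu) and the assignment of each atom to a water monomer.
#' Atoms may appear in any order; each monomer must consist of exactly one
#' oxygen and two hydrogens.
#'
#' @param coords Numeric n x 3 matrix of coordinates in Angstrom.
#' @param elements Character vector of element symbols ("O"/"H").
#' @param mol_index Integer vector assigning atoms to monomers; default
#'   assumes consecutive O,H,H triples.
#' @param params `qspcfw_params` supplying atomic masses.
#' @return Object of class `wc_configuration`.
#' @export
configuration <- function(coords, elements, mol_index = NULL,
                          params = qspcfw_params()) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be an n x 3 matrix")
  n <- nrow(coords)
  if (length(elements) != n) stop("elements length does not match coords")
  if (!all(elements %in% c("O", "H"))) stop("only O and H atoms are supported")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (n %% 3 != 0) stop("atom count must be 3 x n_molecules")
  if (is.null(mol_index)) mol_index <- rep(seq_len(n / 3), each = 3)
  mol_index <- as.integer(mol_index)
  for (m in unique(mol_index)) {
    el <- elements[mol_index == m]
    if (sum(el == "O") != 1 || sum(el == "H") != 2)
      stop("monomer ", m, " is not one O and two H")
  }
  masses <- ifelse(elements == "O", params$m_o, params$m_h)
  structure(list(coords = coords, elements = elements, masses = masses,
                 mol_index = mol_index),
            class = "wc_configuration")
}

#' @export
print.wc_configuration <- function(x, ...) {
  cat(sprintf("water cluster configuration: %d molecules (%d atoms)\n",
              n_molecules(x), nrow(x$coords)))
  invisible(x)
}

#' Number of water molecules in a configuration
#' @param conf `wc_configuration`.
#' @return Integer count of monomers.
#' @export
n_molecules <- function(conf) length(unique(conf$mol_index))

#' Equilibrium water monomer
#'
#' Monomer at the intramolecular equilibrium (both bonds at `l_eq`, angle at
#' `theta_eq`), oxygen at the origin, C2 axis along +z, molecule in the xz
#' plane.
#'
#' @param params `qspcfw_params`.
#' @return `wc_configuration` with one molecule.
#' @export
water_monomer <- function(params = qspcfw_params()) {
  l <- params$l_eq
  th <- params$theta_eq
  coords <- rbind(c(0, 0, 0),
                  c(l * sin(th / 2), 0, l * cos(th / 2)),
                  c(-l * sin(th / 2), 0, l * cos(th / 2)))
  configuration(coords, c("O", "H", "H"), params = params)
}

#' Heuristic starting geometry for an n-water cluster
#'
#' Places monomers on a ring with O-O spacing near 2.9 Angstrom, each
#' oriented to donate a hydrogen bond to its neighbour.  Intended as a
#' deterministic starting point for minimization and isomer search, not as a
#' minimum itself.  For n = 1 the equilibrium monomer is returned; for n = 2
#' a donor-acceptor arrangement.
#'
#' @param n_molecules Number of waters.
#' @param params `qspcfw_params`.
#' @param roo Ring O-O distance in Angstrom.
#' @return `wc_configuration`.
#' @export
initial_geometry <- function(n_molecules, params = qspcfw_params(), roo = 2.9) {
  n <- n_molecules
  mono <- water_monomer(params)$coords  # O origin, bisector +z, in xz plane
  if (n == 1) return(water_monomer(params))
  if (n == 2) {
    # donor-acceptor: donor OH points at acceptor O along x
    acc <- mono[, c(3, 2, 1)]            # bisector along +x
    acc <- sweep(acc, 2, c(0, 0, 0))
    don <- mono
    rot <- function(p, ang) {            # rotate in xz plane
      cbind(p[, 1] * cos(ang) + p[, 3] * sin(ang), p[, 2],
            -p[, 1] * sin(ang) + p[, 3] * cos(ang))
    }
    don <- rot(don, -(pi / 2 + params$theta_eq / 2))  # one OH along -x
    don <- sweep(don, 2, c(roo, 0, 0), `+`)
    coords <- rbind(acc, don)
    return(configuration(coords, rep(c("O", "H", "H"), 2), params = params))
  }
  R <- roo / (2 * sin(pi / n))
  coords <- NULL
  for (k in seq_len(n) - 1) {
    phi <- 2 * pi * k / n
    # donor OH roughly tangential to the ring, free H out of plane
    c1 <- mono
    ang <- phi + pi / 2
    rotz <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
    tilt <- rbind(c(1, 0, 0), c(0, cos(1.2), -sin(1.2)), c(0, sin(1.2), cos(1.2)))
    c1 <- c1 %*% t(tilt) %*% t(rotz)
    c1 <- sweep(c1, 2, c(R * cos(phi), R * sin(phi), 0.15 * (-1)^k), `+`)
    coords <- rbind(coords, c1)
  }
  configuration(coords, rep(c("O", "H", "H"), n), params = params)
}

# flattened coordinates in bohr (row-major per atom)
.coords_au <- function(conf) as.vector(t(conf$coords)) / .BOHR_A

# rebuild a configuration from flattened bohr coordinates
.conf_from_au <- function(x, template) {
  co <- matrix(x, ncol = 3, byrow = TRUE) * .BOHR_A
  out <- template
  out$coords <- co
  out
}
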