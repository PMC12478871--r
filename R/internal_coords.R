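#' Redundant internal-coordinate basis
#'
#' Builds the tagged descriptor list for a cluster.  Level `"n2"`: all
#' intramolecular OH bond lengths and HOH angles plus every intermolecular
#' atom-pair distance (quadratic growth).  Level `"n3"`: `"n2"` plus
#' intermolecular angles (cubic growth).  Ordering is deterministic:
#' intramolecular bonds (monomer order), intramolecular angles, then the
#' intermolecular block.
#'
#' @param conf Template `wc_configuration` (defines atom indices).
#' @param level "n2" or "n3".
#' @param inter_angle_rule For `"n3"`: which angles count as intermolecular.
#'   `"middle_vertex"` (default) takes one angle per sorted atom triple
#'   a < v < c that is not fully intramolecular, with the vertex at the
#'   middle atom index -- the enumeration a plain combinations-of-three
#'   implementation produces.  `"any_cross"` keeps all three vertex choices
#'   per such triple; `"cross_arms"` requires both end atoms to lie outside
#'   the vertex monomer; `"span_ends"` requires the end atoms to belong to
#'   different monomers; `"strict_cross"` requires three distinct monomers.
#'   All rules grow cubically with cluster size.
#' @return Object of class `internal_basis`: data frame of descriptors
#'   (`kind`, atom indices `i`, `j`, `k`, `label`) with attributes `K`
#'   (intramolecular count), `K_bond`, `K_angle`, `M`, `nvib` (3N-6) and
#'   `n_dof`.
#' @export
internal_basis <- function(conf, level = c("n2", "n3"),
                           inter_angle_rule = c("middle_vertex", "any_cross",
                                                "cross_arms", "span_ends",
                                                "strict_cross")) {
  level <- match.arg(level)
  inter_angle_rule <- match.arg(inter_angle_rule)
  el <- conf$elements
  mol <- conf$mol_index
  mols <- sort(unique(mol))
  nat <- nrow(conf$coords)
  kind <- character(0); i <- j <- k <- integer(0); label <- character(0)
  add <- function(kd, a, b, c = NA_integer_, lb) {
    kind <<- c(kind, kd); i <<- c(i, a); j <<- c(j, b); k <<- c(k, c)
    label <<- c(label, lb)
  }
  for (m in mols) {
    idx <- which(mol == m)
    o <- idx[el[idx] == "O"]; h <- idx[el[idx] == "H"]
    add("OH_bond", o, h[1], lb = sprintf("r(O%d-H%d) mol%d", o, h[1], m))
    add("OH_bond", o, h[2], lb = sprintf("r(O%d-H%d) mol%d", o, h[2], m))
  }
  for (m in mols) {
    idx <- which(mol == m)
    o <- idx[el[idx] == "O"]; h <- idx[el[idx] == "H"]
    add("HOH_angle", h[1], o, h[2], lb = sprintf("theta(HOH) mol%d", m))
  }
  for (a in seq_len(nat - 1))
    for (b in (a + 1):nat)
      if (mol[a] != mol[b])
        add("inter_distance", a, b, lb = sprintf("R(%s%d..%s%d)", el[a], a, el[b], b))
  if (level == "n3") {
    if (inter_angle_rule == "middle_vertex") {
      for (a in seq_len(nat - 2))
        for (v in (a + 1):(nat - 1))
          for (b in (v + 1):nat) {
            if (mol[a] == mol[v] && mol[v] == mol[b]) next
            add("inter_angle", a, v, b,
                lb = sprintf("phi(%s%d-%s%d-%s%d)", el[a], a, el[v], v, el[b], b))
          }
    } else {
      for (v in seq_len(nat)) {
        others <- setdiff(seq_len(nat), v)
        for (ai in seq_along(others)) {
          for (bi in seq_along(others)) {
            if (bi <= ai) next
            a <- others[ai]; b <- others[bi]
            keep <- switch(inter_angle_rule,
              any_cross = !(mol[a] == mol[v] && mol[b] == mol[v]),
              cross_arms = mol[a] != mol[v] && mol[b] != mol[v],
              span_ends = mol[a] != mol[b],
              strict_cross = mol[a] != mol[v] && mol[b] != mol[v] &&
                mol[a] != mol[b])
            if (keep)
              add("inter_angle", a, v, b,
                  lb = sprintf("phi(%s%d-%s%d-%s%d)", el[a], a, el[v], v, el[b], b))
          }
        }
      }
    }
  }
  df <- data.frame(kind = kind, i = i, j = j, k = k, label = label,
                   stringsAsFactors = FALSE)
  attr(df, "K_bond") <- sum(kind == "OH_bond")
  attr(df, "K_angle") <- sum(kind == "HOH_angle")
  attr(df, "K") <- attr(df, "K_bond") + attr(df, "K_angle")
  attr(df, "M") <- nrow(df)
  attr(df, "nvib") <- 3 * nat - 6
  attr(df, "n_dof") <- 3 * nat
  attr(df, "level") <- level
  class(df) <- c("internal_basis", "data.frame")
  df
}

# per-walker descriptor values; X is walkers x dof (any length unit, radians
# for angles)
#' Evaluate descriptors for an ensemble
#'
#' @param X Walkers x (3N) coordinate matrix (row-major atom triples).
#' @param basis `internal_basis`.
#' @return Walkers x M matrix of descriptor values (input length unit / rad).
#' @export
descriptor_values <- function(X, basis) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  W <- nrow(X)
  out <- matrix(0, W, nrow(basis))
  cx <- function(a) X[, (3 * a - 2):(3 * a), drop = FALSE]
  for (m in seq_len(nrow(basis))) {
    kd <- basis$kind[m]
    if (kd %in% c("OH_bond", "inter_distance")) {
      d <- cx(basis$i[m]) - cx(basis$j[m])
      out[, m] <- sqrt(rowSums(d * d))
    } else {
      u <- cx(basis$i[m]) - cx(basis$j[m])
      v <- cx(basis$k[m]) - cx(basis$j[m])
      a <- sqrt(rowSums(u * u)); b <- sqrt(rowSums(v * v))
      cth <- pmin(1, pmax(-1, rowSums(u * v) / (a * b)))
      out[, m] <- acos(cth)
    }
  }
  out
}

# Analytic Wilson B rows for one descriptor over a chunk of walkers,
# returned as a (3N x W) matrix (zeros outside the involved atoms).
.b_rows <- function(X, basis, m) {
  W <- nrow(X); nd <- attr(basis, "n_dof")
  B <- matrix(0, nd, W)
  cx <- function(a) X[, (3 * a - 2):(3 * a), drop = FALSE]
  sl <- function(a) (3 * a - 2):(3 * a)
  kd <- basis$kind[m]
  if (kd %in% c("OH_bond", "inter_distance")) {
    ia <- basis$i[m]; ib <- basis$j[m]
    d <- cx(ia) - cx(ib)
    r <- sqrt(rowSums(d * d))
    u <- d / r
    B[sl(ia), ] <- t(u)
    B[sl(ib), ] <- -t(u)
  } else {
    i1 <- basis$i[m]; i0 <- basis$j[m]; i2 <- basis$k[m]
    u <- cx(i1) - cx(i0); v <- cx(i2) - cx(i0)
    a <- sqrt(rowSums(u * u)); b <- sqrt(rowSums(v * v))
    uh <- u / a; vh <- v / b
    cth <- pmin(1, pmax(-1, rowSums(uh * vh)))
    s <- sqrt(pmax(1 - cth^2, 1e-12))
    g1 <- (uh * cth - vh) / (a * s)
    g2 <- (vh * cth - uh) / (b * s)
    B[sl(i1), ] <- t(g1)
    B[sl(i2), ] <- t(g2)
    B[sl(i0), ] <- -t(g1 + g2)
  }
  B
}

#' Wilson B matrix of a single configuration
#'
#' Jacobian `B[m, c] = d r_m / d x_c` of the descriptor vector with respect
#' to Cartesian coordinates (analytic; distance and angle closed forms).
#'
#' @param x Coordinate vector (3N) or 1 x 3N matrix.
#' @param basis `internal_basis`.
#' @return M x 3N matrix.
#' @export
wilson_b <- function(x, basis) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  t(vapply(seq_len(nrow(basis)), function(m) .b_rows(X, basis, m)[, 1],
           numeric(attr(basis, "n_dof"))))
}

#' Ensemble-averaged B machinery
#'
#' Accumulates the weighted ensemble averages `<B>` (Eckart-aligned walkers,
#' amplitude weights) and `<B Lambda B^T>` (`Lambda = diag(1/m)`), the two
#' inputs of the coordinate reduction and of the kinetic-energy metric
#' `<G> = U^T <B Lambda B^T> U`.
#'
#' @param X Walkers x 3N aligned coordinates (bohr).
#' @param basis `internal_basis`.
#' @param weights Per-walker weights (amplitude weights `W_DW w`).
#' @param masses Atomic masses in m_e.
#' @param chunk Walkers per accumulation block.
#' @return List with `Bbar` (M x 3N), `BLB` (M x M), `wsum`.
#' @export
ensemble_b <- function(X, basis, weights, masses, chunk = 1000) {
  W <- nrow(X); M <- nrow(basis); nd <- attr(basis, "n_dof")
  stopifnot(length(weights) == W, 3 * length(masses) == nd)
  sqrt_lam <- rep(1 / sqrt(masses), each = 3)
  Bbar <- matrix(0, M, nd)
  BLB <- matrix(0, M, M)
  wsum <- sum(weights)
  for (st in seq(1, W, by = chunk)) {
    en <- min(st + chunk - 1, W)
    Xc <- X[st:en, , drop = FALSE]
    wt <- weights[st:en]
    Wc <- length(wt)
    Y <- matrix(0, nd * Wc, M)
    for (m in seq_len(M)) {
      Bm <- .b_rows(Xc, basis, m)            # nd x Wc
      Bbar[m, ] <- Bbar[m, ] + as.vector(Bm %*% wt)
      Y[, m] <- as.vector((Bm * sqrt_lam) * rep(sqrt(wt), each = nd))
    }
    BLB <- BLB + crossprod(Y)
  }
  list(Bbar = Bbar / wsum, BLB = BLB / wsum, wsum = wsum)
}

.fix_signs <- function(U) {
  for (c in seq_len(ncol(U))) {
    p <- which.max(abs(U[, c]))
    if (U[p, c] < 0) U[, c] <- -U[, c]
  }
  U
}

#' Standard SVD redundancy reduction
#'
#' Singular value decomposition of `<B>`; the leading `3N - 6` left singular
#' vectors define the reduction matrix `U`.  Columns carry a deterministic
#' sign convention (largest-magnitude entry positive).
#'
#' @param eb Output of [ensemble_b()] (or a list with `Bbar`).
#' @param basis `internal_basis`.
#' @param n_keep Retained columns, default `3N - 6`.
#' @return Object of class `reduction_u`: `U` (M x n_keep), singular values
#'   `d`, `scheme`, `K` (fixed rows, 0 here).
#' @export
reduce_standard <- function(eb, basis, n_keep = NULL) {
  if (is.null(n_keep)) n_keep <- attr(basis, "nvib")
  sv <- svd(eb$Bbar)
  if (n_keep < length(sv$d) &&
      sv$d[n_keep] > 0 &&
      (sv$d[n_keep] - sv$d[n_keep + 1]) / sv$d[n_keep] < 1e-10)
    warning("degenerate singular values at the retained-rank cut; ",
            "tie broken by column order")
  structure(list(U = .fix_signs(sv$u[, seq_len(n_keep), drop = FALSE]),
                 d = sv$d, scheme = "standard", K = 0L),
            class = "reduction_u")
}

#' Chemically informed redundancy reduction
#'
#' Pins the `K` intramolecular descriptors (all OH bonds and HOH angles) as
#' exact coordinates and selects the remaining `3N - 6 - K` directions by
#' SVD of the intermolecular `<B>` rows projected into the orthogonal
#' complement of the intramolecular subspace:
#' QR-factorize `<B>_fixed^T = Q_f R`, project the free rows with
#' `P_perp = I - Q_f Q_f^T`, SVD the projection and assemble the
#' block matrix `U = [[I_K, 0], [0, U_free]]`.  By construction every
#' character-imbalance factor vanishes identically.
#'
#' @inheritParams reduce_standard
#' @return `reduction_u` with `scheme = "chem_informed"` and `K` the number
#'   of pinned intramolecular rows.
#' @export
reduce_chem_informed <- function(eb, basis, n_keep = NULL) {
  if (is.null(n_keep)) n_keep <- attr(basis, "nvib")
  K <- attr(basis, "K")
  M <- attr(basis, "M")
  nd <- attr(basis, "n_dof")
  if (n_keep < K) stop("cannot keep fewer coordinates than fixed rows")
  Bf <- eb$Bbar[seq_len(K), , drop = FALSE]
  qrf <- qr(t(Bf))
  if (qrf$rank < K)
    stop("fixed intramolecular B rows are rank deficient (rank ", qrf$rank,
         " < ", K, "); intramolecular coordinates linearly dependent")
  Qf <- qr.Q(qrf)[, seq_len(K), drop = FALSE]
  n_free <- n_keep - K
  if (n_free == 0)
    return(structure(list(U = diag(nrow = M)[, seq_len(K), drop = FALSE],
                          d = numeric(0), scheme = "chem_informed", K = K),
                     class = "reduction_u"))
  Bfree <- eb$Bbar[(K + 1):M, , drop = FALSE]
  Pperp <- diag(nd) - Qf %*% t(Qf)
  Bproj <- t(Pperp %*% t(Bfree))
  sv <- svd(Bproj)
  Ufree <- .fix_signs(sv$u[, seq_len(n_free), drop = FALSE])
  U <- rbind(cbind(diag(K), matrix(0, K, n_free)),
             cbind(matrix(0, M - K, K), Ufree))
  structure(list(U = U, d = sv$d, scheme = "chem_informed", K = K),
            class = "reduction_u")
}

#' Kinetic-energy metric in reduced coordinates
#'
#' `<G> = U^T <B Lambda B^T> U` with `Lambda = diag(1/m)`.
#'
#' @param eb Output of [ensemble_b()].
#' @param red `reduction_u`.
#' @return Symmetric (3N-6) x (3N-6) matrix (inverse-mass units, 1/m_e).
#' @export
g_matrix <- function(eb, red) {
  G <- t(red$U) %*% eb$BLB %*% red$U
  (G + t(G)) / 2
}

#' Inverse square root of a symmetric positive matrix
#'
#' Symmetric eigendecomposition; eigenvalues below `floor_rel` times the
#' largest are clamped (with a warning) before inversion.
#'
#' @param G Symmetric positive semidefinite matrix.
#' @param floor_rel Relative eigenvalue floor.
#' @return Matrix `G^{-1/2}` with `G^{-1/2} G G^{-1/2} = I` on the retained
#'   subspace.
#' @export
g_inv_sqrt <- function(G, floor_rel = 1e-12) {
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  fl <- floor_rel * max(e$values)
  if (any(e$values < fl))
    warning(sum(e$values < fl), " eigenvalue(s) clamped in G^{-1/2}")
  v <- pmax(e$values, fl)
  e$vectors %*% diag(1 / sqrt(v), length(v)) %*% t(e$vectors)
}

#' Transformation matrix from redundant internals to vibrational modes
#'
#' `T = P^T U^T`, the (3N-6) x M map whose squared entries partition the
#' vibrational basis over the redundant descriptors.
#'
#' @param P Eigenvector matrix of the mass-weighted covariance.
#' @param red `reduction_u` (or bare U matrix).
#' @return (3N-6) x M matrix.
#' @export
transform_matrix <- function(P, red) {
  U <- if (inherits(red, "reduction_u")) red$U else red
  t(P) %*% t(U)
}

#' Character imbalance factors of a coordinate selection
#'
#' `chi_intra_total = sum_l sum_{j <= K} T_lj^2` measures how much of the
#' vibrational basis draws on intramolecular descriptors; a chemically
#' balanced selection has `chi = K`.  `CIF = (chi - K)/K` (and likewise per
#' bond/angle class) quantifies under-representation; all CIFs are zero by
#' construction for the chemically informed reduction and invariant under
#' the orthonormal `P^T`.
#'
#' @param T Transformation matrix from [transform_matrix()] (or `U^T`).
#' @param basis `internal_basis`.
#' @return List with `chi_intra_total`, `cif_intra`, `cif_bond`, `cif_angle`.
#' @export
cif_diagnostics <- function(T, basis) {
  K <- attr(basis, "K")
  ib <- which(basis$kind == "OH_bond")
  ia <- which(basis$kind == "HOH_angle")
  T2 <- T^2
  chi_intra <- sum(T2[, c(ib, ia), drop = FALSE])
  chi_bond <- sum(T2[, ib, drop = FALSE])
  chi_angle <- sum(T2[, ia, drop = FALSE])
  list(chi_intra_total = chi_intra,
       cif_intra = (chi_intra - K) / K,
       cif_bond = (chi_bond - length(ib)) / length(ib),
       cif_angle = (chi_angle - length(ia)) / length(ia))
}

#' Intermolecular-to-intramolecular mixing fraction
#'
#' Share of the first `K` (intramolecular-like) vibrational modes carried by
#' intermolecular descriptors, relative to the total intramolecular
#' character.  Moderate values are physical: displacing an OH bond perturbs
#' nearby intermolecular distances.
#'
#' @inheritParams cif_diagnostics
#' @return Scalar in `[0, 1]`.
#' @export
mixing_fraction <- function(T, basis) {
  K <- attr(basis, "K")
  M <- attr(basis, "M")
  intra <- which(basis$kind %in% c("OH_bond", "HOH_angle"))
  inter <- setdiff(seq_len(M), intra)
  chi_intra <- sum(T[, intra, drop = FALSE]^2)
  sum(T[seq_len(K), inter, drop = FALSE]^2) / chi_intra
}

#' Character index of one vibrational mode
#'
#' Total squared contribution of one descriptor class to mode `l`;
#' values near 1 mean the mode is well localized in its intended motion
#' type.
#'
#' @param T Transformation matrix.
#' @param l Mode index (row of `T`).
#' @param kind "bond", "angle" or "inter".
#' @param basis `internal_basis`.
#' @return Scalar in `[0, 1]`.
#' @export
mode_character <- function(T, l, kind = c("bond", "angle", "inter"), basis) {
  kind <- match.arg(kind)
  cols <- switch(kind,
                 bond = which(basis$kind == "OH_bond"),
                 angle = which(basis$kind == "HOH_angle"),
                 inter = which(!basis$kind %in% c("OH_bond", "HOH_angle")))
  sum(T[l, cols]^2)
}
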