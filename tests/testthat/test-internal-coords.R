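au <- unit_constants()

test_that("descriptor counts follow the N2/N3 enumeration rules", {
  p <- test_params()
  m <- water_monomer(p)
  bm <- internal_basis(m, "n2")
  expect_equal(nrow(bm), 3)
  expect_equal(attr(bm, "K"), 3)
  d <- initial_geometry(2, p)
  b2 <- internal_basis(d, "n2")
  expect_equal(attr(b2, "K"), 6)
  expect_equal(nrow(b2), 6 + 9)          # intra + 3x3 cross distances
  tri <- initial_geometry(3, p)
  b3 <- internal_basis(tri, "n2")
  expect_equal(sum(b3$kind == "inter_distance"), 9 * 3 * (3 - 1) / 2)
  bN3 <- internal_basis(d, "n3")
  expect_equal(sum(bN3$kind == "inter_angle"), 18)   # C(6,3) - 2 intra triples
  bN3a <- internal_basis(d, "n3", inter_angle_rule = "any_cross")
  expect_equal(sum(bN3a$kind == "inter_angle"), 54)  # 6*10 triples - 6 intra
  # strict cross-monomer rule needs three distinct monomers: none in a dimer
  bN3s <- internal_basis(d, "n3", inter_angle_rule = "strict_cross")
  expect_equal(sum(bN3s$kind == "inter_angle"), 0)
  expect_gt(sum(internal_basis(tri, "n3",
                               inter_angle_rule = "strict_cross")$kind ==
                  "inter_angle"), 0)
})

test_that("Wilson B rows have the closed distance form and vanish under translation", {
  p <- test_params()
  gm <- dimer_gm()
  x <- as.vector(t(gm$coords)) / au$bohr_A
  b <- internal_basis(gm, "n2")
  B <- wilson_b(x, b)
  # distance row: +/- unit vector on the two atoms
  m <- which(b$kind == "inter_distance")[1]
  ia <- b$i[m]; ib <- b$j[m]
  d <- x[(3 * ia - 2):(3 * ia)] - x[(3 * ib - 2):(3 * ib)]
  u <- d / sqrt(sum(d^2))
  expect_equal(B[m, (3 * ia - 2):(3 * ia)], u, tolerance = 1e-12)
  expect_equal(B[m, (3 * ib - 2):(3 * ib)], -u, tolerance = 1e-12)
  expect_true(all(abs(B[m, -c((3 * ia - 2):(3 * ia), (3 * ib - 2):(3 * ib))]) == 0))
  # every row sums to zero over atom blocks (translation invariance)
  for (m in seq_len(nrow(B))) {
    blocks <- matrix(B[m, ], ncol = 3, byrow = TRUE)
    expect_lt(max(abs(colSums(blocks))), 1e-10)
  }
})

test_that("angle Jacobians agree with finite differences", {
  p <- test_params()
  set.seed(301)
  d <- dimer_gm()
  d$coords <- d$coords + matrix(rnorm(18, sd = 0.05), 6)
  x <- as.vector(t(d$coords)) / au$bohr_A
  b <- internal_basis(d, "n3")
  B <- wilson_b(x, b)
  rows <- c(which(b$kind == "HOH_angle"), which(b$kind == "inter_angle")[c(1, 10)])
  h <- 1e-6
  for (m in rows) {
    for (c in seq_along(x)) {
      xp <- x; xp[c] <- xp[c] + h
      xm <- x; xm[c] <- xm[c] - h
      fd <- (descriptor_values(matrix(xp, nrow = 1), b)[1, m] -
             descriptor_values(matrix(xm, nrow = 1), b)[1, m]) / (2 * h)
      expect_equal(B[m, c], fd, tolerance = 1e-5)
    }
  }
})

test_that("single-monomer G matrix reproduces the textbook Wilson elements", {
  p <- test_params()
  m <- water_monomer(p)
  b <- internal_basis(m, "n2")
  X <- matrix(as.vector(t(m$coords)) / au$bohr_A, nrow = 1)
  eb <- ensemble_b(X, b, weights = 1, masses = m$masses * au$amu_me)
  # G_bond,bond = 1/mO + 1/mH = 1/mu_OH
  mu_oh <- reduced_masses(p)$mu_oh * au$amu_me
  expect_equal(eb$BLB[1, 1], 1 / mu_oh, tolerance = 1e-10)
  # identity U: <G> = <B Lambda B^T>
  red <- structure(list(U = diag(3), scheme = "standard", K = 0L),
                   class = "reduction_u")
  expect_equal(g_matrix(eb, red), eb$BLB, tolerance = 1e-14)
})

test_that("vectorized <G> equals the element-wise double-sum oracle", {
  p <- test_params()
  set.seed(302)
  gm <- dimer_gm()
  X <- t(replicate(10, as.vector(t(gm$coords + matrix(rnorm(18, sd = 0.04), 6))) /
                     au$bohr_A))
  w <- runif(10, 0.5, 2)
  b <- internal_basis(gm, "n2")
  masses <- gm$masses * au$amu_me
  eb <- ensemble_b(X, b, w, masses)
  # oracle: per-walker numeric B, element-wise sum over Cartesian components
  Gor <- matrix(0, nrow(b), nrow(b))
  h <- 1e-6
  for (wk in 1:10) {
    Bn <- matrix(0, nrow(b), ncol(X))
    for (c in seq_len(ncol(X))) {
      xp <- X[wk, ]; xp[c] <- xp[c] + h
      xm <- X[wk, ]; xm[c] <- xm[c] - h
      Bn[, c] <- (descriptor_values(matrix(xp, 1), b)[1, ] -
                  descriptor_values(matrix(xm, 1), b)[1, ]) / (2 * h)
    }
    lam <- rep(1 / masses, each = 3)
    Gor <- Gor + w[wk] * (Bn %*% (lam * t(Bn)))
  }
  Gor <- Gor / sum(w)
  expect_equal(eb$BLB, Gor, tolerance = 1e-6)
})

test_that("standard SVD reduction is orthonormal with non-increasing spectrum", {
  p <- test_params()
  set.seed(303)
  gm <- dimer_gm()
  X <- t(replicate(30, as.vector(t(gm$coords + matrix(rnorm(18, sd = 0.04), 6))) /
                     au$bohr_A))
  b <- internal_basis(gm, "n2")
  eb <- ensemble_b(X, b, rep(1, 30), gm$masses * au$amu_me)
  red <- reduce_standard(eb, b)
  expect_equal(dim(red$U), c(15, 12))
  expect_equal(crossprod(red$U), diag(12), tolerance = 1e-10)
  expect_true(all(diff(red$d) <= 1e-12))
  # SVD optimality: retained subspace captures more of <B> than random ones
  resid <- function(U) sum((eb$Bbar - U %*% crossprod(U, eb$Bbar))^2)
  r_svd <- resid(red$U)
  for (k in 1:10) {
    Q <- qr.Q(qr(matrix(rnorm(15 * 12), 15, 12)))
    expect_lte(r_svd, resid(Q) + 1e-12)
  }
  # monomer: reduction is a pure rotation of the 3-descriptor space
  m <- water_monomer(p)
  bm <- internal_basis(m, "n2")
  Xm <- matrix(as.vector(t(m$coords)) / au$bohr_A, nrow = 1)
  ebm <- ensemble_b(Xm, bm, 1, m$masses * au$amu_me)
  Um <- reduce_standard(ebm, bm)$U
  expect_equal(crossprod(Um), diag(3), tolerance = 1e-10)
})

test_that("chemically informed reduction pins intramolecular coordinates exactly", {
  set.seed(304)
  gm <- dimer_gm()
  X <- t(replicate(30, as.vector(t(gm$coords + matrix(rnorm(18, sd = 0.04), 6))) /
                     au$bohr_A))
  b <- internal_basis(gm, "n2")
  eb <- ensemble_b(X, b, rep(1, 30), gm$masses * au$amu_me)
  red <- reduce_chem_informed(eb, b)
  K <- attr(b, "K")
  expect_equal(red$U[seq_len(K), seq_len(K)], diag(K))
  expect_true(all(red$U[seq_len(K), -seq_len(K)] == 0))
  expect_true(all(red$U[-seq_len(K), seq_len(K)] == 0))
  expect_equal(crossprod(red$U), diag(12), tolerance = 1e-10)
  # q keeps each intramolecular descriptor unchanged
  r <- descriptor_values(X, b)
  q <- r %*% red$U
  expect_equal(q[, seq_len(K)], r[, seq_len(K)], tolerance = 1e-12)
  # selected free directions live in the projected rows, orthogonal to the
  # fixed intramolecular subspace
  Qf <- qr.Q(qr(t(eb$Bbar[seq_len(K), ])))[, seq_len(K)]
  Bproj <- t((diag(18) - Qf %*% t(Qf)) %*% t(eb$Bbar[-seq_len(K), ]))
  sel_rows <- t(red$U[-seq_len(K), -seq_len(K)]) %*% Bproj
  expect_lt(max(abs(sel_rows %*% Qf)), 1e-10)
})

test_that("T matrix composes P and U and CIFs behave as designed", {
  set.seed(305)
  gm <- dimer_gm()
  b <- internal_basis(gm, "n2")
  X <- t(replicate(40, as.vector(t(gm$coords + matrix(rnorm(18, sd = 0.05), 6))) /
                     au$bohr_A))
  eb <- ensemble_b(X, b, rep(1, 40), gm$masses * au$amu_me)
  for (lv in c("n2", "n3")) {
    bb <- internal_basis(gm, lv)
    ebb <- ensemble_b(X, bb, rep(1, 40), gm$masses * au$amu_me)
    red <- reduce_chem_informed(ebb, bb)
    Prand <- qr.Q(qr(matrix(rnorm(12 * 12), 12, 12)))
    Tm <- transform_matrix(Prand, red)
    cif <- cif_diagnostics(Tm, bb)
    # identically zero by construction, machine precision, any P
    expect_equal(cif$cif_intra, 0, tolerance = 1e-12)
    expect_equal(cif$cif_bond, 0, tolerance = 1e-12)
    expect_equal(cif$cif_angle, 0, tolerance = 1e-12)
    # CIFs invariant under dropping the orthonormal P^T
    cif_u <- cif_diagnostics(t(red$U), bb)
    expect_equal(cif$cif_intra, cif_u$cif_intra, tolerance = 1e-12)
  }
  # identity composition and row norms
  expect_equal(transform_matrix(diag(3), diag(3)), diag(3))
  red2 <- reduce_standard(eb, b)
  P <- qr.Q(qr(matrix(rnorm(144), 12, 12)))
  Tm2 <- transform_matrix(P, red2)
  expect_equal(rowSums(Tm2^2), rep(1, 12), tolerance = 1e-10)
  v <- rnorm(15)
  expect_equal(as.vector(Tm2 %*% v), as.vector(t(P) %*% t(red2$U) %*% v),
               tolerance = 1e-12)
  # standard SVD under-represents intramolecular motion: CIF_intra < 0 and
  # worsens when intermolecular angles flood the basis
  cif_n2 <- cif_diagnostics(transform_matrix(diag(12), red2), b)
  b3 <- internal_basis(gm, "n3")
  eb3 <- ensemble_b(X, b3, rep(1, 40), gm$masses * au$amu_me)
  cif_n3 <- cif_diagnostics(transform_matrix(diag(12), reduce_standard(eb3, b3)), b3)
  expect_lt(cif_n2$cif_intra, 0)
  expect_lt(cif_n3$cif_intra, cif_n2$cif_intra)
})

test_that("mixing fraction and mode characters are normalized", {
  gm <- dimer_gm()
  b <- internal_basis(gm, "n2")
  K <- attr(b, "K"); M <- attr(b, "M")
  # block-diagonal T: no intermolecular leakage into intramolecular modes
  Tb <- cbind(diag(K), matrix(0, K, M - K))
  Tb <- rbind(Tb, cbind(matrix(0, 6, K), qr.Q(qr(matrix(rnorm(54), 9, 6)))[, 1:6] |> t()))
  expect_equal(mixing_fraction(Tb, b), 0)
  # orthonormal T keeps it in [0, 1]
  set.seed(306)
  Q <- qr.Q(qr(matrix(rnorm(M * 12), M, 12)))
  f <- mixing_fraction(t(Q), b)
  expect_gte(f, 0); expect_lte(f, 1)
  # mode aligned with one bond descriptor
  Tm <- matrix(0, 12, M); Tm[3, 1] <- 1
  expect_equal(mode_character(Tm, 3, "bond", b), 1)
  expect_equal(mode_character(Tm, 3, "angle", b), 0)
  chi <- mode_character(t(Q), 5, "bond", b)
  expect_gte(chi, 0); expect_lte(chi, 1)
  # monomer has no intermolecular descriptors: mixing is zero
  m <- water_monomer(test_params())
  bm <- internal_basis(m, "n2")
  expect_equal(mixing_fraction(diag(3), bm), 0)
})

test_that("g_inv_sqrt inverts the metric on the retained subspace", {
  expect_equal(g_inv_sqrt(diag(3)), diag(3), tolerance = 1e-12)
  expect_equal(g_inv_sqrt(diag(c(4, 4))), diag(c(0.5, 0.5)), tolerance = 1e-12)
  set.seed(307)
  A <- crossprod(matrix(rnorm(64), 8, 8)) + diag(8)
  Gi <- g_inv_sqrt(A)
  expect_equal(Gi %*% A %*% Gi, diag(8), tolerance = 1e-10)
})

test_that("the reduced coordinate set is complete (full-rank forward Jacobian)", {
  set.seed(308)
  gm <- dimer_gm()
  X <- t(replicate(30, as.vector(t(gm$coords + matrix(rnorm(18, sd = 0.05), 6))) /
                     au$bohr_A))
  b <- internal_basis(gm, "n2")
  eb <- ensemble_b(X, b, rep(1, 30), gm$masses * au$amu_me)
  for (red in list(reduce_standard(eb, b), reduce_chem_informed(eb, b))) {
    J <- t(eb$Bbar) %*% red$U     # 3N x (3N-6)
    expect_equal(qr(J)$rank, 12)
  }
})
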