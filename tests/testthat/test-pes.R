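test_that("potential is zero at the monomer equilibrium and quadratic in a bond", {
  p <- test_params()
  m <- water_monomer(p)
  expect_equal(potential_energy(m, p), 0, tolerance = 1e-12)
  expect_lt(max(abs(pes_gradient(m, p))), 1e-10)
  delta <- 0.07
  m2 <- m
  m2$coords[2, ] <- m2$coords[2, ] * (1 + delta)   # stretches bond 1 only
  expect_equal(potential_energy(m2, p), p$k_oh / 2 * (delta * p$l_eq)^2,
               tolerance = 1e-10)
})

test_that("potential matches an independent term-by-term implementation", {
  p <- test_params()
  set.seed(101)
  for (rep in 1:5) {
    d <- initial_geometry(2, p)
    d$coords <- d$coords + matrix(rnorm(18, sd = 0.08), 6)
    expect_equal(potential_energy(d, p), oracle_potential(d, p),
                 tolerance = 1e-10)
    expect_equal(potential_energy(d, p, intermolecular = FALSE),
                 oracle_potential(d, p, intermolecular = FALSE),
                 tolerance = 1e-10)
  }
  tri <- initial_geometry(3, p)
  expect_equal(potential_energy(tri, p), oracle_potential(tri, p),
               tolerance = 1e-9)
})

test_that("analytic gradient agrees with finite differences", {
  p <- test_params()
  set.seed(102)
  for (rep in 1:4) {
    d <- initial_geometry(2, p)
    d$coords <- d$coords + matrix(rnorm(18, sd = 0.06), 6)
    gfd <- oracle_fd_gradient(d, function(cf) potential_energy(cf, p))
    expect_lt(max(abs(pes_gradient(d, p) - gfd)), 1e-5)
    # rigid translation: total force vanishes
    expect_lt(max(abs(colSums(pes_gradient(d, p)))), 1e-9)
  }
})

test_that("energy is invariant under rigid rotation and translation", {
  p <- test_params()
  set.seed(103)
  d <- initial_geometry(2, p)
  d$coords <- d$coords + matrix(rnorm(18, sd = 0.05), 6)
  e0 <- potential_energy(d, p)
  e1 <- potential_energy(rotate_conf(d), p)
  expect_equal(e1, e0, tolerance = 1e-10)
})

test_that("degenerate geometries are rejected", {
  p <- test_params()
  d <- initial_geometry(2, p)
  d$coords[4, ] <- d$coords[1, ] + c(0.05, 0, 0)
  expect_error(potential_energy(d, p), "degenerate")
})

test_that("dipole moment is the charge-weighted position sum", {
  p <- test_params()
  m <- water_monomer(p)   # C2 axis along z, in the xz plane
  mu <- dipole_moment(m, p)
  expect_equal(mu[1], 0, tolerance = 1e-12)
  expect_equal(mu[2], 0, tolerance = 1e-12)
  expect_gt(abs(mu[3]), 0.1)
  set.seed(104)
  d <- initial_geometry(2, p)
  d$coords <- d$coords + matrix(rnorm(18, sd = 0.05), 6)
  q <- ifelse(d$elements == "O", p$q_o, p$q_h)
  expect_equal(dipole_moment(d, p), colSums(d$coords * q), tolerance = 1e-10)
  p0 <- p; p0$q_o <- 0; p0$q_h <- 0
  expect_equal(dipole_moment(d, p0), c(0, 0, 0))
})

test_that("guiding function is the product of intramolecular Gaussians", {
  p <- test_params()
  au <- unit_constants()
  m <- water_monomer(p)
  expect_equal(guiding_value(m, p), 1, tolerance = 1e-12)
  delta <- 0.04
  m2 <- m
  m2$coords[2, ] <- m2$coords[2, ] * (1 + delta)
  g <- reduced_masses(p)
  a_l <- sqrt((p$k_oh / au$hartree_kcal * au$bohr_A^2) * (g$mu_oh * au$amu_me))
  dl <- delta * p$l_eq / au$bohr_A
  expect_equal(guiding_value(m2, p), exp(-a_l * dl^2 / 2), tolerance = 1e-10)
  expect_equal(log(guiding_value(m2, p)), guiding_value(m2, p, log = TRUE),
               tolerance = 1e-12)
})

test_that("guiding log-gradient matches finite differences and sums to zero", {
  p <- test_params()
  set.seed(105)
  d <- initial_geometry(2, p)
  d$coords <- d$coords + matrix(rnorm(18, sd = 0.05), 6)
  gfd <- oracle_fd_gradient(d, function(cf) guiding_value(cf, p, log = TRUE))
  g <- guiding_log_gradient(d, p)
  expect_lt(max(abs(g - gfd)), 1e-6)
  expect_lt(max(abs(colSums(g))), 1e-9)
  m <- water_monomer(p)
  expect_lt(max(abs(guiding_log_gradient(m, p))), 1e-10)
})

test_that("local energy kinetic term matches a numeric Laplacian", {
  p <- test_params()
  set.seed(106)
  for (rep in 1:3) {
    d <- initial_geometry(2, p)
    d$coords <- d$coords + matrix(rnorm(18, sd = 0.04), 6)
    el <- local_energy(d, p)
    el_num <- potential_energy(d, p) + oracle_guiding_kinetic(d, p)
    expect_equal(el, el_num, tolerance = 1e-4)
  }
})

test_that("local energy has strongly reduced variance on the intramolecular problem", {
  p <- test_params()
  set.seed(107)
  m <- water_monomer(p)
  els <- vs <- numeric(40)
  for (i in 1:40) {
    mm <- m
    mm$coords <- mm$coords + matrix(rnorm(9, sd = 0.04), 3)
    els[i] <- local_energy(mm, p, intermolecular = FALSE)
    vs[i] <- potential_energy(mm, p, intermolecular = FALSE)
  }
  # the guide is the small-amplitude ground state; curvilinear corrections
  # leave a small residual variance, far below the bare-potential variance
  expect_lt(var(els), 0.1 * var(vs))
  h <- local_mode_harmonics(p)
  zpe_harm <- (2 * h[["stretch"]] + h[["bend"]]) / 2 / 219474.6313632 * 627.509474063
  expect_lt(abs(mean(els) - zpe_harm), 0.6)   # kcal/mol
})

test_that("reduced masses follow the two-body and bend closed forms", {
  p <- test_params()
  g <- reduced_masses(p)
  expect_equal(g$mu_oh, p$m_o * p$m_h / (p$m_o + p$m_h), tolerance = 1e-12)
  expect_equal(g$mu_oh, 0.9483, tolerance = 2e-4)
  expect_equal(g$mu_a,
               p$l_eq^2 / 2 / (1 / p$m_h + (1 - cos(p$theta_eq)) / p$m_o),
               tolerance = 1e-12)
  # m_O -> infinity limit: mu_OH -> m_H
  p2 <- p; p2$m_o <- 1e9
  expect_equal(reduced_masses(p2)$mu_oh, p$m_h, tolerance = 1e-6)
})

test_that("local-mode harmonic scales as sqrt(k)", {
  p <- test_params()
  h1 <- local_mode_harmonics(p)
  p2 <- p; p2$k_oh <- 4 * p$k_oh; p2$k_a <- 4 * p$k_a
  h2 <- local_mode_harmonics(p2)
  expect_equal(h2, 2 * h1, tolerance = 1e-10)
})

test_that("monomer Hessian frequencies bracket the local-mode estimates", {
  p <- test_params()
  nm <- monomer_normal_modes(p)
  h <- local_mode_harmonics(p)
  expect_equal(length(nm), 3)
  # bend normal mode within 1% of the local-mode bend (weak G-matrix coupling)
  expect_lt(abs(nm[1] - h[["bend"]]) / h[["bend"]], 0.01)
  # symmetric/asymmetric stretches split around the local-mode value
  expect_lt(nm[2], h[["stretch"]])
  expect_gt(nm[3], h[["stretch"]])
})
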