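test_that("free diffusion spreads with variance 2 D tau and scales with 1/m", {
  # two "atoms" of different mass, no potential (omega = 0), branching inert
  sys <- harmonic_system(mass = c(1, 16), omega = 0)
  cfg <- dmc_config(n_walkers = 3000, dtau = 0.05, tau_total = 10,
                    tau_eq = 5, diffusion_only_steps = 0, tau_dw = 0,
                    guided = FALSE, n_snapshots = 1, seed = 5)
  run <- run_dmc(sys, cfg)
  X <- run$snapshots[[1]]$x
  n_steps <- 200
  v_light <- apply(X[, 1:3], 2, var)
  v_heavy <- apply(X[, 4:6], 2, var)
  expect_equal(mean(v_light), 2 * 0.5 * 0.05 * n_steps, tolerance = 0.06)
  expect_equal(mean(v_heavy) / mean(v_light), 1 / 16, tolerance = 0.1)
})

test_that("1-D harmonic ZPE is recovered and bias shrinks with walker count", {
  sys <- harmonic_system(mass = 1, omega = 1)   # E0 = 1.5 for 3 dof
  zpes <- sapply(c(200, 2000), function(nw) {
    cfg <- dmc_config(n_walkers = nw, dtau = 0.02, tau_total = 150,
                      tau_eq = 50, tau_dw = 0, guided = FALSE, seed = 9)
    zpe(run_dmc(sys, cfg))
  })
  expect_lt(abs(zpes[2] - 1.5), 0.02)
  expect_lt(abs(zpes[2] - 1.5), abs(zpes[1] - 1.5) + 0.02)
})

test_that("the exact guide gives zero-variance local energy and exact ZPE", {
  sys <- harmonic_system(mass = 2, omega = c(1, 1.5, 2.3), guided = TRUE)
  cfg <- dmc_config(n_walkers = 400, dtau = 0.02, tau_total = 60, tau_eq = 20,
                    tau_dw = 0, guided = TRUE, seed = 10)
  run <- run_dmc(sys, cfg)
  expect_equal(zpe(run), sys$e0_exact, tolerance = 1e-10)
  expect_equal(sd(run$vref[1500:3000]), 0, tolerance = 1e-10)
  expect_gt(run$acceptance, 0.95)
})

test_that("guided sampling is stationary on psi_guide^2 (moment test)", {
  omega <- 1.3
  sys <- harmonic_system(mass = 1, omega = omega, guided = TRUE)
  cfg <- dmc_config(n_walkers = 2000, dtau = 0.05, tau_total = 100,
                    tau_eq = 50, tau_dw = 2, n_dw = 2, guided = TRUE,
                    n_snapshots = 10, seed = 11)
  run <- run_dmc(sys, cfg)
  # sampled density is psi0 * psi_g = psi0^2, with variance 1/(2 m omega)
  x2 <- mean(sapply(run$snapshots, function(s) mean(s$x[, 1]^2)))
  expect_equal(x2, 1 / (2 * omega), tolerance = 0.05)
  # amplitude-weighted <x^2> (Eq 6 weights) agrees too: W_DW is uniform for
  # the exact guide, up to resampling noise
  expect_equal(expectation(run, function(X) X[, 1]^2), 1 / (2 * omega),
               tolerance = 0.05)
})

test_that("discrete and continuous weighting agree statistically on the dimer", {
  p <- test_params()
  gm <- dimer_gm()
  sys <- water_system(gm, p, guided = TRUE)
  z <- sapply(1:3, function(s) {
    zc <- zpe(run_dmc(sys, dmc_config(n_walkers = 600, tau_total = 4000,
                                      tau_eq = 2000, tau_dw = 0, guided = TRUE,
                                      weighting = "continuous", seed = 60 + s)),
              "kcal")
    zd <- zpe(run_dmc(sys, dmc_config(n_walkers = 600, tau_total = 4000,
                                      tau_eq = 2000, tau_dw = 0, guided = TRUE,
                                      weighting = "discrete", seed = 60 + s)),
              "kcal")
    c(zc, zd)
  })
  se <- sqrt(var(z[1, ]) / 3 + var(z[2, ]) / 3)
  expect_lt(abs(mean(z[1, ]) - mean(z[2, ])), max(3 * se, 0.15))
})

test_that("guiding reduces the V_ref variance at equal walker count", {
  p <- test_params()
  sys <- water_system(dimer_gm(), p)
  cfg_g <- dmc_config(n_walkers = 800, tau_total = 3000, tau_eq = 1500,
                      tau_dw = 0, guided = TRUE, seed = 14)
  cfg_u <- dmc_config(n_walkers = 800, tau_total = 3000, tau_eq = 1500,
                      tau_dw = 0, guided = FALSE, seed = 14)
  vg <- var(tail(run_dmc(sys, cfg_g)$vref, 1500))
  vu <- var(tail(run_dmc(sys, cfg_u)$vref, 1500))
  expect_lt(vg / vu, 1)
})

test_that("continuous-weighting resampling keeps weights in a bounded band", {
  p <- test_params()
  sys <- water_system(dimer_gm(), p, guided = TRUE)
  cfg <- dmc_config(n_walkers = 500, tau_total = 3000, tau_eq = 1500,
                    tau_dw = 0, guided = TRUE, seed = 15)
  run <- run_dmc(sys, cfg)
  for (s in run$snapshots) {
    expect_gt(min(s$w), 0.004)       # threshold 0.01, halved duplicates
    expect_equal(mean(s$w), 1, tolerance = 0.3)
  }
})

test_that("descendant weights are uniform for constant potential and normalize the HO moment", {
  sys0 <- harmonic_system(mass = 1, omega = 0)
  cfg <- dmc_config(n_walkers = 300, dtau = 0.05, tau_total = 20, tau_eq = 10,
                    tau_dw = 2, n_dw = 1, guided = FALSE, n_snapshots = 3,
                    seed = 16)
  run0 <- run_dmc(sys0, cfg)
  for (s in run0$snapshots)
    expect_lt(diff(range(s$wdw)), 1e-10)
  # tau_dw = 0 leaves all descendant weights at 1
  run00 <- descendant_weights(run0, tau_dw = 0)
  expect_true(all(vapply(run00$snapshots,
                         function(s) all(s$wdw == 1), logical(1))))
  # 1-D HO: amplitude-weighted <x^2> = 1/(2 m omega)
  sys <- harmonic_system(mass = 1.5, omega = 0.8)
  cfgh <- dmc_config(n_walkers = 2500, dtau = 0.05, tau_total = 150,
                     tau_eq = 75, tau_dw = 5, n_dw = 3, guided = FALSE,
                     n_snapshots = 10, seed = 17)
  runh <- run_dmc(sys, cfgh)
  expect_equal(expectation(runh, function(X) X[, 1]^2),
               1 / (2 * 1.5 * 0.8), tolerance = 0.06)
})

test_that("expectation reduces to plain and single-walker means in edge cases", {
  fake <- structure(list(
    snapshots = list(list(x = matrix(1:8, 4, 2), w = rep(1, 4),
                          wdw = rep(1, 4))),
    config = list(guided = FALSE),
    system = list(model = NULL)), class = "dmc_run")
  expect_equal(expectation(fake, function(X) X[, 1]), mean(1:4))
  fake$snapshots[[1]]$wdw <- c(0, 0, 1, 0)
  expect_equal(expectation(fake, function(X) X[, 1]), 3)
  # brute-force weighted sum
  fake$snapshots[[1]]$wdw <- c(0.2, 1.4, 0.1, 2)
  fake$snapshots[[1]]$w <- c(1, 0.5, 2, 1)
  wt <- c(0.2, 1.4, 0.1, 2) * c(1, 0.5, 2, 1)
  expect_equal(expectation(fake, function(X) X[, 1]),
               sum(wt * (1:4)) / sum(wt))
})

test_that("effective sample fraction is 1 without DW and decays with tau_DW", {
  run0 <- descendant_weights(monomer_run(), tau_dw = 0)
  expect_equal(effective_sample_fraction(run0), 1)
  # dimer: local-energy fluctuations concentrate descendant weights
  sys <- water_system(dimer_gm(), test_params(), guided = TRUE)
  run <- run_dmc(sys, dmc_config(n_walkers = 300, tau_total = 2000,
                                 tau_eq = 1000, n_snapshots = 5, tau_dw = 0,
                                 guided = TRUE, seed = 19))
  fr <- sapply(c(500, 2000), function(td)
    effective_sample_fraction(descendant_weights(run, tau_dw = td, n_dw = 1)))
  expect_true(all(diff(fr) <= 0))
  expect_lt(fr[2], 1)
})

test_that("runs are deterministic given the seed", {
  sys <- harmonic_system(mass = 1, omega = 1)
  cfg <- dmc_config(n_walkers = 200, dtau = 0.05, tau_total = 20, tau_eq = 10,
                    tau_dw = 1, n_dw = 2, guided = FALSE, n_snapshots = 3,
                    seed = 18)
  r1 <- run_dmc(sys, cfg)
  r2 <- run_dmc(sys, cfg)
  expect_identical(r1$vref, r2$vref)
  expect_identical(r1$snapshots[[3]]$x, r2$snapshots[[3]]$x)
  expect_identical(r1$snapshots[[3]]$wdw, r2$snapshots[[3]]$wdw)
})
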