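# Expensive shared fixtures, built once per test session.  Problem sizes are
# scaled-down versions of the production protocol; the methods vignette
# records the sizes used.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

test_params <- function() cached("params", qspcfw_params())

dimer_catalog <- function() cached("dimer_catalog", {
  isomer_search(2, test_params(), n_iter = 1200, seed = 11)
})

dimer_gm <- function() dimer_catalog()$minima[[1]]

# guided continuous dimer runs for spectroscopy: 2 concatenated repetitions,
# N_w = 5000, tau = 20000 (tau_eq = 10000), tau_DW = 1000, N_DW = 3 -- the
# same scaled protocol the acceptance script runs
dimer_runs <- function() cached("dimer_runs", {
  sys <- water_system(dimer_gm(), test_params(), guided = TRUE)
  lapply(1:2, function(r) {
    cfg <- dmc_config(n_walkers = 5000, dtau = 1, tau_total = 20000,
                      tau_eq = 10000, n_snapshots = 20, tau_dw = 1000,
                      n_dw = 3, guided = TRUE, seed = 300 + r)
    run_dmc(sys, cfg)
  })
})

dimer_walkers <- function() cached("dimer_walkers", {
  gather_walkers(dimer_runs(), dimer_gm())
})

dimer_gspa <- function(scheme, level) {
  cached(paste("gspa", scheme, level, sep = "_"), {
    gspa_modes(dimer_walkers(), scheme = scheme, level = level)
  })
}

trimer_catalog <- function() cached("trimer_catalog", {
  isomer_search(3, test_params(), n_iter = 1500, seed = 12)
})

trimer_run <- function() cached("trimer_run", {
  sys <- water_system(trimer_catalog()$minima[[1]], test_params(), guided = TRUE)
  cfg <- dmc_config(n_walkers = 2000, dtau = 1, tau_total = 16000,
                    tau_eq = 8000, n_snapshots = 20, tau_dw = 800,
                    n_dw = 2, guided = TRUE, seed = 41)
  run_dmc(sys, cfg)
})

trimer_gspa <- function(level) {
  cached(paste0("trimer_gspa_", level), {
    gspa_modes(trimer_run(), reference = trimer_catalog()$minima[[1]],
               scheme = "chem_informed", level = level)
  })
}

# small monomer run used by unit tests of the analysis layer
monomer_run <- function() cached("monomer_run", {
  sys <- water_system(water_monomer(test_params()), test_params(), guided = TRUE)
  cfg <- dmc_config(n_walkers = 600, dtau = 1, tau_total = 4000,
                    tau_eq = 2000, n_snapshots = 10, tau_dw = 400,
                    n_dw = 2, guided = TRUE, seed = 21)
  run_dmc(sys, cfg)
})

monomer_gspa <- function() cached("monomer_gspa", {
  gspa_modes(monomer_run(), scheme = "chem_informed", level = "n2")
})
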