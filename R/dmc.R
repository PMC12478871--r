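#' DMC run configuration
#'
#' Holds the propagation protocol.  Defaults follow the standard production
#' protocol: total imaginary time 50000 au with time step 1 au, 30000 au of
#' equilibration whose first 50 steps are diffusion-only (no branching), 20
#' wave-function snapshots at even intervals over the final 20000 au,
#' continuous weighting with resampling threshold 0.01, guided sampling,
#' descendant-weighting time 1000 au averaged over 3 repetitions.
#'
#' @param n_walkers Walker count.
#' @param dtau Imaginary-time step (au).
#' @param tau_total Total propagation time (au).
#' @param tau_eq Equilibration time (au); snapshots and the ZPE average use
#'   only the collection window `tau_total - tau_eq`.
#' @param diffusion_only_steps Initial steps with pure diffusion.
#' @param n_snapshots Snapshots collected over the collection window.
#' @param weighting "continuous" or "discrete".
#' @param guided Use the intramolecular guiding function.
#' @param resample_threshold Continuous-weighting removal threshold.
#' @param tau_dw Descendant-weighting time (au); 0 disables.
#' @param n_dw Independent descendant-weighting repetitions per snapshot.
#' @param seed Integer RNG seed (the run is reproducible given the seed).
#' @param alpha Population-control gain; default `1/dtau`.
#' @param branch_cap Maximum copies per discrete branching event.
#' @return Object of class `dmc_config`.
#' @export
dmc_config <- function(n_walkers = 10000, dtau = 1, tau_total = 50000,
                       tau_eq = 30000, diffusion_only_steps = 50,
                       n_snapshots = 20,
                       weighting = c("continuous", "discrete"),
                       guided = TRUE, resample_threshold = 0.01,
                       tau_dw = 1000, n_dw = 3, seed = 1,
                       alpha = NULL, branch_cap = 3) {
  weighting <- match.arg(weighting)
  if (n_walkers < 2) stop("need at least 2 walkers")
  if (tau_eq >= tau_total) stop("tau_eq must be smaller than tau_total")
  if (resample_threshold <= 0 || resample_threshold >= 1)
    stop("resample_threshold must be in (0, 1)")
  if (is.null(alpha)) alpha <- 1 / dtau
  structure(list(n_walkers = as.integer(n_walkers), dtau = dtau,
                 tau_total = tau_total, tau_eq = tau_eq,
                 diffusion_only_steps = as.integer(diffusion_only_steps),
                 n_snapshots = as.integer(n_snapshots), weighting = weighting,
                 guided = isTRUE(guided),
                 resample_threshold = resample_threshold,
                 tau_dw = tau_dw, n_dw = as.integer(n_dw),
                 seed = as.integer(seed), alpha = alpha,
                 branch_cap = as.integer(branch_cap)),
            class = "dmc_config")
}

#' Water-cluster DMC system
#'
#' Binds initial geometries, the surface and sampling choices into the
#' object `run_dmc()` propagates.
#'
#' @param init A `wc_configuration` or a list of them (walkers are spread
#'   cyclically over the list, e.g. for an isomer-mixture initialization).
#' @param params `qspcfw_params`.
#' @param guided Use the intramolecular guiding function.
#' @param intermolecular Include intermolecular terms.
#' @return Object of class `dmc_system`.
#' @export
water_system <- function(init, params = qspcfw_params(), guided = TRUE,
                         intermolecular = TRUE) {
  if (inherits(init, "wc_configuration")) init <- list(init)
  ref <- init[[1]]
  x0 <- do.call(rbind, lapply(init, .coords_au))
  spec <- .model_spec(ref, params, guided = guided,
                      intermolecular = intermolecular)
  structure(list(model = spec, x0 = x0, reference = ref, params = params,
                 kind = "water"),
            class = "dmc_system")
}

#' Separable harmonic reference system
#'
#' A toy system of independent harmonic coordinates (atomic units) with
#' known ground-state energy `sum omega/2`, used to validate the sampler and
#' the spectral analysis against closed forms.
#'
#' @param mass Per-"atom" masses in m_e (each atom carries 3 coordinates).
#' @param omega Angular frequencies (au), recycled to 3 per atom.
#' @param x0 Initial coordinates (au), default all zero.
#' @param guided Guide with the exact product ground state.
#' @return Object of class `dmc_system`.
#' @export
harmonic_system <- function(mass, omega, x0 = NULL, guided = FALSE) {
  n_at <- length(mass)
  omega <- rep_len(omega, 3 * n_at)
  if (is.null(x0)) x0 <- rep(0, 3 * n_at)
  spec <- list(type = 1L, mass = mass, omega = omega, guided = isTRUE(guided))
  structure(list(model = spec, x0 = matrix(x0, nrow = 1), reference = NULL,
                 kind = "harmonic",
                 e0_exact = sum(rep(mass, each = 3) * 0 + omega) / 2),
            class = "dmc_system")
}

#' Run diffusion Monte Carlo
#'
#' Full protocol: initialization of all walkers at the supplied geometry (or
#' spread over a mixture), an initial pure-diffusion phase, equilibration
#' with branching, then snapshot collection over the final
#' `tau_total - tau_eq`.  The zero-point energy estimate is the mean of
#' `V_ref` over the collection window.  When `tau_dw > 0` every snapshot is
#' continued for `tau_dw` in `n_dw` independent repetitions to obtain
#' descendant weights (the `|psi|^2` weights of all amplitude-level
#' expectations).
#'
#' @param system `dmc_system` from [water_system()] or [harmonic_system()].
#' @param config `dmc_config`.
#' @return Object of class `dmc_run`: `vref` trace (hartree), `population`
#'   (total weight or walker count per step), `acceptance` rate,
#'   `snapshots` (each with coordinates in bohr, weights `w`, descendant
#'   weights `wdw`), `zpe` (hartree), plus the inputs.
#' @export
run_dmc <- function(system, config = dmc_config()) {
  stopifnot(inherits(system, "dmc_system"), inherits(config, "dmc_config"))
  n_steps <- round(config$tau_total / config$dtau)
  n_eq <- round(config$tau_eq / config$dtau)
  n_coll <- n_steps - n_eq
  snap_steps <- n_eq + unique(round(seq_len(config$n_snapshots) *
                                      n_coll / config$n_snapshots))
  discrete <- config$weighting == "discrete"
  system$model$guided <- config$guided
  res <- dmc_cpp(system$model, system$x0, config$n_walkers, config$dtau,
                 n_steps, config$diffusion_only_steps,
                 as.integer(snap_steps), discrete, TRUE,
                 config$resample_threshold, config$alpha, config$branch_cap,
                 config$seed, 0)
  if (isTRUE(res$extinct))
    stop("DMC population went extinct; increase n_walkers or check V_ref control")
  run <- structure(list(vref = res$vref, population = res$population,
                        acceptance = res$acceptance,
                        snapshots = res$snapshots,
                        zpe = mean(res$vref[(n_eq + 1):n_steps]),
                        system = system, config = config,
                        snap_steps = snap_steps),
                   class = "dmc_run")
  if (config$tau_dw > 0) run <- descendant_weights(run) else {
    for (i in seq_along(run$snapshots))
      run$snapshots[[i]]$wdw <- rep(1, length(run$snapshots[[i]]$w))
  }
  run
}

#' @export
print.dmc_run <- function(x, ...) {
  cat(sprintf("DMC run: %d walkers, %s weighting, %s\n",
              x$config$n_walkers, x$config$weighting,
              if (x$config$guided) "guided" else "unguided"))
  cat(sprintf("  ZPE (mean V_ref over collection): %.6f hartree = %.3f kcal/mol\n",
              x$zpe, x$zpe * .HARTREE_KCAL))
  if (!is.na(x$acceptance))
    cat(sprintf("  Metropolis acceptance: %.3f\n", x$acceptance))
  cat(sprintf("  %d snapshots\n", length(x$snapshots)))
  invisible(x)
}

#' Descendant weights for every snapshot of a run
#'
#' Continuous weighting: each snapshot is propagated `tau_dw` further and a
#' walker's descendant weight is the summed final weight of its descendants
#' divided by its weight at the snapshot (duplicates created by resampling
#' credit their ancestor).  Discrete weighting: the descendant count.
#' Averaged over `n_dw` independent repetitions.
#'
#' @param run `dmc_run`.
#' @param tau_dw,n_dw Override the values stored in the run config.
#' @return The run with `wdw` filled in for every snapshot.
#' @export
descendant_weights <- function(run, tau_dw = NULL, n_dw = NULL) {
  cfg <- run$config
  if (is.null(tau_dw)) tau_dw <- cfg$tau_dw
  if (is.null(n_dw)) n_dw <- cfg$n_dw
  n_steps <- round(tau_dw / cfg$dtau)
  discrete <- cfg$weighting == "discrete"
  for (i in seq_along(run$snapshots)) {
    s <- run$snapshots[[i]]
    if (n_steps == 0) { run$snapshots[[i]]$wdw <- rep(1, length(s$w)); next }
    run$snapshots[[i]]$wdw <-
      dmc_descendant_cpp(run$system$model, s$x, s$w, s$vref, cfg$dtau,
                         n_steps, n_dw, discrete, cfg$resample_threshold,
                         cfg$alpha, cfg$branch_cap, cfg$seed,
                         1000 + i)
  }
  run$tau_dw_used <- tau_dw
  run
}

#' Weighted expectation values over the sampled wave function
#'
#' Amplitude mode weights each walker by `W_DW * w` (expectations over
#' `|psi_0|^2`); wavefunction mode weights by `w / psi_guide` (projections of
#' `psi_0` itself, e.g. coordinate histograms).
#'
#' @param run `dmc_run`.
#' @param f Function taking a walkers x dof coordinate matrix (bohr) and
#'   returning a per-walker vector or matrix of observable values.
#' @param mode "amplitude" or "wavefunction".
#' @return Weighted mean of the observable (vector if `f` returns a matrix).
#' @export
expectation <- function(run, f, mode = c("amplitude", "wavefunction")) {
  mode <- match.arg(mode)
  num <- NULL
  den <- 0
  for (s in run$snapshots) {
    v <- f(s$x)
    v <- if (is.matrix(v)) v else matrix(v, ncol = 1)
    wt <- .walker_weights(run, s, mode)
    num <- if (is.null(num)) colSums(v * wt) else num + colSums(v * wt)
    den <- den + sum(wt)
  }
  drop(num / den)
}

.walker_weights <- function(run, snapshot, mode) {
  if (mode == "amplitude") {
    wdw <- snapshot$wdw
    if (is.null(wdw)) stop("snapshot has no descendant weights; run descendant_weights()")
    return(snapshot$w * wdw)
  }
  if (run$config$guided) {
    lg <- guiding_log_ensemble_cpp(run$system$model, snapshot$x)
    snapshot$w * exp(-lg)
  } else snapshot$w
}

#' Fraction of walkers with numerically nonzero descendant weight
#'
#' Diagnostic of descendant-weighting noise: the fraction of walkers whose
#' descendant weight exceeds `threshold`, averaged over snapshots.  It
#' decays with the descendant-weighting time and faster for larger
#' clusters, shrinking the effective sample for amplitude-level averages.
#'
#' @param run `dmc_run` with descendant weights.
#' @param threshold Numerical-zero cutoff.
#' @return Mean fraction in `[0, 1]`.
#' @export
effective_sample_fraction <- function(run, threshold = 1e-7) {
  fr <- vapply(run$snapshots, function(s) {
    if (is.null(s$wdw)) stop("snapshot has no descendant weights")
    mean(s$wdw > threshold)
  }, numeric(1))
  mean(fr)
}

#' Zero-point energy of a run
#'
#' Mean reference energy over the collection window.
#'
#' @param run `dmc_run`.
#' @param units "hartree", "kcal" or "cm".
#' @return Scalar energy.
#' @export
zpe <- function(run, units = c("hartree", "kcal", "cm")) {
  units <- match.arg(units)
  switch(units, hartree = run$zpe,
         kcal = run$zpe * .HARTREE_KCAL,
         cm = run$zpe * .HARTREE_CM)
}
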