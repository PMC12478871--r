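#' Gather Eckart-aligned walkers from one or more DMC runs
#'
#' Concatenates the snapshots of the given runs (independent repetitions are
#' concatenated to reduce statistical noise), aligns every walker to the
#' reference structure in the Eckart frame, and evaluates the per-walker
#' potential energy and point-charge dipole.
#'
#' @param runs A `dmc_run` or list of them (same system).
#' @param reference Reference `wc_configuration` (usually the global
#'   minimum).
#' @return List with `X` (walkers x 3N aligned coordinates, bohr), weights
#'   `w`, descendant weights `wdw`, `V` (hartree), `mu` (walkers x 3,
#'   e bohr), and the reference coordinates in bohr.
#' @export
gather_walkers <- function(runs, reference) {
  if (inherits(runs, "dmc_run")) runs <- list(runs)
  ref_au <- matrix(.coords_au(reference), ncol = 3, byrow = TRUE)
  m <- reference$masses * .AMU_ME
  msum <- sum(m)
  rc <- sweep(ref_au, 2, colSums(ref_au * m) / msum)
  Xs <- list(); ws <- list(); wd <- list(); Vs <- list(); gid <- list()
  snap_no <- 0
  for (run in runs) {
    model <- run$system$model
    for (s in run$snapshots) {
      snap_no <- snap_no + 1
      if (is.null(s$wdw)) stop("snapshots lack descendant weights")
      V <- potential_ensemble_cpp(model, s$x)
      Xa <- s$x
      for (j in seq_len(nrow(Xa))) {
        xm <- matrix(Xa[j, ], ncol = 3, byrow = TRUE)
        Xa[j, ] <- as.vector(t(.eckart_coords(xm, rc, m, msum)))
      }
      Xs[[length(Xs) + 1]] <- Xa
      ws[[length(ws) + 1]] <- s$w
      wd[[length(wd) + 1]] <- s$wdw
      Vs[[length(Vs) + 1]] <- V
      gid[[length(gid) + 1]] <- rep(snap_no, length(s$w))
    }
  }
  X <- do.call(rbind, Xs)
  mu <- dipole_ensemble_cpp(runs[[1]]$system$model, X)
  structure(list(X = X, w = unlist(ws), wdw = unlist(wd), V = unlist(Vs),
                 mu = mu, snapshot = unlist(gid), reference_au = ref_au,
                 reference = reference),
            class = "walker_set")
}

.wmean <- function(v, w) sum(v * w) / sum(w)

#' Fundamental frequency from sampled mode coordinates
#'
#' Core single-mode computation: given amplitude-weighted
#' samples of one mass-weighted vibrational coordinate and the per-sample
#' potential energy, the excitation `f = v - <v>` yields the potential gap
#' `dV = <V f^2>/<f^2> - <V>` and the kinetic gap
#' `dT = (hbar^2/2) <f^2> / (<f^4> - <f^2>^2)`; the fundamental is their
#' sum.  Exposed separately so closed-form oscillators can be fed directly.
#'
#' @param v Samples of the mass-weighted coordinate (au).
#' @param V Potential energies (hartree).
#' @param w Weights.
#' @return List with `dV`, `dT`, `freq` (all hartree), `freq_cm`,
#'   `degenerate` flag (insufficient sampling: `<f^4> <= <f^2>^2`).
#' @export
gspa_fundamental <- function(v, V, w) {
  .gspa_fundamental_f(v - .wmean(v, w), V, w)
}

.gspa_fundamental_f <- function(f, V, w) {
  m2 <- .wmean(f^2, w)
  m4 <- .wmean(f^4, w)
  if (m2 <= 0 || m4 - m2^2 <= 0)
    return(list(dV = NA_real_, dT = NA_real_, freq = NA_real_,
                freq_cm = NA_real_, degenerate = TRUE))
  dV <- .wmean(V * f^2, w) / m2 - .wmean(V, w)
  dT <- 0.5 * m2 / (m4 - m2^2)
  list(dV = dV, dT = dT, freq = dV + dT, freq_cm = (dV + dT) * .HARTREE_CM,
       degenerate = FALSE)
}

#' Effective-harmonic frequency from a covariance eigenvalue
#'
#' For a harmonic ground state the variance of a mass-weighted normal
#' coordinate is `hbar/(2 omega)`, so the PCA eigenvalue maps to
#' `omega = hbar/(2 lambda)`.  Anharmonicity is not captured; the GSPA
#' fundamental is generally more accurate.
#'
#' @param lambda Covariance eigenvalue(s) in au.
#' @return Frequency(ies) in cm^-1.
#' @export
effective_harmonic_frequency <- function(lambda) {
  0.5 / lambda * .HARTREE_CM
}

#' GSPA vibrational analysis of DMC runs
#'
#' Full ground-state probability amplitude analysis: project aligned
#' walkers onto redundant internal coordinates, reduce redundancy (standard
#' or chemically informed SVD), build the ensemble kinetic metric
#' `<G> = U^T <B Lambda B^T> U`, diagonalize the mass-weighted covariance
#' `G^{-1/2} C G^{-1/2}` and compute per-mode fundamentals (potential +
#' kinetic gaps), relative IR intensities from the point-charge dipole, and
#' character diagnostics.
#'
#' Modes are indexed by descending covariance eigenvalue, which ranks them
#' more stably than frequency.
#'
#' @param runs `dmc_run`, list of runs (concatenated repetitions), or a
#'   pre-gathered `walker_set` from [gather_walkers()] (lets several
#'   scheme/basis analyses share one alignment pass).
#' @param reference Reference structure (global minimum); default: minimize
#'   the run's initial configuration.
#' @param scheme "chem_informed" or "standard" redundancy reduction.
#' @param level Redundant basis, "n2" or "n3".
#' @param inter_angle_rule See [internal_basis()].
#' @param center Centering of the excitation polynomial `f = v - <v>`:
#'   `"ensemble"` uses the concatenated-ensemble mean (default),
#'   `"snapshot"` recenters within each snapshot, which suppresses slow
#'   population drift at the cost of a little variance.
#' @return Object of class `gspa_result`: `modes` data frame (eigenvalue,
#'   frequency and gaps in cm^-1, relative intensity, bond/angle/inter
#'   characters, assignment), `cif` diagnostics, `mixing` fraction, and
#'   `vb`, the vibrational basis (U, P, G, `G^{-1/2}`, eigenvalues, mean
#'   mode coordinates, reference) used by the reverse mapping.
#' @export
gspa_modes <- function(runs, reference = NULL,
                       scheme = c("chem_informed", "standard"),
                       level = c("n2", "n3"),
                       inter_angle_rule = c("middle_vertex", "any_cross",
                                            "cross_arms", "span_ends",
                                            "strict_cross"),
                       center = c("ensemble", "snapshot")) {
  scheme <- match.arg(scheme)
  level <- match.arg(level)
  center <- match.arg(center)
  if (inherits(runs, "walker_set")) {
    gw <- runs
    reference <- gw$reference
  } else {
    run1 <- if (inherits(runs, "dmc_run")) runs else runs[[1]]
    if (run1$system$kind != "water")
      stop("gspa_modes expects water-system runs")
    if (is.null(reference))
      reference <- minimize_geometry(run1$system$reference,
                                     run1$system$params)$conf
    gw <- gather_walkers(runs, reference)
  }
  basis <- internal_basis(reference, level, inter_angle_rule)
  wt <- gw$w * gw$wdw
  masses_me <- reference$masses * .AMU_ME
  eb <- ensemble_b(gw$X, basis, wt, masses_me)
  red <- if (scheme == "standard") reduce_standard(eb, basis)
         else reduce_chem_informed(eb, basis)
  G <- g_matrix(eb, red)
  Gi2 <- g_inv_sqrt(G)
  rmat <- descriptor_values(gw$X, basis)
  q <- rmat %*% red$U
  qbar <- colSums(q * wt) / sum(wt)
  qc <- sweep(q, 2, qbar)
  C <- crossprod(qc * wt, qc) / sum(wt)
  A <- Gi2 %*% C %*% Gi2
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  P <- .fix_signs(e$vectors)          # descending eigenvalues
  lambda <- e$values
  vmw <- q %*% Gi2 %*% P
  vbar <- colSums(vmw * wt) / sum(wt)
  fmat <- sweep(vmw, 2, vbar)
  if (center == "snapshot") {
    for (g in unique(gw$snapshot)) {
      sel <- gw$snapshot == g
      mg <- colSums(vmw[sel, , drop = FALSE] * wt[sel]) / sum(wt[sel])
      fmat[sel, ] <- sweep(vmw[sel, , drop = FALSE], 2, mg)
    }
  }
  Tm <- transform_matrix(P, red)
  nvib <- length(lambda)
  rows <- vector("list", nvib)
  for (l in seq_len(nvib)) {
    fr <- .gspa_fundamental_f(fmat[, l], gw$V, wt)
    chib <- mode_character(Tm, l, "bond", basis)
    chia <- mode_character(Tm, l, "angle", basis)
    chii <- mode_character(Tm, l, "inter", basis)
    # strict majority call: heavily mixed modes stay "intermolecular"
    typ <- if (chib > 0.5) "stretch" else if (chia > 0.5) "bend"
           else "intermolecular"
    f <- fmat[, l]
    m2 <- .wmean(f^2, wt)
    tm <- colSums(gw$mu * f * wt) / sum(wt)
    inten <- if (fr$degenerate) 0 else fr$freq * sum(tm^2) / m2
    dom <- which.max(Tm[l, ]^2)
    rows[[l]] <- data.frame(
      mode = l, lambda = lambda[l],
      freq_cm = fr$freq_cm, dV_cm = fr$dV * .HARTREE_CM,
      dT_cm = fr$dT * .HARTREE_CM,
      eff_harmonic_cm = effective_harmonic_frequency(lambda[l]),
      intensity = inten,
      chi_bond = chib, chi_angle = chia, chi_inter = chii,
      character = typ, dominant = basis$label[dom],
      stringsAsFactors = FALSE)
  }
  modes <- do.call(rbind, rows)
  if (any(modes$intensity > 0, na.rm = TRUE))
    modes$intensity <- modes$intensity / max(modes$intensity, na.rm = TRUE)
  vb <- structure(list(U = red$U, P = P, G = G, Ginv2 = Gi2,
                       lambda = lambda, vmw_mean = vbar, basis = basis,
                       reference = reference, scheme = scheme, level = level,
                       masses_me = masses_me),
                  class = "vibrational_basis")
  structure(list(modes = modes, cif = cif_diagnostics(Tm, basis),
                 mixing = mixing_fraction(Tm, basis), Tmat = Tm,
                 vb = vb, scheme = scheme, level = level,
                 vmw = vmw, weights = wt, V = gw$V),
            class = "gspa_result")
}

#' @export
print.gspa_result <- function(x, ...) {
  cat(sprintf("GSPA modes (%s reduction, %s basis); CIF_intra = %.3f\n",
              x$scheme, x$level, x$cif$cif_intra))
  df <- x$modes[, c("mode", "freq_cm", "dV_cm", "dT_cm", "intensity",
                    "chi_bond", "chi_angle", "character")]
  print(format(df, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Select a mode by physical character
#'
#' Convenience accessors for reporting: the lowest-frequency mode whose
#' dominant character is a bend or a stretch, or the mode dominated by a
#' particular descriptor.
#'
#' @param result `gspa_result`.
#' @param what "lowest_bend", "lowest_stretch", or "descriptor".
#' @param descriptor Descriptor index (column of T) when
#'   `what = "descriptor"`: returns the mode with the largest squared
#'   coefficient on that descriptor.
#' @return One row of the mode table.
#' @export
select_mode <- function(result, what = c("lowest_bend", "lowest_stretch",
                                         "descriptor"),
                        descriptor = NULL) {
  what <- match.arg(what)
  md <- result$modes
  if (what == "descriptor") {
    stopifnot(!is.null(descriptor))
    l <- which.max(result$Tmat[, descriptor]^2)
    return(md[l, ])
  }
  typ <- if (what == "lowest_bend") "bend" else "stretch"
  sel <- md[md$character == typ & !is.na(md$freq_cm), ]
  if (!nrow(sel)) stop("no mode with character ", typ)
  sel[which.min(sel$freq_cm), ]
}

#' Index of the hydrogen-bonded donor OH descriptor
#'
#' Identifies, in a reference structure, the OH bond whose hydrogen is
#' closest to an oxygen of another monomer (the donor hydrogen-bonded OH),
#' and returns the index of that bond descriptor in the basis.
#'
#' @param basis `internal_basis`.
#' @param reference `wc_configuration` the basis was built on.
#' @return Column index into the descriptor list.
#' @export
hbonded_oh_descriptor <- function(basis, reference) {
  co <- reference$coords
  el <- reference$elements
  mol <- reference$mol_index
  bonds <- which(basis$kind == "OH_bond")
  best <- Inf; bi <- NA_integer_
  for (b in bonds) {
    h <- basis$j[b]   # bond stored as (O = i, H = j)
    for (o in which(el == "O"))
      if (mol[o] != mol[h]) {
        d <- sqrt(sum((co[h, ] - co[o, ])^2))
        if (d < best) { best <- d; bi <- b }
      }
  }
  bi
}

#' Stick spectrum with Gaussian broadening
#'
#' @param result `gspa_result` (or a data frame with `freq_cm`,
#'   `intensity`).
#' @param fwhm Gaussian full width at half maximum (cm^-1), cosmetic.
#' @param from,to,n Grid for the broadened curve.
#' @return List with `sticks` (frequency, intensity) and `curve`
#'   (data frame `x`, `y`); the integral of the curve equals the summed
#'   stick intensities.
#' @export
vibrational_spectrum <- function(result, fwhm = 10, from = NULL, to = NULL,
                                 n = 2000) {
  md <- if (inherits(result, "gspa_result")) result$modes else result
  md <- md[!is.na(md$freq_cm), ]
  sticks <- data.frame(freq_cm = md$freq_cm, intensity = md$intensity)
  if (!nrow(sticks))
    return(list(sticks = sticks, curve = data.frame(x = numeric(0), y = numeric(0))))
  if (is.null(from)) from <- min(sticks$freq_cm) - 5 * fwhm
  if (is.null(to)) to <- max(sticks$freq_cm) + 5 * fwhm
  x <- seq(from, to, length.out = n)
  sg <- fwhm / (2 * sqrt(2 * log(2)))
  y <- rep(0, n)
  for (i in seq_len(nrow(sticks)))
    y <- y + sticks$intensity[i] * stats::dnorm(x, sticks$freq_cm[i], sg)
  list(sticks = sticks, curve = data.frame(x = x, y = y))
}
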