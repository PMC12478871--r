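#' Eckart alignment to a reference structure
#'
#' Removes the mass-weighted center of mass and rotates the configuration so
#' that the rotational Eckart condition `sum_i m_i x_i_ref x x_i = 0` holds
#' against the reference, which minimizes rotation-vibration coupling.  The
#' rotation is obtained by the Kabsch construction on mass-weighted
#' coordinates (equivalent to solving the Eckart conditions for
#' non-degenerate cases).
#'
#' @param conf `wc_configuration` (or bare n x 3 coordinate matrix).
#' @param reference Reference `wc_configuration` (or matrix).
#' @param masses Atomic masses, required when matrices are passed.
#' @return List with `conf` (aligned configuration or matrix), `rmsd`
#'   (mass-weighted RMSD to the reference, same length unit as the input)
#'   and `rotation` (3 x 3 matrix).
#' @export
eckart_align <- function(conf, reference, masses = NULL) {
  is_conf <- inherits(conf, "wc_configuration")
  x <- if (is_conf) conf$coords else as.matrix(conf)
  r <- if (inherits(reference, "wc_configuration")) reference$coords else as.matrix(reference)
  if (is.null(masses)) {
    if (!is_conf) stop("masses required when aligning bare matrices")
    masses <- conf$masses
  }
  al <- .eckart_core(x, r, masses)
  out_conf <- if (is_conf) { conf$coords <- al$x; conf } else al$x
  list(conf = out_conf, rmsd = al$rmsd, rotation = al$R)
}

.eckart_core <- function(x, r, m) {
  xc <- sweep(x, 2, colSums(x * m) / sum(m))
  rc <- sweep(r, 2, colSums(r * m) / sum(m))
  A <- t(xc * m) %*% rc                 # sum_i m_i x_i r_i^T
  sv <- svd(A)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  xa <- xc %*% t(R)
  rmsd <- sqrt(sum(m * rowSums((xa - rc)^2)) / sum(m))
  list(x = xa, rmsd = rmsd, R = R)
}

# fast path used in walker loops: aligned coordinates only
.eckart_coords <- function(x, rc, m, msum) {
  xc <- sweep(x, 2, colSums(x * m) / msum)
  A <- t(xc * m) %*% rc
  sv <- svd(A)
  d <- sign(det(sv$v %*% t(sv$u)))
  xc %*% (sv$u %*% diag(c(1, 1, d)) %*% t(sv$v))
}

#' Minimize a cluster geometry
#'
#' Quasi-Newton (BFGS) descent on the q-SPC/Fw surface with the analytic
#' gradient, restarted until the gradient norm falls below `tol`.
#'
#' @param conf Starting `wc_configuration`.
#' @param params `qspcfw_params`.
#' @param tol Convergence threshold on the maximum absolute gradient
#'   component (hartree/bohr).
#' @param max_restarts BFGS restarts before giving up.
#' @return List with `conf` (minimized configuration), `energy` (kcal/mol),
#'   `grad_norm` (hartree/bohr) and `converged`.
#' @export
minimize_geometry <- function(conf, params = qspcfw_params(), tol = 1e-8,
                              max_restarts = 6) {
  spec <- .model_spec(conf, params)
  x <- .coords_au(conf)
  fn <- function(z) potential_cpp(spec, z)
  gr <- function(z) gradient_cpp(spec, z)
  converged <- FALSE
  for (r in seq_len(max_restarts)) {
    opt <- stats::optim(x, fn, gr, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-16))
    x <- opt$par
    if (max(abs(gr(x))) < tol) { converged <- TRUE; break }
  }
  g <- gr(x)
  list(conf = .conf_from_au(x, conf), energy = fn(x) * .HARTREE_KCAL,
       grad_norm = max(abs(g)), converged = converged)
}

# permutation/rotation-invariant fingerprint: sorted per-element-pair distances
.fingerprint <- function(conf) {
  co <- conf$coords
  el <- conf$elements
  d <- as.matrix(stats::dist(co))
  iO <- which(el == "O"); iH <- which(el == "H")
  oo <- if (length(iO) > 1) sort(d[iO, iO][upper.tri(d[iO, iO])]) else numeric(0)
  hh <- sort(d[iH, iH][upper.tri(d[iH, iH])])
  oh <- sort(as.vector(d[iO, iH, drop = FALSE]))
  c(oo, oh, hh)
}

.fingerprint_dist <- function(f1, f2) max(abs(f1 - f2))

#' Isomer search by Metropolis Monte Carlo with minimization
#'
#' Explores the cluster landscape with a temperature-annealed Metropolis
#' walk (per-atom Gaussian moves) and periodically minimizes the current
#' configuration; distinct minima are collected into a catalog.  Distinct
#' means different under the permutation/rotation-invariant sorted
#' distance fingerprint, so permutational copies collapse onto one isomer.
#' Doubles as the package's fixture generator: all reference structures are
#' produced by this search, no external geometries are needed.
#'
#' @param n_molecules Cluster size.
#' @param params `qspcfw_params`.
#' Move set: small per-atom Gaussian jitter mixed with rigid-monomer
#' translations and rotations, so the stiff intramolecular modes do not
#' suppress acceptance while the intermolecular arrangement is explored
#' efficiently.
#'
#' @param n_iter Monte Carlo steps.
#' @param step_sd Per-atom jitter width (Angstrom).
#' @param rigid_sd Rigid-monomer translation width (Angstrom); rotation
#'   width is `rigid_sd` radians about the monomer oxygen.
#' @param t_start,t_end Annealing temperatures (K).
#' @param minimize_every Minimize every this many steps.
#' @param seed RNG seed (deterministic catalog for a given seed).
#' @param fp_tol Fingerprint tolerance (Angstrom) for deduplication.
#' @return Object of class `isomer_catalog`: minima sorted by energy
#'   (global minimum first), energies (kcal/mol), fingerprints.
#' @export
isomer_search <- function(n_molecules, params = qspcfw_params(),
                          n_iter = 2000, step_sd = 0.03, rigid_sd = 0.3,
                          t_start = 1500, t_end = 200,
                          minimize_every = 25, seed = 1, fp_tol = 5e-3) {
  set.seed(seed)
  conf <- initial_geometry(n_molecules, params)
  minima <- list(); energies <- numeric(0); fps <- list()
  add_min <- function(m) {
    if (!m$converged || !.is_minimum(m$conf, params)) return(invisible(NULL))
    fp <- .fingerprint(m$conf)
    for (k in seq_along(fps))
      if (length(fps[[k]]) == length(fp) && .fingerprint_dist(fps[[k]], fp) < fp_tol)
        return(invisible(NULL))
    minima[[length(minima) + 1]] <<- m$conf
    energies[length(energies) + 1] <<- m$energy
    fps[[length(fps) + 1]] <<- fp
    invisible(NULL)
  }
  add_min(minimize_geometry(conf, params))
  e <- potential_energy(conf, params)
  n_at <- nrow(conf$coords)
  temps <- t_start * (t_end / t_start)^(seq_len(n_iter) / n_iter)
  for (it in seq_len(n_iter)) {
    prop <- conf
    if (n_molecules > 1 && stats::runif(1) < 0.6) {
      # rigid-monomer move: translate + rotate one molecule about its O
      m <- sample.int(n_molecules, 1)
      idx <- which(conf$mol_index == m)
      o <- idx[conf$elements[idx] == "O"]
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      ang <- stats::rnorm(1, sd = rigid_sd)
      Kx <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
      R <- diag(3) + sin(ang) * Kx + (1 - cos(ang)) * Kx %*% Kx
      rel <- sweep(conf$coords[idx, , drop = FALSE], 2, conf$coords[o, ])
      prop$coords[idx, ] <- sweep(rel %*% t(R), 2,
                                  conf$coords[o, ] + stats::rnorm(3, sd = rigid_sd),
                                  `+`)
    } else {
      prop$coords <- conf$coords + matrix(stats::rnorm(3 * n_at, sd = step_sd),
                                          ncol = 3)
    }
    if (min(stats::dist(prop$coords)) < 0.5) next
    if (n_molecules > 1 && .dissociated(prop)) next
    ep <- potential_energy(prop, params)
    if (ep - e < 0 || stats::runif(1) < exp(-(ep - e) / (.KB_KCAL * temps[it]))) {
      conf <- prop; e <- ep
    }
    if (it %% minimize_every == 0) add_min(minimize_geometry(conf, params))
  }
  ord <- order(energies)
  structure(list(minima = minima[ord], energies = energies[ord],
                 fingerprints = fps[ord], n_molecules = n_molecules,
                 seed = seed),
            class = "isomer_catalog")
}

# finite-difference Hessian check: a stationary point is kept only if no
# eigenvalue beyond the six rigid-motion zeros is significantly negative
.is_minimum <- function(conf, params, h = 1e-3, tol = -1e-7) {
  spec <- .model_spec(conf, params)
  x0 <- .coords_au(conf)
  n <- length(x0)
  hb <- h / .BOHR_A
  H <- matrix(0, n, n)
  for (c in seq_len(n)) {
    xp <- x0; xp[c] <- xp[c] + hb
    xm <- x0; xm[c] <- xm[c] - hb
    H[, c] <- (gradient_cpp(spec, xp) - gradient_cpp(spec, xm)) / (2 * hb)
  }
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sum(ev < tol) == 0
}

.dissociated <- function(conf, cutoff = 5) {
  iO <- which(conf$elements == "O")
  if (length(iO) < 2) return(FALSE)
  d <- as.matrix(stats::dist(conf$coords[iO, , drop = FALSE]))
  diag(d) <- Inf
  any(apply(d, 1, min) > cutoff)
}

#' @export
print.isomer_catalog <- function(x, ...) {
  cat(sprintf("isomer catalog: %d molecules, %d minima (energies kcal/mol)\n",
              x$n_molecules, length(x$minima)))
  for (k in seq_along(x$energies))
    cat(sprintf("  %s%-3d %12.6f\n", if (k == 1) "GM " else "LM ",
                k - 1, x$energies[k]))
  invisible(x)
}

#' Permutation variants of a cluster labeling
#'
#' The group of atom relabelings that leave a water cluster physically
#' unchanged: swapping the two hydrogens within each monomer crossed with
#' relabeling whole monomers, `2^n * n!` maps.  Each map `p` is an index
#' vector such that `coords[p, ]` is the permuted structure; element
#' identity is preserved by construction.
#'
#' @param conf Template `wc_configuration`.
#' @param max_size Guard on the group size.
#' @return List of integer index vectors; the first is the identity.
#' @export
permutation_variants <- function(conf, max_size = 5000) {
  mols <- sort(unique(conf$mol_index))
  n <- length(mols)
  if (2^n * factorial(n) > max_size)
    stop("permutation group too large (", 2^n * factorial(n), " maps)")
  slots <- lapply(mols, function(m) {
    idx <- which(conf$mol_index == m)
    list(O = idx[conf$elements[idx] == "O"],
         H = idx[conf$elements[idx] == "H"])
  })
  perms_of <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  mol_perms <- perms_of(seq_len(n))
  swaps <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  variants <- list()
  nat <- nrow(conf$coords)
  for (mp in mol_perms) {
    for (sr in seq_len(nrow(swaps))) {
      p <- integer(nat)
      for (m in seq_len(n)) {
        src <- slots[[mp[m]]]          # monomer whose atoms land in slot m
        dst <- slots[[m]]
        p[dst$O] <- src$O
        hs <- if (swaps[sr, m]) rev(src$H) else src$H
        p[dst$H] <- hs
      }
      variants[[length(variants) + 1]] <- p
    }
  }
  # identity first
  id <- which(vapply(variants, function(p) all(p == seq_len(nat)), logical(1)))
  variants[c(id, setdiff(seq_along(variants), id))]
}

#' Classify a walker into an isomer and permutation
#'
#' Minimizes the structure, matches the minimum to a catalog isomer by the
#' invariant distance fingerprint, and (optionally) identifies the atom
#' labeling by Eckart-aligning against every permutation variant of the
#' isomer reference; a numerically zero mass-weighted RMSD picks the
#' permutation.
#'
#' @param conf `wc_configuration` (a walker geometry).
#' @param catalog `isomer_catalog`.
#' @param params `qspcfw_params`.
#' @param rmsd_tol Mass-weighted RMSD tolerance (Angstrom) for a permutation
#'   match.
#' @param fp_tol Fingerprint tolerance (Angstrom) for an isomer match.
#' @param permutations Also identify the permutation (requires an
#'   enumerable permutation group).
#' @return List with `isomer` (1 = global minimum, NA if unclassified),
#'   `permutation` (index into [permutation_variants()], 1 = identity, NA if
#'   not identified) and `rmsd`.
#' @export
classify_walker <- function(conf, catalog, params = qspcfw_params(),
                            rmsd_tol = 1e-3, fp_tol = 5e-3,
                            permutations = TRUE) {
  mn <- minimize_geometry(conf, params)
  fp <- .fingerprint(mn$conf)
  dists <- vapply(catalog$fingerprints, .fingerprint_dist, numeric(1), f2 = fp)
  iso <- which.min(dists)
  if (dists[iso] > fp_tol)
    return(list(isomer = NA_integer_, permutation = NA_integer_, rmsd = NA_real_))
  if (!permutations)
    return(list(isomer = iso, permutation = NA_integer_, rmsd = NA_real_))
  ref <- catalog$minima[[iso]]
  vars <- permutation_variants(ref)
  best <- Inf; best_p <- NA_integer_
  for (k in seq_along(vars)) {
    rv <- ref$coords[vars[[k]], ]
    al <- .eckart_core(mn$conf$coords, rv, mn$conf$masses)
    if (al$rmsd < best) { best <- al$rmsd; best_p <- k }
  }
  list(isomer = iso, permutation = if (best < rmsd_tol) best_p else NA_integer_,
       rmsd = best)
}

#' Isomer fractions of a DMC run
#'
#' Classifies walkers of the selected snapshots by energy minimization and
#' returns the weighted share of each isomer, in wavefunction
#' (`w/psi_guide`) or amplitude (`W_DW w`) weighting.
#'
#' @param run `dmc_run` on a water system.
#' @param catalog `isomer_catalog`.
#' @param mode "wavefunction" or "amplitude".
#' @param snapshots Indices of snapshots to use (default: the last).
#' @param subsample Use at most this many walkers per snapshot (0 = all).
#' @return Named numeric vector of fractions (summing to 1), including
#'   an `unclassified` entry when applicable.
#' @export
isomer_fractions <- function(run, catalog, mode = c("wavefunction", "amplitude"),
                             snapshots = length(run$snapshots), subsample = 0) {
  mode <- match.arg(mode)
  params <- run$system$params
  tot <- numeric(length(catalog$minima) + 1)
  ref <- run$system$reference
  for (si in snapshots) {
    s <- run$snapshots[[si]]
    wt <- .walker_weights(run, s, mode)
    idx <- seq_along(wt)
    if (subsample > 0 && length(idx) > subsample)
      idx <- round(seq(1, length(idx), length.out = subsample))
    for (j in idx) {
      cf <- ref
      cf$coords <- matrix(s$x[j, ], ncol = 3, byrow = TRUE) * .BOHR_A
      cl <- classify_walker(cf, catalog, params, permutations = FALSE)
      slot <- if (is.na(cl$isomer)) length(tot) else cl$isomer
      tot[slot] <- tot[slot] + wt[j]
    }
  }
  fr <- tot / sum(tot)
  names(fr) <- c(paste0("isomer", seq_along(catalog$minima) - 1), "unclassified")
  fr
}

#' Probability of non-trivial atom permutations in a DMC ensemble
#'
#' Minimizes each walker of the selected snapshots, aligns it against every
#' permutation variant of its isomer and reports the weighted fraction
#' assigned to a permutation that is *not* a symmetry-equivalent relabeling
#' of the reference.  A variant whose permuted reference superimposes on
#' the reference itself under a (possibly improper) isometry — e.g.
#' swapping the two acceptor hydrogens of the achiral Cs dimer minimum,
#' which merely maps the structure onto its congruent mirror image — is a
#' trivial relabeling with no chemically distinct configuration behind it
#' and is not counted.  What remains are genuine permutation events
#' (hydrogen transfer, monomer exchange), which are energetically costly.
#'
#' @inheritParams isomer_fractions
#' @return Fraction in `[0, 1]` (multiply by 100 for percent).
#' @export
permutation_probability <- function(run, catalog,
                                    mode = c("wavefunction", "amplitude"),
                                    snapshots = length(run$snapshots),
                                    subsample = 0) {
  mode <- match.arg(mode)
  params <- run$system$params
  ref <- run$system$reference
  trivial <- lapply(seq_along(catalog$minima), function(i)
    .trivial_variants(catalog$minima[[i]]))
  num <- 0; den <- 0
  for (si in snapshots) {
    s <- run$snapshots[[si]]
    wt <- .walker_weights(run, s, mode)
    idx <- seq_along(wt)
    if (subsample > 0 && length(idx) > subsample)
      idx <- round(seq(1, length(idx), length.out = subsample))
    for (j in idx) {
      cf <- ref
      cf$coords <- matrix(s$x[j, ], ncol = 3, byrow = TRUE) * .BOHR_A
      cl <- classify_walker(cf, catalog, params, permutations = TRUE)
      den <- den + wt[j]
      if (!is.na(cl$permutation) &&
          !(cl$permutation %in% trivial[[cl$isomer]])) num <- num + wt[j]
    }
  }
  num / den
}

# indices of permutation variants that are symmetry-equivalent relabelings
# of the reference (superimposable on it allowing improper rotations)
.trivial_variants <- function(ref, tol = 1e-3) {
  vars <- permutation_variants(ref)
  m <- ref$masses
  rc <- sweep(ref$coords, 2, colSums(ref$coords * m) / sum(m))
  which(vapply(vars, function(p) {
    xc <- rc[p, ]
    A <- t(xc * m) %*% rc
    sv <- svd(A)
    R <- sv$v %*% t(sv$u)     # best isometry, improper allowed
    sqrt(sum(m * rowSums((xc %*% t(R) - rc)^2)) / sum(m)) < tol
  }, logical(1)))
}

#' O-O distance diagnostic of a walker ensemble
#'
#' Per-walker oxygen-oxygen distances (Angstrom), useful for spotting
#' basin-boundary misassignment of the minimization-based classifier: a
#' class whose O-O distribution matches the global minimum's rather than
#' its own isomer's was probably pulled across an ambiguous basin boundary.
#'
#' @param run `dmc_run` on a water system.
#' @param snapshots Snapshot indices (default all).
#' @return Matrix (walkers x O-O pairs) of distances.
#' @export
oo_distances <- function(run, snapshots = seq_along(run$snapshots)) {
  ref <- run$system$reference
  iO <- which(ref$elements == "O")
  if (length(iO) < 2) stop("need at least two molecules")
  pairs <- utils::combn(iO, 2)
  out <- NULL
  for (si in snapshots) {
    X <- run$snapshots[[si]]$x * .BOHR_A
    d <- sapply(seq_len(ncol(pairs)), function(p) {
      a <- pairs[1, p]; b <- pairs[2, p]
      sqrt((X[, 3 * a - 2] - X[, 3 * b - 2])^2 +
           (X[, 3 * a - 1] - X[, 3 * b - 1])^2 +
           (X[, 3 * a] - X[, 3 * b])^2)
    })
    out <- rbind(out, as.matrix(d))
  }
  out
}
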