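#' Forward map: Cartesian geometry to mass-weighted vibrational coordinates
#'
#' Evaluates the redundant descriptors and applies the stored reduction,
#' `v_MW(x) = P^T <G>^{-1/2} U^T f(x)`, centered on the ensemble mean so
#' the sampled ground state has `<v_MW> = 0`.  Descriptors are invariant to
#' rigid motions, so the map carries a 6-dimensional null space; returned
#' geometries are always gauge-fixed by Eckart alignment to the reference.
#'
#' @param conf `wc_configuration` (Angstrom) or coordinate vector in bohr.
#' @param vb `vibrational_basis` from [gspa_modes()].
#' @param center Subtract the stored ensemble mean (default TRUE).
#' @return Numeric vector of length 3N-6 (au).
#' @export
forward_map <- function(conf, vb, center = TRUE) {
  x <- if (inherits(conf, "wc_configuration")) .coords_au(conf) else as.numeric(conf)
  r <- descriptor_values(matrix(x, nrow = 1), vb$basis)[1, ]
  v <- as.vector(t(vb$P) %*% vb$Ginv2 %*% t(vb$U) %*% r)
  if (center) v - vb$vmw_mean else v
}

.rm_amat <- function(vb) t(vb$P) %*% vb$Ginv2 %*% t(vb$U)

#' Reverse map: reconstruct a geometry from vibrational coordinates
#'
#' Minimizes `err(x) = || v_MW(x) - v_MW,target ||^2` over Cartesian
#' coordinates by BFGS with the analytic Jacobian `2 B^T A^T (v - target)`,
#' starting from `x0`, until the error falls below `tol`.  The rigid-motion
#' null space is left free during optimization and removed afterwards by
#' Eckart alignment to the basis reference.
#'
#' @param target Target vibrational coordinates (length 3N-6, centered
#'   convention of [forward_map()]).
#' @param vb `vibrational_basis`.
#' @param x0 Starting geometry (`wc_configuration` or bohr vector);
#'   default: the basis reference.
#' @param tol Convergence threshold on the squared error.
#' @param max_restarts BFGS restarts before failing.
#' @return List with `conf` (aligned `wc_configuration`), `err`,
#'   `converged`.
#' @export
reverse_map <- function(target, vb, x0 = NULL, tol = 1e-8, max_restarts = 8) {
  if (is.null(x0)) x0 <- vb$reference
  x <- if (inherits(x0, "wc_configuration")) .coords_au(x0) else as.numeric(x0)
  A <- .rm_amat(vb)
  off <- vb$vmw_mean
  fn <- function(z) {
    v <- as.vector(A %*% descriptor_values(matrix(z, nrow = 1), vb$basis)[1, ]) - off
    sum((v - target)^2)
  }
  gr <- function(z) {
    B <- wilson_b(z, vb$basis)
    v <- as.vector(A %*% descriptor_values(matrix(z, nrow = 1), vb$basis)[1, ]) - off
    as.vector(2 * t(B) %*% t(A) %*% (v - target))
  }
  converged <- fn(x) < tol
  r <- 0
  while (!converged && r < max_restarts) {
    opt <- stats::optim(x, fn, gr, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-16))
    x <- opt$par
    converged <- fn(x) < tol
    r <- r + 1
  }
  err <- fn(x)
  if (!converged)
    stop(sprintf("reverse mapping did not converge: err = %.3g after %d restarts",
                 err, r))
  ref <- vb$reference
  cf <- .conf_from_au(x, ref)
  al <- eckart_align(cf, ref)
  list(conf = al$conf, err = err, converged = converged)
}

#' Equilibrium geometry in vibrational coordinates
#'
#' Solves `x_eq = v_MW^{-1}(0, x_GM)`: the Cartesian geometry whose
#' (centered) vibrational coordinates vanish, i.e. the geometry at the
#' center of the sampled probability amplitude.
#'
#' @param vb `vibrational_basis`.
#' @param x_gm Starting structure; default the basis reference.
#' @param ... Passed to [reverse_map()].
#' @return `wc_configuration`.
#' @export
equilibrium_geometry <- function(vb, x_gm = NULL, ...) {
  reverse_map(rep(0, length(vb$lambda)), vb, x0 = x_gm, ...)$conf
}

#' Animate a vibrational mode in Cartesian space
#'
#' Sequential reverse mapping along one mode: targets `+/- k delta e_l` for
#' `k = 1..k_max`, each solved warm-started from the previous frame, then
#' concatenated `-k_max..+k_max` into a trajectory suitable for molecular
#' viewers.
#'
#' @param vb `vibrational_basis`.
#' @param l Mode index.
#' @param delta Step in mass-weighted units; default a quarter of the
#'   mode's ground-state spread, `0.25 sqrt(lambda_l)`.
#' @param k_max Steps in each direction.
#' @param file Optional XYZ output path (multi-frame).
#' @param ... Passed to [reverse_map()].
#' @return List of `wc_configuration` frames (invisibly if written).
#' @export
animate_mode <- function(vb, l, delta = NULL, k_max = 8, file = NULL, ...) {
  if (is.null(delta)) delta <- 0.25 * sqrt(vb$lambda[l])
  stopifnot(delta > 0, k_max >= 0)
  nv <- length(vb$lambda)
  eq <- equilibrium_geometry(vb, ...)
  plus <- list(); minus <- list()
  prev <- eq
  for (k in seq_len(k_max)) {
    tgt <- rep(0, nv); tgt[l] <- k * delta
    sol <- reverse_map(tgt, vb, x0 = prev, ...)
    plus[[k]] <- sol$conf; prev <- sol$conf
  }
  prev <- eq
  for (k in seq_len(k_max)) {
    tgt <- rep(0, nv); tgt[l] <- -k * delta
    sol <- reverse_map(tgt, vb, x0 = prev, ...)
    minus[[k]] <- sol$conf; prev <- sol$conf
  }
  frames <- c(rev(minus), list(eq), plus)
  if (!is.null(file)) {
    write_xyz(frames, file,
              comment = sprintf("mode %d displacement %+d x %.4g", l,
                                seq(-k_max, k_max), delta))
    return(invisible(frames))
  }
  frames
}
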