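# Independent reference implementations used as oracles.  These are written
# from the model definitions directly (plain R, no shared code with the
# package internals beyond parameter values).

# term-by-term q-SPC/Fw energy in kcal/mol
oracle_potential <- function(conf, p, intermolecular = TRUE) {
  co <- conf$coords
  el <- conf$elements
  mol <- conf$mol_index
  v <- 0
  for (m in unique(mol)) {
    idx <- which(mol == m)
    o <- idx[el[idx] == "O"]; h <- idx[el[idx] == "H"]
    l1 <- sqrt(sum((co[h[1], ] - co[o, ])^2))
    l2 <- sqrt(sum((co[h[2], ] - co[o, ])^2))
    u <- co[h[1], ] - co[o, ]; w <- co[h[2], ] - co[o, ]
    th <- acos(sum(u * w) / (l1 * l2))
    v <- v + p$k_oh / 2 * ((l1 - p$l_eq)^2 + (l2 - p$l_eq)^2) +
      p$k_a / 2 * (th - p$theta_eq)^2
  }
  if (intermolecular && length(unique(mol)) > 1) {
    q <- ifelse(el == "O", p$q_o, p$q_h)
    n <- nrow(co)
    # Coulomb constant in kcal/mol * A / e^2: hartree*bohr in mixed units
    kc <- 627.509474063 * 0.529177210903
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      if (mol[a] == mol[b]) next
      r <- sqrt(sum((co[a, ] - co[b, ])^2))
      v <- v + kc * q[a] * q[b] / r
      if (el[a] == "O" && el[b] == "O")
        v <- v + 4 * p$epsilon * ((p$sigma / r)^12 - (p$sigma / r)^6)
    }
  }
  v
}

# central finite-difference gradient of any scalar function of a configuration
oracle_fd_gradient <- function(conf, fn, h = 1e-5) {
  g <- matrix(0, nrow(conf$coords), 3)
  for (a in seq_len(nrow(conf$coords))) for (k in 1:3) {
    cp <- conf; cp$coords[a, k] <- cp$coords[a, k] + h
    cm <- conf; cm$coords[a, k] <- cm$coords[a, k] - h
    g[a, k] <- (fn(cp) - fn(cm)) / (2 * h)
  }
  g
}

# numeric Laplacian sum_i (1/2 m_i) (lap_i psi)/psi of the guiding function,
# for validating the closed-form local-energy kinetic term
oracle_guiding_kinetic <- function(conf, p, h = 1e-4) {
  au <- unit_constants()
  m_me <- conf$masses * au$amu_me
  s0 <- guiding_value(conf, p, log = TRUE)
  kin <- 0
  for (a in seq_len(nrow(conf$coords))) for (k in 1:3) {
    cp <- conf; cp$coords[a, k] <- cp$coords[a, k] + h
    cm <- conf; cm$coords[a, k] <- cm$coords[a, k] - h
    sp <- guiding_value(cp, p, log = TRUE)
    sm <- guiding_value(cm, p, log = TRUE)
    hb <- h / au$bohr_A
    d1 <- (sp - sm) / (2 * hb)
    d2 <- (sp - 2 * s0 + sm) / hb^2
    kin <- kin - 0.5 / m_me[a] * (d2 + d1^2)   # (lap psi)/psi = S'' + S'^2
  }
  kin * au$hartree_kcal
}

# exact Morse oscillator: V = De (1 - exp(-a x))^2, hbar = m = 1
morse_exact_levels <- function(De, a, n) {
  we <- a * sqrt(2 * De)
  we * (n + 0.5) - we^2 * (n + 0.5)^2 / (4 * De)
}

# sample the exact Morse ground state |psi_0|^2 via its Gamma representation:
# z = 2 lambda exp(-a x), |psi0|^2 dx ~ z^(2 lambda - 2) e^-z dz
morse_ground_samples <- function(n, De, a) {
  lam <- sqrt(2 * De) / a
  z <- stats::rgamma(n, shape = 2 * lam - 1, rate = 1)
  -log(z / (2 * lam)) / a
}

# weighted covariance (plain definition)
oracle_wcov <- function(X, w) {
  mu <- colSums(X * w) / sum(w)
  Xc <- sweep(X, 2, mu)
  crossprod(Xc * w, Xc) / sum(w)
}

rotate_conf <- function(conf, ang = c(0.3, -0.7, 1.1), shift = c(1, -2, 0.5)) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])), c(0, sin(ang[1]), cos(ang[1])))
  Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0), c(-sin(ang[2]), 0, cos(ang[2])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0), c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  conf$coords <- sweep(conf$coords %*% t(Rz %*% Ry %*% Rx), 2, shift, `+`)
  conf
}
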