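#ifndef DMCVIB_MODEL_H
#define DMCVIB_MODEL_H

#include <Rcpp.h>
#include <vector>
#include <cmath>

// All quantities in atomic units: hbar = 1, mass in m_e, length in bohr,
// energy in hartree.  Unit conversion happens on the R side.

enum ModelType { MODEL_QSPCFW = 0, MODEL_HARMONIC = 1 };

struct Model {
  int type;
  int n_at;
  int n_dof;
  std::vector<double> mass;   // per atom (m_e)
  std::vector<double> invm;

  // q-SPC/Fw water
  int n_mol;
  std::vector<int> iO, iH1, iH2;  // atom index per monomer
  double kOH, leq, kA, theq;
  double eps, sig;
  std::vector<double> charge;     // per atom (e)
  bool intermolecular;
  double rmin;                    // Coulomb clamp distance (bohr)

  // guiding function (product of intramolecular Gaussians)
  bool guided;
  double a_l, a_th;               // sqrt(k_OH * mu_OH), sqrt(k_A * mu_A)

  // separable harmonic model
  std::vector<double> omega;      // per dof
};

inline Model parse_model(const Rcpp::List& spec) {
  Model m;
  m.type = Rcpp::as<int>(spec["type"]);
  Rcpp::NumericVector mass = spec["mass"];
  m.n_at = mass.size();
  m.n_dof = 3 * m.n_at;
  m.mass.assign(mass.begin(), mass.end());
  m.invm.resize(m.n_at);
  for (int i = 0; i < m.n_at; ++i) m.invm[i] = 1.0 / m.mass[i];
  m.guided = Rcpp::as<bool>(spec["guided"]);
  if (m.type == MODEL_QSPCFW) {
    Rcpp::IntegerVector iO = spec["iO"], iH1 = spec["iH1"], iH2 = spec["iH2"];
    m.n_mol = iO.size();
    m.iO.assign(iO.begin(), iO.end());
    m.iH1.assign(iH1.begin(), iH1.end());
    m.iH2.assign(iH2.begin(), iH2.end());
    m.kOH = Rcpp::as<double>(spec["kOH"]);
    m.leq = Rcpp::as<double>(spec["leq"]);
    m.kA  = Rcpp::as<double>(spec["kA"]);
    m.theq = Rcpp::as<double>(spec["theq"]);
    m.eps = Rcpp::as<double>(spec["eps"]);
    m.sig = Rcpp::as<double>(spec["sig"]);
    Rcpp::NumericVector q = spec["charge"];
    m.charge.assign(q.begin(), q.end());
    m.intermolecular = Rcpp::as<bool>(spec["intermolecular"]);
    m.rmin = Rcpp::as<double>(spec["rmin"]);
    m.a_l = Rcpp::as<double>(spec["a_l"]);
    m.a_th = Rcpp::as<double>(spec["a_th"]);
  } else {
    Rcpp::NumericVector om = spec["omega"];
    m.omega.assign(om.begin(), om.end());
  }
  return m;
}

// ---- geometry helpers -----------------------------------------------------

struct AngleGeom {
  double a, b, c, s, th;     // |u|, |v|, cos, sin, angle
  double ux[3], vx[3];       // unit vectors
  double g1[3], g2[3], g0[3];  // dtheta/dr1, dtheta/dr2, dtheta/dr0
};

inline double bond_length(const double* x, int ia, int ib, double* uhat) {
  double d[3];
  double r2 = 0.0;
  for (int k = 0; k < 3; ++k) {
    d[k] = x[3 * ia + k] - x[3 * ib + k];
    r2 += d[k] * d[k];
  }
  double r = std::sqrt(r2);
  if (uhat) for (int k = 0; k < 3; ++k) uhat[k] = d[k] / r;
  return r;
}

// angle at vertex i0 between atoms i1 and i2, with gradients
inline void angle_geom(const double* x, int i0, int i1, int i2, AngleGeom& g) {
  double u[3], v[3];
  double a2 = 0.0, b2 = 0.0;
  for (int k = 0; k < 3; ++k) {
    u[k] = x[3 * i1 + k] - x[3 * i0 + k];
    v[k] = x[3 * i2 + k] - x[3 * i0 + k];
    a2 += u[k] * u[k];
    b2 += v[k] * v[k];
  }
  g.a = std::sqrt(a2);
  g.b = std::sqrt(b2);
  double c = 0.0;
  for (int k = 0; k < 3; ++k) {
    g.ux[k] = u[k] / g.a;
    g.vx[k] = v[k] / g.b;
    c += g.ux[k] * g.vx[k];
  }
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  g.c = c;
  double s2 = 1.0 - c * c;
  g.s = std::sqrt(s2 > 1e-12 ? s2 : 1e-12);  // near-linear regularization
  g.th = std::acos(c);
  for (int k = 0; k < 3; ++k) {
    g.g1[k] = (c * g.ux[k] - g.vx[k]) / (g.a * g.s);
    g.g2[k] = (c * g.vx[k] - g.ux[k]) / (g.b * g.s);
    g.g0[k] = -(g.g1[k] + g.g2[k]);
  }
}

// ---- potential energy and gradient ---------------------------------------

inline double model_potential(const Model& m, const double* x) {
  if (m.type == MODEL_HARMONIC) {
    double v = 0.0;
    for (int i = 0; i < m.n_at; ++i)
      for (int k = 0; k < 3; ++k) {
        const int c = 3 * i + k;
        v += 0.5 * m.mass[i] * m.omega[c] * m.omega[c] * x[c] * x[c];
      }
    return v;
  }
  double v = 0.0;
  for (int mol = 0; mol < m.n_mol; ++mol) {
    const int o = m.iO[mol], h1 = m.iH1[mol], h2 = m.iH2[mol];
    const double l1 = bond_length(x, h1, o, nullptr);
    const double l2 = bond_length(x, h2, o, nullptr);
    AngleGeom g;
    angle_geom(x, o, h1, h2, g);
    const double d1 = l1 - m.leq, d2 = l2 - m.leq, dth = g.th - m.theq;
    v += 0.5 * m.kOH * (d1 * d1 + d2 * d2) + 0.5 * m.kA * dth * dth;
  }
  if (m.intermolecular && m.n_mol > 1) {
    // O-O Lennard-Jones
    for (int i = 0; i < m.n_mol; ++i)
      for (int j = i + 1; j < m.n_mol; ++j) {
        const double r = bond_length(x, m.iO[i], m.iO[j], nullptr);
        const double sr6 = std::pow(m.sig / r, 6);
        v += 4.0 * m.eps * (sr6 * sr6 - sr6);
      }
    // intermolecular Coulomb, all atom pairs across monomers
    for (int mi = 0; mi < m.n_mol; ++mi)
      for (int mj = mi + 1; mj < m.n_mol; ++mj) {
        const int ai[3] = { m.iO[mi], m.iH1[mi], m.iH2[mi] };
        const int aj[3] = { m.iO[mj], m.iH1[mj], m.iH2[mj] };
        for (int p = 0; p < 3; ++p)
          for (int q = 0; q < 3; ++q) {
            double r = bond_length(x, ai[p], aj[q], nullptr);
            if (r < m.rmin) r = m.rmin;
            v += m.charge[ai[p]] * m.charge[aj[q]] / r;
          }
      }
  }
  return v;
}

inline void model_gradient(const Model& m, const double* x, double* grad) {
  for (int c = 0; c < m.n_dof; ++c) grad[c] = 0.0;
  if (m.type == MODEL_HARMONIC) {
    for (int i = 0; i < m.n_at; ++i)
      for (int k = 0; k < 3; ++k) {
        const int c = 3 * i + k;
        grad[c] = m.mass[i] * m.omega[c] * m.omega[c] * x[c];
      }
    return;
  }
  double uh[3];
  for (int mol = 0; mol < m.n_mol; ++mol) {
    const int o = m.iO[mol], h1 = m.iH1[mol], h2 = m.iH2[mol];
    double l = bond_length(x, h1, o, uh);
    double f = m.kOH * (l - m.leq);
    for (int k = 0; k < 3; ++k) { grad[3 * h1 + k] += f * uh[k]; grad[3 * o + k] -= f * uh[k]; }
    l = bond_length(x, h2, o, uh);
    f = m.kOH * (l - m.leq);
    for (int k = 0; k < 3; ++k) { grad[3 * h2 + k] += f * uh[k]; grad[3 * o + k] -= f * uh[k]; }
    AngleGeom g;
    angle_geom(x, o, h1, h2, g);
    const double ft = m.kA * (g.th - m.theq);
    for (int k = 0; k < 3; ++k) {
      grad[3 * h1 + k] += ft * g.g1[k];
      grad[3 * h2 + k] += ft * g.g2[k];
      grad[3 * o  + k] += ft * g.g0[k];
    }
  }
  if (m.intermolecular && m.n_mol > 1) {
    for (int i = 0; i < m.n_mol; ++i)
      for (int j = i + 1; j < m.n_mol; ++j) {
        const int a = m.iO[i], b = m.iO[j];
        const double r = bond_length(x, a, b, uh);
        const double sr6 = std::pow(m.sig / r, 6);
        const double dvdr = (24.0 * m.eps / r) * (sr6 - 2.0 * sr6 * sr6);
        for (int k = 0; k < 3; ++k) { grad[3 * a + k] += dvdr * uh[k]; grad[3 * b + k] -= dvdr * uh[k]; }
      }
    for (int mi = 0; mi < m.n_mol; ++mi)
      for (int mj = mi + 1; mj < m.n_mol; ++mj) {
        const int ai[3] = { m.iO[mi], m.iH1[mi], m.iH2[mi] };
        const int aj[3] = { m.iO[mj], m.iH1[mj], m.iH2[mj] };
        for (int p = 0; p < 3; ++p)
          for (int q = 0; q < 3; ++q) {
            const int a = ai[p], b = aj[q];
            const double r = bond_length(x, a, b, uh);
            if (r < m.rmin) continue;  // clamped region: flat
            const double dvdr = -m.charge[a] * m.charge[b] / (r * r);
            for (int k = 0; k < 3; ++k) { grad[3 * a + k] += dvdr * uh[k]; grad[3 * b + k] -= dvdr * uh[k]; }
          }
      }
  }
}

// ---- guiding function -----------------------------------------------------
// S = log psi_guide = -1/2 sum_mol [a_l dl1^2 + a_l dl2^2 + a_th dth^2]
// (harmonic model: exact ground state, a_c = m_i * omega_c)

inline double model_guiding_log(const Model& m, const double* x) {
  if (m.type == MODEL_HARMONIC) {
    double s = 0.0;
    for (int i = 0; i < m.n_at; ++i)
      for (int k = 0; k < 3; ++k) {
        const int c = 3 * i + k;
        s -= 0.5 * m.mass[i] * m.omega[c] * x[c] * x[c];
      }
    return s;
  }
  double s = 0.0;
  for (int mol = 0; mol < m.n_mol; ++mol) {
    const int o = m.iO[mol], h1 = m.iH1[mol], h2 = m.iH2[mol];
    const double d1 = bond_length(x, h1, o, nullptr) - m.leq;
    const double d2 = bond_length(x, h2, o, nullptr) - m.leq;
    AngleGeom g;
    angle_geom(x, o, h1, h2, g);
    const double dth = g.th - m.theq;
    s -= 0.5 * (m.a_l * (d1 * d1 + d2 * d2) + m.a_th * dth * dth);
  }
  return s;
}

inline void model_guiding_grad(const Model& m, const double* x, double* gs) {
  for (int c = 0; c < m.n_dof; ++c) gs[c] = 0.0;
  if (m.type == MODEL_HARMONIC) {
    for (int i = 0; i < m.n_at; ++i)
      for (int k = 0; k < 3; ++k) {
        const int c = 3 * i + k;
        gs[c] = -m.mass[i] * m.omega[c] * x[c];
      }
    return;
  }
  double uh[3];
  for (int mol = 0; mol < m.n_mol; ++mol) {
    const int o = m.iO[mol], h1 = m.iH1[mol], h2 = m.iH2[mol];
    double l = bond_length(x, h1, o, uh);
    double f = -m.a_l * (l - m.leq);
    for (int k = 0; k < 3; ++k) { gs[3 * h1 + k] += f * uh[k]; gs[3 * o + k] -= f * uh[k]; }
    l = bond_length(x, h2, o, uh);
    f = -m.a_l * (l - m.leq);
    for (int k = 0; k < 3; ++k) { gs[3 * h2 + k] += f * uh[k]; gs[3 * o + k] -= f * uh[k]; }
    AngleGeom g;
    angle_geom(x, o, h1, h2, g);
    const double ft = -m.a_th * (g.th - m.theq);
    for (int k = 0; k < 3; ++k) {
      gs[3 * h1 + k] += ft * g.g1[k];
      gs[3 * h2 + k] += ft * g.g2[k];
      gs[3 * o  + k] += ft * g.g0[k];
    }
  }
}

// Laplacian of S per atom, summed into lap[atom].
// Closed forms: lap(l) = 2/l at either bond endpoint;
// lap(theta) = c/(a^2 s) at arm atoms, c/(a^2 s)+c/(b^2 s)-2/(a b s) at vertex;
// |grad theta|^2 = 1/a^2 (arm), 1/a^2 + 1/b^2 - 2 c/(a b) (vertex).
inline void model_guiding_lap(const Model& m, const double* x, double* lap) {
  for (int i = 0; i < m.n_at; ++i) lap[i] = 0.0;
  if (m.type == MODEL_HARMONIC) {
    for (int i = 0; i < m.n_at; ++i)
      for (int k = 0; k < 3; ++k) lap[i] -= m.mass[i] * m.omega[3 * i + k];
    return;
  }
  for (int mol = 0; mol < m.n_mol; ++mol) {
    const int o = m.iO[mol], h1 = m.iH1[mol], h2 = m.iH2[mol];
    const double l1 = bond_length(x, h1, o, nullptr);
    const double l2 = bond_length(x, h2, o, nullptr);
    const double d1 = l1 - m.leq, d2 = l2 - m.leq;
    // bonds: lap(-a_l/2 * dl^2) = -a_l (|grad l|^2 + dl * lap l) = -a_l (1 + 2 dl/l)
    lap[h1] += -m.a_l * (1.0 + 2.0 * d1 / l1);
    lap[h2] += -m.a_l * (1.0 + 2.0 * d2 / l2);
    lap[o]  += -m.a_l * (2.0 + 2.0 * d1 / l1 + 2.0 * d2 / l2);
    AngleGeom g;
    angle_geom(x, o, h1, h2, g);
    const double dth = g.th - m.theq;
    const double ia2 = 1.0 / (g.a * g.a), ib2 = 1.0 / (g.b * g.b);
    const double iab = 1.0 / (g.a * g.b);
    lap[h1] += -m.a_th * (ia2 + dth * g.c * ia2 / g.s);
    lap[h2] += -m.a_th * (ib2 + dth * g.c * ib2 / g.s);
    lap[o]  += -m.a_th * (ia2 + ib2 - 2.0 * g.c * iab
                          + dth * (g.c * ia2 / g.s + g.c * ib2 / g.s - 2.0 * iab / g.s));
  }
}

// local energy E_L = V - sum_i (1/2 m_i) [lap_i S + |grad_i S|^2]
inline double model_local_energy(const Model& m, const double* x, double* gs_buf, double* lap_buf) {
  const double v = model_potential(m, x);
  if (!m.guided) return v;
  model_guiding_grad(m, x, gs_buf);
  model_guiding_lap(m, x, lap_buf);
  double kin = 0.0;
  for (int i = 0; i < m.n_at; ++i) {
    double g2 = 0.0;
    for (int k = 0; k < 3; ++k) g2 += gs_buf[3 * i + k] * gs_buf[3 * i + k];
    kin -= 0.5 * m.invm[i] * (lap_buf[i] + g2);
  }
  return v + kin;
}

// Fused single-pass evaluator used by the DMC inner loop: potential energy,
// log psi_guide, grad log psi_guide and the local energy in one geometry
// traversal.  For water every guiding term lives within one monomer, so the
// per-atom |grad S|^2 and laplacian contributions close monomer by monomer.
inline void model_eval(const Model& m, const double* x, bool guided,
                       double* gS, double& V, double& S, double& EL) {
  V = 0.0; S = 0.0;
  double kin = 0.0;
  if (m.type == MODEL_HARMONIC) {
    for (int i = 0; i < m.n_at; ++i) {
      const double mi = m.mass[i];
      for (int k = 0; k < 3; ++k) {
        const int c = 3 * i + k;
        const double om = m.omega[c], xc = x[c];
        V += 0.5 * mi * om * om * xc * xc;
        if (guided) {
          const double a = mi * om;
          S -= 0.5 * a * xc * xc;
          gS[c] = -a * xc;
          kin -= 0.5 * m.invm[i] * (-a + a * a * xc * xc);
        }
      }
    }
    EL = guided ? V + kin : V;
    return;
  }
  for (int mol = 0; mol < m.n_mol; ++mol) {
    const int o = m.iO[mol], h1 = m.iH1[mol], h2 = m.iH2[mol];
    const double* xo = x + 3 * o;
    const double* x1 = x + 3 * h1;
    const double* x2 = x + 3 * h2;
    double u[3], v[3];
    double a2 = 0.0, b2 = 0.0, uv = 0.0;
    for (int k = 0; k < 3; ++k) {
      u[k] = x1[k] - xo[k];
      v[k] = x2[k] - xo[k];
      a2 += u[k] * u[k]; b2 += v[k] * v[k]; uv += u[k] * v[k];
    }
    const double a = std::sqrt(a2), b = std::sqrt(b2);
    const double ia = 1.0 / a, ib = 1.0 / b;
    double c = uv * ia * ib;
    if (c > 1.0) c = 1.0; else if (c < -1.0) c = -1.0;
    double s2 = 1.0 - c * c;
    const double s = std::sqrt(s2 > 1e-12 ? s2 : 1e-12);
    const double th = std::acos(c);
    const double d1 = a - m.leq, d2 = b - m.leq, dth = th - m.theq;
    V += 0.5 * m.kOH * (d1 * d1 + d2 * d2) + 0.5 * m.kA * dth * dth;
    if (guided) {
      S -= 0.5 * (m.a_l * (d1 * d1 + d2 * d2) + m.a_th * dth * dth);
      const double f1 = -m.a_l * d1 * ia, f2 = -m.a_l * d2 * ib;
      const double ft = -m.a_th * dth;
      const double ias = ia / s, ibs = ib / s;
      double g1[3], g2[3], go[3];
      for (int k = 0; k < 3; ++k) {
        const double uh = u[k] * ia, vh = v[k] * ib;
        const double t1 = (c * uh - vh) * ias;   // dtheta/dx_h1
        const double t2 = (c * vh - uh) * ibs;   // dtheta/dx_h2
        g1[k] = f1 * u[k] + ft * t1;
        g2[k] = f2 * v[k] + ft * t2;
        go[k] = -(f1 * u[k] + f2 * v[k]) - ft * (t1 + t2);
        gS[3 * h1 + k] = g1[k];
        gS[3 * h2 + k] = g2[k];
        gS[3 * o + k] = go[k];
      }
      const double ia2 = ia * ia, ib2 = ib * ib, iab = ia * ib;
      const double lap1 = -m.a_l * (1.0 + 2.0 * d1 * ia)
        - m.a_th * (ia2 + dth * c * ia2 / s);
      const double lap2 = -m.a_l * (1.0 + 2.0 * d2 * ib)
        - m.a_th * (ib2 + dth * c * ib2 / s);
      const double lapo = -m.a_l * (2.0 + 2.0 * d1 * ia + 2.0 * d2 * ib)
        - m.a_th * (ia2 + ib2 - 2.0 * c * iab
                    + dth * (c * ia2 + c * ib2 - 2.0 * iab) / s);
      kin -= 0.5 * m.invm[h1] * (lap1 + g1[0]*g1[0] + g1[1]*g1[1] + g1[2]*g1[2]);
      kin -= 0.5 * m.invm[h2] * (lap2 + g2[0]*g2[0] + g2[1]*g2[1] + g2[2]*g2[2]);
      kin -= 0.5 * m.invm[o]  * (lapo + go[0]*go[0] + go[1]*go[1] + go[2]*go[2]);
    }
  }
  if (m.intermolecular && m.n_mol > 1) {
    const double sig2 = m.sig * m.sig;
    for (int i = 0; i < m.n_mol; ++i) {
      const double* oi = x + 3 * m.iO[i];
      for (int j = i + 1; j < m.n_mol; ++j) {
        const double* oj = x + 3 * m.iO[j];
        const double dx = oi[0] - oj[0], dy = oi[1] - oj[1], dz = oi[2] - oj[2];
        const double sr2 = sig2 / (dx * dx + dy * dy + dz * dz);
        const double sr6 = sr2 * sr2 * sr2;
        V += 4.0 * m.eps * (sr6 * sr6 - sr6);
      }
    }
    for (int mi = 0; mi < m.n_mol; ++mi) {
      const int ai[3] = { m.iO[mi], m.iH1[mi], m.iH2[mi] };
      for (int mj = mi + 1; mj < m.n_mol; ++mj) {
        const int aj[3] = { m.iO[mj], m.iH1[mj], m.iH2[mj] };
        for (int p = 0; p < 3; ++p) {
          const double* xa = x + 3 * ai[p];
          const double qa = m.charge[ai[p]];
          for (int q = 0; q < 3; ++q) {
            const double* xb = x + 3 * aj[q];
            const double dx = xa[0] - xb[0], dy = xa[1] - xb[1], dz = xa[2] - xb[2];
            double r = std::sqrt(dx * dx + dy * dy + dz * dz);
            if (r < m.rmin) r = m.rmin;
            V += qa * m.charge[aj[q]] / r;
          }
        }
      }
    }
  }
  EL = guided ? V + kin : V;
}

inline void model_dipole(const Model& m, const double* x, double* mu) {
  mu[0] = mu[1] = mu[2] = 0.0;
  if (m.type != MODEL_QSPCFW) return;
  for (int i = 0; i < m.n_at; ++i)
    for (int k = 0; k < 3; ++k) mu[k] += m.charge[i] * x[3 * i + k];
}

#endif
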