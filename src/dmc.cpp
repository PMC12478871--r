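#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include "model.h"
#include "rng.h"
using namespace Rcpp;

// Diffusion Monte Carlo propagation in imaginary time.  Continuous weighting
// keeps the population fixed and evolves per-walker weights with threshold
// resampling (remove w < threshold, split the heaviest walkers at half
// weight); discrete weighting uses integer birth/death branching.  Guided
// runs drift walkers along grad log psi_guide, accept moves by Metropolis on
// psi_guide^2, and branch on the analytic local energy.

struct Walkers {
  int n_at, n_dof;
  std::vector<double> x, w, E, S, gS;
  std::vector<int> anc;
  int n() const { return (int)w.size(); }
};

struct StepScratch {
  std::vector<double> xp, gSp, lap, sd, d2;  // proposal, grad, laplacian, step widths
};

static void init_energies(const Model& m, Walkers& W, StepScratch& sc) {
  const int n = W.n();
  double V, S, EL;
  for (int j = 0; j < n; ++j) {
    double* xj = &W.x[(size_t)j * W.n_dof];
    if (m.guided) {
      model_eval(m, xj, true, &W.gS[(size_t)j * W.n_dof], V, S, EL);
      W.S[j] = S;
      W.E[j] = EL;
    } else {
      model_eval(m, xj, false, nullptr, V, S, EL);
      W.E[j] = V;
    }
  }
}

// one propagation step; returns weighted mean energy after the move
static double move_walkers(const Model& m, Walkers& W, StepScratch& sc, double dtau,
                           bool drift, Xoshiro& rng, double& acc_num, double& acc_den) {
  const int n = W.n(), nd = W.n_dof;
  double esum = 0.0, wsum = 0.0;
  double V, Sp, ELp;
  for (int j = 0; j < n; ++j) {
    double* xj = &W.x[(size_t)j * nd];
    if (m.guided && drift) {
      double* gj = &W.gS[(size_t)j * nd];
      double lnqf = 0.0;
      for (int c = 0; c < nd; ++c) {
        const double eta = rng.norm();
        sc.xp[c] = xj[c] + sc.d2[c] * gj[c] + sc.sd[c] * eta;
        lnqf -= 0.5 * eta * eta;
      }
      model_eval(m, sc.xp.data(), true, sc.gSp.data(), V, Sp, ELp);
      double lnqr = 0.0;
      for (int c = 0; c < nd; ++c) {
        const double r = xj[c] - sc.xp[c] - sc.d2[c] * sc.gSp[c];
        lnqr -= r * r / (2.0 * sc.sd[c] * sc.sd[c]);
      }
      const double lnA = 2.0 * (Sp - W.S[j]) + lnqr - lnqf;
      acc_den += 1.0;
      if (lnA >= 0.0 || std::log(rng.unif()) < lnA) {
        acc_num += 1.0;
        std::copy(sc.xp.begin(), sc.xp.end(), xj);
        std::copy(sc.gSp.begin(), sc.gSp.end(), gj);
        W.S[j] = Sp;
        W.E[j] = ELp;  // rejected moves keep the cached local energy
      }
    } else {
      for (int c = 0; c < nd; ++c) xj[c] += sc.sd[c] * rng.norm();
      if (m.guided) {  // pure-diffusion phase of a guided run: refresh caches
        model_eval(m, xj, true, &W.gS[(size_t)j * nd], V, Sp, ELp);
        W.S[j] = Sp;
        W.E[j] = ELp;
      } else {
        model_eval(m, xj, false, nullptr, V, Sp, ELp);
        W.E[j] = V;
      }
    }
    esum += W.w[j] * W.E[j];
    wsum += W.w[j];
  }
  return esum / wsum;
}

static void resample_continuous(Walkers& W, double thresh) {
  const int n = W.n(), nd = W.n_dof;
  std::vector<int> low;
  for (int j = 0; j < n; ++j) if (W.w[j] < thresh) low.push_back(j);
  if (low.empty()) return;
  const int k = (int)low.size();
  std::vector<int> ord(n);
  std::iota(ord.begin(), ord.end(), 0);
  std::partial_sort(ord.begin(), ord.begin() + std::min(k, n), ord.end(),
                    [&](int a, int b) { return W.w[a] > W.w[b]; });
  for (int i = 0; i < k; ++i) {
    const int h = ord[i], l = low[i];
    if (W.w[h] < thresh) break;  // pathological: nothing heavy left to split
    W.w[h] *= 0.5;
    W.w[l] = W.w[h];
    std::copy(&W.x[(size_t)h * nd], &W.x[(size_t)h * nd] + nd, &W.x[(size_t)l * nd]);
    if (!W.gS.empty())
      std::copy(&W.gS[(size_t)h * nd], &W.gS[(size_t)h * nd] + nd, &W.gS[(size_t)l * nd]);
    W.E[l] = W.E[h];
    if (!W.S.empty()) W.S[l] = W.S[h];
    W.anc[l] = W.anc[h];
  }
}

static void branch_discrete(Walkers& W, double vref, double dtau, int cap,
                            Xoshiro& rng) {
  const int n = W.n(), nd = W.n_dof;
  std::vector<double> x2, E2, S2, gS2;
  std::vector<int> anc2;
  x2.reserve(W.x.size());
  for (int j = 0; j < n; ++j) {
    const double p = std::exp(-(W.E[j] - vref) * dtau);
    int nc = (int)std::floor(p + rng.unif());
    if (nc > cap) nc = cap;
    for (int r = 0; r < nc; ++r) {
      x2.insert(x2.end(), &W.x[(size_t)j * nd], &W.x[(size_t)j * nd] + nd);
      E2.push_back(W.E[j]);
      if (!W.S.empty()) S2.push_back(W.S[j]);
      if (!W.gS.empty())
        gS2.insert(gS2.end(), &W.gS[(size_t)j * nd], &W.gS[(size_t)j * nd] + nd);
      anc2.push_back(W.anc[j]);
    }
  }
  W.x.swap(x2);
  W.E.swap(E2);
  W.S.swap(S2);
  W.gS.swap(gS2);
  W.anc.swap(anc2);
  W.w.assign(W.anc.size(), 1.0);
}

// [[Rcpp::export]]
List dmc_cpp(List model_spec, NumericMatrix x0, int n_walkers, double dtau,
             int n_steps, int n_diff_only, IntegerVector snap_steps,
             bool discrete, bool branch, double thresh, double alpha, int cap,
             double seed, double stream) {
  Model m = parse_model(model_spec);
  const int nd = m.n_dof;
  if (x0.ncol() != nd) stop("initial coordinates have wrong dimension");
  Xoshiro rng((uint64_t)seed, (uint64_t)stream);

  Walkers W;
  W.n_at = m.n_at; W.n_dof = nd;
  W.x.resize((size_t)n_walkers * nd);
  for (int j = 0; j < n_walkers; ++j) {
    const int src = x0.nrow() == 1 ? 0 : j % x0.nrow();
    for (int c = 0; c < nd; ++c) W.x[(size_t)j * nd + c] = x0(src, c);
  }
  W.w.assign(n_walkers, 1.0);
  W.E.assign(n_walkers, 0.0);
  W.anc.resize(n_walkers);
  std::iota(W.anc.begin(), W.anc.end(), 0);
  if (m.guided) {
    W.S.assign(n_walkers, 0.0);
    W.gS.assign((size_t)n_walkers * nd, 0.0);
  }

  StepScratch sc;
  sc.xp.resize(nd); sc.gSp.resize(nd); sc.lap.resize(m.n_at);
  sc.sd.resize(nd); sc.d2.resize(nd);
  for (int i = 0; i < m.n_at; ++i)
    for (int k = 0; k < 3; ++k) {
      const double D = 0.5 * m.invm[i];
      sc.sd[3 * i + k] = std::sqrt(2.0 * D * dtau);
      sc.d2[3 * i + k] = 2.0 * D * dtau;
    }

  init_energies(m, W, sc);
  double vref = 0.0, wsum0 = 0.0;
  for (int j = 0; j < W.n(); ++j) { vref += W.w[j] * W.E[j]; wsum0 += W.w[j]; }
  vref /= wsum0;
  const double w_target = wsum0;
  const int n0_target = n_walkers;

  NumericVector vref_trace(n_steps), pop_trace(n_steps);
  double acc_num = 0.0, acc_den = 0.0;
  List snapshots;
  std::vector<int> snaps(snap_steps.begin(), snap_steps.end());
  bool extinct = false;

  for (int step = 1; step <= n_steps; ++step) {
    const bool drifting = step > n_diff_only;
    const bool branching = branch && step > n_diff_only;
    const double ebar = move_walkers(m, W, sc, dtau, drifting, rng, acc_num, acc_den);
    if (branching) {
      if (!discrete) {
        double wsum = 0.0, esum = 0.0;
        for (int j = 0; j < W.n(); ++j) {
          W.w[j] *= std::exp(-(W.E[j] - vref) * dtau);
          wsum += W.w[j];
          esum += W.w[j] * W.E[j];
        }
        vref = esum / wsum - alpha * std::log(wsum / w_target);
        resample_continuous(W, thresh);
        double wtot = 0.0;
        for (int j = 0; j < W.n(); ++j) wtot += W.w[j];
        pop_trace[step - 1] = wtot;
      } else {
        branch_discrete(W, vref, dtau, cap, rng);
        const int n = W.n();
        pop_trace[step - 1] = n;
        if (n == 0) { extinct = true; vref_trace[step - 1] = NA_REAL; break; }
        double esum = 0.0;
        for (int j = 0; j < n; ++j) esum += W.E[j];
        vref = esum / n - alpha * (double)(n - n0_target) / n0_target;
      }
    } else {
      vref = ebar;
      double wtot = 0.0;
      for (int j = 0; j < W.n(); ++j) wtot += W.w[j];
      pop_trace[step - 1] = discrete ? (double)W.n() : wtot;
    }
    vref_trace[step - 1] = vref;
    if (std::find(snaps.begin(), snaps.end(), step) != snaps.end()) {
      const int n = W.n();
      NumericMatrix xs(n, nd);
      NumericVector ws(n);
      for (int j = 0; j < n; ++j) {
        ws[j] = W.w[j];
        for (int c = 0; c < nd; ++c) xs(j, c) = W.x[(size_t)j * nd + c];
      }
      snapshots.push_back(List::create(_["x"] = xs, _["w"] = ws,
                                       _["vref"] = vref, _["step"] = step));
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["vref"] = vref_trace,
    _["population"] = pop_trace,
    _["acceptance"] = acc_den > 0 ? acc_num / acc_den : NA_REAL,
    _["snapshots"] = snapshots,
    _["extinct"] = extinct);
}

// Descendant weighting: propagate a stored snapshot tau_DW further and credit
// each final weight to the walker's ancestor at the start of the window;
// averaged over n_rep independent continuations.
// [[Rcpp::export]]
NumericVector dmc_descendant_cpp(List model_spec, NumericMatrix xs, NumericVector ws,
                                 double vref0, double dtau, int n_steps, int n_rep,
                                 bool discrete, double thresh, double alpha, int cap,
                                 double seed, double stream) {
  Model m = parse_model(model_spec);
  const int nd = m.n_dof, n0 = xs.nrow();
  NumericVector wdw(n0);

  StepScratch sc;
  sc.xp.resize(nd); sc.gSp.resize(nd); sc.lap.resize(m.n_at);
  sc.sd.resize(nd); sc.d2.resize(nd);
  for (int i = 0; i < m.n_at; ++i)
    for (int k = 0; k < 3; ++k) {
      const double D = 0.5 * m.invm[i];
      sc.sd[3 * i + k] = std::sqrt(2.0 * D * dtau);
      sc.d2[3 * i + k] = 2.0 * D * dtau;
    }

  for (int rep = 0; rep < n_rep; ++rep) {
    Xoshiro rng((uint64_t)seed, (uint64_t)stream + 7919 * (uint64_t)(rep + 1));
    Walkers W;
    W.n_at = m.n_at; W.n_dof = nd;
    W.x.resize((size_t)n0 * nd);
    W.w.resize(n0);
    std::vector<double> w_start(n0);
    for (int j = 0; j < n0; ++j) {
      W.w[j] = discrete ? 1.0 : ws[j];
      w_start[j] = W.w[j];
      for (int c = 0; c < nd; ++c) W.x[(size_t)j * nd + c] = xs(j, c);
    }
    W.E.assign(n0, 0.0);
    W.anc.resize(n0);
    std::iota(W.anc.begin(), W.anc.end(), 0);
    if (m.guided) { W.S.assign(n0, 0.0); W.gS.assign((size_t)n0 * nd, 0.0); }
    init_energies(m, W, sc);

    double vref = vref0;
    double w_target = 0.0;
    for (int j = 0; j < n0; ++j) w_target += W.w[j];
    double acc_num = 0.0, acc_den = 0.0;

    for (int step = 1; step <= n_steps; ++step) {
      move_walkers(m, W, sc, dtau, true, rng, acc_num, acc_den);
      if (!discrete) {
        double wsum = 0.0, esum = 0.0;
        for (int j = 0; j < W.n(); ++j) {
          W.w[j] *= std::exp(-(W.E[j] - vref) * dtau);
          wsum += W.w[j];
          esum += W.w[j] * W.E[j];
        }
        vref = esum / wsum - alpha * std::log(wsum / w_target);
        resample_continuous(W, thresh);
      } else {
        branch_discrete(W, vref, dtau, cap, rng);
        const int n = W.n();
        if (n == 0) break;
        double esum = 0.0;
        for (int j = 0; j < n; ++j) esum += W.E[j];
        vref = esum / n - alpha * (double)(n - n0) / n0;
      }
      if (step % 2000 == 0) Rcpp::checkUserInterrupt();
    }

    for (int j = 0; j < W.n(); ++j) wdw[W.anc[j]] += discrete ? 1.0 : W.w[j] / w_start[W.anc[j]];
  }
  for (int j = 0; j < n0; ++j) wdw[j] /= n_rep;
  return wdw;
}
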