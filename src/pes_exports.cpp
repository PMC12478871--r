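#include <Rcpp.h>
#include "model.h"
using namespace Rcpp;

// Thin exports of the analytic surface; everything in atomic units.

// [[Rcpp::export]]
double potential_cpp(List model, NumericVector x) {
  Model m = parse_model(model);
  return model_potential(m, x.begin());
}

// [[Rcpp::export]]
NumericVector gradient_cpp(List model, NumericVector x) {
  Model m = parse_model(model);
  NumericVector g(m.n_dof);
  model_gradient(m, x.begin(), g.begin());
  return g;
}

// [[Rcpp::export]]
NumericVector potential_ensemble_cpp(List model, NumericMatrix X) {
  Model m = parse_model(model);
  const int n = X.nrow();
  NumericVector v(n);
  std::vector<double> x(m.n_dof);
  for (int w = 0; w < n; ++w) {
    for (int c = 0; c < m.n_dof; ++c) x[c] = X(w, c);
    v[w] = model_potential(m, x.data());
  }
  return v;
}

// [[Rcpp::export]]
double guiding_log_cpp(List model, NumericVector x) {
  Model m = parse_model(model);
  return model_guiding_log(m, x.begin());
}

// [[Rcpp::export]]
NumericVector guiding_log_ensemble_cpp(List model, NumericMatrix X) {
  Model m = parse_model(model);
  const int n = X.nrow();
  NumericVector v(n);
  std::vector<double> x(m.n_dof);
  for (int w = 0; w < n; ++w) {
    for (int c = 0; c < m.n_dof; ++c) x[c] = X(w, c);
    v[w] = model_guiding_log(m, x.data());
  }
  return v;
}

// [[Rcpp::export]]
NumericVector guiding_grad_cpp(List model, NumericVector x) {
  Model m = parse_model(model);
  NumericVector g(m.n_dof);
  model_guiding_grad(m, x.begin(), g.begin());
  return g;
}

// [[Rcpp::export]]
double local_energy_cpp(List model, NumericVector x) {
  Model m = parse_model(model);
  std::vector<double> gs(m.n_dof), lap(m.n_at);
  return model_local_energy(m, x.begin(), gs.data(), lap.data());
}

// [[Rcpp::export]]
NumericVector local_energy_ensemble_cpp(List model, NumericMatrix X) {
  Model m = parse_model(model);
  const int n = X.nrow();
  NumericVector v(n);
  std::vector<double> x(m.n_dof), gs(m.n_dof), lap(m.n_at);
  for (int w = 0; w < n; ++w) {
    for (int c = 0; c < m.n_dof; ++c) x[c] = X(w, c);
    v[w] = model_local_energy(m, x.data(), gs.data(), lap.data());
  }
  return v;
}

// [[Rcpp::export]]
NumericVector dipole_cpp(List model, NumericVector x) {
  Model m = parse_model(model);
  NumericVector mu(3);
  model_dipole(m, x.begin(), mu.begin());
  return mu;
}

// [[Rcpp::export]]
NumericMatrix dipole_ensemble_cpp(List model, NumericMatrix X) {
  Model m = parse_model(model);
  const int n = X.nrow();
  NumericMatrix out(n, 3);
  std::vector<double> x(m.n_dof);
  double mu[3];
  for (int w = 0; w < n; ++w) {
    for (int c = 0; c < m.n_dof; ++c) x[c] = X(w, c);
    model_dipole(m, x.data(), mu);
    out(w, 0) = mu[0]; out(w, 1) = mu[1]; out(w, 2) = mu[2];
  }
  return out;
}
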