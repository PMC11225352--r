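// Exact piecewise propagation of the linear compartment system
//   x' = A x + prod_rate * s(t) * e1
// with s(t) a per-segment sum of terms coef * t^pow * exp(rate * t)
// (pow in {0,1}) and instantaneous withdrawal events at the sampling times.
// Matrix exponentials use Armadillo's scaling-and-squaring expmat; results
// are identical (to rounding) to the reference R propagation.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <map>

using namespace arma;

struct Basis {
  mat W;      // 5 x m particular-solution vectors
  vec mu;     // m exponential rates
  vec pw;     // m polynomial powers (0 or 1)
  bool empty;
};

static Basis make_basis(const mat& A, const mat& terms) {
  Basis b;
  b.empty = (terms.n_rows == 0);
  if (b.empty) return b;
  const uword n = A.n_rows;
  vec e1 = zeros<vec>(n); e1(0) = 1.0;
  std::vector<vec> cols;
  std::vector<double> mus, pws;
  for (uword i = 0; i < terms.n_rows; ++i) {
    const double coef = terms(i, 0), mu = terms(i, 1), pw = terms(i, 2);
    if (pw == 0.0) {
      mat M = mu * eye<mat>(n, n) - A;
      if (rcond(M) < 1e-13)          // mu collides with an eigenvalue
        M += 1e-10 * eye<mat>(n, n);
      vec w = solve(M, e1);
      cols.push_back(w * coef); mus.push_back(mu); pws.push_back(0.0);
    } else if (mu == 0.0) {
      vec b0 = -solve(A, e1) * coef;
      vec a0 = solve(A, b0);
      cols.push_back(a0); mus.push_back(0.0); pws.push_back(0.0);
      cols.push_back(b0); mus.push_back(0.0); pws.push_back(1.0);
    } else {
      mat M = mu * eye<mat>(n, n) - A;
      if (rcond(M) < 1e-13)
        M += 1e-10 * eye<mat>(n, n);
      vec w2 = solve(M, e1) * coef;
      vec w1 = solve(M, vec(-w2));
      cols.push_back(w1); mus.push_back(mu); pws.push_back(0.0);
      cols.push_back(w2); mus.push_back(mu); pws.push_back(1.0);
    }
  }
  b.W.set_size(n, cols.size());
  b.mu.set_size(cols.size());
  b.pw.set_size(cols.size());
  for (size_t j = 0; j < cols.size(); ++j) {
    b.W.col(j) = cols[j]; b.mu(j) = mus[j]; b.pw(j) = pws[j];
  }
  return b;
}

static vec basis_at(const Basis& b, double t, double scale) {
  if (b.empty || scale == 0.0) return zeros<vec>(5);
  vec f = exp(b.mu * t);
  for (uword j = 0; j < b.pw.n_elem; ++j) if (b.pw(j) == 1.0) f(j) *= t;
  return (b.W * f) * scale;
}

// [[Rcpp::export]]
Rcpp::List sim_core(const arma::mat& A, double prod_rate,
                    const arma::vec& x_u0, const arma::vec& cuts,
                    const arma::ivec& seg_idx, const Rcpp::List& lab_terms,
                    const Rcpp::List& unl_terms, const arma::vec& tt,
                    double frac_draw) {
  const uword n_seg = lab_terms.size();
  std::vector<Basis> bl(n_seg), bu(n_seg);
  std::vector<bool> made(n_seg, false);
  std::map<double, mat> expms;

  const uword nt = tt.n_elem;
  mat Lm(nt, 5, fill::zeros), Um(nt, 5, fill::zeros);
  vec x_l = zeros<vec>(5), x_u = x_u0;
  uword k_out = 0;

  if (cuts(0) == tt(0)) {
    Lm.row(0) = x_l.t(); Um.row(0) = x_u.t();
    if (frac_draw > 0) {
      x_l(4) += frac_draw * (x_l(2) - x_l(4));
      x_u(4) += frac_draw * (x_u(2) - x_u(4));
    }
    k_out = 1;
  }
  for (uword i = 0; i + 1 < cuts.n_elem; ++i) {
    const double a = cuts(i), b = cuts(i + 1), dt = b - a;
    auto it = expms.find(dt);
    if (it == expms.end())
      it = expms.emplace(dt, expmat(A * dt)).first;
    const mat& E = it->second;
    const uword s = static_cast<uword>(seg_idx(i));
    if (!made[s]) {
      bl[s] = make_basis(A, Rcpp::as<mat>(lab_terms[s]));
      bu[s] = make_basis(A, Rcpp::as<mat>(unl_terms[s]));
      made[s] = true;
    }
    x_l = E * (x_l - basis_at(bl[s], a, prod_rate)) +
      basis_at(bl[s], b, prod_rate);
    x_u = E * (x_u - basis_at(bu[s], a, prod_rate)) +
      basis_at(bu[s], b, prod_rate);
    if (k_out < nt && b == tt(k_out)) {
      x_l.clamp(0.0, datum::inf); x_u.clamp(0.0, datum::inf);
      Lm.row(k_out) = x_l.t(); Um.row(k_out) = x_u.t();
      if (frac_draw > 0) {
        x_l(4) += frac_draw * (x_l(2) - x_l(4));
        x_u(4) += frac_draw * (x_u(2) - x_u(4));
      }
      ++k_out;
    }
  }
  return Rcpp::List::create(Rcpp::Named("labeled") = Lm,
                            Rcpp::Named("unlabeled") = Um);
}
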