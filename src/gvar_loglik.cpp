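// FIML objective for the random-intercept panel GVAR, plus numeric
// derivatives. Parameter vector layout (must match the R packing):
//   free entries of B (column-major over the temporal pattern),
//   free lower-triangle incl. diagonal of K_zeta,
//   free lower-triangle incl. diagonal of K_between,
//   wave means nu (wave-major, always free).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double BIG = 1e10; // proposal-rejection value for invalid parameters

struct GvarProb {
  int p, T, d;
  umat patB, patKz, patKb;
  std::vector<uvec> idx;     // observed cell indices per missingness pattern
  std::vector<double> n;     // persons per pattern
  std::vector<vec> ybar;     // pattern mean vector
  std::vector<mat> S;        // pattern scatter / n (around ybar)
  double scale;              // objective = scale * (-loglik); 1/n_total in fits
};

static GvarProb parse_prob(const Rcpp::List& prob) {
  GvarProb P;
  P.p = Rcpp::as<int>(prob["p"]);
  P.T = Rcpp::as<int>(prob["n_waves"]);
  P.d = P.p * P.T;
  P.patB  = Rcpp::as<umat>(prob["pat_beta"]);
  P.patKz = Rcpp::as<umat>(prob["pat_kz"]);
  P.patKb = Rcpp::as<umat>(prob["pat_kb"]);
  Rcpp::List idx = prob["pat_idx"];
  Rcpp::NumericVector nn = prob["pat_n"];
  Rcpp::List yb = prob["pat_ybar"];
  Rcpp::List sc = prob["pat_scatter"];
  for (int g = 0; g < idx.size(); ++g) {
    P.idx.push_back(Rcpp::as<uvec>(idx[g]));  // 0-based
    P.n.push_back(nn[g]);
    P.ybar.push_back(Rcpp::as<vec>(yb[g]));
    P.S.push_back(Rcpp::as<mat>(sc[g]));
  }
  P.scale = Rcpp::as<double>(prob["scale"]);
  return P;
}

static void unpack(const vec& theta, const GvarProb& P,
                   mat& B, mat& Kz, mat& Kb, vec& nu) {
  int p = P.p, pos = 0;
  B.zeros(p, p); Kz.zeros(p, p); Kb.zeros(p, p);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < p; ++i)
      if (P.patB(i, j)) B(i, j) = theta(pos++);
  for (int j = 0; j < p; ++j)
    for (int i = j; i < p; ++i)
      if (P.patKz(i, j)) { Kz(i, j) = theta(pos); Kz(j, i) = theta(pos); ++pos; }
  for (int j = 0; j < p; ++j)
    for (int i = j; i < p; ++i)
      if (P.patKb(i, j)) { Kb(i, j) = theta(pos); Kb(j, i) = theta(pos); ++pos; }
  nu = theta.subvec(pos, pos + P.d - 1);
}

static double negll(const vec& theta, const GvarProb& P) {
  const int p = P.p, T = P.T, d = P.d;
  mat B, Kz, Kb; vec nu;
  unpack(theta, P, B, Kz, Kb, nu);

  mat Lz, Lb;
  if (!chol(Lz, Kz, "lower")) return BIG;
  if (!chol(Lb, Kb, "lower")) return BIG;
  cx_vec ev;
  if (!eig_gen(ev, B)) return BIG;
  if (max(abs(ev)) >= 1.0 - 1e-8) return BIG;

  mat Sz, Sb;
  if (!inv_sympd(Sz, Kz)) return BIG;
  if (!inv_sympd(Sb, Kb)) return BIG;

  // stationary within-person covariance: Sigma* = B Sigma* B' + Sigma_zeta,
  // by squaring/doubling: S <- S + A S A', A <- A^2 (quadratic convergence
  // since the spectral radius of B is below 1)
  mat Sstar = Sz, A = B;
  for (int it = 0; it < 64; ++it) {
    Sstar += A * Sstar * A.t();
    A = A * A;
    if (norm(A, "fro") < 1e-14) break;
  }
  Sstar = 0.5 * (Sstar + Sstar.t());

  // stacked implied covariance: block(t,s), t>=s, = B^{t-s} Sigma* + Sigma_B
  std::vector<mat> Bp(T);
  Bp[0] = eye(p, p);
  for (int t = 1; t < T; ++t) Bp[t] = B * Bp[t - 1];
  mat Sig(d, d);
  for (int t = 0; t < T; ++t)
    for (int s = 0; s <= t; ++s) {
      mat blk = Bp[t - s] * Sstar + Sb;
      Sig.submat(t * p, s * p, t * p + p - 1, s * p + p - 1) = blk;
      if (t != s)
        Sig.submat(s * p, t * p, s * p + p - 1, t * p + p - 1) = blk.t();
    }

  const double l2pi = std::log(2.0 * M_PI);
  double ll = 0.0;
  for (size_t g = 0; g < P.idx.size(); ++g) {
    const uvec& o = P.idx[g];
    const int dg = o.n_elem;
    mat Sg = Sig.submat(o, o);
    mat L;
    if (!chol(L, Sg, "lower")) return BIG;
    double logdet = 2.0 * accu(log(L.diag()));
    mat M  = solve(trimatl(L), P.S[g]);
    mat M2 = solve(trimatl(L), M.t());
    double tr = trace(M2);
    vec u = solve(trimatl(L), P.ybar[g] - nu.elem(o));
    ll += -0.5 * P.n[g] * (dg * l2pi + logdet + tr + dot(u, u));
  }
  return -ll * P.scale;
}

// [[Rcpp::export]]
double cpp_gvar_negll(const arma::vec& theta, const Rcpp::List& prob) {
  GvarProb P = parse_prob(prob);
  return negll(theta, P);
}

// central differences with one-sided fallback at the feasibility boundary
// [[Rcpp::export]]
arma::vec cpp_gvar_grad(const arma::vec& theta, const Rcpp::List& prob,
                        const double h = 1e-6) {
  GvarProb P = parse_prob(prob);
  const int k = theta.n_elem;
  vec g(k, fill::zeros);
  double f0 = negll(theta, P);
  vec th = theta;
  for (int i = 0; i < k; ++i) {
    double xi = theta(i);
    th(i) = xi + h; double fp = negll(th, P);
    th(i) = xi - h; double fm = negll(th, P);
    th(i) = xi;
    if (fp < BIG / 2 && fm < BIG / 2)      g(i) = (fp - fm) / (2 * h);
    else if (fp < BIG / 2)                 g(i) = (fp - f0) / h;
    else if (fm < BIG / 2)                 g(i) = (f0 - fm) / h;
    else                                   g(i) = 0.0;
  }
  return g;
}

// [[Rcpp::export]]
arma::mat cpp_gvar_hessian(const arma::vec& theta, const Rcpp::List& prob,
                           const double h = 1e-4) {
  GvarProb P = parse_prob(prob);
  const int k = theta.n_elem;
  vec hs(k);
  for (int i = 0; i < k; ++i) hs(i) = h * (1.0 + std::abs(theta(i)));
  mat H(k, k, fill::zeros);
  vec th = theta;
  for (int i = 0; i < k; ++i) {
    for (int j = 0; j <= i; ++j) {
      double xi = theta(i), xj = theta(j);
      double fpp, fpm, fmp, fmm;
      if (i == j) {
        double f0 = negll(theta, P);
        th(i) = xi + hs(i); fpp = negll(th, P);
        th(i) = xi - hs(i); fmm = negll(th, P);
        th(i) = xi;
        H(i, i) = (fpp - 2 * f0 + fmm) / (hs(i) * hs(i));
      } else {
        th(i) = xi + hs(i); th(j) = xj + hs(j); fpp = negll(th, P);
        th(j) = xj - hs(j); fpm = negll(th, P);
        th(i) = xi - hs(i); fmm = negll(th, P);
        th(j) = xj + hs(j); fmp = negll(th, P);
        th(i) = xi; th(j) = xj;
        H(i, j) = H(j, i) = (fpp - fpm - fmp + fmm) / (4 * hs(i) * hs(j));
      }
    }
  }
  return H;
}
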