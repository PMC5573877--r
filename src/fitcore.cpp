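// Core numerics for multigroup CFA maximum-likelihood estimation.
//
// The model for one group is Sigma = Lambda Psi Lambda' + Theta.  Because the
// configural model carries no cross-group constraints, each group can be
// fitted independently; the R layer assembles multigroup results.
//
// Free parameters are addressed through an integer map (q x 3, zero-based):
//   column 0: matrix id (1 = Lambda, 2 = Theta, 3 = Psi)
//   column 1: row index
//   column 2: column index (row <= col for symmetric matrices)
//
// Every parameter's derivative matrix has the rank-two form
//   dSigma/dtheta_a = u_a v_a' + v_a u_a'
// (diagonal entries use u = 0.5 e_i, v = e_i), which gives closed forms for
// the gradient of the ML discrepancy F and its expected (Fisher) Hessian:
//   g_a     = 2 u_a' A v_a,                 A = K - K S K,  K = Sigma^-1
//   H_(a,b) = 2 [ (U'KU)(V'KV) + (U'KV) o (U'KV)' ]   (elementwise products)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void set_params(mat& L, mat& Th, mat& Ps, const imat& map, const vec& th) {
  for (uword a = 0; a < map.n_rows; ++a) {
    const int m = map(a, 0), i = map(a, 1), j = map(a, 2);
    if (m == 1) {
      L(i, j) = th(a);
    } else if (m == 2) {
      Th(i, j) = th(a); Th(j, i) = th(a);
    } else {
      Ps(i, j) = th(a); Ps(j, i) = th(a);
    }
  }
}

// Sigma, its inverse and log-determinant; false if Sigma is not PD.
static bool implied(const mat& L, const mat& Th, const mat& Ps,
                    mat& Sig, mat& K, double& ld) {
  Sig = symmatu(L * Ps * L.t() + Th);
  mat R;
  if (!chol(R, Sig)) return false;
  ld = 2.0 * accu(log(R.diag()));
  mat Ri = inv(trimatu(R));
  K = Ri * Ri.t();
  return true;
}

static double fml_value(const mat& S, const mat& K, double ldSig,
                        double ldS, int p) {
  return ldSig - ldS + accu(S % K) - (double)p;
}

static void build_UV(mat& U, mat& V, const imat& map,
                     const mat& L, const mat& Ps) {
  const uword p = L.n_rows, q = map.n_rows;
  const mat LP = L * Ps;
  U.zeros(p, q);
  V.zeros(p, q);
  for (uword a = 0; a < q; ++a) {
    const int m = map(a, 0), i = map(a, 1), j = map(a, 2);
    if (m == 1) {                 // loading (indicator i, factor j)
      U(i, a) = 1.0;
      V.col(a) = LP.col(j);
    } else if (m == 2) {          // residual (co)variance
      if (i == j) { U(i, a) = 0.5; V(i, a) = 1.0; }
      else        { U(i, a) = 1.0; V(j, a) = 1.0; }
    } else {                      // factor (co)variance
      if (i == j) { U.col(a) = 0.5 * L.col(i); V.col(a) = L.col(i); }
      else        { U.col(a) = L.col(i);       V.col(a) = L.col(j); }
    }
  }
}

static vec gradient_F(const mat& A, const mat& U, const mat& V) {
  const mat AV = A * V;
  return 2.0 * sum(U % AV, 0).t();
}

static mat einfo_F(const mat& K, const mat& U, const mat& V) {
  const mat KU = K * U, KV = K * V;
  const mat P1 = U.t() * KU, P2 = V.t() * KV, P3 = U.t() * KV;
  return 2.0 * (P1 % P2 + P3 % P3.t());
}

static double logdet_sym(const mat& S) {
  double val, sign;
  log_det(val, sign, S);
  if (sign <= 0) Rcpp::stop("sample covariance matrix is not positive definite");
  return val;
}

// Fisher scoring with step halving on the ML discrepancy of a single group.
// [[Rcpp::export]]
Rcpp::List cfa_fit_group_cpp(const arma::mat& S,
                             arma::mat L, arma::mat Th, arma::mat Ps,
                             const arma::imat& map, const arma::vec& start,
                             double tol = 1e-6, int maxit = 500) {
  const int p = S.n_rows;
  const double ldS = logdet_sym(S);

  vec th = start;
  set_params(L, Th, Ps, map, th);

  mat Sig, K;
  double ldSig;
  if (!implied(L, Th, Ps, Sig, K, ldSig))
    Rcpp::stop("implied covariance at the starting values is not positive definite");

  double F = fml_value(S, K, ldSig, ldS, p);
  double maxg = datum::nan;
  bool converged = false;
  int it = 0;

  for (it = 0; it < maxit; ++it) {
    const mat A = K - K * S * K;
    mat U, V;
    build_UV(U, V, map, L, Ps);
    const vec g = gradient_F(A, U, V);
    maxg = g.n_elem ? abs(g).max() : 0.0;
    if (maxg < tol) { converged = true; break; }

    mat H = einfo_F(K, U, V);
    vec d;
    if (!solve(d, H, g, solve_opts::no_approx)) {
      H.diag() += 1e-8 * (trace(H) / H.n_rows + 1.0);
      if (!solve(d, H, g, solve_opts::no_approx)) break;
    }

    double step = 1.0;
    bool accepted = false;
    for (int h = 0; h < 40; ++h) {
      const vec thn = th - step * d;
      mat Ln = L, Thn = Th, Psn = Ps;
      set_params(Ln, Thn, Psn, map, thn);
      mat Sign, Kn;
      double ldn;
      if (implied(Ln, Thn, Psn, Sign, Kn, ldn)) {
        const double Fn = fml_value(S, Kn, ldn, ldS, p);
        if (Fn < F + 1e-12) {
          th = thn; L = Ln; Th = Thn; Ps = Psn;
          Sig = Sign; K = Kn; F = Fn;
          accepted = true;
          break;
        }
      }
      step *= 0.5;
    }
    if (!accepted) break;  // no admissible decrease in this direction
  }

  return Rcpp::List::create(
    Rcpp::Named("theta") = th,
    Rcpp::Named("F") = F,
    Rcpp::Named("max_grad") = maxg,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("Sigma") = Sig,
    Rcpp::Named("Lambda") = L,
    Rcpp::Named("Theta") = Th,
    Rcpp::Named("Psi") = Ps);
}

// Gradient of F and expected information over an arbitrary parameter map,
// evaluated at the supplied (typically fitted) matrices.  Used for score
// tests over free-plus-candidate parameter sets.
// [[Rcpp::export]]
Rcpp::List cfa_score_info_cpp(const arma::mat& S,
                              const arma::mat& L, const arma::mat& Th,
                              const arma::mat& Ps, const arma::imat& map) {
  mat Sig, K;
  double ldSig;
  if (!implied(L, Th, Ps, Sig, K, ldSig))
    Rcpp::stop("implied covariance matrix is not positive definite");
  const mat A = K - K * S * K;
  mat U, V;
  build_UV(U, V, map, L, Ps);
  return Rcpp::List::create(
    Rcpp::Named("gradient") = gradient_F(A, U, V),
    Rcpp::Named("information") = einfo_F(K, U, V));
}

// ML discrepancy for one group at fixed matrices (no optimisation).
// [[Rcpp::export]]
double cfa_fml_group_cpp(const arma::mat& S, const arma::mat& L,
                         const arma::mat& Th, const arma::mat& Ps) {
  mat Sig, K;
  double ldSig;
  if (!implied(L, Th, Ps, Sig, K, ldSig))
    Rcpp::stop("implied covariance matrix is not positive definite");
  return fml_value(S, K, ldSig, logdet_sym(S), S.n_rows);
}
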