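// Core SPD-manifold primitives under the affine-invariant metric, plus a
// batched zero-phase IIR filter. All eigen work goes through eig_sym on
// symmetrized/whitened products; explicit inverses are never formed.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat sym(const mat& A) { return 0.5 * (A + A.t()); }

// eigendecomposition-based matrix functions for symmetric input
static mat fun_sym(const mat& A, double (*f)(double)) {
  vec eval;
  mat evec;
  eig_sym(eval, evec, sym(A));
  vec fe(eval.n_elem);
  for (uword i = 0; i < eval.n_elem; ++i) fe(i) = f(eval(i));
  return evec * diagmat(fe) * evec.t();
}

static double log_chk(double x) {
  if (x <= 0) Rcpp::stop("matrix is not positive definite (eigenvalue %g <= 0)", x);
  return std::log(x);
}
static double sqrt_chk(double x) {
  if (x <= 0) Rcpp::stop("matrix is not positive definite (eigenvalue %g <= 0)", x);
  return std::sqrt(x);
}
static double invsqrt_chk(double x) {
  if (x <= 0) Rcpp::stop("matrix is not positive definite (eigenvalue %g <= 0)", x);
  return 1.0 / std::sqrt(x);
}

// [[Rcpp::export]]
arma::mat cpp_logm_spd(const arma::mat& A) { return fun_sym(A, log_chk); }

// [[Rcpp::export]]
arma::mat cpp_expm_sym(const arma::mat& A) { return fun_sym(A, std::exp); }

// [[Rcpp::export]]
arma::mat cpp_sqrtm_spd(const arma::mat& A) { return fun_sym(A, sqrt_chk); }

// [[Rcpp::export]]
arma::mat cpp_invsqrtm_spd(const arma::mat& A) { return fun_sym(A, invsqrt_chk); }

// geodesic distance via generalized eigenvalues: lambda(P1^-1 P2) equals
// eig_sym(L^-1 P2 L^-T) with P1 = L L^T
// [[Rcpp::export]]
double cpp_airm_dist(const arma::mat& P1, const arma::mat& P2) {
  mat L = chol(sym(P1), "lower");
  mat W = solve(trimatl(L), sym(P2));
  mat A = solve(trimatl(L), W.t());
  vec ev = eig_sym(sym(A));
  double s = 0;
  for (uword i = 0; i < ev.n_elem; ++i) {
    if (ev(i) <= 0)
      Rcpp::stop("non-positive generalized eigenvalue %g; inputs not SPD", ev(i));
    double l = std::log(ev(i));
    s += l * l;
  }
  return std::sqrt(s);
}

// [[Rcpp::export]]
arma::mat cpp_airm_pairwise(const arma::cube& P) {
  uword I = P.n_slices;
  mat D(I, I, fill::zeros);
  std::vector<mat> chols(I);
  for (uword i = 0; i < I; ++i) chols[i] = chol(sym(P.slice(i)), "lower");
  for (uword i = 0; i + 1 < I; ++i) {
    const mat& L = chols[i];
    for (uword j = i + 1; j < I; ++j) {
      mat W = solve(trimatl(L), sym(P.slice(j)));
      mat A = solve(trimatl(L), W.t());
      vec ev = eig_sym(sym(A));
      double s = 0;
      for (uword k = 0; k < ev.n_elem; ++k) {
        if (ev(k) <= 0)
          Rcpp::stop("non-positive generalized eigenvalue between trials %d and %d",
                     (int)i + 1, (int)j + 1);
        double l = std::log(ev(k));
        s += l * l;
      }
      D(i, j) = D(j, i) = std::sqrt(s);
    }
  }
  return D;
}

// [[Rcpp::export]]
arma::mat cpp_eucl_pairwise(const arma::cube& P) {
  uword I = P.n_slices;
  mat D(I, I, fill::zeros);
  for (uword i = 0; i + 1 < I; ++i)
    for (uword j = i + 1; j < I; ++j)
      D(i, j) = D(j, i) = norm(P.slice(i) - P.slice(j), "fro");
  return D;
}

// one evaluation pass: manifold gradient, gradient norm, and the Frechet
// cost sum_k d_R^2(M, P_k), all from the same whitened matrix logs
static void karcher_eval(const cube& P, const mat& M, mat& G, double& gnorm,
                         double& cost) {
  uword I = P.n_slices;
  mat Mi = fun_sym(M, invsqrt_chk);
  G.zeros(M.n_rows, M.n_cols);
  cost = 0;
  for (uword k = 0; k < I; ++k) {
    mat L = fun_sym(Mi * P.slice(k) * Mi, log_chk);
    cost += dot(L, L);
    G += L;
  }
  G /= (double)I;
  gnorm = norm(G, "fro");
}

// Karcher (Frechet) mean by adaptive-step geodesic gradient descent,
// initialized at the arithmetic mean
// [[Rcpp::export]]
Rcpp::List cpp_karcher_mean(const arma::cube& P, double tol, int max_iter) {
  mat M = mean(P, 2);
  mat G, G1;
  double gnorm, cost, gnorm1, cost1, tau = 1.0;
  karcher_eval(P, M, G, gnorm, cost);
  int it = 0;
  // Adaptive step with uncapped growth: dispersed covariance sets have
  // very ill-conditioned Frechet Hessians, and the slow modes need
  // effective steps 1/(1 - contraction rate) >> 1. A candidate is kept iff
  // it strictly lowers the cost or lowers the gradient norm; once the cost
  // plateaus at machine precision, only gradient-norm decreases are
  // accepted, which stops the step from wandering at the floor.
  for (it = 0; it < max_iter && gnorm > tol; ++it) {
    if (tau * gnorm > 20.0) tau = 20.0 / gnorm;  // expm overflow guard
    mat Ms = fun_sym(M, sqrt_chk);
    mat M1 = sym(Ms * fun_sym(tau * G, std::exp) * Ms);
    karcher_eval(P, M1, G1, gnorm1, cost1);
    if (cost1 < cost * (1.0 - 1e-15) || gnorm1 < gnorm) {
      M = M1; G = G1; gnorm = gnorm1; cost = cost1;
      tau *= 1.3;
    } else {
      tau *= 0.5;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("mean") = M, Rcpp::Named("grad_norm") = gnorm,
      Rcpp::Named("iterations") = it,
      Rcpp::Named("converged") = (gnorm <= tol));
}

// Tangent-space coordinates at `ref`: row-major upper-triangle vectorization
// of logm(ref^-1/2 P_i ref^-1/2), off-diagonals weighted by sqrt(2) so the
// vector norm equals the geodesic distance to the reference.
// [[Rcpp::export]]
arma::mat cpp_tangent_map(const arma::cube& P, const arma::mat& ref) {
  uword I = P.n_slices, n = ref.n_rows;
  uword m = n * (n + 1) / 2;
  mat W = fun_sym(ref, invsqrt_chk);
  mat S(I, m);
  const double w = std::sqrt(2.0);
  for (uword k = 0; k < I; ++k) {
    mat Lg = fun_sym(W * P.slice(k) * W, log_chk);
    uword c = 0;
    for (uword i = 0; i < n; ++i)
      for (uword j = i; j < n; ++j)
        S(k, c++) = (i == j) ? Lg(i, j) : w * Lg(i, j);
  }
  return S;
}

// ---- zero-phase IIR filtering -------------------------------------------

// steady-state initial conditions for a unit step (transposed direct form II)
static vec lfilter_zi(const vec& b, const vec& a) {
  uword n = std::max(b.n_elem, a.n_elem);
  vec bb(n, fill::zeros), aa(n, fill::zeros);
  bb.head(b.n_elem) = b;
  aa.head(a.n_elem) = a;
  bb /= aa(0);
  aa /= aa(0);
  // companion matrix of aa, transposed
  mat A(n - 1, n - 1, fill::zeros);
  for (uword i = 0; i < n - 1; ++i) A(i, 0) = -aa(i + 1);
  for (uword i = 0; i + 1 < n - 1; ++i) A(i, i + 1) = 1.0;
  vec B = bb.tail(n - 1) - aa.tail(n - 1) * bb(0);
  mat IminusA = eye(n - 1, n - 1) - A;
  return solve(IminusA, B);
}

static vec filt_zi(const vec& b, const vec& a, const vec& x, const vec& zi) {
  uword n = std::max(b.n_elem, a.n_elem);
  vec bb(n, fill::zeros), aa(n, fill::zeros);
  bb.head(b.n_elem) = b;
  aa.head(a.n_elem) = a;
  bb /= aa(0);
  aa /= aa(0);
  vec z = zi;  // length n-1
  vec y(x.n_elem);
  for (uword t = 0; t < x.n_elem; ++t) {
    double xt = x(t);
    double yt = bb(0) * xt + (n > 1 ? z(0) : 0.0);
    for (uword i = 0; i + 1 < n - 1; ++i)
      z(i) = bb(i + 1) * xt + z(i + 1) - aa(i + 1) * yt;
    if (n > 1) z(n - 2) = bb(n - 1) * xt - aa(n - 1) * yt;
    y(t) = yt;
  }
  return y;
}

// forward-backward filter with odd-reflection edge padding; rows of X are
// independent signals
// [[Rcpp::export]]
arma::mat cpp_filtfilt_rows(const arma::vec& b, const arma::vec& a,
                            const arma::mat& X) {
  uword n = std::max(b.n_elem, a.n_elem);
  uword edge = 3 * (n - 1);
  uword ns = X.n_cols;
  if (ns <= edge)
    Rcpp::stop("signal too short for zero-phase filtering (need > %d samples)",
               (int)edge);
  vec zi = lfilter_zi(b, a);
  mat Y(X.n_rows, ns);
  for (uword r = 0; r < X.n_rows; ++r) {
    rowvec x = X.row(r);
    vec ext(ns + 2 * edge);
    for (uword i = 0; i < edge; ++i) ext(i) = 2 * x(0) - x(edge - i);
    for (uword i = 0; i < ns; ++i) ext(edge + i) = x(i);
    for (uword i = 0; i < edge; ++i)
      ext(edge + ns + i) = 2 * x(ns - 1) - x(ns - 2 - i);
    vec y = filt_zi(b, a, ext, zi * ext(0));
    y = reverse(y);
    y = filt_zi(b, a, y, zi * y(0));
    y = reverse(y);
    Y.row(r) = y.subvec(edge, edge + ns - 1).t();
  }
  return Y;
}

// trial-wise covariance: P_k = X_k X_k^T / (ns - 1), optional row centering
// and trace-normalized shrinkage toward the identity
// [[Rcpp::export]]
arma::cube cpp_scm_cube(const arma::cube& X, double shrinkage, bool center) {
  uword nc = X.n_rows, ns = X.n_cols, I = X.n_slices;
  cube P(nc, nc, I);
  for (uword k = 0; k < I; ++k) {
    mat Xk = X.slice(k);
    if (center) Xk.each_col() -= mean(Xk, 1);
    mat C = Xk * Xk.t() / double(ns - 1);
    if (shrinkage > 0) {
      double mu = trace(C) / double(nc);
      C = (1.0 - shrinkage) * C + shrinkage * mu * eye(nc, nc);
    }
    P.slice(k) = sym(C);
  }
  return P;
}
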