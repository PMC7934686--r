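// Per-voxel diffusion tensor estimation engines.
//
// Parameter vector beta (length 7) is ordered
//   [ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz]
// matching the design matrix rows
//   [1, -b gx^2, -b gy^2, -b gz^2, -2 b gx gy, -2 b gx gz, -2 b gy gz].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double EXP_CAP = 700.0; // exp() overflow guard on the linear predictor

// Diagnostic flag bits (kept in sync with R/tensor_fit.R)
static const int FLAG_EMPTY = 1;      // all-zero voxel, tensor left at zero
static const int FLAG_CLAMPED = 2;    // non-positive signals clamped before log
static const int FLAG_NOCONV = 4;     // NLLS did not converge; LLS estimate returned
static const int FLAG_REVERTED = 8;   // RESTORE kept too few volumes; WLLS returned

static arma::vec predict_signal(const arma::mat& X, const arma::vec& beta) {
  arma::vec eta = X * beta;
  eta.transform([](double v) { return v > EXP_CAP ? EXP_CAP : v; });
  return arma::exp(eta);
}

static double objective(const arma::vec& S, const arma::mat& X,
                        const arma::vec& beta, const arma::vec& w) {
  arma::vec r = S - predict_signal(X, beta);
  return arma::dot(w, r % r);
}

// Damped Gauss-Newton (Levenberg-Marquardt schedule) for the unconstrained
// exponential model, minimising sum w_i (S_i - exp(x_i beta))^2.
// Returns true on convergence (relative step < tol).
static bool lm_fit(const arma::vec& S, const arma::mat& X, const arma::vec& w,
                   arma::vec& beta, int max_iter, double tol) {
  double lambda = 1e-3;
  double f = objective(S, X, beta, w);
  for (int it = 0; it < max_iter; ++it) {
    arma::vec m = predict_signal(X, beta);
    arma::vec r = S - m;
    arma::mat J = X.each_col() % m;            // dm/dbeta
    arma::mat A = J.t() * (J.each_col() % w);
    arma::vec g = J.t() * (w % r);
    bool stepped = false;
    for (int tries = 0; tries < 40; ++tries) {
      arma::mat Ad = A;
      for (arma::uword k = 0; k < Ad.n_rows; ++k)
        Ad(k, k) = A(k, k) * (1.0 + lambda) + 1e-300;
      arma::vec delta;
      if (!arma::solve(delta, Ad, g, arma::solve_opts::no_approx)) {
        lambda *= 10.0;
        continue;
      }
      arma::vec beta_try = beta + delta;
      double f_try = objective(S, X, beta_try, w);
      if (f_try <= f) {
        double rel = arma::norm(delta) / (arma::norm(beta) + 1e-300);
        beta = beta_try;
        f = f_try;
        lambda = std::max(lambda / 10.0, 1e-12);
        stepped = true;
        if (rel < tol) return true;
        break;
      }
      lambda *= 10.0;
      if (lambda > 1e12) return false;
    }
    if (!stepped) return false;
  }
  return false;
}

// --- Cholesky-parameterised (positive semidefinite) variant ----------------
// gamma = [ln S0, r11, r12, r13, r22, r23, r33], D = R'R with R upper
// triangular, guaranteeing D is PSD.

static arma::vec gamma_to_beta(const arma::vec& g) {
  double r11 = g(1), r12 = g(2), r13 = g(3), r22 = g(4), r23 = g(5), r33 = g(6);
  arma::vec beta(7);
  beta(0) = g(0);
  beta(1) = r11 * r11;                       // Dxx
  beta(2) = r12 * r12 + r22 * r22;           // Dyy
  beta(3) = r13 * r13 + r23 * r23 + r33 * r33; // Dzz
  beta(4) = r11 * r12;                       // Dxy
  beta(5) = r11 * r13;                       // Dxz
  beta(6) = r12 * r13 + r22 * r23;           // Dyz
  return beta;
}

static arma::mat dbeta_dgamma(const arma::vec& g) {
  double r11 = g(1), r12 = g(2), r13 = g(3), r22 = g(4), r23 = g(5), r33 = g(6);
  arma::mat P(7, 7, arma::fill::zeros);
  P(0, 0) = 1.0;
  P(1, 1) = 2.0 * r11;                        // Dxx
  P(2, 2) = 2.0 * r12; P(2, 4) = 2.0 * r22;   // Dyy
  P(3, 3) = 2.0 * r13; P(3, 5) = 2.0 * r23; P(3, 6) = 2.0 * r33; // Dzz
  P(4, 1) = r12; P(4, 2) = r11;               // Dxy
  P(5, 1) = r13; P(5, 3) = r11;               // Dxz
  P(6, 2) = r13; P(6, 3) = r12; P(6, 4) = r23; P(6, 5) = r22;   // Dyz
  return P;
}

static double objective_chol(const arma::vec& S, const arma::mat& X,
                             const arma::vec& gam, const arma::vec& w) {
  return objective(S, X, gamma_to_beta(gam), w);
}

static bool lm_fit_chol(const arma::vec& S, const arma::mat& X, const arma::vec& w,
                        arma::vec& gam, int max_iter, double tol) {
  double lambda = 1e-3;
  double f = objective_chol(S, X, gam, w);
  for (int it = 0; it < max_iter; ++it) {
    arma::vec beta = gamma_to_beta(gam);
    arma::vec m = predict_signal(X, beta);
    arma::vec r = S - m;
    arma::mat Jb = X.each_col() % m;
    arma::mat J = Jb * dbeta_dgamma(gam);
    arma::mat A = J.t() * (J.each_col() % w);
    arma::vec grad = J.t() * (w % r);
    bool stepped = false;
    for (int tries = 0; tries < 40; ++tries) {
      arma::mat Ad = A;
      for (arma::uword k = 0; k < Ad.n_rows; ++k)
        Ad(k, k) = A(k, k) * (1.0 + lambda) + 1e-300;
      arma::vec delta;
      if (!arma::solve(delta, Ad, grad, arma::solve_opts::no_approx)) {
        lambda *= 10.0;
        continue;
      }
      arma::vec gam_try = gam + delta;
      double f_try = objective_chol(S, X, gam_try, w);
      if (f_try <= f) {
        double rel = arma::norm(delta) / (arma::norm(gam) + 1e-300);
        gam = gam_try;
        f = f_try;
        lambda = std::max(lambda / 10.0, 1e-12);
        stepped = true;
        if (rel < tol) return true;
        break;
      }
      lambda *= 10.0;
      if (lambda > 1e12) return false;
    }
    if (!stepped) return false;
  }
  return false;
}

static arma::vec chol_init_from_beta(const arma::vec& beta) {
  arma::mat D(3, 3);
  D(0, 0) = beta(1); D(1, 1) = beta(2); D(2, 2) = beta(3);
  D(0, 1) = D(1, 0) = beta(4);
  D(0, 2) = D(2, 0) = beta(5);
  D(1, 2) = D(2, 1) = beta(6);
  arma::vec ev;
  arma::mat V;
  arma::eig_sym(ev, V, D);
  double mx = std::max(ev.max(), 1e-12);
  for (arma::uword i = 0; i < 3; ++i)
    ev(i) = std::max(ev(i), 1e-7 * mx);
  arma::mat Dp = V * arma::diagmat(ev) * V.t();
  arma::mat R;
  if (!arma::chol(R, Dp)) { // fall back to a scaled identity factor
    R = arma::eye(3, 3) * std::sqrt(1e-7 * mx);
  }
  arma::vec g(7);
  g(0) = beta(0);
  g(1) = R(0, 0); g(2) = R(0, 1); g(3) = R(0, 2);
  g(4) = R(1, 1); g(5) = R(1, 2); g(6) = R(2, 2);
  return g;
}

static arma::vec lls_solve(const arma::mat& X, const arma::vec& logS) {
  return arma::solve(X, logS);
}

static arma::vec wlls_solve(const arma::mat& X, const arma::vec& logS,
                            const arma::vec& beta_lls) {
  arma::vec eta = X * beta_lls;
  eta.transform([](double v) { return v > EXP_CAP / 2 ? EXP_CAP / 2 : v; });
  arma::vec w = arma::exp(2.0 * eta); // predicted squared signal from pass 1
  arma::mat Xw = X.each_col() % w;
  return arma::solve(X.t() * Xw, X.t() * (w % logS));
}

struct RestoreResult {
  arma::vec beta;
  arma::uvec outlier; // one per measurement
  int flag;
};

static RestoreResult restore_fit(const arma::vec& S, const arma::mat& X,
                                 const arma::vec& beta_lls, const arma::vec& beta_wlls,
                                 double sigma, int max_iter, double tol) {
  int n = S.n_elem;
  arma::vec ones_w(n, arma::fill::ones);
  RestoreResult out;
  out.outlier = arma::uvec(n, arma::fill::zeros);
  out.flag = 0;

  // (1) initial NLLS
  arma::vec beta = beta_lls;
  if (!lm_fit(S, X, ones_w, beta, max_iter, tol)) {
    beta = beta_lls;
  }
  arma::vec r = S - predict_signal(X, beta);

  // (2) early accept when every residual is within 3 sigma
  if (arma::max(arma::abs(r)) <= 3.0 * sigma) {
    out.beta = beta;
    return out;
  }

  // (3) iteratively reweighted NLLS with Geman-McClure weights
  arma::vec w_prev(n, arma::fill::zeros);
  for (int it = 0; it < 50; ++it) {
    r = S - predict_signal(X, beta);
    double C = 1.4826 * arma::median(arma::abs(r));
    double C2 = std::max(C * C, 1e-300);
    arma::vec w = 1.0 / (r % r + C2);
    arma::vec wn = w / arma::accu(w);
    if (it > 0 && arma::max(arma::abs(wn - w_prev)) < 1e-6) break;
    w_prev = wn;
    lm_fit(S, X, w, beta, max_iter, tol);
  }

  // (4) flag outliers from the robust fit, refit without them
  r = S - predict_signal(X, beta);
  arma::uvec keep = arma::find(arma::abs(r) <= 3.0 * sigma);
  for (arma::uword i = 0; i < (arma::uword)n; ++i)
    if (std::abs(r(i)) > 3.0 * sigma) out.outlier(i) = 1;

  // count retained diffusion-weighted rows (design column 2 is -b gx^2; a b=0
  // row has zeros in all tensor columns)
  arma::vec brow = arma::sum(arma::abs(X.cols(1, 6)), 1);
  int n_dwi = arma::accu(brow > 0);
  int kept_dwi = 0;
  for (arma::uword j = 0; j < keep.n_elem; ++j)
    if (brow(keep(j)) > 0) ++kept_dwi;
  int min_keep = std::max(7, n_dwi / 2);

  if (kept_dwi < min_keep) {                  // (5) too many exclusions
    out.beta = beta_wlls;
    out.flag = FLAG_REVERTED;
    return out;
  }

  arma::vec Sk = S(keep);
  arma::mat Xk = X.rows(keep);
  arma::vec ones_k(Sk.n_elem, arma::fill::ones);
  arma::vec beta_final = beta;
  if (!lm_fit(Sk, Xk, ones_k, beta_final, max_iter, tol)) {
    beta_final = beta;
  }
  out.beta = beta_final;
  return out;
}

// [[Rcpp::export]]
List cpp_fit_dti(const arma::mat& S, const arma::mat& X, std::string method,
                 double sigma, int max_iter, double tol) {
  const arma::uword n = S.n_rows, V = S.n_cols;
  arma::mat beta_out(7, V, arma::fill::zeros);
  arma::ivec flags(V, arma::fill::zeros);
  arma::ivec nout(V, arma::fill::zeros);
  arma::umat outliers;
  bool want_outliers = (method == "restore");
  if (want_outliers) outliers.zeros(n, V);

  for (arma::uword v = 0; v < V; ++v) {
    arma::vec Sv = S.col(v);
    double mx = Sv.max();
    if (!(mx > 0)) {
      flags(v) = FLAG_EMPTY;
      continue;
    }
    // log-domain guard: clamp non-positive signals before taking logs
    double floor_val = std::numeric_limits<double>::epsilon() * mx;
    int flag = 0;
    arma::vec Sc = Sv;
    for (arma::uword i = 0; i < n; ++i) {
      if (Sc(i) < floor_val) { Sc(i) = floor_val; flag |= FLAG_CLAMPED; }
    }
    arma::vec logS = arma::log(Sc);
    arma::vec beta = lls_solve(X, logS);

    if (method == "lls") {
      beta_out.col(v) = beta;
    } else if (method == "wlls") {
      beta_out.col(v) = wlls_solve(X, logS, beta);
    } else if (method == "nlls" || method == "nlls-pos") {
      arma::vec ones_w(n, arma::fill::ones);
      if (method == "nlls") {
        arma::vec b = beta;
        if (lm_fit(Sc, X, ones_w, b, max_iter, tol)) {
          beta_out.col(v) = b;
        } else {
          beta_out.col(v) = beta;
          flag |= FLAG_NOCONV;
        }
      } else {
        arma::vec g = chol_init_from_beta(beta);
        if (lm_fit_chol(Sc, X, ones_w, g, max_iter, tol)) {
          beta_out.col(v) = gamma_to_beta(g);
        } else {
          beta_out.col(v) = gamma_to_beta(chol_init_from_beta(beta));
          flag |= FLAG_NOCONV;
        }
      }
    } else if (method == "restore") {
      arma::vec bw = wlls_solve(X, logS, beta);
      RestoreResult rr = restore_fit(Sc, X, beta, bw, sigma, max_iter, tol);
      beta_out.col(v) = rr.beta;
      flag |= rr.flag;
      nout(v) = arma::accu(rr.outlier);
      outliers.col(v) = rr.outlier;
    } else {
      stop("unknown fit method '%s'", method.c_str());
    }
    flags(v) = flag;
  }

  List res = List::create(_["beta"] = beta_out,
                          _["flags"] = IntegerVector(flags.begin(), flags.end()),
                          _["n_outliers"] = IntegerVector(nout.begin(), nout.end()));
  if (want_outliers) res["outliers"] = outliers;
  return res;
}

// Eigen-decomposition of the 6-element tensors; FA from eigenvalues with
// negatives clamped to zero, result clipped to [0, 1]. Returned eigenvalues
// are the unclamped spectrum in descending order.
// [[Rcpp::export]]
List cpp_fa(const arma::mat& D6) {
  const arma::uword V = D6.n_cols;
  arma::vec fa(V, arma::fill::zeros);
  arma::mat evals(3, V, arma::fill::zeros);
  arma::mat D(3, 3);
  arma::vec ev;
  for (arma::uword v = 0; v < V; ++v) {
    D(0, 0) = D6(0, v); D(1, 1) = D6(1, v); D(2, 2) = D6(2, v);
    D(0, 1) = D(1, 0) = D6(3, v);
    D(0, 2) = D(2, 0) = D6(4, v);
    D(1, 2) = D(2, 1) = D6(5, v);
    if (!D.is_finite()) { fa(v) = NA_REAL; evals.col(v).fill(NA_REAL); continue; }
    arma::eig_sym(ev, D);
    evals(0, v) = ev(2); evals(1, v) = ev(1); evals(2, v) = ev(0);
    double l1 = std::max(ev(2), 0.0), l2 = std::max(ev(1), 0.0),
           l3 = std::max(ev(0), 0.0);
    double ss = l1 * l1 + l2 * l2 + l3 * l3;
    if (ss <= 0) { fa(v) = 0.0; continue; }
    double m = (l1 + l2 + l3) / 3.0;
    double num = (l1 - m) * (l1 - m) + (l2 - m) * (l2 - m) + (l3 - m) * (l3 - m);
    double val = std::sqrt(1.5) * std::sqrt(num / ss);
    fa(v) = std::min(std::max(val, 0.0), 1.0);
  }
  return List::create(_["fa"] = fa, _["evals"] = evals);
}
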