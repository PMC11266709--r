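// Elastic-net coordinate descent on the (1/(2n)) least-squares objective
//   (1/(2n)) ||y - b0 - X b||^2 + lambda * (alpha ||b||_1 + (1-alpha)/2 ||b||^2)
// Columns are centered internally (intercept recovered as ybar - xbar'b), so the
// solver works on Gram quantities G = Xc'Xc/n, g = Xc'yc/n. With p of order 20
// covariance updates make a full lambda path essentially free, which is what the
// replicate-based selection loop (tens of thousands of tuned fits) relies on.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double soft_threshold(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// One coordinate-descent solve at fixed (alpha, lambda), warm-started from
// beta. The gradient residual gr = g - G beta is maintained incrementally
// (rank-one axpy per changed coordinate), which is what makes long warm
// paths cheap. Returns number of sweeps used, or -1 on non-convergence.
static int cd_solve(const arma::mat& G, const arma::vec& g,
                    double alpha, double lambda,
                    arma::vec& beta, arma::vec& gr,
                    double tol, int max_sweeps,
                    std::vector<double>* obj_trace = nullptr,
                    double yty_n = 0.0) {
  const int p = G.n_cols;
  const double l1 = lambda * alpha;
  const double l2 = lambda * (1.0 - alpha);
  const double* Gmem = G.memptr();
  double* b = beta.memptr();
  double* r = gr.memptr();
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double max_change = 0.0;
    for (int j = 0; j < p; ++j) {
      const double gjj = Gmem[(size_t)j * p + j];
      const double denom = gjj + l2;
      if (denom <= 0.0) { b[j] = 0.0; continue; }
      const double rho = r[j] + gjj * b[j];
      const double bnew = soft_threshold(rho, l1) / denom;
      const double d = bnew - b[j];
      if (d != 0.0) {
        const double* Gj = Gmem + (size_t)j * p;
        for (int k = 0; k < p; ++k) r[k] -= d * Gj[k];
        b[j] = bnew;
        const double ad = std::fabs(d);
        if (ad > max_change) max_change = ad;
      }
    }
    if (obj_trace) {
      double fit = yty_n - 2.0 * arma::dot(beta, g) +
        arma::as_scalar(beta.t() * G * beta);
      double pen = lambda * (alpha * arma::norm(beta, 1) +
                             0.5 * (1.0 - alpha) * arma::dot(beta, beta));
      obj_trace->push_back(0.5 * fit + pen);
    }
    if (max_change < tol) return sweep + 1;
  }
  return -1;
}

static double lambda_max_from(const arma::vec& g, double alpha) {
  // KKT: all-zero solution iff lambda*alpha >= max|g|; alpha = 0 uses the
  // conventional floor so a finite ridge path exists.
  double a = std::max(alpha, 1e-3);
  return arma::abs(g).max() / a;
}

static arma::vec geometric_path(double lmax, double ratio, int nlambda) {
  arma::vec out(nlambda);
  if (nlambda == 1) { out[0] = lmax; return out; }
  double step = std::pow(ratio, 1.0 / (nlambda - 1));
  out[0] = lmax;
  for (int i = 1; i < nlambda; ++i) out[i] = out[i - 1] * step;
  return out;
}

// Solve a whole decreasing lambda path with warm starts; returns p x nlambda.
static arma::mat path_solve(const arma::mat& G, const arma::vec& g,
                            double alpha, const arma::vec& lambdas,
                            double tol, int max_sweeps, bool& ok) {
  const int p = G.n_cols, nl = lambdas.n_elem;
  arma::mat B(p, nl, arma::fill::zeros);
  arma::vec beta(p, arma::fill::zeros);
  arma::vec gr = g;  // gradient residual at beta = 0
  ok = true;
  for (int l = 0; l < nl; ++l) {
    int s = cd_solve(G, g, alpha, lambdas[l], beta, gr, tol, max_sweeps);
    if (s < 0) { ok = false; }
    B.col(l) = beta;
  }
  return B;
}

// [[Rcpp::export(name = ".enet_fit_cpp")]]
List enet_fit_cpp(const arma::mat& X, const arma::vec& y,
                  double alpha, double lambda,
                  int nlambda_warm = 30, double tol = 1e-7,
                  int max_sweeps = 100000) {
  const int n = X.n_rows, p = X.n_cols;
  arma::rowvec xbar = arma::mean(X, 0);
  double ybar = arma::mean(y);
  arma::mat Xc = X.each_row() - xbar;
  arma::vec yc = y - ybar;
  arma::mat G = (Xc.t() * Xc) / n;
  arma::vec g = (Xc.t() * yc) / n;
  double yty_n = arma::dot(yc, yc) / n;

  double lmax = lambda_max_from(g, alpha);
  arma::vec beta(p, arma::fill::zeros);
  arma::vec gr = g;
  int sweeps = 0;
  // warm-start down a short geometric path when the target is interior
  if (lambda < lmax && nlambda_warm > 1) {
    double ratio = std::max(lambda / lmax, 1e-6);
    if (lambda <= 0.0) ratio = 1e-4;
    arma::vec path = geometric_path(lmax, ratio, nlambda_warm);
    for (int l = 0; l < (int)path.n_elem; ++l) {
      if (path[l] <= lambda) break;
      cd_solve(G, g, alpha, path[l], beta, gr, tol, max_sweeps);
    }
  }
  std::vector<double> obj_trace;
  sweeps = cd_solve(G, g, alpha, lambda, beta, gr, tol, max_sweeps,
                    &obj_trace, yty_n);
  double b0 = ybar - arma::dot(xbar.t(), beta);
  return List::create(
    _["beta"] = beta, _["intercept"] = b0,
    _["converged"] = sweeps >= 0, _["sweeps"] = sweeps,
    _["lambda_max"] = lmax,
    _["objective_trace"] = obj_trace);
}

// Joint 10-fold CV over (alpha grid) x (per-alpha geometric lambda path).
// foldid is 1-based. Returns the minimising pair with ties resolved toward
// larger lambda, then larger alpha, plus the full CV error surface.
// [[Rcpp::export(name = ".cv_tune_cpp")]]
List cv_tune_cpp(const arma::mat& X, const arma::vec& y,
                 const arma::ivec& foldid, const arma::vec& alpha_grid,
                 int nlambda = 100, double lambda_min_ratio = 1e-3,
                 double tol = 1e-7, int max_sweeps = 100000) {
  const int n = X.n_rows, p = X.n_cols;
  const int k = foldid.max();
  const int na = alpha_grid.n_elem;

  // full-data Gram for the per-alpha lambda paths
  arma::rowvec xbar = arma::mean(X, 0);
  double ybar = arma::mean(y);
  arma::mat Xc = X.each_row() - xbar;
  arma::vec yc = y - ybar;
  arma::vec g_full = (Xc.t() * yc) / n;

  // per-fold centered Gram matrices
  std::vector<arma::mat> Gtr(k);
  std::vector<arma::vec> gtr(k);
  std::vector<arma::rowvec> xbar_tr(k);
  std::vector<double> ybar_tr(k);
  std::vector<arma::uvec> test_idx(k);
  for (int f = 0; f < k; ++f) {
    arma::uvec tr = arma::find(foldid != (f + 1));
    arma::uvec te = arma::find(foldid == (f + 1));
    if (te.n_elem < 1 || tr.n_elem < 2) stop("cross-validation fold too small");
    test_idx[f] = te;
    arma::mat Xtr = X.rows(tr);
    arma::vec ytr = y.elem(tr);
    xbar_tr[f] = arma::mean(Xtr, 0);
    ybar_tr[f] = arma::mean(ytr);
    arma::mat Xtrc = Xtr.each_row() - xbar_tr[f];
    arma::vec ytrc = ytr - ybar_tr[f];
    int ntr = Xtr.n_rows;
    Gtr[f] = (Xtrc.t() * Xtrc) / ntr;
    gtr[f] = (Xtrc.t() * ytrc) / ntr;
  }

  arma::mat mse(na, nlambda, arma::fill::zeros);
  arma::mat lambda_grid(na, nlambda);
  bool all_ok = true;
  for (int a = 0; a < na; ++a) {
    double lmax = lambda_max_from(g_full, alpha_grid[a]);
    arma::vec path = geometric_path(lmax, lambda_min_ratio, nlambda);
    lambda_grid.row(a) = path.t();
    arma::mat sse(1, nlambda, arma::fill::zeros);
    for (int f = 0; f < k; ++f) {
      bool ok;
      arma::mat B = path_solve(Gtr[f], gtr[f], alpha_grid[a], path,
                               tol, max_sweeps, ok);
      if (!ok) all_ok = false;
      arma::mat Xte = X.rows(test_idx[f]);
      arma::vec yte = y.elem(test_idx[f]);
      for (int l = 0; l < nlambda; ++l) {
        double b0 = ybar_tr[f] - arma::dot(xbar_tr[f].t(), B.col(l));
        arma::vec pred = b0 + Xte * B.col(l);
        sse(0, l) += arma::accu(arma::square(yte - pred));
      }
    }
    mse.row(a) = sse / n;
  }

  // minimise; ties (common at the all-zero end of the path) go to the
  // largest lambda, then the largest alpha
  double best = mse.min();
  double tol_tie = 1e-12 * std::max(1.0, std::fabs(best));
  int best_a = -1, best_l = -1;
  double best_lambda = -1.0, best_alpha = -2.0;
  for (int a = 0; a < na; ++a) {
    for (int l = 0; l < nlambda; ++l) {
      if (mse(a, l) <= best + tol_tie) {
        double lam = lambda_grid(a, l);
        if (lam > best_lambda ||
            (lam == best_lambda && alpha_grid[a] > best_alpha)) {
          best_lambda = lam; best_alpha = alpha_grid[a];
          best_a = a; best_l = l;
        }
      }
    }
  }
  return List::create(
    _["alpha"] = alpha_grid[best_a], _["lambda"] = lambda_grid(best_a, best_l),
    _["cv_mse"] = mse(best_a, best_l), _["mse"] = mse,
    _["lambda_grid"] = lambda_grid, _["alpha_grid"] = alpha_grid,
    _["converged"] = all_ok);
}
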