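// L1-penalized Gaussian linear mixed model with a single random intercept
// per cluster (patient).  Objective, for V = sigma_e^2 (I + gamma * Z Z')
// with gamma = sigma_b^2 / sigma_e^2:
//
//   f(beta, gamma, sigma_e^2) =
//     0.5 * [ N log(2 pi sigma_e^2) + sum_i log(1 + n_i gamma)
//             + r' V^{-1} r ]  +  lambda * sum_{j penalized} |beta_j|
//
// minimized by block-coordinate descent: (i) with variance components held
// fixed, whiten by V^{-1/2} (closed form per cluster) and run cyclic
// coordinate descent with soft-thresholding on the fixed effects;
// (ii) with beta held fixed, profile the likelihood over gamma (golden-section
// on log(1+gamma)) and set sigma_e^2 to its closed-form ML value.
// Both steps decrease f, so the objective trace is non-increasing.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double LOG2PI = 1.8378770664093453;

// q(gamma) = r' (I + gamma ZZ')^{-1} r = ssq - sum_i gamma s_i^2/(1 + n_i gamma)
static double q_of_gamma(double gamma, const vec& ni, const vec& si2, double ssq) {
  double q = ssq - gamma * accu(si2 / (1.0 + ni * gamma));
  return (q > 1e-300) ? q : 1e-300;
}

// profile negative log-likelihood in gamma (sigma_e^2 profiled out), times 2,
// up to constants
static double profile_nll(double gamma, const vec& ni, const vec& si2,
                          double ssq, double N) {
  double q = q_of_gamma(gamma, ni, si2, ssq);
  return N * std::log(q / N) + accu(log(1.0 + ni * gamma));
}

// golden-section minimization of the profile over u = log1p(gamma)
static double optimize_gamma(const vec& ni, const vec& si2, double ssq,
                             double N, double gamma_max) {
  const double gr = 0.6180339887498949;
  double lo = 0.0, hi = std::log1p(gamma_max);
  double x1 = hi - gr * (hi - lo), x2 = lo + gr * (hi - lo);
  double f1 = profile_nll(std::expm1(x1), ni, si2, ssq, N);
  double f2 = profile_nll(std::expm1(x2), ni, si2, ssq, N);
  for (int it = 0; it < 200 && (hi - lo) > 1e-12; ++it) {
    if (f1 < f2) {
      hi = x2; x2 = x1; f2 = f1;
      x1 = hi - gr * (hi - lo);
      f1 = profile_nll(std::expm1(x1), ni, si2, ssq, N);
    } else {
      lo = x1; x1 = x2; f1 = f2;
      x2 = lo + gr * (hi - lo);
      f2 = profile_nll(std::expm1(x2), ni, si2, ssq, N);
    }
  }
  double gmid = std::expm1(0.5 * (lo + hi));
  // the boundary gamma = 0 is a legal ML solution; keep it when not worse
  if (profile_nll(0.0, ni, si2, ssq, N) <=
      profile_nll(gmid, ni, si2, ssq, N) + 1e-12)
    return 0.0;
  return gmid;
}

// [[Rcpp::export(name = ".lassolmm_fit_cpp")]]
Rcpp::List lassolmm_fit_cpp(const arma::mat& X, const arma::vec& y,
                            const arma::uvec& cluster,  // 0-based, contiguous
                            const arma::vec& penalized, // 0/1 per column
                            double lambda, arma::vec beta,
                            double gamma, double sige2, bool fix_variance,
                            int max_iter, double tol, double cd_tol,
                            int cd_max_sweeps, double gamma_max) {
  const uword N = X.n_rows, p = X.n_cols;
  const uword K = cluster.max() + 1;

  vec ni(K, fill::zeros);
  for (uword t = 0; t < N; ++t) ni(cluster(t)) += 1.0;

  double obj = datum::inf;
  std::vector<double> trace;
  bool converged = false;
  int iter = 0;

  mat Xt(N, p);
  vec yt(N);
  vec beta_prev = beta;

  for (iter = 1; iter <= max_iter; ++iter) {
    beta_prev = beta;
    // ---- variance step given beta ----
    vec r = y - X * beta;
    vec s(K, fill::zeros);
    for (uword t = 0; t < N; ++t) {
      s(cluster(t)) += r(t);
    }
    double ssq = dot(r, r);
    vec si2 = square(s);
    if (!fix_variance) {
      gamma = optimize_gamma(ni, si2, ssq, (double)N, gamma_max);
      sige2 = q_of_gamma(gamma, ni, si2, ssq) / (double)N;
      if (sige2 < 1e-12) sige2 = 1e-12;
    }

    // ---- whiten:  V^{-1/2} = (1/sigma_e) (I - (d_i/n_i) J_i) per cluster,
    //      d_i = 1 - 1/sqrt(1 + n_i gamma) ----
    vec d(K);
    for (uword i = 0; i < K; ++i)
      d(i) = 1.0 - 1.0 / std::sqrt(1.0 + ni(i) * gamma);
    double sige = std::sqrt(sige2);

    mat Sx(K, p, fill::zeros);
    vec Sy(K, fill::zeros);
    for (uword t = 0; t < N; ++t) {
      Sx.row(cluster(t)) += X.row(t);
      Sy(cluster(t)) += y(t);
    }
    for (uword t = 0; t < N; ++t) {
      uword i = cluster(t);
      double w = d(i) / ni(i);
      Xt.row(t) = (X.row(t) - w * Sx.row(i)) / sige;
      yt(t) = (y(t) - w * Sy(i)) / sige;
    }

    mat G = Xt.t() * Xt;
    vec c = Xt.t() * yt;
    double yty = dot(yt, yt);

    // ---- coordinate descent with soft-thresholding given the whitening ----
    for (int sweep = 0; sweep < cd_max_sweeps; ++sweep) {
      double delta = 0.0;
      for (uword j = 0; j < p; ++j) {
        double gjj = G(j, j);
        if (gjj <= 0) continue;
        double rho = c(j) - dot(G.col(j), beta) + gjj * beta(j);
        double bnew;
        if (penalized(j) > 0.5) {
          double a = std::fabs(rho) - lambda;
          bnew = (a > 0.0) ? std::copysign(a, rho) / gjj : 0.0;
        } else {
          bnew = rho / gjj;
        }
        double ch = std::fabs(bnew - beta(j));
        if (ch > delta) delta = ch;
        beta(j) = bnew;
      }
      if (delta < cd_tol) break;
    }

    // ---- objective ----
    double rss_w = yty - 2.0 * dot(c, beta) + as_scalar(beta.t() * G * beta);
    double logdet = accu(log(1.0 + ni * gamma));
    double pen = 0.0;
    for (uword j = 0; j < p; ++j)
      if (penalized(j) > 0.5) pen += std::fabs(beta(j));
    double obj_new = 0.5 * ((double)N * (LOG2PI + std::log(sige2)) +
                            logdet + rss_w) + lambda * pen;
    trace.push_back(obj_new);

    double beta_move = abs(beta - beta_prev).max();
    if (iter > 1 && std::fabs(obj - obj_new) < tol && beta_move < 1e-7) {
      obj = obj_new;
      converged = true;
      break;
    }
    obj = obj_new;
  }

  return Rcpp::List::create(
      Rcpp::Named("beta") = beta,
      Rcpp::Named("gamma") = gamma,
      Rcpp::Named("sigma_e") = std::sqrt(sige2),
      Rcpp::Named("sigma_b") = std::sqrt(gamma * sige2),
      Rcpp::Named("objective") = obj,
      Rcpp::Named("trace") = trace,
      Rcpp::Named("n_iter") = iter,
      Rcpp::Named("converged") = converged);
}
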