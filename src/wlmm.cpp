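// Weighted linear mixed model: per-subject cross-products, the profiled
// weighted ML deviance, and a compact Nelder-Mead search over the
// relative random-effects covariance.
//
// Model: y_i = X_i beta + Z_i b_i + e_i, b_i ~ N(0, sigma^2 Psi),
// e_i ~ N(0, sigma^2 I); subject i's log-likelihood contribution is
// multiplied by its weight w_i. beta and sigma^2 are profiled
// analytically; the optimizer searches par = (log sd0, log sd1, atanh-
// style correlation) parameterising Psi.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct WlmmData {
  arma::mat A, B, C, XtX, Xty;
  arma::vec yty, nobs, w;
  int p, m;
};

// Stack per-subject cross-products. group must be 0..m-1.
// [[Rcpp::export]]
List wlmm_prepare(const arma::mat& X, const arma::vec& t,
                  const arma::vec& y, const arma::ivec& group, int m) {
  int p = X.n_cols;
  arma::mat A(m, 3, arma::fill::zeros);      // ZtZ: n, sum t, sum t^2
  arma::mat B(m, 2 * p, arma::fill::zeros);  // ZtX rows: [sum x, sum t x]
  arma::mat C(m, 2, arma::fill::zeros);      // Zty: sum y, sum t y
  arma::mat XtX(m, p * p, arma::fill::zeros);
  arma::mat Xty(m, p, arma::fill::zeros);
  arma::vec yty(m, arma::fill::zeros);
  arma::vec nobs(m, arma::fill::zeros);

  for (arma::uword r = 0; r < X.n_rows; ++r) {
    int g = group[r];
    double tr = t[r], yr = y[r];
    A(g, 0) += 1.0; A(g, 1) += tr; A(g, 2) += tr * tr;
    C(g, 0) += yr;  C(g, 1) += tr * yr;
    yty[g] += yr * yr;
    nobs[g] += 1.0;
    for (int j = 0; j < p; ++j) {
      double xj = X(r, j);
      B(g, j) += xj;
      B(g, p + j) += tr * xj;
      Xty(g, j) += xj * yr;
      for (int k = 0; k <= j; ++k) XtX(g, j * p + k) += xj * X(r, k);
    }
  }
  for (int g = 0; g < m; ++g)
    for (int j = 0; j < p; ++j)
      for (int k = j + 1; k < p; ++k)
        XtX(g, j * p + k) = XtX(g, k * p + j);

  return List::create(_["A"] = A, _["B"] = B, _["C"] = C, _["XtX"] = XtX,
                      _["Xty"] = Xty, _["yty"] = yty, _["nobs"] = nobs,
                      _["p"] = p, _["m"] = m);
}

static WlmmData unpack(const List& prep, const arma::vec& w) {
  WlmmData d;
  d.A = as<arma::mat>(prep["A"]);
  d.B = as<arma::mat>(prep["B"]);
  d.C = as<arma::mat>(prep["C"]);
  d.XtX = as<arma::mat>(prep["XtX"]);
  d.Xty = as<arma::mat>(prep["Xty"]);
  d.yty = as<arma::vec>(prep["yty"]);
  d.nobs = as<arma::vec>(prep["nobs"]);
  d.p = as<int>(prep["p"]);
  d.m = as<int>(prep["m"]);
  d.w = w;
  return d;
}

static arma::mat psi_from_par(const arma::vec& par, bool diagonal) {
  double s0 = std::exp(par[0]), s1 = std::exp(par[1]);
  double rho = diagonal ? 0.0 : std::tanh(par[2]);
  arma::mat Psi(2, 2);
  Psi(0, 0) = s0 * s0;
  Psi(1, 1) = s1 * s1;
  Psi(0, 1) = Psi(1, 0) = rho * s0 * s1;
  return Psi;
}

// profiled deviance; fills beta/S/sigma2 when details is true
static double deviance(const WlmmData& d, const arma::mat& Psi,
                       bool details, arma::vec& beta_out,
                       arma::mat& S_out, double& sigma2_out) {
  int p = d.p;
  arma::mat S(p, p, arma::fill::zeros);
  arma::vec s(p, arma::fill::zeros);
  double yVy = 0.0, logdet = 0.0, wn = 0.0;
  arma::mat Bg(2, p), K(2, 2), M(2, 2);
  arma::vec cg(2);

  for (int g = 0; g < d.m; ++g) {
    double a0 = d.A(g, 0), a1 = d.A(g, 1), a2 = d.A(g, 2);
    // M = I + Ag * Psi
    M(0, 0) = 1.0 + a0 * Psi(0, 0) + a1 * Psi(1, 0);
    M(0, 1) = a0 * Psi(0, 1) + a1 * Psi(1, 1);
    M(1, 0) = a1 * Psi(0, 0) + a2 * Psi(1, 0);
    M(1, 1) = 1.0 + a1 * Psi(0, 1) + a2 * Psi(1, 1);
    double dM = M(0, 0) * M(1, 1) - M(0, 1) * M(1, 0);
    // K = Psi * inv(M), symmetrised
    arma::mat Minv(2, 2);
    Minv(0, 0) = M(1, 1) / dM;  Minv(1, 1) = M(0, 0) / dM;
    Minv(0, 1) = -M(0, 1) / dM; Minv(1, 0) = -M(1, 0) / dM;
    K = Psi * Minv;
    K = 0.5 * (K + K.t());

    for (int j = 0; j < p; ++j) {
      Bg(0, j) = d.B(g, j);
      Bg(1, j) = d.B(g, p + j);
    }
    cg[0] = d.C(g, 0); cg[1] = d.C(g, 1);
    double wg = d.w[g];

    arma::mat KB = K * Bg;
    // reconstruct XtX (p x p) for subject g from the packed row
    arma::mat Xm(p, p);
    for (int j = 0; j < p; ++j)
      for (int k = 0; k < p; ++k) Xm(k, j) = d.XtX(g, j * p + k);
    S += wg * (Xm - Bg.t() * KB);
    arma::vec Kc = K * cg;
    for (int j = 0; j < p; ++j)
      s[j] += wg * (d.Xty(g, j) - (Bg(0, j) * Kc[0] + Bg(1, j) * Kc[1]));
    yVy += wg * (d.yty[g] - arma::dot(cg, Kc));
    logdet += wg * std::log(dM);
    wn += wg * d.nobs[g];
  }

  arma::vec beta = arma::solve(S, s, arma::solve_opts::likely_sympd);
  double q = yVy - arma::dot(s, beta);
  double sigma2 = std::max(q / wn, 1e-12);
  double dev = wn * (std::log(2.0 * M_PI * sigma2) + 1.0) + logdet;
  if (details) {
    beta_out = beta;
    S_out = S;
    sigma2_out = sigma2;
  }
  return dev;
}

// Profiled deviance at a given Psi (exported for tests/diagnostics).
// [[Rcpp::export]]
List wlmm_profile(const arma::mat& Psi, const List& prep,
                  const arma::vec& w, bool details) {
  WlmmData d = unpack(prep, w);
  arma::vec beta;
  arma::mat S;
  double sigma2 = 0.0;
  double dev = deviance(d, Psi, true, beta, S, sigma2);
  if (!details) return List::create(_["deviance"] = dev);
  arma::mat vc = sigma2 * arma::inv_sympd(0.5 * (S + S.t()));
  return List::create(_["deviance"] = dev, _["beta"] = beta,
                      _["vcov"] = vc, _["sigma2"] = sigma2,
                      _["loglik"] = -0.5 * dev);
}

// Nelder-Mead over par (length 3, or 2 with diagonal Psi).
// [[Rcpp::export]]
List wlmm_fit(const List& prep, const arma::vec& w, const arma::vec& start,
              bool diagonal, int maxit, double reltol) {
  WlmmData d = unpack(prep, w);
  int np = diagonal ? 2 : 3;
  arma::vec beta;
  arma::mat S;
  double sigma2 = 0.0;

  auto fn = [&](const arma::vec& q) {
    arma::vec par(3, arma::fill::zeros);
    for (int j = 0; j < np; ++j) par[j] = q[j];
    return deviance(d, psi_from_par(par, diagonal), false, beta, S, sigma2);
  };

  // simplex init
  std::vector<arma::vec> px(np + 1);
  arma::vec fv(np + 1);
  arma::vec q0 = start.head(np);
  px[0] = q0;
  fv[0] = fn(q0);
  for (int j = 0; j < np; ++j) {
    arma::vec q = q0;
    q[j] += 0.5;
    px[j + 1] = q;
    fv[j + 1] = fn(q);
  }
  int neval = np + 1;
  for (int it = 0; it < maxit; ++it) {
    arma::uvec ord = arma::sort_index(fv);
    std::vector<arma::vec> px2(np + 1);
    arma::vec fv2(np + 1);
    for (int j = 0; j <= np; ++j) { px2[j] = px[ord[j]]; fv2[j] = fv[ord[j]]; }
    px = px2; fv = fv2;
    if (std::abs(fv[np] - fv[0]) <
        reltol * (std::abs(fv[0]) + reltol)) break;
    arma::vec cen(np, arma::fill::zeros);
    for (int j = 0; j < np; ++j) cen += px[j];
    cen /= np;
    arma::vec xr = cen + (cen - px[np]);
    double fr = fn(xr); ++neval;
    if (fr < fv[0]) {
      arma::vec xe = cen + 2.0 * (cen - px[np]);
      double fe = fn(xe); ++neval;
      if (fe < fr) { px[np] = xe; fv[np] = fe; }
      else { px[np] = xr; fv[np] = fr; }
    } else if (fr < fv[np - 1]) {
      px[np] = xr; fv[np] = fr;
    } else {
      arma::vec xc = cen + 0.5 * (px[np] - cen);
      double fc = fn(xc); ++neval;
      if (fc < fv[np]) { px[np] = xc; fv[np] = fc; }
      else {
        for (int j = 1; j <= np; ++j) {
          px[j] = px[0] + 0.5 * (px[j] - px[0]);
          fv[j] = fn(px[j]); ++neval;
        }
      }
    }
  }
  arma::uvec ord = arma::sort_index(fv);
  arma::vec qbest = px[ord[0]];
  arma::vec par(3, arma::fill::zeros);
  for (int j = 0; j < np; ++j) par[j] = qbest[j];

  arma::mat Psi = psi_from_par(par, diagonal);
  double dev = deviance(d, Psi, true, beta, S, sigma2);
  arma::mat vc = sigma2 * arma::inv_sympd(0.5 * (S + S.t()));
  return List::create(_["par"] = par, _["deviance"] = dev,
                      _["beta"] = beta, _["vcov"] = vc,
                      _["sigma2"] = sigma2, _["psi"] = Psi,
                      _["loglik"] = -0.5 * dev, _["neval"] = neval);
}
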