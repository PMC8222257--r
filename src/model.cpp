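// Core numerics for the marginalized posterior of the plant-pollinator
// visitation model. Everything here is deterministic; all RNG lives in R.
//
// Model: M_ij ~ Poisson(C * sigma_i * tau_j * (1 + r * B_ij)), B_ij ~ Bern(rho),
// with B summed out analytically:
//   log P(theta | M) = -C - lambda*r + sum_ij M_ij log(C sigma_i tau_j)
//                      + sum_ij Y_ij + const,
//   Y_ij = logsumexp(a, b_ij),  a = log(1-rho),
//   b_ij = log(rho) + M_ij log(1+r) - C r sigma_i tau_j.
// The stable branch evaluation of Y_ij avoids overflow for large M_ij or r.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double log1pexp_(double x) {
  // log(1 + e^x), stable for all x
  if (x > 35.0) return x + std::exp(-x);
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// logsumexp of two values, either of which may be -Inf
static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  return (a > b) ? a + log1pexp_(b - a) : b + log1pexp_(a - b);
}

// [[Rcpp::export]]
double cpp_log_marginal(const arma::mat& M, double C, double r, double rho,
                        const arma::vec& sigma, const arma::vec& tau,
                        double lambda_r) {
  const arma::uword np = M.n_rows, na = M.n_cols;
  const double logC = std::log(C);           // -Inf at C = 0 handled below
  const double log1pr = std::log1p(r);
  const double lrho = std::log(rho);         // -Inf at rho = 0
  const double l1mrho = std::log1p(-rho);    // -Inf at rho = 1
  double lp = -C - lambda_r * r;

  for (arma::uword j = 0; j < na; ++j) {
    for (arma::uword i = 0; i < np; ++i) {
      const double m = M(i, j);
      const double st = sigma(i) * tau(j);
      if (m > 0.0) {
        if (st <= 0.0 || C <= 0.0) return NEG_INF;
        lp += m * (logC + std::log(st));
      }
      const double b = (lrho == NEG_INF) ? NEG_INF
                                         : lrho + m * log1pr - C * r * st;
      lp += lse2(l1mrho, b);
      if (lp == NEG_INF) return NEG_INF;
    }
  }
  return lp;
}

// [[Rcpp::export]]
arma::mat cpp_edge_prob(const arma::mat& M, double C, double r, double rho,
                        const arma::vec& sigma, const arma::vec& tau) {
  const arma::uword np = M.n_rows, na = M.n_cols;
  arma::mat Q(np, na);
  if (rho <= 0.0) { Q.zeros(); return Q; }
  if (rho >= 1.0) { Q.ones(); return Q; }
  const double log1pr = std::log1p(r);
  const double logit_rho = std::log(rho) - std::log1p(-rho);
  for (arma::uword j = 0; j < na; ++j) {
    for (arma::uword i = 0; i < np; ++i) {
      // logit Q_ij = logit rho + M_ij log(1+r) - C r sigma_i tau_j
      const double d = logit_rho + M(i, j) * log1pr - C * r * sigma(i) * tau(j);
      Q(i, j) = 1.0 / (1.0 + std::exp(-d));
    }
  }
  return Q;
}

// Log-density targeted by HMC, on the unconstrained scale
//   z = (zC, zr, zrho, s[1..np], t[1..na]),
//   C = e^zC, r = e^zr, rho = logistic(zrho),
//   sigma = softmax(s), tau = softmax(t),
// with change-of-variables terms: +zC (uniform prior on C), +zr together with
// -lambda e^zr (exponential prior on r), +log rho(1-rho) (uniform prior on
// rho), and sum(s_i - e^{s_i}) which makes softmax(s) exactly flat-Dirichlet
// (the log-gamma representation of the simplex). Returns the log-density and
// its analytic gradient.
// [[Rcpp::export]]
List cpp_target_grad(const arma::mat& M, const arma::vec& z,
                     double lambda_r, double c_upper) {
  const arma::uword np = M.n_rows, na = M.n_cols;
  arma::vec grad(3 + np + na, arma::fill::zeros);
  const double bad = NEG_INF;

  if (z.n_elem != 3 + np + na) stop("unconstrained vector has wrong length");
  const double zC = z(0), zr = z(1), zrho = z(2);
  if (!z.is_finite() || zC > 690.0 || zr > 690.0 ||
      z.max() > 690.0) {
    return List::create(_["lp"] = bad, _["grad"] = NumericVector(grad.begin(), grad.end()));
  }

  const double C = std::exp(zC);
  const double r = std::exp(zr);
  if (c_upper > 0.0 && C > c_upper) {
    return List::create(_["lp"] = bad, _["grad"] = NumericVector(grad.begin(), grad.end()));
  }
  const double rho = 1.0 / (1.0 + std::exp(-zrho));
  const double lrho = -log1pexp_(-zrho);    // log rho
  const double l1mrho = -log1pexp_(zrho);   // log(1 - rho)

  const arma::vec s = z.subvec(3, 2 + np);
  const arma::vec t = z.subvec(3 + np, 2 + np + na);
  arma::vec sigma = arma::exp(s - s.max());
  sigma /= arma::accu(sigma);
  arma::vec tau = arma::exp(t - t.max());
  tau /= arma::accu(tau);

  const arma::vec R = arma::sum(M, 1);
  const arma::vec K = arma::sum(M, 0).t();
  const double Mtot = arma::accu(M);
  const double log1pr = std::log1p(r);

  double lp = -C + Mtot * std::log(C) - lambda_r * r
              + zC + zr + lrho + l1mrho
              + arma::accu(s) - arma::accu(arma::exp(s))
              + arma::accu(t) - arma::accu(arma::exp(t));
  for (arma::uword i = 0; i < np; ++i)
    if (R(i) > 0.0) lp += R(i) * std::log(sigma(i));
  for (arma::uword j = 0; j < na; ++j)
    if (K(j) > 0.0) lp += K(j) * std::log(tau(j));
  if (!std::isfinite(lp)) {
    return List::create(_["lp"] = bad, _["grad"] = NumericVector(grad.begin(), grad.end()));
  }

  // Accumulate Y_ij and the pieces of the gradient that involve the
  // responsibilities w_ij = Q_ij (softmax weight of the edge branch).
  double S = 0.0;        // sum_ij w st
  double sum_w = 0.0;    // sum_ij w
  double sum_wb = 0.0;   // sum_ij w (M_ij/(1+r) - C st)
  arma::vec Wtau(np, arma::fill::zeros);  // row sums of w_ij tau_j
  arma::vec Wsig(na, arma::fill::zeros);  // col sums of w_ij sigma_i
  for (arma::uword j = 0; j < na; ++j) {
    for (arma::uword i = 0; i < np; ++i) {
      const double m = M(i, j);
      const double st = sigma(i) * tau(j);
      const double b = lrho + m * log1pr - C * r * st;
      const double d = b - l1mrho;
      lp += (d > 0.0) ? b + log1pexp_(-d) : l1mrho + log1pexp_(d);
      const double w = 1.0 / (1.0 + std::exp(-d));
      S += w * st;
      sum_w += w;
      sum_wb += w * (m / (1.0 + r) - C * st);
      Wtau(i) += w * tau(j);
      Wsig(j) += w * sigma(i);
    }
  }
  if (!std::isfinite(lp)) {
    grad.zeros();
    return List::create(_["lp"] = bad, _["grad"] = NumericVector(grad.begin(), grad.end()));
  }

  grad(0) = -C + Mtot - C * r * S + 1.0;
  grad(1) = r * sum_wb - lambda_r * r + 1.0;
  grad(2) = (sum_w - double(np * na) * rho) + (1.0 - 2.0 * rho);
  const double CrS = Mtot - C * r * S;
  for (arma::uword i = 0; i < np; ++i) {
    grad(3 + i) = R(i) - C * r * sigma(i) * Wtau(i) - sigma(i) * CrS
                  + 1.0 - std::exp(s(i));
  }
  for (arma::uword j = 0; j < na; ++j) {
    grad(3 + np + j) = K(j) - C * r * tau(j) * Wsig(j) - tau(j) * CrS
                       + 1.0 - std::exp(t(j));
  }
  if (!grad.is_finite()) {
    // an overflowing gradient (e.g. C*r beyond double range with lp still
    // representable) is treated as a divergence: reject, do not propagate
    grad.zeros();
    return List::create(_["lp"] = bad,
                        _["grad"] = NumericVector(grad.begin(), grad.end()));
  }
  return List::create(_["lp"] = lp,
                      _["grad"] = NumericVector(grad.begin(), grad.end()));
}
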