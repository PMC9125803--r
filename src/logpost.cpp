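// Unconstrained-scale log posterior and analytic gradient of the
// hierarchical log-ratio model. Mirrors the pure-R reference
// implementation (.logpost_grad_r); the R version is kept as the oracle in
// the test suite and this one does the sampling work.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double plogis_stable(double x) {
  return 0.5 * (1.0 + std::tanh(0.5 * x));
}

// dnorm(x)/pnorm(x) via logs so it survives strongly negative arguments
static inline double mills(double z) {
  return std::exp(R::dnorm(z, 0.0, 1.0, 1) - R::pnorm(z, 0.0, 1.0, 1, 1));
}

// [[Rcpp::export(.logpost_grad_cpp)]]
List logpost_grad_cpp(const arma::vec& theta, const arma::mat& Y,
                      const arma::mat& X, const arma::mat& omega,
                      double logdet, double tau, double pi1_alpha,
                      double pi1_beta, double sigma2_fixed, bool infer_sigma2,
                      bool full_variant, const arma::mat& GammaFix) {
  const arma::uword n = Y.n_rows, K = Y.n_cols, q = X.n_cols, kq = K * q;
  const arma::uword d = theta.n_elem;
  arma::vec grad(d, arma::fill::zeros);
  List fail = List::create(Named("lp") = R_NegInf, Named("grad") = grad);

  const arma::uword i_ta = 0, i_tb = q;
  const arma::uword i_g1 = q + kq, i_g2 = q + 2 * kq;
  const arma::uword i_lambda = full_variant ? (q + 3 * kq) : (q + kq);
  const arma::uword i_ts = i_lambda + 1;

  arma::vec ta = theta.subvec(i_ta, i_ta + q - 1);
  arma::vec a = arma::exp(ta);
  arma::mat B = arma::reshape(arma::exp(theta.subvec(i_tb, i_tb + kq - 1)), K, q);
  double lambda = theta(i_lambda);
  double pi1 = plogis_stable(lambda);
  double sigma2 = infer_sigma2 ? std::exp(theta(i_ts)) : sigma2_fixed;
  if (!a.is_finite() || !B.is_finite() || !std::isfinite(sigma2) ||
      sigma2 <= 0.0 || pi1 <= 0.0 || pi1 >= 1.0)
    return fail;
  double sigma = std::sqrt(sigma2);

  arma::mat Gamma, delta, g1, g2;
  if (full_variant) {
    g1 = arma::reshape(theta.subvec(i_g1, i_g1 + kq - 1), K, q);
    g2 = arma::reshape(theta.subvec(i_g2, i_g2 + kq - 1), K, q);
    delta.set_size(K, q);
    for (arma::uword i = 0; i < kq; ++i)
      delta(i) = plogis_stable((lambda + g1(i) - g2(i)) / tau);
    Gamma = 2.0 * delta - 1.0;
  } else {
    Gamma = GammaFix;
  }

  arma::mat M = Gamma % B;
  arma::mat R_ = Y - X * M.t();
  arma::mat RO = R_ * omega;
  double ll = -0.5 * arma::accu(RO % R_) - 0.5 * n * logdet -
              0.5 * n * K * std::log(2.0 * M_PI);
  arma::mat dM = RO.t() * X;  // d ll / d M, K x q

  // magnitude prior N+(a_j, sigma2) with its a-dependent normaliser
  double lp = ll;
  arma::mat arow(K, q);
  for (arma::uword j = 0; j < q; ++j) arow.col(j).fill(a(j));
  for (arma::uword i = 0; i < kq; ++i)
    lp += R::dnorm(B(i), arow(i), sigma, 1);
  arma::vec z = a / sigma, hz(q);
  for (arma::uword j = 0; j < q; ++j) {
    lp -= K * R::pnorm(z(j), 0.0, 1.0, 1, 1);
    hz(j) = mills(z(j));
  }
  // global-effect prior N+(0, 1), pi1 Beta prior + logit Jacobian, exp Jacobians
  for (arma::uword j = 0; j < q; ++j) lp += R::dnorm(a(j), 0.0, 1.0, 1);
  lp += q * std::log(2.0);
  lp += R::dbeta(pi1, pi1_alpha, pi1_beta, 1);
  lp += std::log(pi1) + std::log1p(-pi1);
  lp += arma::accu(ta) + arma::accu(arma::log(B));

  arma::mat dB = dM % Gamma - (B - arow) / sigma2;
  arma::vec da = arma::sum(B - arow, 0).t() / sigma2 -
                 double(K) * hz / sigma - a;
  double dlambda = (pi1_alpha - 1.0) * (1.0 - pi1) -
                   (pi1_beta - 1.0) * pi1 + (1.0 - 2.0 * pi1);

  if (full_variant) {
    lp += arma::accu(-g1 - arma::exp(-g1)) + arma::accu(-g2 - arma::exp(-g2));
    arma::mat w = (2.0 * dM % B) % delta % (1.0 - delta) / tau;
    arma::mat gg1 = w - 1.0 + arma::exp(-g1);
    arma::mat gg2 = -w - 1.0 + arma::exp(-g2);
    grad.subvec(i_g1, i_g1 + kq - 1) = arma::vectorise(gg1);
    grad.subvec(i_g2, i_g2 + kq - 1) = arma::vectorise(gg2);
    dlambda += arma::accu(w);
  } else {
    double npos = arma::accu(Gamma > 0), nneg = double(kq) - npos;
    lp += npos * std::log(pi1) + nneg * std::log1p(-pi1);
    dlambda += npos * (1.0 - pi1) - nneg * pi1;
  }

  if (infer_sigma2) {
    lp += R::dnorm(sigma2, 0.0, 1.0, 1) + std::log(2.0) + theta(i_ts);
    double dsigma = arma::accu(-1.0 / sigma +
                               arma::square(B - arow) / std::pow(sigma, 3));
    for (arma::uword j = 0; j < q; ++j)
      dsigma += K * hz(j) * a(j) / sigma2;
    grad(i_ts) = dsigma * sigma / 2.0 - sigma2 * sigma2 + 1.0;
  }

  grad.subvec(i_ta, i_ta + q - 1) = a % da + 1.0;
  grad.subvec(i_tb, i_tb + kq - 1) = arma::vectorise(B % dB + 1.0);
  grad(i_lambda) = dlambda;

  if (!std::isfinite(lp)) return fail;
  return List::create(Named("lp") = lp,
                      Named("grad") = NumericVector(grad.begin(), grad.end()));
}
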