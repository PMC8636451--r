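// Hamiltonian Monte Carlo for the Bernoulli-logit latent trait family.
//
// Given the observed histories, every model in the family has a linear
// predictor eta_n = z_n' xi + theta_{person(n)} over the I*J observations,
// with independent normal priors on the structural block xi and standard
// normal priors on the abilities theta.  The sampler works on the joint
// vector q = (xi, theta) with a fixed diagonal metric (supplied from a
// Laplace approximation) and dual-averaging step-size adaptation during
// warmup.  R's RNG is used throughout, so chains are reproducible from
// set.seed() on the R side.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double log1pexp_c(double x) {
  if (x > 33.3) return x;
  if (x > 18.0) return x + std::exp(-x);
  return std::log1p(std::exp(x));
}

struct Posterior {
  const arma::mat& Z;        // n x P structural design
  const arma::vec& y;        // n responses
  const arma::uvec& person;  // n person indices, 0-based
  const arma::vec& prec;     // P + I prior precisions
  const arma::vec& offset;   // n fixed offsets (prior-mean shift)
  int P, I;

  Posterior(const arma::mat& Z_, const arma::vec& y_, const arma::uvec& person_,
            const arma::vec& prec_, const arma::vec& offset_, int P_, int I_)
    : Z(Z_), y(y_), person(person_), prec(prec_), offset(offset_), P(P_), I(I_) {}

  // log posterior and gradient at q = (xi, theta); with_lp = false skips
  // the log terms (only the gradient is needed during inner leapfrog
  // steps)
  double logp_grad(const arma::vec& q, arma::vec& grad,
                   bool with_lp = true) const {
    arma::vec xi = q.head(P);
    arma::vec eta = Z * xi;
    const int n = eta.n_elem;
    double lp = 0.0;
    arma::vec g(n);
    for (int k = 0; k < n; ++k) {
      const double e = eta[k] + q[P + person[k]] + offset[k];
      const double t = std::exp(-std::fabs(e));
      const double s = 1.0 / (1.0 + t);          // sigmoid(|e|)
      g[k] = y[k] - (e >= 0.0 ? s : 1.0 - s);
      if (with_lp) lp += y[k] * e - (e >= 0.0 ? e + std::log1p(t)
                                              : std::log1p(t));
    }
    grad.zeros(q.n_elem);
    grad.head(P) = Z.t() * g;
    for (int k = 0; k < n; ++k) grad[P + person[k]] += g[k];
    if (with_lp) lp -= 0.5 * arma::dot(prec, arma::square(q));
    grad -= prec % q;
    return lp;
  }
};

// Structured metric: the Laplace precision in arrow form
//   H = [[A, B], [B', diag(c)]],  A - B diag(1/c) B' = S'S  (S upper tri).
// With U = [[S, 0], [C^{-1/2} B', C^{1/2}]] we have H = U'U, so momenta
// are drawn as p = U'z with z standard normal, and H^{-1} p costs two
// triangular solves plus O(P*I) work.
struct ArrowMetric {
  const arma::mat& S;       // P x P upper triangular, S'S = Schur
  const arma::mat& B;       // P x I cross block
  arma::vec c, sqrt_c;      // length-I diagonal of the theta block
  int P, I;

  ArrowMetric(const arma::mat& S_, const arma::mat& B_, const arma::vec& c_)
    : S(S_), B(B_), c(c_), sqrt_c(arma::sqrt(c_)),
      P(S_.n_rows), I(c_.n_elem) {}

  arma::vec sample_momentum() const {
    arma::vec z(P + I);
    for (arma::uword d = 0; d < z.n_elem; ++d) z[d] = norm_rand();
    arma::vec p(P + I);
    p.head(P) = S.t() * z.head(P) + B * (z.tail(I) / sqrt_c);
    p.tail(I) = sqrt_c % z.tail(I);
    return p;
  }

  arma::vec solve(const arma::vec& p) const {
    // U' v = p
    arma::vec v2 = p.tail(I) / sqrt_c;
    arma::vec v1 = arma::solve(arma::trimatl(S.t()),
                               p.head(P) - B * (p.tail(I) / c));
    // U x = v
    arma::vec x(P + I);
    x.head(P) = arma::solve(arma::trimatu(S), v1);
    x.tail(I) = v2 / sqrt_c - B.t() * x.head(P) / c;
    return x;
  }
};

// [[Rcpp::export(name = ".hmc_chain")]]
List hmc_chain(const arma::mat& Z, const arma::vec& y, const arma::uvec& person,
               int n_person, const arma::vec& prior_prec,
               const arma::vec& offset, const arma::vec& init,
               const arma::mat& chol_schur, const arma::mat& cross,
               const arma::vec& theta_prec, int iter, int warmup,
               double target_accept, int leap_min, int leap_max,
               double init_step) {
  const int P = Z.n_cols;
  const int D = P + n_person;
  Posterior post(Z, y, person, prior_prec, offset, P, n_person);
  ArrowMetric metric(chol_schur, cross, theta_prec);

  arma::vec q = init, grad(D);
  double lp = post.logp_grad(q, grad);
  if (!std::isfinite(lp)) stop("non-finite log posterior at the initial value");

  // dual averaging (Hoffman & Gelman 2014 defaults)
  double eps = init_step, mu = std::log(10.0 * init_step);
  double log_eps_bar = 0.0, H_bar = 0.0;
  const double gamma_da = 0.05, t0 = 10.0, kappa = 0.75;

  const int keep = iter - warmup;
  arma::mat draws(keep, D);
  int n_div = 0, n_acc = 0;

  for (int it = 0; it < iter; ++it) {
    arma::vec p = metric.sample_momentum();
    double H0 = -lp + 0.5 * arma::dot(p, metric.solve(p));

    int L = leap_min + (int)std::floor(unif_rand() * (leap_max - leap_min + 1));
    if (L < 1) L = 1;

    arma::vec q_prop = q, p_prop = p;
    arma::vec g = grad;
    bool diverged = false;
    double lp_prop = lp;
    for (int l = 0; l < L; ++l) {
      p_prop += 0.5 * eps * g;
      q_prop += eps * metric.solve(p_prop);
      bool last = (l == L - 1);
      lp_prop = post.logp_grad(q_prop, g, last);
      if (!q_prop.is_finite() || !g.is_finite() ||
          (last && !std::isfinite(lp_prop))) { diverged = true; break; }
      p_prop += 0.5 * eps * g;
    }

    double accept_prob = 0.0;
    if (!diverged) {
      double H1 = -lp_prop + 0.5 * arma::dot(p_prop, metric.solve(p_prop));
      double dH = H0 - H1;
      if (dH < -1000.0 || !std::isfinite(dH)) diverged = true;
      else accept_prob = std::min(1.0, std::exp(dH));
    }
    if (diverged) ++n_div;

    if (!diverged && unif_rand() < accept_prob) {
      q = q_prop; lp = lp_prop; grad = g;
      if (it >= warmup) ++n_acc;
    }

    if (it < warmup) {
      double eta_da = 1.0 / (it + 1 + t0);
      H_bar = (1.0 - eta_da) * H_bar + eta_da * (target_accept - accept_prob);
      double log_eps = mu - std::sqrt(it + 1.0) / gamma_da * H_bar;
      eps = std::exp(log_eps);
      double w = std::pow(it + 1.0, -kappa);
      log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
      if (it == warmup - 1) eps = std::exp(log_eps_bar);
    } else {
      draws.row(it - warmup) = q.t();
    }
  }

  return List::create(_["draws"] = draws,
                      _["accept_rate"] = (double)n_acc / std::max(keep, 1),
                      _["divergences"] = n_div,
                      _["step_size"] = eps);
}

// pointwise log-likelihood over draws: returns L x n matrix
// [[Rcpp::export(name = ".pointwise_ll_draws")]]
arma::mat pointwise_ll_draws(const arma::mat& Z, const arma::vec& y,
                             const arma::uvec& person,
                             const arma::mat& xi_draws,
                             const arma::mat& theta_draws) {
  const int L = xi_draws.n_rows, n = Z.n_rows;
  arma::mat out(L, n);
  for (int l = 0; l < L; ++l) {
    arma::vec eta = Z * xi_draws.row(l).t();
    for (int k = 0; k < n; ++k) {
      double e = eta[k] + theta_draws(l, person[k]);
      out(l, k) = y[k] * e - log1pexp_c(e);
    }
  }
  return out;
}
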