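// Hamiltonian Monte Carlo for the hierarchical Bernoulli daily-survival
// model. Parameters: fixed-effect coefficients beta (Gaussian(0, 2) priors,
// optionally one Cauchy(0, 2) coefficient for the categorical incubation
// effect), year effects v_g (centred scale, v_g ~ N(0, sigma^2), reported
// together with u_g = v_g / sigma) and log(sigma) with a half-Cauchy(0, 5)
// prior on sigma. The sampler uses leapfrog trajectories with jittered
// length, dual-averaging step-size adaptation and a dense mass matrix
// estimated from the warmup posterior covariance. All randomness comes
// from a per-chain
// mt19937_64 stream, so runs are reproducible for a given seed.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct DsrPosterior {
  const arma::mat& X;
  const arma::vec& y;
  const arma::uvec& yr;  // 0-based year index per row; unused when G == 0
  int K;
  int G;
  int cauchy_idx;  // 0-based column with the Cauchy prior, or -1

  int dim() const { return K + (G > 0 ? G + 1 : 0); }

  // log posterior and gradient; returns -inf on numerical failure
  double lp_grad(const arma::vec& th, arma::vec& grad) const {
    const int d = dim();
    grad.zeros(d);
    arma::vec beta = th.subvec(0, K - 1);
    arma::vec eta = X * beta;
    double ls = 0.0, sigma = 1.0;
    arma::vec v;
    if (G > 0) {
      v = th.subvec(K, K + G - 1);
      ls = th(K + G);
      if (ls > 30.0 || ls < -30.0) return -arma::datum::inf;
      sigma = std::exp(ls);
      for (arma::uword i = 0; i < eta.n_elem; ++i) eta(i) += v(yr(i));
    }
    double lp = 0.0;
    arma::vec r(eta.n_elem);
    for (arma::uword i = 0; i < eta.n_elem; ++i) {
      const double e = eta(i);
      double l1pe;
      if (e > 35.0)
        l1pe = e;
      else if (e < -35.0)
        l1pe = std::exp(e);
      else
        l1pe = std::log1p(std::exp(e));
      lp += y(i) * e - l1pe;
      r(i) = y(i) - 1.0 / (1.0 + std::exp(-e));
    }
    grad.subvec(0, K - 1) = X.t() * r;
    for (int k = 0; k < K; ++k) {
      const double b = beta(k);
      if (k == cauchy_idx) {
        lp += -std::log1p(b * b / 4.0);
        grad(k) += -(b / 2.0) / (1.0 + b * b / 4.0);
      } else {
        lp += -b * b / 8.0;
        grad(k) += -b / 4.0;
      }
    }
    if (G > 0) {
      const double s2 = sigma * sigma;
      double sumv2 = 0.0;
      for (int g = 0; g < G; ++g) {
        lp += -0.5 * v(g) * v(g) / s2;
        grad(K + g) += -v(g) / s2;
        sumv2 += v(g) * v(g);
      }
      for (arma::uword i = 0; i < r.n_elem; ++i) grad(K + yr(i)) += r(i);
      // v ~ N(0, sigma^2) contributes -G*ls; half-Cauchy(5) on sigma with
      // the log-scale Jacobian contributes -log(1 + sigma^2/25) + ls.
      lp += -static_cast<double>(G) * ls - std::log1p(s2 / 25.0) + ls;
      grad(K + G) = sumv2 / s2 - static_cast<double>(G) + 1.0 -
                    2.0 * s2 / (25.0 + s2);
    }
    if (!std::isfinite(lp)) return -arma::datum::inf;
    return lp;
  }
};

struct ChainResult {
  arma::mat draws;  // keep x dim (internal parameterisation)
  double accept_rate;
  int divergences;
  double step_size;
};

ChainResult run_chain(const DsrPosterior& post, int n_iter, int n_warmup,
                      double target_accept, std::uint64_t seed,
                      const arma::vec& init) {
  const int d = post.dim();
  std::mt19937_64 rng(seed);
  std::normal_distribution<double> rnorm(0.0, 1.0);
  std::uniform_real_distribution<double> runif(0.0, 1.0);

  arma::vec th = init;
  arma::vec grad(d);
  double lp = post.lp_grad(th, grad);
  if (!std::isfinite(lp)) {
    th.zeros();
    lp = post.lp_grad(th, grad);
  }

  // Mass matrix: momenta p ~ N(0, Cov^-1) with Cov the estimated posterior
  // covariance, so the leapfrog moves in approximately whitened coordinates
  // (handles the strongly correlated covariate pairs). U is chol(Cov).
  arma::mat cov_m(d, d, arma::fill::eye);
  arma::mat U = arma::chol(cov_m);
  double eps = 0.1;
  // dual averaging state
  double mu = std::log(10.0 * eps), log_eps_bar = std::log(eps), hbar = 0.0;
  int da_count = 0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  auto da_reset = [&](double eps_now) {
    mu = std::log(10.0 * eps_now);
    log_eps_bar = std::log(eps_now);
    hbar = 0.0;
    da_count = 0;
  };

  const int win_lo = static_cast<int>(0.15 * n_warmup);
  const int win_hi = static_cast<int>(0.85 * n_warmup);
  bool mass_set = false;
  arma::mat cov_draws(std::max(win_hi - win_lo, 1), d, arma::fill::zeros);

  const int keep = n_iter - n_warmup;
  arma::mat draws(keep, d);
  int divergences = 0;
  double accept_sum = 0.0;
  int accept_n = 0;

  for (int it = 0; it < n_iter; ++it) {
    const bool warm = it < n_warmup;
    arma::vec z(d);
    for (int j = 0; j < d; ++j) z(j) = rnorm(rng);
    // p = U^-1 z  ~  N(0, Cov^-1)
    arma::vec p = arma::solve(arma::trimatu(U), z);
    const double h0 = -lp + 0.5 * arma::dot(p, cov_m * p);

    // jittered trajectory length around lambda / eps
    const double lambda = 1.0;
    int lmax = static_cast<int>(lambda / eps);
    if (lmax < 1) lmax = 1;
    if (lmax > 128) lmax = 128;
    int L = static_cast<int>(lmax * (0.5 + 0.5 * runif(rng)));
    if (L < 1) L = 1;
    // before the mass matrix is estimated the identity metric makes
    // long trajectories wasteful; keep them short
    if (!mass_set && L > 8) L = 8;

    arma::vec th_new = th, grad_new = grad, p_new = p;
    double lp_new = lp;
    bool bad = false;
    p_new += 0.5 * eps * grad_new;
    for (int l = 0; l < L; ++l) {
      th_new += eps * (cov_m * p_new);
      lp_new = post.lp_grad(th_new, grad_new);
      if (!std::isfinite(lp_new)) { bad = true; break; }
      p_new += (l + 1 == L ? 0.5 : 1.0) * eps * grad_new;
    }
    double alpha = 0.0;
    if (!bad) {
      const double h1 =
          -lp_new + 0.5 * arma::dot(p_new, cov_m * p_new);
      const double dh = h0 - h1;
      if (std::isfinite(dh) && dh > -1000.0) {
        alpha = dh > 0 ? 1.0 : std::exp(dh);
        if (runif(rng) < alpha) {
          th = th_new;
          grad = grad_new;
          lp = lp_new;
        }
      } else {
        if (!warm) ++divergences;
      }
    } else {
      if (!warm) ++divergences;
    }

    if (warm) {
      // dual averaging step-size update
      ++da_count;
      const double eta_h = 1.0 / (da_count + t0);
      hbar = (1.0 - eta_h) * hbar + eta_h * (target_accept - alpha);
      const double log_eps =
          mu - std::sqrt(static_cast<double>(da_count)) / gamma * hbar;
      const double w = std::pow(static_cast<double>(da_count), -kappa);
      log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
      eps = std::exp(log_eps);
      if (it >= win_lo && it < win_hi) cov_draws.row(it - win_lo) = th.t();
      if (it + 1 == win_hi && win_hi - win_lo > 10) {
        arma::mat C = arma::cov(cov_draws);
        // regularise towards its diagonal for stability
        arma::vec dg = C.diag();
        C = 0.9 * C;
        C.diag() = dg + 1e-6;
        arma::mat Utry;
        if (arma::chol(Utry, C)) {
          cov_m = C;
          U = Utry;
        } else {
          cov_m = arma::diagmat(arma::clamp(dg, 1e-8, arma::datum::inf));
          U = arma::chol(cov_m);
        }
        mass_set = true;
        eps = std::exp(log_eps_bar);
        da_reset(eps);
      }
      if (it + 1 == n_warmup) eps = std::exp(log_eps_bar);
    } else {
      accept_sum += alpha;
      ++accept_n;
      draws.row(it - n_warmup) = th.t();
    }
  }
  ChainResult res;
  res.draws = draws;
  res.accept_rate = accept_n > 0 ? accept_sum / accept_n : 0.0;
  res.divergences = divergences;
  res.step_size = eps;
  return res;
}

}  // namespace

// [[Rcpp::export]]
List hmc_sampler(const arma::mat& X, const arma::vec& y,
                 const arma::ivec& yridx, int G, int cauchy_idx, int chains,
                 int iter, int warmup, double target_accept, int seed) {
  const int K = X.n_cols;
  arma::uvec yr;
  if (G > 0) {
    yr.set_size(yridx.n_elem);
    for (arma::uword i = 0; i < yridx.n_elem; ++i) {
      yr(i) = static_cast<arma::uword>(yridx(i) - 1);
    }
  }
  DsrPosterior post{X, y, yr, K, G, cauchy_idx};
  const int d = post.dim();
  const int keep = iter - warmup;
  const int P = K + (G > 0 ? G + 1 : 0);  // reported: beta, sigma, v

  // shared starting point: empirical logit for the intercept
  double ybar = arma::mean(y);
  ybar = std::min(std::max(ybar, 1e-4), 1.0 - 1e-4);
  arma::vec base(d, arma::fill::zeros);
  base(0) = std::log(ybar / (1.0 - ybar));

  arma::cube out(keep, chains, P);
  NumericVector accept(chains), stepsz(chains);
  IntegerVector divs(chains);
  for (int c = 0; c < chains; ++c) {
    std::uint64_t chain_seed =
        static_cast<std::uint64_t>(seed) * 1000003ULL + 7919ULL * (c + 1);
    std::mt19937_64 init_rng(chain_seed ^ 0x9e3779b97f4a7c15ULL);
    std::normal_distribution<double> jit(0.0, 0.1);
    arma::vec init = base;
    for (int j = 0; j < d; ++j) init(j) += jit(init_rng);
    ChainResult res =
        run_chain(post, iter, warmup, target_accept, chain_seed, init);
    for (int i = 0; i < keep; ++i) {
      for (int k = 0; k < K; ++k) out(i, c, k) = res.draws(i, k);
      if (G > 0) {
        out(i, c, K) = std::exp(res.draws(i, K + G));  // sigma
        for (int g = 0; g < G; ++g) out(i, c, K + 1 + g) = res.draws(i, K + g);
      }
    }
    accept[c] = res.accept_rate;
    divs[c] = res.divergences;
    stepsz[c] = res.step_size;
  }
  return List::create(_["draws"] = out, _["accept"] = accept,
                      _["divergences"] = divs, _["step_size"] = stepsz);
}
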