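// Hierarchical bounded-softmax choice model: log posterior, gradient, and a
// No-U-Turn sampler with dual-averaging step-size and diagonal metric
// adaptation.
//
// Model (all seven utility functions reduce to this form):
//   dv_i   = offset_i + X[i,] %*% theta[subj_i,]        (SV_accept - SV_reject)
//   P(accept_i) = logistic(tau[subj_i] * dv_i)
//   theta[s,k] = lb_k + (ub_k - lb_k) * Phi(mu_k + sigma_k * z[s,k])
//   tau[s]     = tau_ub * Phi(mu_tau + sigma_tau * z_tau[s])
//   mu ~ Normal(0, prior_mu_sd), sigma ~ half-Normal(prior_sigma_sd),
//   z ~ Normal(0, 1)
//
// Unconstrained parameter vector q (length P*(2+S), P = K+1 with the last
// slot for tau): [mu_raw (P) | log_sigma (P) | z column-major (S*P)].

#include <RcppArmadillo.h>
#include <cstdint>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double SQRT2 = 1.4142135623730951;
static const double DIVERGENCE_THRESHOLD = 1000.0;

// Portable RNG: mt19937_64 bits -> doubles, Box-Muller normals. Avoids the
// implementation-defined std::*_distribution templates so draws are
// reproducible for a given seed on any standard library.
struct Rng {
  std::mt19937_64 gen;
  bool have_spare = false;
  double spare = 0.0;
  explicit Rng(std::uint64_t seed) : gen(seed) {}
  double unif() {  // (0, 1)
    std::uint64_t x = gen();
    return ((x >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

static inline double norm_cdf(double x) { return 0.5 * std::erfc(-x / SQRT2); }
static inline double norm_pdf(double x) {
  return 0.3989422804014327 * std::exp(-0.5 * x * x);
}
static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

struct ChoiceModel {
  mat X;          // N x K design of (accept - reject) payoff features
  vec offset;     // fixed part of dv (nonzero for inequity-aversion models)
  vec y;          // 0/1 choices
  ivec subj;      // 0-based subject index per trial; must be sorted
  int S, K, P, n; // subjects, utility params, P = K+1, n = P*(2+S)
  vec lb, ub;     // utility parameter bounds (length K)
  double tau_ub;
  double prior_mu_sd, prior_sigma_sd;
  uvec starts;    // block start row of each subject (length S+1)

  void index_subjects() {
    int N = X.n_rows;
    starts.set_size(S + 1);
    int s = 0;
    starts[0] = 0;
    for (int i = 0; i < N; ++i) {
      if (subj[i] < s || subj[i] >= S)
        Rcpp::stop("trials must be sorted by subject");
      while (s < subj[i]) starts[++s] = i;
    }
    while (s < S) starts[++s] = N;
  }

  // Log posterior density (up to a constant) and its gradient.
  double lp_grad(const vec& q, vec& grad) const {
    const double* mu_raw = q.memptr();
    const double* ls = q.memptr() + P;
    const double* z = q.memptr() + 2 * P;
    grad.zeros(n);
    double* g_mu = grad.memptr();
    double* g_ls = grad.memptr() + P;
    double* g_z = grad.memptr() + 2 * P;

    vec sigma(P);
    for (int k = 0; k < P; ++k) sigma[k] = std::exp(ls[k]);

    // Transformed parameters and the Jacobian factor d theta / d a.
    mat theta(S, K), jac(S, P);
    vec tau(S);
    for (int k = 0; k < P; ++k) {
      double range = (k < K) ? (ub[k] - lb[k]) : tau_ub;
      double lo = (k < K) ? lb[k] : 0.0;
      for (int s = 0; s < S; ++s) {
        double a = mu_raw[k] + sigma[k] * z[k * S + s];
        double val = lo + range * norm_cdf(a);
        if (k < K) theta(s, k) = val; else tau[s] = val;
        jac(s, k) = range * norm_pdf(a);
      }
    }

    // Likelihood and per-subject score accumulation (BLAS per block).
    double lp = 0.0;
    mat g_theta(S, K, fill::zeros);
    vec g_tau(S, fill::zeros);
    for (int s = 0; s < S; ++s) {
      int a = starts[s], b = starts[s + 1] - 1;
      if (b < a) continue;
      vec dv = offset.subvec(a, b) + X.rows(a, b) * theta.row(s).t();
      int len = b - a + 1;
      vec r(len);
      for (int i = 0; i < len; ++i) {
        double eta = tau[s] * dv[i];
        double ae = std::fabs(eta);
        double e = std::exp(-ae);
        double yy = y[a + i];
        lp += yy * eta - (std::max(eta, 0.0) + std::log1p(e));
        double sig = (eta >= 0.0) ? 1.0 / (1.0 + e) : e / (1.0 + e);
        r[i] = yy - sig;
      }
      g_theta.row(s) = tau[s] * (r.t() * X.rows(a, b));
      g_tau[s] = dot(r, dv);
    }

    // Chain rule through the bounded transform, plus priors.
    double inv_mu_var = 1.0 / (prior_mu_sd * prior_mu_sd);
    double inv_sg_var = 1.0 / (prior_sigma_sd * prior_sigma_sd);
    for (int k = 0; k < P; ++k) {
      double sum_ga = 0.0, sum_gaz = 0.0;
      for (int s = 0; s < S; ++s) {
        double zz = z[k * S + s];
        double ga = ((k < K) ? g_theta(s, k) : g_tau[s]) * jac(s, k);
        sum_ga += ga;
        sum_gaz += ga * zz;
        g_z[k * S + s] = ga * sigma[k] - zz;
        lp -= 0.5 * zz * zz;
      }
      g_mu[k] = sum_ga - mu_raw[k] * inv_mu_var;
      g_ls[k] = sum_gaz * sigma[k] - sigma[k] * sigma[k] * inv_sg_var + 1.0;
      lp += -0.5 * mu_raw[k] * mu_raw[k] * inv_mu_var
            - 0.5 * sigma[k] * sigma[k] * inv_sg_var + ls[k];
    }
    return lp;
  }
};

struct Sampler {
  const ChoiceModel& m;
  Rng rng;
  vec inv_metric;  // estimated posterior variances (velocity = p % inv_metric)
  double eps = 0.1;
  int max_depth;
  int n_divergent_iter = 0;

  Sampler(const ChoiceModel& model, std::uint64_t seed, int max_depth_)
      : m(model), rng(seed), inv_metric(model.n, fill::ones),
        max_depth(max_depth_) {}

  double kinetic(const vec& p) const {
    return 0.5 * dot(p % inv_metric, p);
  }

  // One leapfrog step of size (dir * eps); updates q, p, grad, returns lp.
  double leapfrog(vec& q, vec& p, vec& grad, double dir) {
    double e = dir * eps;
    p += 0.5 * e * grad;
    q += e * (p % inv_metric);
    double lp = m.lp_grad(q, grad);
    p += 0.5 * e * grad;
    return lp;
  }

  struct Tree {
    vec q_minus, p_minus, g_minus, q_plus, p_plus, g_plus, q_prop, g_prop;
    double lp_prop = 0.0;
    double n_valid = 0.0;
    bool ok = true;
    double sum_alpha = 0.0;
    int n_alpha = 0;
  };

  bool no_uturn(const vec& q_minus, const vec& q_plus,
                const vec& p_minus, const vec& p_plus) const {
    vec dq = q_plus - q_minus;
    return dot(dq, p_minus % inv_metric) >= 0.0 &&
           dot(dq, p_plus % inv_metric) >= 0.0;
  }

  void build_tree(int depth, double dir, double log_u, double h0,
                  const vec& q, const vec& p, const vec& g, Tree& out,
                  bool& divergent) {
    if (depth == 0) {
      vec q1 = q, p1 = p, g1 = g;
      double lp1 = leapfrog(q1, p1, g1, dir);
      double ljoint = lp1 - kinetic(p1);
      if (!std::isfinite(ljoint)) ljoint = -datum::inf;
      out.q_minus = out.q_plus = out.q_prop = q1;
      out.p_minus = out.p_plus = p1;
      out.g_minus = out.g_plus = out.g_prop = g1;
      out.lp_prop = lp1;
      out.n_valid = (log_u <= ljoint) ? 1.0 : 0.0;
      out.ok = (log_u < ljoint + DIVERGENCE_THRESHOLD);
      if (!out.ok) divergent = true;
      double da = ljoint - h0;
      out.sum_alpha = (da > 0.0) ? 1.0 : std::exp(da);
      out.n_alpha = 1;
      return;
    }
    build_tree(depth - 1, dir, log_u, h0, q, p, g, out, divergent);
    if (!out.ok) return;
    Tree right;
    if (dir > 0) {
      build_tree(depth - 1, dir, log_u, h0, out.q_plus, out.p_plus,
                 out.g_plus, right, divergent);
      out.q_plus = right.q_plus; out.p_plus = right.p_plus;
      out.g_plus = right.g_plus;
    } else {
      build_tree(depth - 1, dir, log_u, h0, out.q_minus, out.p_minus,
                 out.g_minus, right, divergent);
      out.q_minus = right.q_minus; out.p_minus = right.p_minus;
      out.g_minus = right.g_minus;
    }
    double total = out.n_valid + right.n_valid;
    if (right.n_valid > 0.0 && rng.unif() < right.n_valid / total) {
      out.q_prop = right.q_prop;
      out.g_prop = right.g_prop;
      out.lp_prop = right.lp_prop;
    }
    out.n_valid = total;
    out.sum_alpha += right.sum_alpha;
    out.n_alpha += right.n_alpha;
    out.ok = right.ok &&
             no_uturn(out.q_minus, out.q_plus, out.p_minus, out.p_plus);
  }

  // One NUTS transition; q/lp/grad updated in place. Returns mean Metropolis
  // acceptance statistic (for dual averaging); fills depth/divergent.
  double transition(vec& q, double& lp, vec& grad, int& depth_out,
                    bool& divergent) {
    const int n = m.n;
    vec p0(n);
    for (int i = 0; i < n; ++i) p0[i] = rng.norm() / std::sqrt(inv_metric[i]);
    double h0 = lp - kinetic(p0);
    double log_u = std::log(rng.unif()) + h0;

    Tree tr;
    tr.q_minus = tr.q_plus = q;
    tr.p_minus = tr.p_plus = p0;
    tr.g_minus = tr.g_plus = grad;
    tr.q_prop = q; tr.g_prop = grad; tr.lp_prop = lp;
    tr.n_valid = 1.0;
    divergent = false;

    double sum_alpha = 0.0;
    int n_alpha = 0, depth = 0;
    bool ok = true;
    while (ok && depth < max_depth) {
      double dir = (rng.unif() < 0.5) ? -1.0 : 1.0;
      Tree sub;
      if (dir > 0) {
        build_tree(depth, dir, log_u, h0, tr.q_plus, tr.p_plus, tr.g_plus,
                   sub, divergent);
        tr.q_plus = sub.q_plus; tr.p_plus = sub.p_plus; tr.g_plus = sub.g_plus;
      } else {
        build_tree(depth, dir, log_u, h0, tr.q_minus, tr.p_minus, tr.g_minus,
                   sub, divergent);
        tr.q_minus = sub.q_minus; tr.p_minus = sub.p_minus;
        tr.g_minus = sub.g_minus;
      }
      if (sub.ok && sub.n_valid > 0.0 &&
          rng.unif() < sub.n_valid / tr.n_valid) {
        tr.q_prop = sub.q_prop;
        tr.g_prop = sub.g_prop;
        tr.lp_prop = sub.lp_prop;
      }
      tr.n_valid += sub.n_valid;
      sum_alpha += sub.sum_alpha;
      n_alpha += sub.n_alpha;
      ok = sub.ok &&
           no_uturn(tr.q_minus, tr.q_plus, tr.p_minus, tr.p_plus);
      ++depth;
    }
    q = tr.q_prop;
    grad = tr.g_prop;
    lp = tr.lp_prop;
    depth_out = depth;
    if (divergent) ++n_divergent_iter;
    return (n_alpha > 0) ? sum_alpha / n_alpha : 0.0;
  }

  void find_initial_eps(const vec& q0, const vec& grad0, double lp0) {
    eps = 0.1;
    vec p0(m.n);
    for (int i = 0; i < m.n; ++i)
      p0[i] = rng.norm() / std::sqrt(inv_metric[i]);
    double h0 = lp0 - kinetic(p0);
    vec q = q0, p = p0, g = grad0;
    double lp1 = leapfrog(q, p, g, 1.0);
    double h1 = lp1 - kinetic(p);
    if (!std::isfinite(h1)) h1 = -datum::inf;
    double dir = (h1 - h0 > std::log(0.5)) ? 1.0 : -1.0;
    for (int it = 0; it < 50; ++it) {
      q = q0; p = p0; g = grad0;
      lp1 = leapfrog(q, p, g, 1.0);
      h1 = lp1 - kinetic(p);
      if (!std::isfinite(h1)) h1 = -datum::inf;
      if (dir > 0 && h1 - h0 <= std::log(0.5)) break;
      if (dir < 0 && h1 - h0 >= std::log(0.5)) break;
      eps *= (dir > 0) ? 2.0 : 0.5;
      if (eps < 1e-8 || eps > 1e3) break;
    }
  }
};

// Dual-averaging step-size adaptation (target acceptance `delta`).
struct DualAverage {
  double mu, log_eps, log_eps_bar = 0.0, h_bar = 0.0;
  double delta, gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int count = 0;
  DualAverage(double eps0, double delta_) : mu(std::log(10.0 * eps0)),
      log_eps(std::log(eps0)), delta(delta_) {}
  double update(double alpha) {
    ++count;
    double w = 1.0 / (count + t0);
    h_bar = (1.0 - w) * h_bar + w * (delta - alpha);
    log_eps = mu - std::sqrt((double)count) / gamma * h_bar;
    double pw = std::pow((double)count, -kappa);
    log_eps_bar = pw * log_eps + (1.0 - pw) * log_eps_bar;
    return std::exp(log_eps);
  }
  double final_eps() const { return std::exp(log_eps_bar); }
};

static ChoiceModel make_model(const mat& X, const vec& offset, const vec& y,
                              const ivec& subj, int S, const vec& lb,
                              const vec& ub, double tau_ub, double prior_mu_sd,
                              double prior_sigma_sd) {
  int K = lb.n_elem;
  ChoiceModel m{X, offset, y, subj, S, K, K + 1, (K + 1) * (2 + S),
                lb, ub, tau_ub, prior_mu_sd, prior_sigma_sd, uvec()};
  m.index_subjects();
  return m;
}

// [[Rcpp::export]]
double hier_lp(const arma::vec& q, const arma::mat& X, const arma::vec& offset,
               const arma::vec& y, const arma::ivec& subj, int S,
               const arma::vec& lb, const arma::vec& ub, double tau_ub,
               double prior_mu_sd, double prior_sigma_sd) {
  ChoiceModel m = make_model(X, offset, y, subj, S, lb, ub, tau_ub,
                             prior_mu_sd, prior_sigma_sd);
  vec g;
  return m.lp_grad(q, g);
}

// [[Rcpp::export]]
arma::vec hier_grad(const arma::vec& q, const arma::mat& X,
                    const arma::vec& offset, const arma::vec& y,
                    const arma::ivec& subj, int S, const arma::vec& lb,
                    const arma::vec& ub, double tau_ub, double prior_mu_sd,
                    double prior_sigma_sd) {
  ChoiceModel m = make_model(X, offset, y, subj, S, lb, ub, tau_ub,
                             prior_mu_sd, prior_sigma_sd);
  vec g;
  m.lp_grad(q, g);
  return g;
}

// Run one NUTS chain. Warmup schedule: 15% step-size only, then two diagonal
// metric windows ending at 50% and 95% (each followed by a dual-averaging
// restart), final 5% step-size only.
// [[Rcpp::export]]
Rcpp::List nuts_chain(const arma::mat& X, const arma::vec& offset,
                      const arma::vec& y, const arma::ivec& subj, int S,
                      const arma::vec& lb, const arma::vec& ub, double tau_ub,
                      const arma::vec& q_init, int n_warmup, int n_iter,
                      int seed, double adapt_delta, int max_depth,
                      double prior_mu_sd, double prior_sigma_sd) {
  int n = ((int)lb.n_elem + 1) * (2 + S);
  ChoiceModel m = make_model(X, offset, y, subj, S, lb, ub, tau_ub,
                             prior_mu_sd, prior_sigma_sd);
  Sampler smp(m, (std::uint64_t)seed * 2654435761ULL + 1ULL, max_depth);

  vec q = q_init, grad(n);
  double lp = m.lp_grad(q, grad);
  if (!std::isfinite(lp)) Rcpp::stop("initial point has non-finite density");
  smp.find_initial_eps(q, grad, lp);
  DualAverage da(smp.eps, adapt_delta);

  int w_init = (int)std::floor(0.15 * n_warmup);
  int w_mid = (int)std::floor(0.50 * n_warmup);
  int w_end = (int)std::floor(0.95 * n_warmup);

  // Welford accumulators for the metric windows.
  vec wf_mean(n, fill::zeros), wf_m2(n, fill::zeros);
  int wf_n = 0;
  auto wf_reset = [&]() { wf_mean.zeros(); wf_m2.zeros(); wf_n = 0; };
  auto wf_update = [&](const vec& x) {
    ++wf_n;
    vec d = x - wf_mean;
    wf_mean += d / wf_n;
    wf_m2 += d % (x - wf_mean);
  };

  mat draws(n_iter, n);
  vec out_lp(n_iter);
  ivec out_depth(n_iter), out_div(n_iter);
  vec out_alpha(n_iter);
  int divergent_total = 0;

  for (int it = 0; it < n_warmup + n_iter; ++it) {
    int depth;
    bool div;
    double alpha = smp.transition(q, lp, grad, depth, div);
    if (it < n_warmup) {
      smp.eps = da.update(alpha);
      if (it >= w_init && it < w_end) wf_update(q);
      if ((it + 1 == w_mid || it + 1 == w_end) && wf_n > 10) {
        vec var = wf_m2 / (wf_n - 1.0);
        // Regularise towards unit variance as in adaptive HMC practice.
        smp.inv_metric = (wf_n / (wf_n + 5.0)) * var
                         + (5.0 / (wf_n + 5.0)) * vec(n, fill::ones) * 1e-3;
        smp.inv_metric.transform([](double v) {
          return std::max(v, 1e-10);
        });
        wf_reset();
        smp.find_initial_eps(q, grad, lp);
        da = DualAverage(smp.eps, adapt_delta);
      }
    } else {
      if (it == n_warmup) smp.eps = da.final_eps();
      int j = it - n_warmup;
      draws.row(j) = q.t();
      out_lp[j] = lp;
      out_depth[j] = depth;
      out_div[j] = div ? 1 : 0;
      out_alpha[j] = alpha;
      if (div) ++divergent_total;
    }
    if (it % 64 == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("draws") = draws,
      Rcpp::Named("lp") = out_lp,
      Rcpp::Named("treedepth") = out_depth,
      Rcpp::Named("divergent") = out_div,
      Rcpp::Named("accept_stat") = out_alpha,
      Rcpp::Named("step_size") = smp.eps,
      Rcpp::Named("inv_metric") = smp.inv_metric,
      Rcpp::Named("n_divergent") = divergent_total);
}

// Pointwise log-likelihood (draws x trials) from unconstrained draws.
// [[Rcpp::export]]
arma::mat pointwise_loglik(const arma::mat& draws, const arma::mat& X,
                           const arma::vec& offset, const arma::vec& y,
                           const arma::ivec& subj, int S, const arma::vec& lb,
                           const arma::vec& ub, double tau_ub) {
  int K = lb.n_elem, P = K + 1, N = X.n_rows, D = draws.n_rows;
  mat out(D, N);
  for (int d = 0; d < D; ++d) {
    auto at = [&](int j) { return draws(d, j); };
    mat theta(S, K);
    vec tau(S);
    for (int k = 0; k < P; ++k) {
      double sigma = std::exp(at(P + k));
      double mu = at(k);
      double range = (k < K) ? (ub[k] - lb[k]) : tau_ub;
      double lo = (k < K) ? lb[k] : 0.0;
      for (int s = 0; s < S; ++s) {
        double a = mu + sigma * at(2 * P + k * S + s);
        double val = lo + range * norm_cdf(a);
        if (k < K) theta(s, k) = val; else tau[s] = val;
      }
    }
    for (int i = 0; i < N; ++i) {
      int s = subj[i];
      double dv = offset[i];
      for (int k = 0; k < K; ++k) dv += X(i, k) * theta(s, k);
      double eta = tau[s] * dv;
      out(d, i) = y[i] * eta - softplus(eta);
    }  // (no sortedness requirement here)
  }
  return out;
}
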