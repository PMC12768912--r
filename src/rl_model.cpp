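// Hierarchical Rescorla-Wagner Q-learning model: log posterior with analytic
// gradients, and a No-U-Turn sampler (dual-averaging step size, diagonal
// metric adaptation) so fits are reproducible from a single integer seed.
//
// Parameterisation (unconstrained), P = 3 (dual learning rate) or 2 (single):
//   theta = [mu_1..mu_P, log_sigma_1..log_sigma_P, z_{s,p} (subject-major per
//   parameter, column p stored contiguously)]
//   subject-level: eta_{s,p} = mu_p + sigma_p * z_{s,p}   (non-centred)
//   alpha_reward = inv_logit(eta_1), alpha_loss = inv_logit(eta_2),
//   beta = exp(eta_last)
// Priors: mu_p ~ N(0,1); sigma_p ~ half-N(0,1) (sampled as log_sigma with
// Jacobian); z ~ N(0,1).

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct RLData {
  int n_subj = 0;
  int n_symbols = 0;
  double q_init = 0.5;
  bool two_lr = true;
  // per-subject trial sequences (0-based symbol indices)
  std::vector<std::vector<int>> chosen, other;
  std::vector<std::vector<double>> reward;
  int P() const { return two_lr ? 3 : 2; }
  int npar() const { return 2 * P() + n_subj * P(); }
};

inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// log probability of the recorded choices for one subject, optionally with
// gradients wrt (alpha_reward, alpha_loss, beta) on the constrained scale
double subj_loglik(const RLData &d, int s, double aR, double aL, double b,
                   double *gaR, double *gaL, double *gb) {
  const int K = d.n_symbols;
  std::vector<double> Q(K, d.q_init), dA(K, 0.0), dB(K, 0.0);
  const bool grad = gaR != nullptr;
  double ll = 0.0, gA = 0.0, gB = 0.0, gBeta = 0.0;
  const std::vector<int> &ch = d.chosen[s];
  const std::vector<int> &ot = d.other[s];
  const std::vector<double> &rw = d.reward[s];
  const size_t T = ch.size();
  for (size_t t = 0; t < T; ++t) {
    const int c = ch[t], o = ot[t];
    const double x = b * (Q[c] - Q[o]);
    ll += -log1pexp_(-x);
    if (grad) {
      const double e = 1.0 / (1.0 + std::exp(x)); // 1 - p(choice)
      gBeta += e * (Q[c] - Q[o]);
      const double common = e * b;
      gA += common * (dA[c] - dA[o]);
      gB += common * (dB[c] - dB[o]);
    }
    const double pe = rw[t] - Q[c];
    // ties (pe == 0) take the reward learning rate
    if (pe >= 0.0) {
      if (grad) {
        dA[c] = (1.0 - aR) * dA[c] + pe;
        dB[c] = (1.0 - aR) * dB[c];
      }
      Q[c] += aR * pe;
    } else {
      if (grad) {
        dA[c] = (1.0 - aL) * dA[c];
        dB[c] = (1.0 - aL) * dB[c] + pe;
      }
      Q[c] += aL * pe;
    }
  }
  if (grad) { *gaR = gA; *gaL = gB; *gb = gBeta; }
  return ll;
}

// joint log density and gradient on the unconstrained scale
double lp_grad(const RLData &d, const std::vector<double> &th,
               std::vector<double> *grad) {
  const int P = d.P(), n = d.n_subj;
  const double *mu = th.data();
  const double *ls = th.data() + P;
  const double *z = th.data() + 2 * P;
  double lp = 0.0;
  std::vector<double> sig(P);
  for (int p = 0; p < P; ++p) {
    sig[p] = std::exp(ls[p]);
    lp += -0.5 * mu[p] * mu[p];              // mu ~ N(0,1)
    lp += -0.5 * sig[p] * sig[p] + ls[p];    // sigma ~ half-N(0,1) + Jacobian
  }
  if (grad) {
    std::fill(grad->begin(), grad->end(), 0.0);
    for (int p = 0; p < P; ++p) {
      (*grad)[p] = -mu[p];
      (*grad)[P + p] = 1.0 - sig[p] * sig[p];
    }
  }
  for (int s = 0; s < n; ++s) {
    std::vector<double> eta(P), zs(P);
    for (int p = 0; p < P; ++p) {
      zs[p] = z[p * n + s];
      eta[p] = mu[p] + sig[p] * zs[p];
      lp += -0.5 * zs[p] * zs[p];            // z ~ N(0,1)
    }
    const double aR = 1.0 / (1.0 + std::exp(-eta[0]));
    const double aL = d.two_lr ? 1.0 / (1.0 + std::exp(-eta[1])) : aR;
    const double b = std::exp(eta[P - 1]);
    double gaR, gaL, gb;
    lp += subj_loglik(d, s, aR, aL, b, grad ? &gaR : nullptr, &gaL, &gb);
    if (grad) {
      std::vector<double> geta(P);
      if (d.two_lr) {
        geta[0] = gaR * aR * (1.0 - aR);
        geta[1] = gaL * aL * (1.0 - aL);
        geta[2] = gb * b;
      } else {
        geta[0] = (gaR + gaL) * aR * (1.0 - aR);
        geta[1] = gb * b;
      }
      for (int p = 0; p < P; ++p) {
        (*grad)[p] += geta[p];
        (*grad)[P + p] += geta[p] * zs[p] * sig[p];
        (*grad)[2 * P + p * n + s] += geta[p] * sig[p] - zs[p];
      }
    }
  }
  return lp;
}

RLData build_data(const IntegerVector &subj, const IntegerVector &chosen,
                  const IntegerVector &other, const NumericVector &reward,
                  int n_subj, int n_symbols, bool two_lr, double q_init) {
  RLData d;
  d.n_subj = n_subj;
  d.n_symbols = n_symbols;
  d.two_lr = two_lr;
  d.q_init = q_init;
  d.chosen.resize(n_subj);
  d.other.resize(n_subj);
  d.reward.resize(n_subj);
  const int T = subj.size();
  for (int t = 0; t < T; ++t) {
    const int s = subj[t] - 1;
    if (s < 0 || s >= n_subj) stop("subject index out of range");
    d.chosen[s].push_back(chosen[t] - 1);
    d.other[s].push_back(other[t] - 1);
    d.reward[s].push_back(reward[t]);
  }
  return d;
}

// ---------------- NUTS ----------------

struct Sampler {
  const RLData *d;
  int npar;
  std::mt19937_64 rng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};
  std::normal_distribution<double> norm{0.0, 1.0};
  std::vector<double> inv_metric; // posterior variance estimates
  int n_grad = 0;

  double joint(const std::vector<double> &q, const std::vector<double> &p,
               double lp) const {
    double K = 0.0;
    for (int i = 0; i < npar; ++i) K += 0.5 * p[i] * p[i] * inv_metric[i];
    return lp - K;
  }

  void leapfrog(std::vector<double> &q, std::vector<double> &p,
                std::vector<double> &g, double &lp, double eps) {
    for (int i = 0; i < npar; ++i) p[i] += 0.5 * eps * g[i];
    for (int i = 0; i < npar; ++i) q[i] += eps * p[i] * inv_metric[i];
    lp = lp_grad(*d, q, &g);
    ++n_grad;
    for (int i = 0; i < npar; ++i) p[i] += 0.5 * eps * g[i];
  }
};

struct Tree {
  std::vector<double> q_minus, p_minus, g_minus;
  std::vector<double> q_plus, p_plus, g_plus;
  std::vector<double> q_prop;
  double lp_minus, lp_plus, lp_prop;
  double n_valid;      // number of valid states in the slice
  bool ok;             // subtree free of divergence / U-turn
  bool divergent;
  double sum_accept;   // accumulated Metropolis acceptance statistic
  int n_accept;
};

bool uturn(const Sampler &S, const std::vector<double> &qm,
           const std::vector<double> &qp, const std::vector<double> &pm,
           const std::vector<double> &pp) {
  double a = 0.0, b = 0.0;
  for (int i = 0; i < S.npar; ++i) {
    const double dq = qp[i] - qm[i];
    a += dq * pm[i] * S.inv_metric[i];
    b += dq * pp[i] * S.inv_metric[i];
  }
  return (a < 0.0) || (b < 0.0);
}

void build_tree(Sampler &S, Tree &T, std::vector<double> q,
                std::vector<double> p, std::vector<double> g, double lp,
                double log_u, int dir, int depth, double eps, double joint0) {
  if (depth == 0) {
    S.leapfrog(q, p, g, lp, dir * eps);
    const double j = S.joint(q, p, lp);
    T.divergent = (log_u - j > 1000.0) || !std::isfinite(j);
    T.n_valid = (log_u <= j) ? 1.0 : 0.0;
    T.ok = !T.divergent;
    T.q_minus = q; T.p_minus = p; T.g_minus = g; T.lp_minus = lp;
    T.q_plus = q; T.p_plus = p; T.g_plus = g; T.lp_plus = lp;
    T.q_prop = q; T.lp_prop = lp;
    const double a = j - joint0;
    // non-finite Hamiltonians count as zero acceptance, not NaN
    T.sum_accept = std::isfinite(a) ? ((a > 0.0) ? 1.0 : std::exp(a)) : 0.0;
    T.n_accept = 1;
    return;
  }
  build_tree(S, T, q, p, g, lp, log_u, dir, depth - 1, eps, joint0);
  if (!T.ok) return;
  Tree T2;
  if (dir == -1) {
    build_tree(S, T2, T.q_minus, T.p_minus, T.g_minus, T.lp_minus, log_u, dir,
               depth - 1, eps, joint0);
    T.q_minus = T2.q_minus; T.p_minus = T2.p_minus; T.g_minus = T2.g_minus;
    T.lp_minus = T2.lp_minus;
  } else {
    build_tree(S, T2, T.q_plus, T.p_plus, T.g_plus, T.lp_plus, log_u, dir,
               depth - 1, eps, joint0);
    T.q_plus = T2.q_plus; T.p_plus = T2.p_plus; T.g_plus = T2.g_plus;
    T.lp_plus = T2.lp_plus;
  }
  if (T2.n_valid > 0.0 &&
      S.unif(S.rng) < T2.n_valid / std::max(1.0, T.n_valid + T2.n_valid)) {
    T.q_prop = T2.q_prop;
    T.lp_prop = T2.lp_prop;
  }
  T.n_valid += T2.n_valid;
  T.sum_accept += T2.sum_accept;
  T.n_accept += T2.n_accept;
  T.divergent = T.divergent || T2.divergent;
  T.ok = T2.ok && !uturn(S, T.q_minus, T.q_plus, T.p_minus, T.p_plus);
}

} // namespace

// [[Rcpp::export]]
List rl_nuts_sample(IntegerVector subj, IntegerVector chosen,
                    IntegerVector other, NumericVector reward, int n_subj,
                    int n_symbols, bool two_lr, double q_init, int chains,
                    int warmup, int iter, int seed, int max_treedepth,
                    double target_accept) {
  RLData d = build_data(subj, chosen, other, reward, n_subj, n_symbols, two_lr,
                        q_init);
  const int npar = d.npar();
  const int total = chains * iter;
  NumericMatrix draws(total, npar);
  IntegerVector chain_id(total), treedepth(total), divergent(total),
      n_leapfrog(total);
  NumericVector lp_out(total), energy(total), accept_out(total),
      stepsizes(chains);

  for (int c = 0; c < chains; ++c) {
    Sampler S;
    S.d = &d;
    S.npar = npar;
    S.rng.seed(static_cast<uint64_t>(seed) * 1000003ULL + 17ULL * (c + 1));
    S.inv_metric.assign(npar, 1.0);

    std::vector<double> q(npar), g(npar);
    for (int i = 0; i < npar; ++i) q[i] = (S.unif(S.rng) * 2.0 - 1.0);
    double lp = lp_grad(d, q, &g);

    // crude initial step size by one-step heuristic
    double eps = 0.1;
    {
      std::vector<double> p(npar), q1 = q, g1 = g;
      for (int i = 0; i < npar; ++i) p[i] = S.norm(S.rng);
      double lp1 = lp;
      const double j0 = S.joint(q1, p, lp1);
      S.leapfrog(q1, p, g1, lp1, eps);
      double dj = S.joint(q1, p, lp1) - j0;
      int guard = 0;
      while (std::isfinite(dj) ? (dj > std::log(0.8) ? false : true) : true) {
        eps *= 0.5;
        if (++guard > 30) break;
        q1 = q; g1 = g; lp1 = lp;
        for (int i = 0; i < npar; ++i) p[i] = S.norm(S.rng);
        const double jj0 = S.joint(q1, p, lp1);
        S.leapfrog(q1, p, g1, lp1, eps);
        dj = S.joint(q1, p, lp1) - jj0;
      }
    }

    // dual averaging state
    double mu_da = std::log(10.0 * eps), log_eps_bar = 0.0, h_bar = 0.0;
    const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
    int da_count = 0;

    // metric adaptation windows (Stan-style buffers)
    const int init_buf = std::min(75, std::max(10, warmup / 6));
    const int term_buf = std::min(50, std::max(10, warmup / 10));
    int win_start = init_buf, win_size = 25;
    int win_end = std::min(win_start + win_size, warmup - term_buf);
    std::vector<double> w_mean(npar, 0.0), w_m2(npar, 0.0);
    int w_n = 0;

    for (int it = 0; it < warmup + iter; ++it) {
      std::vector<double> p(npar);
      for (int i = 0; i < npar; ++i)
        p[i] = S.norm(S.rng) / std::sqrt(S.inv_metric[i]);
      const double joint0 = S.joint(q, p, lp);
      const double log_u = joint0 + std::log(S.unif(S.rng));

      Tree T;
      T.q_minus = q; T.p_minus = p; T.g_minus = g; T.lp_minus = lp;
      T.q_plus = q; T.p_plus = p; T.g_plus = g; T.lp_plus = lp;
      T.q_prop = q; T.lp_prop = lp;
      T.n_valid = 1.0;
      T.ok = true; T.divergent = false;
      T.sum_accept = 0.0; T.n_accept = 0;

      int depth = 0;
      const int ngrad0 = S.n_grad;
      bool any_div = false;
      while (T.ok && depth < max_treedepth) {
        Tree T2;
        const int dir = (S.unif(S.rng) < 0.5) ? -1 : 1;
        if (dir == -1) {
          build_tree(S, T2, T.q_minus, T.p_minus, T.g_minus, T.lp_minus, log_u,
                     dir, depth, eps, joint0);
          T.q_minus = T2.q_minus; T.p_minus = T2.p_minus;
          T.g_minus = T2.g_minus; T.lp_minus = T2.lp_minus;
        } else {
          build_tree(S, T2, T.q_plus, T.p_plus, T.g_plus, T.lp_plus, log_u,
                     dir, depth, eps, joint0);
          T.q_plus = T2.q_plus; T.p_plus = T2.p_plus;
          T.g_plus = T2.g_plus; T.lp_plus = T2.lp_plus;
        }
        any_div = any_div || T2.divergent;
        if (T2.ok && T2.n_valid > 0.0 &&
            S.unif(S.rng) < T2.n_valid / T.n_valid) {
          T.q_prop = T2.q_prop;
          T.lp_prop = T2.lp_prop;
        }
        T.sum_accept += T2.sum_accept;
        T.n_accept += T2.n_accept;
        if (!T2.ok) break;
        T.n_valid += T2.n_valid;
        if (uturn(S, T.q_minus, T.q_plus, T.p_minus, T.p_plus)) break;
        ++depth;
      }

      q = T.q_prop;
      lp = lp_grad(d, q, &g); // refresh gradient at accepted state
      ++S.n_grad;
      const double accept_stat =
          (T.n_accept > 0) ? T.sum_accept / T.n_accept : 0.0;

      if (it < warmup) {
        // dual averaging step-size update
        ++da_count;
        const double eta = 1.0 / (da_count + t0);
        h_bar = (1.0 - eta) * h_bar + eta * (target_accept - accept_stat);
        const double log_eps = mu_da - std::sqrt((double)da_count) / gamma * h_bar;
        const double w = std::pow((double)da_count, -kappa);
        log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
        eps = std::exp(log_eps);
        if (!std::isfinite(eps) || eps <= 0.0) { // recover from blow-ups
          eps = 0.01;
          mu_da = std::log(10.0 * eps);
          h_bar = 0.0; log_eps_bar = std::log(eps); da_count = 0;
        }

        if (it >= win_start && it < win_end) {
          ++w_n;
          for (int i = 0; i < npar; ++i) {
            const double delta = q[i] - w_mean[i];
            w_mean[i] += delta / w_n;
            w_m2[i] += delta * (q[i] - w_mean[i]);
          }
          if (it == win_end - 1 && w_n > 3) {
            for (int i = 0; i < npar; ++i) {
              const double var = w_m2[i] / (w_n - 1);
              S.inv_metric[i] =
                  (w_n / (w_n + 5.0)) * var + 1e-3 * (5.0 / (w_n + 5.0));
            }
            std::fill(w_mean.begin(), w_mean.end(), 0.0);
            std::fill(w_m2.begin(), w_m2.end(), 0.0);
            w_n = 0;
            win_start = win_end;
            win_size *= 2;
            win_end = win_start + win_size;
            if (win_end + 2 * win_size > warmup - term_buf)
              win_end = warmup - term_buf;
            // restart step-size adaptation for the new metric
            mu_da = std::log(10.0 * eps);
            h_bar = 0.0; log_eps_bar = std::log(eps); da_count = 0;
          }
        }
        if (it == warmup - 1) eps = std::exp(log_eps_bar);
      } else {
        const int row = c * iter + (it - warmup);
        for (int i = 0; i < npar; ++i) draws(row, i) = q[i];
        chain_id[row] = c + 1;
        lp_out[row] = lp;
        energy[row] = -joint0;
        treedepth[row] = depth;
        divergent[row] = any_div ? 1 : 0;
        accept_out[row] = accept_stat;
        n_leapfrog[row] = S.n_grad - ngrad0;
      }
    }
    stepsizes[c] = eps;
  }

  return List::create(
      _["draws"] = draws, _["chain"] = chain_id, _["lp"] = lp_out,
      _["energy"] = energy, _["treedepth"] = treedepth,
      _["divergent"] = divergent, _["accept_stat"] = accept_out,
      _["n_leapfrog"] = n_leapfrog, _["stepsize"] = stepsizes,
      _["n_par"] = npar);
}

// [[Rcpp::export]]
double rl_lp(IntegerVector subj, IntegerVector chosen, IntegerVector other,
             NumericVector reward, int n_subj, int n_symbols, bool two_lr,
             double q_init, NumericVector theta) {
  RLData d = build_data(subj, chosen, other, reward, n_subj, n_symbols, two_lr,
                        q_init);
  std::vector<double> th(theta.begin(), theta.end());
  return lp_grad(d, th, nullptr);
}

// [[Rcpp::export]]
NumericVector rl_lp_gradient(IntegerVector subj, IntegerVector chosen,
                             IntegerVector other, NumericVector reward,
                             int n_subj, int n_symbols, bool two_lr,
                             double q_init, NumericVector theta) {
  RLData d = build_data(subj, chosen, other, reward, n_subj, n_symbols, two_lr,
                        q_init);
  std::vector<double> th(theta.begin(), theta.end()), g(th.size());
  lp_grad(d, th, &g);
  return NumericVector(g.begin(), g.end());
}

// [[Rcpp::export]]
double rl_trial_loglik_cpp(double alpha_reward, double alpha_loss, double beta,
                           IntegerVector chosen, IntegerVector other,
                           NumericVector reward, int n_symbols,
                           double q_init) {
  RLData d;
  d.n_subj = 1;
  d.n_symbols = n_symbols;
  d.two_lr = true;
  d.q_init = q_init;
  d.chosen.resize(1); d.other.resize(1); d.reward.resize(1);
  for (int t = 0; t < chosen.size(); ++t) {
    d.chosen[0].push_back(chosen[t] - 1);
    d.other[0].push_back(other[t] - 1);
    d.reward[0].push_back(reward[t]);
  }
  return subj_loglik(d, 0, alpha_reward, alpha_loss, beta, nullptr, nullptr,
                     nullptr);
}

// Per-draw, per-subject pointwise log-likelihood for LOO.
// alpha matrices are (draws x subjects) on the constrained scale.
// [[Rcpp::export]]
NumericMatrix rl_pointwise_loglik(IntegerVector subj, IntegerVector chosen,
                                  IntegerVector other, NumericVector reward,
                                  int n_subj, int n_symbols,
                                  NumericMatrix alpha_reward,
                                  NumericMatrix alpha_loss, NumericMatrix beta,
                                  double q_init) {
  RLData d = build_data(subj, chosen, other, reward, n_subj, n_symbols, true,
                        q_init);
  const int S = alpha_reward.nrow();
  NumericMatrix out(S, n_subj);
  for (int s = 0; s < n_subj; ++s)
    for (int i = 0; i < S; ++i)
      out(i, s) = subj_loglik(d, s, alpha_reward(i, s), alpha_loss(i, s),
                              beta(i, s), nullptr, nullptr, nullptr);
  return out;
}
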