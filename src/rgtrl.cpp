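#include <Rcpp.h>
using namespace Rcpp;

// Model ids (kept in sync with R's rl_models() registry):
// 0 basic, 1 scaled, 2 scaled_offset, 3 nonlinear, 4 reward_scaled
//
// Natural-scale parameter layout per model:
// basic:         beta, eta_plus, eta_minus
// scaled:        beta, eta_plus, eta_minus, m
// scaled_offset: beta, eta_plus, eta_minus, m, b
// nonlinear:     beta, eta_plus, eta_minus, b, r
// reward_scaled: beta, eta_plus, eta_minus, m, mRew

static inline double win_target(int model, const double *p, double R) {
  if (model == 4) return p[4] * R;  // mRew * R
  return R;
}

static inline double clamp_target(double x) {
  // keeps Q finite under extreme sampler proposals (e.g. huge r in T^r)
  if (!(x > -1e6)) return -1e6;
  if (x > 1e6) return 1e6;
  return x;
}

static inline double loss_target(int model, const double *p, double T) {
  double t;
  switch (model) {
  case 0: t = 0.0; break;
  case 1: t = -p[3] * T; break;              // -m T
  case 2: t = p[4] - p[3] * T; break;        // b - m T
  case 3: t = p[3] - std::pow(T, p[4]); break; // b - T^r
  case 4: t = -p[3] * T; break;              // same loss transform as scaled cost
  default: t = 0.0;
  }
  return clamp_target(t);
}

// softmax log-probability of `choice` given q and beta; overflow-guarded
static inline double log_softmax_choice(const double q[4], double beta, int choice) {
  double z[4], zmax = -1e300;
  for (int k = 0; k < 4; ++k) {
    z[k] = beta * q[k];
    if (z[k] > 700.0) z[k] = 700.0;
    if (z[k] < -700.0) z[k] = -700.0;
    if (z[k] > zmax) zmax = z[k];
  }
  double s = 0.0;
  for (int k = 0; k < 4; ++k) s += std::exp(z[k] - zmax);
  return (z[choice] - zmax) - std::log(s);
}

static inline void softmax_vec(const double q[4], double beta, double out[4]) {
  double z[4], zmax = -1e300;
  for (int k = 0; k < 4; ++k) {
    z[k] = beta * q[k];
    if (z[k] > 700.0) z[k] = 700.0;
    if (z[k] < -700.0) z[k] = -700.0;
    if (z[k] > zmax) zmax = z[k];
  }
  double s = 0.0;
  for (int k = 0; k < 4; ++k) { out[k] = std::exp(z[k] - zmax); s += out[k]; }
  for (int k = 0; k < 4; ++k) out[k] /= s;
}

// Pointwise log-likelihood for one subject's ordered valid trials.
// choice is 1-based (P1..P4), win is 1/0, Q starts at zero and carries
// across the whole sequence (session boundaries do not reset it).
// [[Rcpp::export]]
NumericVector cpp_pointwise_loglik(IntegerVector choice, IntegerVector win,
                                   NumericVector pellets, NumericVector penalty,
                                   int model, NumericVector pars) {
  int n = choice.size();
  NumericVector ll(n);
  const double *p = pars.begin();
  double q[4] = {0.0, 0.0, 0.0, 0.0};
  double beta = p[0], etap = p[1], etam = p[2];
  for (int t = 0; t < n; ++t) {
    int c = choice[t] - 1;
    ll[t] = log_softmax_choice(q, beta, c);
    if (win[t] == 1) {
      double tgt = win_target(model, p, pellets[t]);
      q[c] += etap * (tgt - q[c]);
    } else {
      double tgt = loss_target(model, p, penalty[t]);
      q[c] += etam * (tgt - q[c]);
    }
  }
  return ll;
}

// Forward simulation of one agent under a fixed trial count per session.
// sched: 4 x 4 matrix, columns reward_pellets, p_win, penalty_s, p_penalty.
// outcome_mode: 0 = sampled outcomes, 1 = expected-outcome propagation
// (choices still sampled; the chosen Q moves by the probability-weighted
// mixture of the win and loss updates and pellets are recorded in
// expectation). Uses R's RNG.
// [[Rcpp::export]]
List cpp_simulate_agent(int model, NumericVector pars, NumericMatrix sched,
                        int n_sessions, int trials_per_session,
                        int outcome_mode, NumericVector q0) {
  RNGScope scope;
  int n = n_sessions * trials_per_session;
  NumericMatrix probs(n, 4);
  IntegerVector session(n), trial(n), choice(n), win(n);
  NumericVector pellets(n), penalty(n);
  const double *p = pars.begin();
  double q[4];
  for (int k = 0; k < 4; ++k) q[k] = q0[k];
  double beta = p[0], etap = p[1], etam = p[2];
  double pr[4];
  int t = 0;
  for (int s = 0; s < n_sessions; ++s) {
    for (int i = 0; i < trials_per_session; ++i, ++t) {
      session[t] = s + 1;
      trial[t] = i + 1;
      softmax_vec(q, beta, pr);
      for (int k = 0; k < 4; ++k) probs(t, k) = pr[k];
      double u = unif_rand(), acc = 0.0;
      int c = 3;
      for (int k = 0; k < 4; ++k) { acc += pr[k]; if (u <= acc) { c = k; break; } }
      choice[t] = c + 1;
      double R = sched(c, 0), pwin = sched(c, 1), Tpen = sched(c, 2);
      if (outcome_mode == 0) {
        if (unif_rand() < pwin) {
          win[t] = 1; pellets[t] = R; penalty[t] = 0.0;
          q[c] += etap * (win_target(model, p, R) - q[c]);
        } else {
          win[t] = 0; pellets[t] = 0.0; penalty[t] = Tpen;
          q[c] += etam * (loss_target(model, p, Tpen) - q[c]);
        }
      } else {
        win[t] = NA_INTEGER;
        pellets[t] = pwin * R; penalty[t] = (1.0 - pwin) * Tpen;
        double dq = pwin * etap * (win_target(model, p, R) - q[c]) +
          (1.0 - pwin) * etam * (loss_target(model, p, Tpen) - q[c]);
        q[c] += dq;
      }
    }
  }
  return List::create(_["session"] = session, _["trial"] = trial,
                      _["choice"] = choice, _["win"] = win,
                      _["pellets"] = pellets, _["penalty_s"] = penalty,
                      _["probs"] = probs);
}

// ---------------------------------------------------------------------------
// Hierarchical sampler: adaptive Metropolis-within-Gibbs on the noncentered
// parameterization. Subject parameter p of subject s is
//   theta_{s,p} = constrain_p( mu_p + sigma_p * z_{s,p} )
// with mu_p ~ Normal(prior_mu_mean_p, prior_mu_sd_p), sigma_p ~ half-Normal(0,1)
// sampled as tau_p = log sigma_p (Jacobian + tau_p), z ~ Normal(0,1).
// constrain codes: 0 = exp, 1 = probit (standard-normal CDF), 2 = identity.

struct SubjData {
  std::vector<int> choice, win;
  std::vector<double> pellets, penalty;
};

static inline double constrain1(int code, double x) {
  switch (code) {
  case 0: return std::exp(x > 30.0 ? 30.0 : x);
  case 1: return R::pnorm(x, 0.0, 1.0, 1, 0);
  default: return x;
  }
}

static double subj_loglik_raw(const SubjData &d, int model, const double *theta) {
  double q[4] = {0, 0, 0, 0};
  double ll = 0.0;
  double beta = theta[0], etap = theta[1], etam = theta[2];
  int n = d.choice.size();
  for (int t = 0; t < n; ++t) {
    int c = d.choice[t] - 1;
    ll += log_softmax_choice(q, beta, c);
    if (d.win[t] == 1) {
      q[c] += etap * (win_target(model, theta, d.pellets[t]) - q[c]);
    } else {
      q[c] += etam * (loss_target(model, theta, d.penalty[t]) - q[c]);
    }
  }
  return ll;
}

// one chain; returns draws and diagnostics. All randomness from R's RNG.
// [[Rcpp::export]]
List cpp_fit_chain(List subj_list, int model, int n_params,
                   IntegerVector trans, NumericVector prior_mu_mean,
                   NumericVector prior_mu_sd, int n_warmup, int n_samples,
                   int thin, double target_accept) {
  RNGScope scope;
  int S = subj_list.size();
  std::vector<SubjData> dat(S);
  int n_points = 0;
  for (int s = 0; s < S; ++s) {
    List d = subj_list[s];
    IntegerVector ch = d["choice"], wn = d["win"];
    NumericVector pe = d["pellets"], ty = d["penalty_s"];
    dat[s].choice.assign(ch.begin(), ch.end());
    dat[s].win.assign(wn.begin(), wn.end());
    dat[s].pellets.assign(pe.begin(), pe.end());
    dat[s].penalty.assign(ty.begin(), ty.end());
    n_points += ch.size();
  }
  int P = n_params;

  // state
  std::vector<double> mu(P, 0.0), tau(P, 0.0);  // tau = log sigma
  std::vector<double> z(S * P);
  for (int i = 0; i < S * P; ++i) z[i] = norm_rand() * 0.1;
  for (int p = 0; p < P; ++p) { mu[p] = prior_mu_mean[p] + 0.1 * norm_rand(); tau[p] = -1.0 + 0.1 * norm_rand(); }

  std::vector<double> theta(S * P), sigma(P);
  std::vector<double> ll_subj(S);

  auto update_theta_subj = [&](int s) {
    for (int p = 0; p < P; ++p)
      theta[s * P + p] = constrain1(trans[p], mu[p] + sigma[p] * z[s * P + p]);
  };
  auto recompute_all = [&]() {
    for (int p = 0; p < P; ++p) sigma[p] = std::exp(tau[p]);
    for (int s = 0; s < S; ++s) { update_theta_subj(s); ll_subj[s] = subj_loglik_raw(dat[s], model, &theta[s * P]); }
  };
  recompute_all();

  auto zprior = [&](int s) {
    double lp = 0.0;
    for (int p = 0; p < P; ++p) { double v = z[s * P + p]; lp += -0.5 * v * v; }
    return lp;
  };
  auto group_prior = [&]() {
    double lp = 0.0;
    for (int p = 0; p < P; ++p) {
      double dm = (mu[p] - prior_mu_mean[p]) / prior_mu_sd[p];
      lp += -0.5 * dm * dm;
      lp += -0.5 * sigma[p] * sigma[p] + tau[p];  // half-normal on sigma + Jacobian
    }
    return lp;
  };

  // adaptation state: per-block log step scale + per-dim running variance
  int n_blocks = S + P;  // subject z-blocks then per-parameter (mu,tau) blocks
  std::vector<double> lstep(n_blocks, std::log(0.2));
  std::vector<double> acc_n(n_blocks, 0.0), acc_sum(n_blocks, 0.0);
  // Welford accumulators per block dimension
  std::vector<double> w_n(n_blocks, 0.0);
  std::vector<std::vector<double>> w_mean(n_blocks), w_m2(n_blocks);
  for (int b = 0; b < n_blocks; ++b) {
    int d = (b < S) ? P : 2;
    w_mean[b].assign(d, 0.0);
    w_m2[b].assign(d, 1.0);
  }
  // full covariance adaptation for subject z-blocks (captures the strong
  // beta/learning-rate tradeoffs in the subject-level posterior)
  std::vector<std::vector<double>> w_cov(S), chol(S);
  for (int s = 0; s < S; ++s) { w_cov[s].assign(P * P, 0.0); chol[s].assign(P * P, 0.0); for (int p = 0; p < P; ++p) chol[s][p * P + p] = 1.0; }
  auto update_chol = [&](int s) {
    // Cholesky of (cov + eps I); fall back to identity on failure
    std::vector<double> a(P * P);
    double denom = std::max(1.0, w_n[s] - 1.0);
    for (int i = 0; i < P; ++i)
      for (int j = 0; j < P; ++j)
        a[i * P + j] = w_cov[s][i * P + j] / denom + (i == j ? 1e-4 : 0.0);
    std::vector<double> L(P * P, 0.0);
    for (int i = 0; i < P; ++i) {
      for (int j = 0; j <= i; ++j) {
        double sum = a[i * P + j];
        for (int k2 = 0; k2 < j; ++k2) sum -= L[i * P + k2] * L[j * P + k2];
        if (i == j) {
          if (sum <= 0.0) return;  // keep previous factor
          L[i * P + i] = std::sqrt(sum);
        } else L[i * P + j] = sum / L[j * P + j];
      }
    }
    chol[s] = L;
  };
  double lstep_tau = std::log(0.5);  // scale for the centered-step tau update

  if (thin < 1) thin = 1;
  int n_iter = n_warmup + n_samples * thin;
  NumericMatrix draw_mu(n_samples, P), draw_sigma(n_samples, P), draw_group(n_samples, P);
  NumericVector draw_theta(n_samples * S * P);
  NumericMatrix draw_ll(n_samples, n_points);
  NumericVector lp_trace(n_samples);

  std::vector<double> prop(P > 2 ? P : 2);

  for (int it = 0; it < n_iter; ++it) {
    bool warm = it < n_warmup;
    // --- subject blocks (repeated: each touches one subject's likelihood
    // only, so extra sweeps are cheap relative to the group blocks) ---
    for (int rep2 = 0; rep2 < 3; ++rep2)
    for (int s = 0; s < S; ++s) {
      double step = std::exp(lstep[s]);
      double cur = ll_subj[s] + zprior(s);
      std::vector<double> zold(P), eps(P);
      for (int p = 0; p < P; ++p) { zold[p] = z[s * P + p]; eps[p] = norm_rand(); }
      bool indep = unif_rand() < 0.15;  // prior-independence move: jumps ridges
      for (int p = 0; p < P; ++p) {
        if (indep) { z[s * P + p] = norm_rand(); continue; }
        double d = 0.0;
        for (int k2 = 0; k2 <= p; ++k2) d += chol[s][p * P + k2] * eps[k2];
        z[s * P + p] += step * d;
      }
      update_theta_subj(s);
      double ll_new = subj_loglik_raw(dat[s], model, &theta[s * P]);
      // for the independence move the N(0,I) proposal cancels the z prior
      double lr = indep ? ll_new - ll_subj[s] : ll_new + zprior(s) - cur;
      double a = std::isfinite(lr) ? std::exp(std::min(0.0, lr)) : 0.0;
      if (unif_rand() < a) {
        ll_subj[s] = ll_new;
      } else {
        for (int p = 0; p < P; ++p) z[s * P + p] = zold[p];
        update_theta_subj(s);
      }
      if (warm && !indep) {
        lstep[s] += (a - target_accept) / std::sqrt(it / 10.0 + 1.0);
        w_n[s] += 1.0;
        std::vector<double> dlt(P);
        for (int p = 0; p < P; ++p) {
          double x = z[s * P + p];
          dlt[p] = x - w_mean[s][p];
          w_mean[s][p] += dlt[p] / w_n[s];
        }
        for (int i = 0; i < P; ++i)
          for (int j = 0; j < P; ++j)
            w_cov[s][i * P + j] += dlt[i] * (z[s * P + j] - w_mean[s][j]);
        if (((it + 1) % 50) == 0 && w_n[s] > 2 * P) update_chol(s);
      } else { acc_n[s] += 1.0; acc_sum[s] += a; }
    }
    // --- group blocks (mu_p, tau_p): full-likelihood updates ---
    for (int p = 0; p < P; ++p) {
      int b = S + p;
      double step = std::exp(lstep[b]);
      double cur = group_prior();
      for (int s = 0; s < S; ++s) cur += ll_subj[s];
      double mu_old = mu[p], tau_old = tau[p];
      std::vector<double> ll_old(ll_subj);
      double sd0 = std::sqrt(w_m2[b][0] / std::max(1.0, w_n[b] - 1.0) + 1e-6);
      double sd1 = std::sqrt(w_m2[b][1] / std::max(1.0, w_n[b] - 1.0) + 1e-6);
      mu[p] += step * sd0 * norm_rand();
      tau[p] += step * sd1 * norm_rand();
      sigma[p] = std::exp(tau[p]);
      double nl = group_prior();
      for (int s = 0; s < S; ++s) {
        update_theta_subj(s);
        ll_subj[s] = subj_loglik_raw(dat[s], model, &theta[s * P]);
        nl += ll_subj[s];
      }
      double lr2 = nl - cur;
      double a = std::isfinite(lr2) ? std::exp(std::min(0.0, lr2)) : 0.0;
      if (unif_rand() >= a) {
        mu[p] = mu_old; tau[p] = tau_old; sigma[p] = std::exp(tau_old);
        ll_subj = ll_old;
        for (int s = 0; s < S; ++s) update_theta_subj(s);
      }
      if (warm) {
        lstep[b] += (a - target_accept) / std::sqrt(it / 10.0 + 1.0);
        w_n[b] += 1.0;
        double xs[2] = {mu[p], tau[p]};
        for (int d = 0; d < 2; ++d) {
          double dlt = xs[d] - w_mean[b][d];
          w_mean[b][d] += dlt / w_n[b];
          w_m2[b][d] += dlt * (xs[d] - w_mean[b][d]);
        }
      } else { acc_n[b] += 1.0; acc_sum[b] += a; }
    }
    // --- interweaved centered step ---
    // Hold the unconstrained subject values x_sp = mu_p + sigma_p * z_sp
    // fixed: theta and the likelihood are unchanged, while (mu_p, sigma_p)
    // move under p(mu, sigma | x) = prior x prod_s N(x_sp | mu_p, sigma_p).
    // This is the centered half of an interweaving scheme; it decorrelates
    // the group-level parameters from the subject deviates, which a purely
    // noncentered random walk mixes slowly.
    for (int p = 0; p < P; ++p) {
      std::vector<double> x(S);
      double xsum = 0.0;
      for (int s = 0; s < S; ++s) { x[s] = mu[p] + sigma[p] * z[s * P + p]; xsum += x[s]; }
      // conjugate Gibbs draw for mu_p | sigma_p, x
      double s0 = prior_mu_sd[p], m0 = prior_mu_mean[p];
      double prec = 1.0 / (s0 * s0) + S / (sigma[p] * sigma[p]);
      double mean = (m0 / (s0 * s0) + xsum / (sigma[p] * sigma[p])) / prec;
      mu[p] = mean + norm_rand() / std::sqrt(prec);
      // short random walk on tau_p | mu_p, x (no likelihood involved)
      auto tau_target = [&](double tauv) {
        double sg = std::exp(tauv);
        double lp = -0.5 * sg * sg + tauv;  // half-normal prior + Jacobian
        for (int s = 0; s < S; ++s) {
          double d = (x[s] - mu[p]) / sg;
          lp += -0.5 * d * d - tauv;
        }
        return lp;
      };
      double curt = tau_target(tau[p]);
      for (int rep = 0; rep < 3; ++rep) {
        double propv = tau[p] + std::exp(lstep_tau) * norm_rand();
        double nl = tau_target(propv);
        double lr3 = nl - curt;
        double a = std::isfinite(lr3) ? std::exp(std::min(0.0, lr3)) : 0.0;
        if (unif_rand() < a) { tau[p] = propv; curt = nl; }
        if (warm) lstep_tau += (a - target_accept) / std::sqrt(it / 10.0 + 1.0) / (3.0 * P);
      }
      sigma[p] = std::exp(tau[p]);
      for (int s = 0; s < S; ++s) z[s * P + p] = (x[s] - mu[p]) / sigma[p];
    }

    // --- save (every thin-th post-warmup sweep) ---
    if (!warm && ((it - n_warmup + 1) % thin) == 0) {
      int j = (it - n_warmup + 1) / thin - 1;
      double lp = group_prior();
      for (int p = 0; p < P; ++p) {
        draw_mu(j, p) = mu[p];
        draw_sigma(j, p) = sigma[p];
        draw_group(j, p) = constrain1(trans[p], mu[p]);
      }
      int col = 0;
      for (int s = 0; s < S; ++s) {
        lp += ll_subj[s] + zprior(s);
        for (int p = 0; p < P; ++p)
          draw_theta[j + n_samples * (s * P + p)] = theta[s * P + p];
        // pointwise log-lik for WAIC
        double q[4] = {0, 0, 0, 0};
        const double *th = &theta[s * P];
        int n = dat[s].choice.size();
        for (int t = 0; t < n; ++t, ++col) {
          int c = dat[s].choice[t] - 1;
          draw_ll(j, col) = log_softmax_choice(q, th[0], c);
          if (dat[s].win[t] == 1)
            q[c] += th[1] * (win_target(model, th, dat[s].pellets[t]) - q[c]);
          else
            q[c] += th[2] * (loss_target(model, th, dat[s].penalty[t]) - q[c]);
        }
      }
      lp_trace[j] = lp;
    }
  }

  double mean_acc = 0.0;
  for (int b = 0; b < n_blocks; ++b)
    mean_acc += (acc_n[b] > 0 ? acc_sum[b] / acc_n[b] : 0.0) / n_blocks;

  draw_theta.attr("dim") = IntegerVector::create(n_samples, S * P);
  return List::create(_["mu"] = draw_mu, _["sigma"] = draw_sigma,
                      _["group"] = draw_group, _["theta"] = draw_theta,
                      _["loglik"] = draw_ll, _["lp"] = lp_trace,
                      _["accept"] = mean_acc);
}
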