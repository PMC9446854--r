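// Single-site Gibbs samplers for the BayesR model family with annotation
// categories (BayesCpi, BayesR, BayesRC, BayesRCpi, BayesRC+).
//
// All randomness goes through R's RNG (norm_rand / unif_rand / R::r*), so a
// set.seed() call on the R side makes chains bit-reproducible.
//
// Model codes: 0 = BayesCpi, 1 = BayesR, 2 = BayesRC, 3 = BayesRCpi,
//              4 = BayesRC+.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// log marginal likelihood of effect class k (relative to the null class)
// for one SNP: s = x'x, t = x'r_adj where r_adj has the SNP's own
// contribution restored. theta_k = 0 gives 0 by convention.
static inline double cls_loglik(double s, double t, double theta,
                                double se2) {
  if (theta <= 0.0) return 0.0;
  return -0.5 * std::log1p(s * theta / se2) +
         0.5 * t * t * theta / (se2 * (se2 + s * theta));
}

// sample an index from unnormalized log-weights via log-sum-exp
static int sample_logweights(const std::vector<double>& lw) {
  const int K = (int)lw.size();
  double mx = -INFINITY;
  for (int k = 0; k < K; ++k)
    if (lw[k] > mx) mx = lw[k];
  if (!R_FINITE(mx)) stop("all class probabilities underflowed");
  double tot = 0.0;
  std::vector<double> w(K);
  for (int k = 0; k < K; ++k) {
    w[k] = std::isfinite(lw[k]) ? std::exp(lw[k] - mx) : 0.0;
    tot += w[k];
  }
  double u = unif_rand() * tot, cum = 0.0;
  for (int k = 0; k < K; ++k) {
    cum += w[k];
    if (u <= cum) return k;
  }
  return K - 1;
}

static inline double dot_col(const double* x, const double* r, int n) {
  double t = 0.0;
  for (int i = 0; i < n; ++i) t += x[i] * r[i];
  return t;
}

static inline void axpy_col(const double* x, double a, double* r, int n) {
  if (a == 0.0) return;
  for (int i = 0; i < n; ++i) r[i] += a * x[i];
}

// scaled inverse chi-square draw: ss / chisq(df)
static inline double rinvchisq(double df, double ss) {
  return ss / R::rchisq(df);
}

// Dirichlet draw into out (length K), shape alpha + gamma
static void rdirich(const double* alpha, const double* gamma_, int K,
                    double* out) {
  double tot = 0.0;
  for (int k = 0; k < K; ++k) {
    out[k] = R::rgamma(alpha[k] + gamma_[k], 1.0);
    tot += out[k];
  }
  if (tot <= 0.0) {  // numerically degenerate; fall back to uniform
    for (int k = 0; k < K; ++k) out[k] = 1.0 / K;
  } else {
    for (int k = 0; k < K; ++k) out[k] /= tot;
  }
}

// ---------------------------------------------------------------------------
// exported single-update kernels (internal names; used by unit tests and by
// the R-level operation wrappers)
// ---------------------------------------------------------------------------

// [[Rcpp::export(.cls_loglik_cpp)]]
NumericVector cls_loglik_cpp(double s, double t, NumericVector theta,
                             double sigma_e2) {
  if (!R_FINITE(s) || !R_FINITE(t) || sigma_e2 <= 0)
    stop("non-finite input to class likelihood");
  int K = theta.size();
  NumericVector out(K);
  for (int k = 0; k < K; ++k) out[k] = cls_loglik(s, t, theta[k], sigma_e2);
  return out;
}

// repeated class + effect draws on a fixed conditional (Monte-Carlo test
// harness for the in-chain update)
// [[Rcpp::export(.draw_class_effect_cpp)]]
List draw_class_effect_cpp(NumericVector x, NumericVector r_adj,
                           NumericVector pi_c, NumericVector theta,
                           double sigma_e2, int n_draws) {
  int n = x.size(), K = theta.size();
  double s = dot_col(REAL(x), REAL(x), n);
  double t = dot_col(REAL(x), REAL(r_adj), n);
  std::vector<double> lw(K);
  for (int k = 0; k < K; ++k)
    lw[k] = (pi_c[k] > 0 ? std::log(pi_c[k]) : -INFINITY) +
            cls_loglik(s, t, theta[k], sigma_e2);
  IntegerVector cls(n_draws);
  NumericVector eff(n_draws);
  for (int d = 0; d < n_draws; ++d) {
    int k = sample_logweights(lw);
    cls[d] = k + 1;
    if (k == 0 || theta[k] <= 0.0) {
      eff[d] = 0.0;
    } else {
      double denom = sigma_e2 + s * theta[k];
      eff[d] = t * theta[k] / denom +
               norm_rand() * std::sqrt(theta[k] * sigma_e2 / denom);
    }
  }
  return List::create(_["class"] = cls, _["effect"] = eff);
}

// repeated annotation-assignment draws for one multi-annotated SNP
// (BayesRCpi step), on fixed conditionals; pi_mat is |C| x K
// [[Rcpp::export(.draw_annotation_cpp)]]
IntegerVector draw_annotation_cpp(NumericVector x, NumericVector r_adj,
                                  NumericMatrix pi_mat, NumericVector p_i,
                                  NumericVector theta, double sigma_e2,
                                  int n_draws) {
  int n = x.size(), K = theta.size(), C = pi_mat.nrow();
  double s = dot_col(REAL(x), REAL(x), n);
  double t = dot_col(REAL(x), REAL(r_adj), n);
  std::vector<double> l(K);
  for (int k = 0; k < K; ++k) l[k] = cls_loglik(s, t, theta[k], sigma_e2);
  std::vector<double> lw(C);
  for (int c = 0; c < C; ++c) {
    double mx = -INFINITY;
    std::vector<double> v(K);
    for (int k = 0; k < K; ++k) {
      v[k] = (pi_mat(c, k) > 0 ? std::log(pi_mat(c, k)) : -INFINITY) + l[k];
      if (v[k] > mx) mx = v[k];
    }
    double sum = 0.0;
    for (int k = 0; k < K; ++k)
      if (std::isfinite(v[k])) sum += std::exp(v[k] - mx);
    lw[c] = (p_i[c] > 0 ? std::log(p_i[c]) : -INFINITY) + mx + std::log(sum);
  }
  IntegerVector out(n_draws);
  for (int d = 0; d < n_draws; ++d) out[d] = sample_logweights(lw) + 1;
  return out;
}

// ---------------------------------------------------------------------------
// full chain
// ---------------------------------------------------------------------------

// [[Rcpp::export(.gibbs_core)]]
List gibbs_core(NumericMatrix X, NumericVector y, int model, IntegerMatrix A,
                NumericVector kappa, NumericVector alpha, int n_iter,
                int burn_in, int thin, bool permute, bool update_mu,
                bool update_pi, bool update_var, double mu_init,
                double sigma_e2_init, double sigma_g2_init,
                NumericMatrix pi_init, bool store_beta) {
  const int n = X.nrow(), p = X.ncol(), K = kappa.size(), m = A.ncol();
  if ((int)y.size() != n) stop("y length does not match X rows");
  if (A.nrow() != p) stop("annotation rows do not match marker count");

  // per-SNP category sets
  std::vector<std::vector<int> > cats(p);
  int n_slots = 0;
  for (int i = 0; i < p; ++i) {
    for (int c = 0; c < m; ++c)
      if (A(i, c) != 0) cats[i].push_back(c);
    if (cats[i].empty()) stop("marker without any annotation category");
    if (model == 2 && cats[i].size() > 1)
      stop("BayesRC requires disjoint annotations");
    n_slots += (int)cats[i].size();
  }
  // slot offsets for per-(SNP, category) storage (sub-effects, p_i weights)
  std::vector<int> off(p + 1, 0);
  for (int i = 0; i < p; ++i) off[i + 1] = off[i] + (int)cats[i].size();

  std::vector<double> s(p);  // x'x per column
  for (int j = 0; j < p; ++j)
    s[j] = dot_col(&X(0, j), &X(0, j), n);

  // state
  double mu = mu_init, se2 = sigma_e2_init, sg2 = sigma_g2_init;
  std::vector<double> beta(p, 0.0), sub(n_slots, 0.0);
  std::vector<int> cls(p, 0);          // class of beta (models 0-3)
  std::vector<int> sub_cls(n_slots, 0);  // class per sub-effect (model 4)
  std::vector<int> assign(p, 0);       // assigned category slot (model 3)
  std::vector<double> pw(n_slots);     // p_i weights (model 3)
  for (int i = 0; i < p; ++i) {
    int C = (int)cats[i].size();
    for (int c = 0; c < C; ++c) pw[off[i] + c] = 1.0 / C;
  }
  std::vector<double> pi(m * K);  // row-major m x K
  for (int c = 0; c < m; ++c)
    for (int k = 0; k < K; ++k) pi[c * K + k] = pi_init(c, k);
  std::vector<double> theta(K);
  for (int k = 0; k < K; ++k) theta[k] = kappa[k] * sg2;

  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i] - mu;  // beta = 0 at start

  // accumulators
  int n_kept = 0;
  const int n_keep_max =
      (n_iter > burn_in) ? (n_iter - burn_in - 1) / thin + 1 : 0;
  std::vector<double> acc_beta(p, 0.0), acc_beta2(p, 0.0);
  std::vector<double> acc_pi(m * K, 0.0);
  std::vector<double> acc_clsfreq(p * K, 0.0);   // p x K
  std::vector<double> acc_paip(n_slots, 0.0);
  double acc_mu = 0.0, acc_se2 = 0.0, acc_sg2 = 0.0;
  NumericMatrix trace(n_keep_max, 3 + m * K);
  NumericMatrix beta_chain(store_beta ? n_keep_max : 0,
                           store_beta ? p : 0);
  double max_resid_dev = 0.0;

  std::vector<double> gamma_(m * K);
  std::vector<int> order(p);
  for (int j = 0; j < p; ++j) order[j] = j;
  std::vector<double> lw(K), l(K);

  for (int iter = 1; iter <= n_iter; ++iter) {
    if (iter % 2000 == 0) checkUserInterrupt();

    // intercept (flat prior)
    if (update_mu) {
      double mr = 0.0;
      for (int i = 0; i < n; ++i) mr += r[i];
      mr /= n;
      double mu_new = mu + mr + norm_rand() * std::sqrt(se2 / n);
      double d = mu - mu_new;
      for (int i = 0; i < n; ++i) r[i] += d;
      mu = mu_new;
    }

    std::fill(gamma_.begin(), gamma_.end(), 0.0);
    if (permute) {
      // Fisher-Yates with R's RNG
      for (int j = p - 1; j > 0; --j) {
        int k = (int)(unif_rand() * (j + 1));
        if (k > j) k = j;
        std::swap(order[j], order[k]);
      }
    }

    for (int jj = 0; jj < p; ++jj) {
      const int j = order[jj];
      const double* xj = &X(0, j);
      const int C = (int)cats[j].size();

      if (model == 4) {
        // BayesRC+: per-annotation sub-effects in turn; total = sum
        double bsum = 0.0;
        int kmax = 0;
        for (int ci = 0; ci < C; ++ci) {
          const int slot = off[j] + ci, c = cats[j][ci];
          const double bold = sub[slot];
          const double t = dot_col(xj, r.data(), n) + s[j] * bold;
          for (int k = 0; k < K; ++k) {
            double pk = pi[c * K + k];
            lw[k] = (pk > 0 ? std::log(pk) : -INFINITY) +
                    cls_loglik(s[j], t, theta[k], se2);
          }
          int k = sample_logweights(lw);
          double bnew = 0.0;
          if (k > 0 && theta[k] > 0.0) {
            double denom = se2 + s[j] * theta[k];
            bnew = t * theta[k] / denom +
                   norm_rand() * std::sqrt(theta[k] * se2 / denom);
          }
          gamma_[c * K + k] += 1.0;
          sub_cls[slot] = k;
          axpy_col(xj, bold - bnew, r.data(), n);
          sub[slot] = bnew;
          bsum += bnew;
          if (k > kmax) kmax = k;
        }
        beta[j] = bsum;
        cls[j] = kmax;  // summary class: largest class among sub-effects
        continue;
      }

      // models 0-3: one governing category
      const double bold = beta[j];
      const double t = dot_col(xj, r.data(), n) + s[j] * bold;
      int ci = 0;  // index within cats[j]
      if (model == 3 && C > 1) {
        // annotation assignment step (before the class/effect update)
        for (int k = 0; k < K; ++k) l[k] = cls_loglik(s[j], t, theta[k], se2);
        std::vector<double> law(C);
        for (int cc = 0; cc < C; ++cc) {
          const int c = cats[j][cc];
          double mx = -INFINITY;
          std::vector<double> v(K);
          for (int k = 0; k < K; ++k) {
            double pk = pi[c * K + k];
            v[k] = (pk > 0 ? std::log(pk) : -INFINITY) + l[k];
            if (v[k] > mx) mx = v[k];
          }
          double sum = 0.0;
          for (int k = 0; k < K; ++k)
            if (std::isfinite(v[k])) sum += std::exp(v[k] - mx);
          double pic = pw[off[j] + cc];
          law[cc] = (pic > 0 ? std::log(pic) : -INFINITY) + mx + std::log(sum);
        }
        ci = sample_logweights(law);
        assign[j] = ci;
        // refresh p_i ~ Dirichlet(1 + one-hot)
        double tot = 0.0;
        for (int cc = 0; cc < C; ++cc) {
          pw[off[j] + cc] = R::rgamma(1.0 + (cc == ci ? 1.0 : 0.0), 1.0);
          tot += pw[off[j] + cc];
        }
        for (int cc = 0; cc < C; ++cc) pw[off[j] + cc] /= tot;
      } else {
        assign[j] = 0;
      }
      const int c = cats[j][ci];
      for (int k = 0; k < K; ++k) {
        double pk = pi[c * K + k];
        lw[k] = (pk > 0 ? std::log(pk) : -INFINITY) +
                cls_loglik(s[j], t, theta[k], se2);
      }
      int k = sample_logweights(lw);
      double bnew = 0.0;
      if (k > 0 && theta[k] > 0.0) {
        double denom = se2 + s[j] * theta[k];
        bnew = t * theta[k] / denom +
               norm_rand() * std::sqrt(theta[k] * se2 / denom);
      }
      gamma_[c * K + k] += 1.0;
      cls[j] = k;
      axpy_col(xj, bold - bnew, r.data(), n);
      beta[j] = bnew;
    }

    // mixing proportions per category
    if (update_pi) {
      for (int c = 0; c < m; ++c)
        rdirich(REAL(alpha), &gamma_[c * K], K, &pi[c * K]);
    }

    // variance components (flat scaled-inv-chisq hyper-priors nu0=-2, s0=0)
    if (update_var) {
      double sse = dot_col(r.data(), r.data(), n);
      se2 = rinvchisq((double)n - 2.0, sse);
      double ssb = 0.0;
      int q = 0;
      if (model == 4) {
        for (int sl = 0; sl < n_slots; ++sl)
          if (sub_cls[sl] > 0) {
            ssb += sub[sl] * sub[sl] / kappa[sub_cls[sl]];
            ++q;
          }
      } else {
        for (int j = 0; j < p; ++j)
          if (cls[j] > 0) {
            ssb += beta[j] * beta[j] / kappa[cls[j]];
            ++q;
          }
      }
      if (q > 2) sg2 = rinvchisq((double)q - 2.0, ssb);
      // q <= 2: conditional is improper under the flat hyper-prior; retain
      for (int k = 0; k < K; ++k) theta[k] = kappa[k] * sg2;
    }

    // periodic residual refresh against drift (check first, then rebuild)
    if (iter % 500 == 0 || iter == n_iter) {
      for (int i = 0; i < n; ++i) {
        double ri = y[i] - mu;
        for (int j = 0; j < p; ++j) ri -= X(i, j) * beta[j];
        double dev = std::fabs(ri - r[i]);
        if (dev > max_resid_dev) max_resid_dev = dev;
        r[i] = ri;
      }
    }

    if (!R_FINITE(se2) || !R_FINITE(sg2))
      stop("divergent variance component at iteration %d", iter);

    // keep?
    if (iter > burn_in && (iter - burn_in - 1) % thin == 0) {
      for (int j = 0; j < p; ++j) {
        acc_beta[j] += beta[j];
        acc_beta2[j] += beta[j] * beta[j];
        acc_clsfreq[j * K + cls[j]] += 1.0;
        acc_paip[off[j] + assign[j]] += 1.0;
      }
      for (int c = 0; c < m * K; ++c) acc_pi[c] += pi[c];
      acc_mu += mu;
      acc_se2 += se2;
      acc_sg2 += sg2;
      trace(n_kept, 0) = mu;
      trace(n_kept, 1) = se2;
      trace(n_kept, 2) = sg2;
      for (int c = 0; c < m * K; ++c) trace(n_kept, 3 + c) = pi[c];
      if (store_beta)
        for (int j = 0; j < p; ++j) beta_chain(n_kept, j) = beta[j];
      ++n_kept;
    }
  }

  if (n_kept == 0) stop("no kept samples (check n_iter/burn_in/thin)");

  NumericVector beta_hat(p), beta_sq_hat(p);
  NumericMatrix class_freq(p, K), paip(p, m), pi_hat(m, K);
  for (int j = 0; j < p; ++j) {
    beta_hat[j] = acc_beta[j] / n_kept;
    beta_sq_hat[j] = acc_beta2[j] / n_kept;
    for (int k = 0; k < K; ++k)
      class_freq(j, k) = acc_clsfreq[j * K + k] / n_kept;
    if (model == 3) {
      for (int ci = 0; ci < (int)cats[j].size(); ++ci)
        paip(j, cats[j][ci]) = acc_paip[off[j] + ci] / n_kept;
    } else if (model == 4) {
      // cumulative model: uniform membership placeholder (not chain-derived)
      for (int ci = 0; ci < (int)cats[j].size(); ++ci)
        paip(j, cats[j][ci]) = 1.0 / cats[j].size();
    } else {
      paip(j, cats[j][0]) = 1.0;
    }
  }
  for (int c = 0; c < m; ++c)
    for (int k = 0; k < K; ++k) pi_hat(c, k) = acc_pi[c * K + k] / n_kept;

  return List::create(
      _["beta_hat"] = beta_hat, _["beta_sq_hat"] = beta_sq_hat,
      _["class_freq"] = class_freq, _["paip"] = paip, _["pi_hat"] = pi_hat,
      _["mu_hat"] = acc_mu / n_kept, _["sigma_e2_hat"] = acc_se2 / n_kept,
      _["sigma_g2_hat"] = acc_sg2 / n_kept, _["n_kept"] = n_kept,
      _["trace"] = trace, _["beta_chain"] = beta_chain,
      _["max_residual_dev"] = max_resid_dev);
}
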