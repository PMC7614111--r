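// Adaptive random-walk Metropolis sampler for the geographically-powered
// posterior. One call runs one chain for one centre.
//
// The target factorizes over locations: prior(phi) + prior(log theta_k) +
// sum_k w_k * loglik_k(theta_k, phi). Location 0 is the centre (w_0 = 1,
// theta_0 = the centre's nuisance parameter); locations 1..K-1 are active
// neighbours carrying auxiliary nuisance copies. The negative binomial
// log-likelihood is decomposed so that terms constant in phi are cached
// across the phi block (lgamma terms cancel in its Metropolis ratio) and
// terms constant in theta are cached across the scalar blocks:
//   log p(y | mu, r) = lgamma(y+r) - lgamma(r) - lgamma(y+1)
//                      + r log r - (r+y) log(r+mu) + y log mu,  r = 1/theta.
// Nuisance parameters are sampled on the log scale; the prior is placed
// directly on log theta as N(log_theta_mean, log_theta_sd^2), equivalent to
// a lognormal prior on theta with the Jacobian absorbed.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

const double HALF_LOG_2PI = 0.9189385332046727;

struct Packed {
  int family;                 // 0 = negative binomial, 1 = gaussian
  int p, K, nrows;
  const double *y, *off, *w;
  const int *start, *len;     // rows of location k: start[k] .. start[k]+len[k)-1
  const double *X;            // nrows x p, column-major
};

inline double dot_row(const Packed &pk, int row, const std::vector<double> &phi) {
  double s = 0.0;
  for (int j = 0; j < pk.p; ++j) s += pk.X[row + j * pk.nrows] * phi[j];
  return s;
}

// theta-only part of the weighted NB loglik for location k
double nb_A(const Packed &pk, int k, double r) {
  const int s = pk.start[k], m = pk.len[k];
  double a = 0.0;
  for (int i = s; i < s + m; ++i) a += lgamma(pk.y[i] + r);
  return a - m * lgamma(r) + m * r * std::log(r);
}

// cross part -(r+y) log(r+mu); needs current mu
double nb_B(const Packed &pk, int k, double r, const std::vector<double> &mu) {
  const int s = pk.start[k], m = pk.len[k];
  double b = 0.0;
  for (int i = s; i < s + m; ++i) b -= (r + pk.y[i]) * std::log(r + mu[i]);
  return b;
}

// Cholesky of a small SPD matrix (row-major p x p); returns false on failure
bool chol_lower(int p, const std::vector<double> &A, std::vector<double> &L) {
  L.assign(p * p, 0.0);
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * p + j];
      for (int k = 0; k < j; ++k) s -= L[i * p + k] * L[j * p + k];
      if (i == j) {
        if (s <= 0.0) return false;
        L[i * p + i] = std::sqrt(s);
      } else {
        L[i * p + j] = s / L[j * p + j];
      }
    }
  }
  return true;
}

}  // namespace

// Full unnormalized log powered posterior, all constants included.
// [[Rcpp::export]]
double cpp_log_target(int family, NumericVector y, NumericMatrix X,
                      NumericVector offset, IntegerVector loc_start,
                      IntegerVector loc_len, NumericVector w,
                      double phi_sd, double ltheta_mean, double ltheta_sd,
                      NumericVector phi, NumericVector ltheta) {
  Packed pk{family, (int)X.ncol(), (int)w.size(), (int)X.nrow(),
            y.begin(), offset.begin(), w.begin(),
            loc_start.begin(), loc_len.begin(), X.begin()};
  std::vector<double> ph(phi.begin(), phi.end());
  double lp = 0.0;
  for (int j = 0; j < pk.p; ++j)
    lp += -HALF_LOG_2PI - std::log(phi_sd) - 0.5 * ph[j] * ph[j] / (phi_sd * phi_sd);
  for (int k = 0; k < pk.K; ++k) {
    double z = (ltheta[k] - ltheta_mean) / ltheta_sd;
    lp += -HALF_LOG_2PI - std::log(ltheta_sd) - 0.5 * z * z - ltheta[k];
    // -ltheta[k]: Jacobian making this the lognormal density of theta
  }
  for (int k = 0; k < pk.K; ++k) {
    const int s = pk.start[k], m = pk.len[k];
    double ll = 0.0;
    if (family == 0) {
      double r = std::exp(-ltheta[k]);
      ll = nb_A(pk, k, r);
      for (int i = s; i < s + m; ++i) {
        double lmu = dot_row(pk, i, ph) + pk.off[i];
        double mu = std::exp(lmu);
        ll += -(r + pk.y[i]) * std::log(r + mu) + pk.y[i] * lmu
              - lgamma(pk.y[i] + 1.0);
      }
    } else {
      double th = std::exp(ltheta[k]);
      for (int i = s; i < s + m; ++i) {
        double mu = dot_row(pk, i, ph) + pk.off[i];
        double e = pk.y[i] - mu;
        ll += -HALF_LOG_2PI - ltheta[k] - 0.5 * e * e / (th * th);
      }
    }
    lp += pk.w[k] * ll;
  }
  return lp;
}

// [[Rcpp::export]]
List cpp_run_chain(int family, NumericVector y, NumericMatrix X,
                   NumericVector offset, IntegerVector loc_start,
                   IntegerVector loc_len, NumericVector w,
                   double phi_sd, double ltheta_mean, double ltheta_sd,
                   NumericVector phi_init, NumericVector ltheta_init,
                   int n_iter, int burn_in, bool fix_theta,
                   double target_block, double target_scalar,
                   bool adapt, bool keep_aux) {
  Packed pk{family, (int)X.ncol(), (int)w.size(), (int)X.nrow(),
            y.begin(), offset.begin(), w.begin(),
            loc_start.begin(), loc_len.begin(), X.begin()};
  const int p = pk.p, K = pk.K, n = pk.nrows;
  const int kept = n_iter - burn_in;

  std::vector<double> phi(phi_init.begin(), phi_init.end());
  std::vector<double> lt(ltheta_init.begin(), ltheta_init.end());
  std::vector<double> r(K), th(K);
  for (int k = 0; k < K; ++k) { th[k] = std::exp(lt[k]); r[k] = std::exp(-lt[k]); }

  // caches
  std::vector<double> mu(n), lmu(n);           // NB: mu, log mu; gaussian: mu only
  std::vector<double> A(K, 0.0), B(K, 0.0), E(K, 0.0), SSE(K, 0.0);
  std::vector<double> mu_new(n), lmu_new(n), Bn(K), En(K), SSEn(K);

  auto refresh_phi_cache = [&](const std::vector<double> &ph,
                               std::vector<double> &mu_, std::vector<double> &lmu_,
                               std::vector<double> &B_, std::vector<double> &E_,
                               std::vector<double> &SSE_) {
    for (int k = 0; k < K; ++k) {
      const int s = pk.start[k], m = pk.len[k];
      if (family == 0) {
        double b = 0.0, e = 0.0, rk = r[k];
        for (int i = s; i < s + m; ++i) {
          double lm = dot_row(pk, i, ph) + pk.off[i];
          double mm = std::exp(lm);
          lmu_[i] = lm; mu_[i] = mm;
          b -= (rk + pk.y[i]) * std::log(rk + mm);
          e += pk.y[i] * lm;
        }
        B_[k] = b; E_[k] = e;
      } else {
        double ss = 0.0;
        for (int i = s; i < s + m; ++i) {
          double mm = dot_row(pk, i, ph) + pk.off[i];
          mu_[i] = mm;
          double d = pk.y[i] - mm;
          ss += d * d;
        }
        SSE_[k] = ss;
      }
    }
  };

  refresh_phi_cache(phi, mu, lmu, B, E, SSE);
  if (family == 0) for (int k = 0; k < K; ++k) A[k] = nb_A(pk, k, r[k]);

  // full target value (constants included) for diagnostics
  double lp_cur = cpp_log_target(family, y, X, offset, loc_start, loc_len, w,
                                 phi_sd, ltheta_mean, ltheta_sd,
                                 NumericVector(phi.begin(), phi.end()),
                                 NumericVector(lt.begin(), lt.end()));
  if (!std::isfinite(lp_cur)) {
    stop("initialization error: log powered posterior is not finite at the initial state");
  }

  // phi proposal: lambda^2 * Sigma_hat, Sigma_hat = sd0^2 I before warm-up,
  // then (2.38^2/p) * (empirical covariance + eps I); lambda Robbins-Monro
  // adapted toward target_block during burn-in only.
  const int warm = std::min(100, burn_in / 2 > 1 ? burn_in / 2 : 1);
  double log_lambda = 0.0;
  const double sd0 = 0.05;
  std::vector<double> Sig(p * p, 0.0), L(p * p, 0.0);
  for (int j = 0; j < p; ++j) Sig[j * p + j] = sd0 * sd0;
  std::vector<double> cmean(p, 0.0), M2(p * p, 0.0);
  long cn = 0;
  auto rebuild_L = [&]() {
    std::vector<double> P(p * p);
    double scale = std::exp(2.0 * log_lambda);
    for (int i = 0; i < p * p; ++i) P[i] = scale * Sig[i];
    if (!chol_lower(p, P, L)) {
      L.assign(p * p, 0.0);
      for (int j = 0; j < p; ++j)
        L[j * p + j] = std::exp(log_lambda) * std::sqrt(std::max(Sig[j * p + j], 1e-20));
    }
  };
  rebuild_L();

  std::vector<double> ls(K, std::log(0.2));    // scalar proposal log-sds
  std::vector<double> z(p), phi_new(p);

  long acc_phi = 0, n_phi = 0;
  std::vector<long> acc_th(K, 0);
  long n_th = 0;

  NumericMatrix draws(kept, 1 + p);
  NumericMatrix aux(keep_aux ? kept : 0, keep_aux ? (K > 1 ? K - 1 : 0) : 0);
  NumericVector lp_trace(kept);

  const double inv2ps = 0.5 / (phi_sd * phi_sd);
  const double inv2ls = 0.5 / (ltheta_sd * ltheta_sd);

  for (int t = 1; t <= n_iter; ++t) {
    const bool adapting = adapt && t <= burn_in;
    const double gam = adapting ? std::pow((double)t, -0.6) : 0.0;

    // ---- phi block -------------------------------------------------------
    for (int j = 0; j < p; ++j) z[j] = norm_rand();
    for (int i = 0; i < p; ++i) {
      double s = 0.0;
      for (int j = 0; j <= i; ++j) s += L[i * p + j] * z[j];
      phi_new[i] = phi[i] + s;
    }
    double delta = 0.0;
    for (int j = 0; j < p; ++j)
      delta += inv2ps * (phi[j] * phi[j] - phi_new[j] * phi_new[j]);
    refresh_phi_cache(phi_new, mu_new, lmu_new, Bn, En, SSEn);
    if (family == 0) {
      for (int k = 0; k < K; ++k)
        delta += pk.w[k] * (Bn[k] + En[k] - B[k] - E[k]);
    } else {
      for (int k = 0; k < K; ++k)
        delta += pk.w[k] * (SSE[k] - SSEn[k]) * 0.5 / (th[k] * th[k]);
    }
    double alpha = delta >= 0.0 ? 1.0 : std::exp(delta);
    if (unif_rand() < alpha) {
      phi.swap(phi_new);
      mu.swap(mu_new); lmu.swap(lmu_new);
      B.swap(Bn); E.swap(En); SSE.swap(SSEn);
      lp_cur += delta;
      if (t > burn_in) ++acc_phi;
    }
    if (t > burn_in) ++n_phi;
    if (adapting) {
      log_lambda += gam * (alpha - target_block);
      // running mean / covariance of the chain states
      ++cn;
      for (int i = 0; i < p; ++i) {
        double d = phi[i] - cmean[i];
        cmean[i] += d / cn;
        for (int j = 0; j <= i; ++j) {
          double upd = d * (phi[j] - cmean[j]);
          M2[i * p + j] += upd;
          if (i != j) M2[j * p + i] += upd;
        }
      }
      if (t >= warm && cn > 2 * p) {
        double sc = 5.6644 / p;  // 2.38^2 / p
        double tr = 0.0;
        for (int j = 0; j < p; ++j) tr += M2[j * p + j] / (cn - 1);
        double eps = std::max(1e-12, 1e-6 * tr / p);
        for (int i = 0; i < p; ++i)
          for (int j = 0; j < p; ++j)
            Sig[i * p + j] = sc * (M2[i * p + j] / (cn - 1) + (i == j ? eps : 0.0));
      }
      rebuild_L();
    }

    // ---- nuisance scalars (centre + auxiliary copies) --------------------
    if (!fix_theta) {
      for (int k = 0; k < K; ++k) {
        double lt_new = lt[k] + std::exp(ls[k]) * norm_rand();
        double dl = 0.0;
        double An = 0.0, Bn1 = 0.0, SSn = 0.0;
        if (family == 0) {
          double rn = std::exp(-lt_new);
          An = nb_A(pk, k, rn);
          Bn1 = nb_B(pk, k, rn, mu);
          dl = pk.w[k] * (An + Bn1 - A[k] - B[k]);
        } else {
          double thn = std::exp(lt_new);
          double m = (double)pk.len[k];
          dl = pk.w[k] * (-m * (lt_new - lt[k])
                          - SSE[k] * (0.5 / (thn * thn) - 0.5 / (th[k] * th[k])));
        }
        double zo = lt[k] - ltheta_mean, zn = lt_new - ltheta_mean;
        dl += inv2ls * (zo * zo - zn * zn) + (lt[k] - lt_new);  // prior + Jacobian
        double al = dl >= 0.0 ? 1.0 : std::exp(dl);
        if (unif_rand() < al) {
          lt[k] = lt_new;
          th[k] = std::exp(lt_new);
          if (family == 0) { r[k] = std::exp(-lt_new); A[k] = An; B[k] = Bn1; }
          lp_cur += dl;
          if (t > burn_in) ++acc_th[k];
        }
        if (adapting) ls[k] += gam * (al - target_scalar);
      }
      if (t > burn_in) ++n_th;
    }

    // ---- record ----------------------------------------------------------
    if (t > burn_in) {
      int row = t - burn_in - 1;
      draws(row, 0) = th[0];
      for (int j = 0; j < p; ++j) draws(row, 1 + j) = phi[j];
      if (keep_aux) for (int k = 1; k < K; ++k) aux(row, k - 1) = th[k];
      lp_trace[row] = lp_cur;
    }
  }

  NumericVector th_rates(K);
  for (int k = 0; k < K; ++k)
    th_rates[k] = n_th > 0 ? (double)acc_th[k] / n_th : NA_REAL;
  return List::create(
      _["draws"] = draws,
      _["aux"] = aux,
      _["lp"] = lp_trace,
      _["accept_phi"] = n_phi > 0 ? (double)acc_phi / n_phi : NA_REAL,
      _["accept_theta"] = th_rates);
}
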