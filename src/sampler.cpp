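#include <Rcpp.h>
using namespace Rcpp;

// Adaptive random-walk Metropolis-within-Gibbs for the integrated model.
//
// Parameter vector: beta (p entries), delta0, delta1, alpha.
// Log-posterior components:
//   PO (thinned PPP):  sum_i n_i (eta_i + log b_i)  -  sum_k lam_k b_k A_k
//   PA (occupancy, latent state marginalized per surveyed cell)
//   priors: Normal(0, beta_sd) on beta, standard Logistic on delta, alpha
//
// The chain maintains eta = X beta, lam = exp(eta), b and log b as state,
// plus the cached scalars each parameter's update needs, so a proposal
// costs one fused pass over the cells (beta, delta) or only the surveyed
// cells (alpha).

static inline double log_plogis(double u) {
  // log(1/(1+exp(-u))) without overflow
  return u < 0.0 ? u - std::log1p(std::exp(u)) : -std::log1p(std::exp(-u));
}

static inline double logistic_logdens(double x) {
  return -x - 2.0 * std::log1p(std::exp(-x));
}

// Occupancy likelihood of the surveyed cells for a given linear predictor.
static double pa_loglik_eta(const NumericVector& eta,
                            const NumericVector& area,
                            const IntegerVector& pa_cell,
                            const NumericVector& pa_d,
                            const NumericVector& pa_w,
                            const NumericVector& pa_xshift, double diff,
                            double alpha) {
  const int m = pa_cell.size();
  if (m == 0) return 0.0;
  const double logp = log_plogis(alpha);
  const double log1mp = log_plogis(-alpha);
  double s = 0.0;
  for (int j = 0; j < m; ++j) {
    const int k = pa_cell[j];
    const double mu = std::exp(eta[k] + diff * pa_xshift[j]) * area[k];
    const double psi = -std::expm1(-mu);
    if (pa_d[j] > 0.0) {
      if (psi <= 0.0) return R_NegInf;
      s += std::log(psi) + pa_d[j] * logp + (pa_w[j] - pa_d[j]) * log1mp;
    } else {
      s += std::log(std::exp(-mu) + psi * std::exp(pa_w[j] * log1mp));
    }
  }
  return s;
}

// [[Rcpp::export]]
List run_chain_cpp(NumericMatrix X, NumericVector area, NumericVector bias,
                   IntegerVector po_idx, NumericVector po_n, bool include_po,
                   IntegerVector pa_cell, NumericVector pa_d,
                   NumericVector pa_w, NumericVector init,
                   int n_adapt, int n_burn, int n_sample, int thin,
                   double target_acc, double beta_prior_sd) {
  const int n = X.nrow();
  const int p = X.ncol();
  const int npar = p + 3;
  const int npo = po_idx.size();
  const int m = pa_cell.size();
  if (init.size() != npar) stop("init length mismatch");

  NumericVector theta = clone(init);
  NumericVector eta(n), lam(n), b(n);
  NumericVector lam_prop(n), b_prop(n);
  NumericVector logb_po(npo), logb_po_prop(npo);
  NumericVector zero_shift(m);

  for (int k = 0; k < n; ++k) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(k, j) * theta[j];
    eta[k] = e;
    lam[k] = std::exp(e);
    const double u = theta[p] + theta[p + 1] * bias[k];
    b[k] = 1.0 / (1.0 + std::exp(-u));
  }
  for (int i = 0; i < npo; ++i)
    logb_po[i] = log_plogis(theta[p] + theta[p + 1] * bias[po_idx[i]]);

  // cached scalars of the current state
  double po_void = 0.0, po_point = 0.0;
  if (include_po) {
    for (int k = 0; k < n; ++k) po_void += lam[k] * b[k] * area[k];
    for (int i = 0; i < npo; ++i)
      po_point += po_n[i] * (eta[po_idx[i]] + logb_po[i]);
  }
  double pa_ll = pa_loglik_eta(eta, area, pa_cell, pa_d, pa_w, zero_shift,
                               0.0, theta[npar - 1]);
  if (!std::isfinite(po_void) || !std::isfinite(po_point) ||
      !std::isfinite(pa_ll))
    stop("non-finite log-posterior at initialization");

  NumericVector lstep(npar, std::log(0.2));
  IntegerVector acc_count(npar);
  int post_burn_iters = 0;

  const int n_keep = n_sample / thin;
  NumericMatrix draws(n_keep, npar);
  int keep_row = 0;

  NumericVector pa_xshift(m);

  const int total = n_adapt + n_burn + n_sample;
  for (int t = 1; t <= total; ++t) {
    for (int j = 0; j < npar; ++j) {
      const double step = std::exp(lstep[j]);
      const double cur = theta[j];
      const double prop = cur + step * R::norm_rand();
      bool accepted = false;
      if (j < p) {
        // intensity coefficient: one fused pass over cells
        const double diff = prop - cur;
        const double* xj = &X(0, j);
        double void_new = 0.0;
        if (include_po) {
          for (int k = 0; k < n; ++k) {
            lam_prop[k] = std::exp(eta[k] + diff * xj[k]);
            void_new += lam_prop[k] * b[k] * area[k];
          }
        } else {
          for (int k = 0; k < n; ++k)
            lam_prop[k] = std::exp(eta[k] + diff * xj[k]);
        }
        double point_new = 0.0;
        for (int i = 0; i < npo; ++i) {
          const int k = po_idx[i];
          point_new += po_n[i] * (eta[k] + diff * xj[k] + logb_po[i]);
        }
        for (int jj = 0; jj < m; ++jj) pa_xshift[jj] = X(pa_cell[jj], j);
        const double pa_new = pa_loglik_eta(eta, area, pa_cell, pa_d, pa_w,
                                            pa_xshift, diff, theta[npar - 1]);
        const double dprior = -0.5 * (prop * prop - cur * cur) /
          (beta_prior_sd * beta_prior_sd);
        const double dlp = (point_new - po_point) - (void_new - po_void) +
          (pa_new - pa_ll) + dprior;
        if (std::isfinite(dlp) && std::log(R::unif_rand()) < dlp) {
          theta[j] = prop;
          for (int k = 0; k < n; ++k) eta[k] += diff * xj[k];
          std::swap(lam, lam_prop);
          po_void = void_new; po_point = point_new; pa_ll = pa_new;
          accepted = true;
        }
      } else if (j < p + 2) {
        // thinning parameter: PO component only
        const double d0 = (j == p) ? prop : theta[p];
        const double d1 = (j == p + 1) ? prop : theta[p + 1];
        double void_new = 0.0;
        for (int k = 0; k < n; ++k) {
          const double u = d0 + d1 * bias[k];
          b_prop[k] = 1.0 / (1.0 + std::exp(-u));
          void_new += lam[k] * b_prop[k] * area[k];
        }
        double point_new = 0.0;
        for (int i = 0; i < npo; ++i) {
          const int k = po_idx[i];
          logb_po_prop[i] = log_plogis(d0 + d1 * bias[k]);
          point_new += po_n[i] * (eta[k] + logb_po_prop[i]);
        }
        const double dprior = logistic_logdens(prop) - logistic_logdens(cur);
        const double dlp = include_po
          ? (point_new - po_point) - (void_new - po_void) + dprior
          : dprior;
        if (std::isfinite(dlp) && std::log(R::unif_rand()) < dlp) {
          theta[j] = prop;
          std::swap(b, b_prop);
          std::swap(logb_po, logb_po_prop);
          if (include_po) { po_void = void_new; po_point = point_new; }
          accepted = true;
        }
      } else {
        // detection intercept: PA component only
        const double pa_new = pa_loglik_eta(eta, area, pa_cell, pa_d, pa_w,
                                            zero_shift, 0.0, prop);
        const double dprior = logistic_logdens(prop) - logistic_logdens(cur);
        const double dlp = (pa_new - pa_ll) + dprior;
        if (std::isfinite(dlp) && std::log(R::unif_rand()) < dlp) {
          theta[j] = prop;
          pa_ll = pa_new;
          accepted = true;
        }
      }
      if (t <= n_adapt) {
        // Robbins-Monro drift of the log step toward the target acceptance
        const double gamma = std::min(0.25, 2.0 / std::sqrt((double) t));
        lstep[j] += gamma * ((accepted ? 1.0 : 0.0) - target_acc);
      } else if (t > n_adapt + n_burn && accepted) {
        acc_count[j]++;
      }
    }
    if (t > n_adapt + n_burn) {
      post_burn_iters++;
      if ((t - n_adapt - n_burn) % thin == 0 && keep_row < n_keep) {
        for (int j = 0; j < npar; ++j) draws(keep_row, j) = theta[j];
        keep_row++;
      }
    }
    if (t % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector acc_rate(npar);
  for (int j = 0; j < npar; ++j)
    acc_rate[j] = post_burn_iters > 0
      ? (double) acc_count[j] / post_burn_iters : NA_REAL;

  return List::create(_["draws"] = draws, _["acceptance"] = acc_rate,
                      _["step"] = exp(lstep));
}
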