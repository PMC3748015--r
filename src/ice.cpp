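// Iterative conditional expectation (ICE) estimation of marker effects under
// a point-mass/Laplace mixture prior, with optional pairwise epistatic
// sources streamed from the main-effect design columns (interaction columns
// are never materialised genome-wide).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

// Mean of N(mu, s2) truncated to (0, Inf) ["upper" part] or (-Inf, 0).
inline double trunc_mean_upper(double mu, double sd) {
  double z = mu / sd;
  return mu + sd * std::exp(R::dnorm(z, 0.0, 1.0, 1) - R::pnorm(z, 0.0, 1.0, 1, 1));
}
inline double trunc_mean_lower(double mu, double sd) {
  double z = mu / sd;
  return mu - sd * std::exp(R::dnorm(z, 0.0, 1.0, 1) - R::pnorm(-z, 0.0, 1.0, 1, 1));
}

// Posterior mean of a single effect g with prior
//   g = 0 with probability 1 - gamma,  g ~ Laplace(rate lambda) otherwise,
// given the univariate Gaussian summary Y ~ N(g, s2). All three mixture
// terms are evaluated in the log domain so exp(lambda*|Y|) cannot overflow.
inline double posterior_mean_one(double Y, double s2, double lambda,
                                 double gamma) {
  double sd = std::sqrt(s2);
  double Ym = Y - lambda * s2;
  double Yp = Y + lambda * s2;
  double lT1 = -lambda * Y + R::pnorm(Ym / sd, 0.0, 1.0, 1, 1);
  double lT2 = lambda * Y + R::pnorm(-Yp / sd, 0.0, 1.0, 1, 1);
  double lT3;
  if (gamma >= 1.0) {
    lT3 = R_NegInf;  // no point mass
  } else {
    lT3 = std::log(2.0 * (1.0 - gamma) / (gamma * lambda)) -
          0.5 * lambda * lambda * s2 + R::dnorm(Y, 0.0, sd, 1);
  }
  double M = std::max(lT1, std::max(lT2, lT3));
  double w1 = std::exp(lT1 - M);
  double w2 = std::exp(lT2 - M);
  double w3 = std::exp(lT3 - M);
  double num = w1 * trunc_mean_upper(Ym, sd) + w2 * trunc_mean_lower(Yp, sd);
  return num / (w1 + w2 + w3);
}

struct EpiSource {
  const double* P;  // first parent block (column-major, n x m)
  const double* Q;  // second parent block
  const int* inertP;
  const int* inertQ;
  double* g;        // estimates, length m(m-1)/2, upper-triangle row-major
  double gamma;
  double lambda;
};

} // namespace

// [[Rcpp::export]]
NumericVector cpp_posterior_mean(NumericVector Y, NumericVector sigma2,
                                 double lambda, double gamma) {
  const int n = Y.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = posterior_mean_one(Y[i], sigma2[i % sigma2.size()], lambda, gamma);
  return out;
}

// [[Rcpp::export]]
List cpp_ice_fit(NumericVector y, NumericMatrix Xa, NumericMatrix Xd,
                 int model, NumericVector gamma, NumericVector lambda,
                 double L, int kmax, IntegerVector inertA, IntegerVector inertD,
                 Nullable<NumericMatrix> W_, Nullable<NumericMatrix> Winv_,
                 int check_every) {
  const int n = y.size();
  const int m = Xa.ncol();
  const R_xlen_t mm = (R_xlen_t) m * (m - 1) / 2;

  std::vector<double> r(y.begin(), y.end());
  std::vector<double> ga(m, 0.0), gd(m, 0.0);
  std::vector<double> gaa, gad, gda, gdd;
  if (model == 2) {
    gaa.assign(mm, 0.0);
    gad.assign(mm, 0.0);
    gda.assign(mm, 0.0);
    gdd.assign(mm, 0.0);
  }
  // X'X of the main columns
  std::vector<double> xtxA(m, 0.0), xtxD(m, 0.0);
  for (int j = 0; j < m; ++j) {
    const double* x = &Xa(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += x[i] * x[i];
    xtxA[j] = s;
    const double* xd = &Xd(0, j);
    s = 0.0;
    for (int i = 0; i < n; ++i) s += xd[i] * xd[i];
    xtxD[j] = s;
  }
  double sigma2 = 0.0;  // initial residual variance = Var(y)
  {
    double mu = 0.0;
    for (int i = 0; i < n; ++i) mu += y[i];
    mu /= n;
    for (int i = 0; i < n; ++i) sigma2 += (y[i] - mu) * (y[i] - mu);
    sigma2 /= (n - 1);
  }
  if (sigma2 <= 0) stop("phenotypes have zero variance");

  bool has_cov = W_.isNotNull();
  NumericMatrix W, Winv;
  int q = 0;
  if (has_cov) {
    W = NumericMatrix(W_);
    Winv = NumericMatrix(Winv_);
    q = W.ncol();
  }

  std::vector<EpiSource> epi;
  if (model == 2) {
    epi.push_back({&Xa(0, 0), &Xa(0, 0), inertA.begin(), inertA.begin(),
                   gaa.data(), gamma[2], lambda[2]});
    epi.push_back({&Xa(0, 0), &Xd(0, 0), inertA.begin(), inertD.begin(),
                   gad.data(), gamma[3], lambda[3]});
    epi.push_back({&Xd(0, 0), &Xa(0, 0), inertD.begin(), inertA.begin(),
                   gda.data(), gamma[4], lambda[4]});
    epi.push_back({&Xd(0, 0), &Xd(0, 0), inertD.begin(), inertD.begin(),
                   gdd.data(), gamma[5], lambda[5]});
  }

  std::vector<double> crit_trace, sigma_trace;
  bool converged = false;
  int iter = 0;
  double resid_check = 0.0;
  std::vector<double> colbuf(n);

  for (int k = 1; k <= kmax; ++k) {
    iter = k;
    if (has_cov) {
      // least-squares covariate correction refreshed each outer iteration:
      // r <- r - W (W'W)^{-1} W' r,  Winv = W (W'W)^{-1}
      std::vector<double> theta(q, 0.0);
      for (int c = 0; c < q; ++c) {
        const double* wc = &Winv(0, c);
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += wc[i] * r[i];
        theta[c] = s;
      }
      for (int c = 0; c < q; ++c) {
        const double* wc = &W(0, c);
        for (int i = 0; i < n; ++i) r[i] -= wc[i] * theta[c];
      }
    }
    double diffsq = 0.0, normsq = 0.0;

    // main sources, processed a then d
    for (int src = 0; src < ((model >= 1) ? 2 : 1); ++src) {
      const bool is_a = (src == 0);
      NumericMatrix& X = is_a ? Xa : Xd;
      const std::vector<double>& xtx = is_a ? xtxA : xtxD;
      const IntegerVector& inert = is_a ? inertA : inertD;
      std::vector<double>& g = is_a ? ga : gd;
      const double gam = gamma[src], lam = lambda[src];
      for (int j = 0; j < m; ++j) {
        if (inert[j]) continue;
        const double* x = &X(0, j);
        double xr = 0.0;
        for (int i = 0; i < n; ++i) xr += x[i] * r[i];
        double Y = xr / xtx[j] + g[j];
        double s2 = sigma2 / xtx[j];
        double gn = posterior_mean_one(Y, s2, lam, gam);
        double dlt = gn - g[j];
        if (dlt != 0.0) {
          for (int i = 0; i < n; ++i) r[i] -= x[i] * dlt;
        }
        diffsq += dlt * dlt;
        normsq += gn * gn;
        g[j] = gn;
      }
    }

    // epistatic sources in the order aa, ad, da, dd
    for (const EpiSource& es : epi) {
      R_xlen_t idx = 0;
      for (int j = 0; j < m - 1; ++j) {
        const double* pj = es.P + (R_xlen_t) n * j;
        bool ij = es.inertP[j];
        for (int k2 = j + 1; k2 < m; ++k2, ++idx) {
          if (ij || es.inertQ[k2]) continue;
          const double* qk = es.Q + (R_xlen_t) n * k2;
          double xtx = 0.0, xr = 0.0;
          for (int i = 0; i < n; ++i) {
            double c = pj[i] * qk[i];
            colbuf[i] = c;
            xtx += c * c;
            xr += c * r[i];
          }
          if (xtx <= 1e-12) continue;
          double g0 = es.g[idx];
          double Y = xr / xtx + g0;
          double gn = posterior_mean_one(Y, sigma2 / xtx, es.lambda, es.gamma);
          double dlt = gn - g0;
          if (dlt != 0.0) {
            for (int i = 0; i < n; ++i) r[i] -= colbuf[i] * dlt;
          }
          diffsq += dlt * dlt;
          normsq += gn * gn;
          es.g[idx] = gn;
        }
        Rcpp::checkUserInterrupt();
      }
    }

    // residual variance update, once per outer iteration over all sources
    double rss = 0.0;
    for (int i = 0; i < n; ++i) rss += r[i] * r[i];
    sigma2 = rss / (n - 1);
    if (!std::isfinite(sigma2) || sigma2 <= 0.0)
      stop("residual variance diverged (sigma_e^2 = %g at iteration %d)",
           sigma2, k);
    sigma_trace.push_back(sigma2);

    // criterion: ratio of Euclidean norms ||g(k) - g(k-1)|| / ||g(k)||
    double crit;
    if (normsq > 0.0) crit = std::sqrt(diffsq / normsq);
    else crit = (diffsq == 0.0) ? 0.0 : R_PosInf;
    crit_trace.push_back(crit);
    if (crit <= L) {
      converged = true;
      break;
    }

    // periodic residual bookkeeping: recompute r = y - fitted from scratch
    // (skipped when covariates are corrected, since their fit lives in r)
    if (!has_cov && check_every > 0 && k % check_every == 0) {
      std::vector<double> fit(n, 0.0);
      for (int j = 0; j < m; ++j) {
        if (ga[j] != 0.0) {
          const double* x = &Xa(0, j);
          for (int i = 0; i < n; ++i) fit[i] += x[i] * ga[j];
        }
        if (gd[j] != 0.0) {
          const double* x = &Xd(0, j);
          for (int i = 0; i < n; ++i) fit[i] += x[i] * gd[j];
        }
      }
      for (const EpiSource& es : epi) {
        R_xlen_t idx = 0;
        for (int j = 0; j < m - 1; ++j) {
          const double* pj = es.P + (R_xlen_t) n * j;
          for (int k2 = j + 1; k2 < m; ++k2, ++idx) {
            double g0 = es.g[idx];
            if (g0 == 0.0) continue;
            const double* qk = es.Q + (R_xlen_t) n * k2;
            for (int i = 0; i < n; ++i) fit[i] += pj[i] * qk[i] * g0;
          }
        }
      }
      double dev = 0.0, scale = 0.0;
      for (int i = 0; i < n; ++i) {
        double ri = y[i] - fit[i];
        dev += (r[i] - ri) * (r[i] - ri);
        scale += r[i] * r[i];
      }
      resid_check = std::max(resid_check,
                             std::sqrt(dev / std::max(scale, 1e-300)));
      for (int i = 0; i < n; ++i) r[i] = y[i] - fit[i];
    }
  }

  List g_out = List::create(_["a"] = wrap(ga));
  if (model >= 1) g_out["d"] = wrap(gd);
  if (model == 2) {
    g_out["aa"] = wrap(gaa);
    g_out["ad"] = wrap(gad);
    g_out["da"] = wrap(gda);
    g_out["dd"] = wrap(gdd);
  }
  return List::create(
      _["estimates"] = g_out, _["sigmaE2"] = sigma2,
      _["iterations"] = iter, _["converged"] = converged,
      _["criterionTrace"] = wrap(crit_trace),
      _["sigmaTrace"] = wrap(sigma_trace), _["residual"] = wrap(r),
      _["residualCheck"] = resid_check);
}

// Per-source genetic values X_s %*% g_s for given individuals; epistatic
// columns are streamed. Columns of the result follow the source order.
// [[Rcpp::export]]
NumericMatrix cpp_predict_parts(NumericMatrix Xa, NumericMatrix Xd, List g,
                                int model) {
  const int n = Xa.nrow();
  const int m = Xa.ncol();
  const int nsrc = (model == 2) ? 6 : (model == 1 ? 2 : 1);
  NumericMatrix parts(n, nsrc);
  {
    NumericVector ga = g["a"];
    for (int j = 0; j < m; ++j) {
      if (ga[j] == 0.0) continue;
      const double* x = &Xa(0, j);
      for (int i = 0; i < n; ++i) parts(i, 0) += x[i] * ga[j];
    }
  }
  if (model >= 1) {
    NumericVector gd = g["d"];
    for (int j = 0; j < m; ++j) {
      if (gd[j] == 0.0) continue;
      const double* x = &Xd(0, j);
      for (int i = 0; i < n; ++i) parts(i, 1) += x[i] * gd[j];
    }
  }
  if (model == 2) {
    const char* keys[4] = {"aa", "ad", "da", "dd"};
    const double* P[4] = {&Xa(0, 0), &Xa(0, 0), &Xd(0, 0), &Xd(0, 0)};
    const double* Q[4] = {&Xa(0, 0), &Xd(0, 0), &Xa(0, 0), &Xd(0, 0)};
    for (int s = 0; s < 4; ++s) {
      NumericVector gs = g[keys[s]];
      R_xlen_t idx = 0;
      for (int j = 0; j < m - 1; ++j) {
        const double* pj = P[s] + (R_xlen_t) n * j;
        for (int k2 = j + 1; k2 < m; ++k2, ++idx) {
          double gv = gs[idx];
          if (gv == 0.0) continue;
          const double* qk = Q[s] + (R_xlen_t) n * k2;
          for (int i = 0; i < n; ++i) parts(i, 2 + s) += pj[i] * qk[i] * gv;
        }
      }
    }
  }
  return parts;
}
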