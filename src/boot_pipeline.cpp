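#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Shared IRLS core (see fast_logit.cpp for the exported single-fit API).
// The weighted cross-products are accumulated column-pair-wise with plain
// loops: the linked reference BLAS is slower than what the compiler
// auto-vectorizes here, and these products dominate the bootstrap cost.
static bool irls_core(const mat& X, const vec& y, vec& beta, vec& fitted,
                      int max_iter = 50, double tol = 1e-9) {
  const uword n = X.n_rows, p = X.n_cols;
  if (beta.n_elem != p) beta = vec(p, fill::zeros);
  bool converged = false;
  vec eta(n), wz(n), w(n);
  for (int it = 0; it < max_iter; ++it) {
    eta = X * beta;
    for (uword i = 0; i < n; ++i) {
      double mu = 1.0 / (1.0 + std::exp(-eta(i)));
      double wi = mu * (1.0 - mu);
      if (wi < 1e-10) wi = 1e-10;
      w(i) = wi;
      wz(i) = wi * eta(i) + (y(i) - mu);   // w * z with z = eta + (y-mu)/w
    }
    mat A = X.t() * (X.each_col() % w);
    vec rhs = X.t() * wz;
    vec beta_new;
    bool ok = solve(beta_new, A, rhs,
                    solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) beta_new = pinv(A) * rhs;
    double delta = max(abs(beta_new - beta));
    beta = beta_new;
    if (delta < tol) { converged = true; break; }
  }
  fitted = 1.0 / (1.0 + exp(-(X * beta)));
  fitted.transform([](double v) {
    if (v < 1e-12) return 1e-12;
    if (v > 1.0 - 1e-12) return 1.0 - 1e-12;
    return v;
  });
  return converged;
}

static double clamp01(double p) {
  if (p < 1e-12) return 1e-12;
  if (p > 1.0 - 1e-12) return 1.0 - 1e-12;
  return p;
}

// type-7 quantile of a sorted vector
static double quantile7(const vec& sorted, double prob) {
  const uword n = sorted.n_elem;
  if (n == 1) return sorted(0);
  double h = (n - 1) * prob;
  uword lo = static_cast<uword>(std::floor(h));
  uword hi = lo + 1 < n ? lo + 1 : lo;
  return sorted(lo) + (h - lo) * (sorted(hi) - sorted(lo));
}

// Person-bootstrap of the whole weighting + GLS pipeline.
//
// Xden/Xcen: design matrices over all person-wave rows (intercept included).
// wave/active/expo/expo_lag/cens/outcome/time: row-level vectors; missing
//   values in expo/cens coded -1, outcome missing as NaN.
// er_ok / cr_ok: 0/1 flags marking rows eligible for the exposure /
//   censoring risk set at their wave (complete covariates etc.).
// pstart/plen: 0-based row offsets and lengths per person.
// draws: n_persons x B matrix of 0-based person indices.
// Returns a B x 3 matrix of (exposure, time, exposure:time) coefficients,
// NaN rows on replicate failure.
// [[Rcpp::export(name = ".boot_pipeline_cpp")]]
arma::mat boot_pipeline(const arma::mat& Xden, const arma::mat& Xcen,
                        const arma::mat& Xbase,
                        const arma::ivec& wave, const arma::vec& expo,
                        const arma::vec& expo_lag, const arma::vec& cens,
                        const arma::vec& outcome, const arma::vec& time,
                        const arma::ivec& er_ok, const arma::ivec& cr_ok,
                        const arma::ivec& b_ok,
                        const arma::ivec& pstart, const arma::ivec& plen,
                        const arma::imat& draws, int n_waves,
                        double p_lo, double p_hi, bool cap_mode,
                        bool weight_baseline) {
  const uword B = draws.n_cols;
  const uword n_persons = draws.n_rows;
  mat out(B, 3);
  out.fill(datum::nan);

  // reusable warm starts across replicates (from previous successful fits)
  std::vector<vec> warm_e(n_waves + 1), warm_c(n_waves + 1);
  vec warm_b;

  for (uword b = 0; b < B; ++b) {
    // gather rows of this replicate
    uword total = 0;
    for (uword j = 0; j < n_persons; ++j) total += plen(draws(j, b));
    uvec rows(total);
    uvec person_of(total);
    uword k = 0;
    for (uword j = 0; j < n_persons; ++j) {
      int pid = draws(j, b);
      for (int r = 0; r < plen(pid); ++r, ++k) {
        rows(k) = pstart(pid) + r;
        person_of(k) = j;
      }
    }

    vec sw(total);
    sw.fill(datum::nan);
    bool failed = false;

    if (weight_baseline) {
      std::vector<uword> b0;
      b0.reserve(n_persons + 8);
      for (uword i = 0; i < total; ++i) {
        if (wave(rows(i)) == 0 && b_ok(rows(i))) b0.push_back(i);
      }
      if (!b0.empty()) {
        uword m = b0.size();
        uvec sel(m);
        vec y(m);
        for (uword i = 0; i < m; ++i) {
          sel(i) = rows(b0[i]);
          y(i) = expo(sel(i));
        }
        mat X = Xbase.rows(sel);
        vec beta = warm_b, fitted;
        bool conv = irls_core(X, y, beta, fitted);
        if (!conv && warm_b.n_elem > 0) {
          beta = vec(X.n_cols, fill::zeros);
          conv = irls_core(X, y, beta, fitted);
        }
        if (conv && warm_b.n_elem == 0) warm_b = beta;
        double pn = clamp01(accu(y) / m);
        for (uword i = 0; i < m; ++i) {
          sw(b0[i]) = y(i) == 1.0 ? pn / fitted(i)
                                  : (1.0 - pn) / (1.0 - fitted(i));
        }
      }
    } else {
      for (uword i = 0; i < total; ++i) {
        uword r = rows(i);
        if (wave(r) == 0 && expo(r) >= 0) sw(i) = 1.0;
      }
    }

    for (int t = 1; t <= n_waves && !failed; ++t) {
      std::vector<uword> er, cr;
      er.reserve(total / n_waves + 8);
      cr.reserve(total / n_waves + 8);
      for (uword i = 0; i < total; ++i) {
        uword r = rows(i);
        if (wave(r) != t) continue;
        if (er_ok(r)) er.push_back(i);
        if (cr_ok(r)) cr.push_back(i);
      }
      if (er.empty() || cr.empty()) continue;

      // exposure models
      {
        uword m = er.size();
        uvec sel(m);
        vec y(m), xlag(m);
        for (uword i = 0; i < m; ++i) {
          sel(i) = rows(er[i]);
          y(i) = expo(sel(i));
          xlag(i) = expo_lag(sel(i));
        }
        mat X = Xden.rows(sel);
        // warm starts are frozen at their first converged value so one
        // degenerate replicate cannot poison the next
        vec beta = warm_e[t], fitted;
        bool conv = irls_core(X, y, beta, fitted);
        if (!conv && warm_e[t].n_elem > 0) {
          beta = vec(X.n_cols, fill::zeros);
          conv = irls_core(X, y, beta, fitted);
        }
        if (conv && warm_e[t].n_elem == 0) warm_e[t] = beta;
        double n1 = accu(xlag), s1 = accu(y % xlag);
        double n0 = m - n1, s0 = accu(y) - s1;
        double p1 = clamp01(n1 > 0 ? s1 / n1 : accu(y) / m);
        double p0 = clamp01(n0 > 0 ? s0 / n0 : accu(y) / m);
        for (uword i = 0; i < m; ++i) {
          double pn = xlag(i) == 1.0 ? p1 : p0;
          double pd = fitted(i);
          sw(er[i]) = y(i) == 1.0 ? pn / pd : (1.0 - pn) / (1.0 - pd);
        }
      }
      // censoring models (probability of remaining uncensored)
      {
        uword m = cr.size();
        uvec sel(m);
        vec y(m), xlag(m);
        for (uword i = 0; i < m; ++i) {
          sel(i) = rows(cr[i]);
          y(i) = cens(sel(i));
          xlag(i) = expo_lag(sel(i));
        }
        mat X = Xcen.rows(sel);
        vec beta = warm_c[t], fitted;
        bool conv = irls_core(X, y, beta, fitted);
        if (!conv && warm_c[t].n_elem > 0) {
          beta = vec(X.n_cols, fill::zeros);
          conv = irls_core(X, y, beta, fitted);
        }
        if (conv && warm_c[t].n_elem == 0) warm_c[t] = beta;
        double n1 = accu(xlag), s1 = accu(y % xlag);
        double n0 = m - n1, s0 = accu(y) - s1;
        double p1 = clamp01(n1 > 0 ? s1 / n1 : accu(y) / m);
        double p0 = clamp01(n0 > 0 ? s0 / n0 : accu(y) / m);
        // map censoring weight back onto the exposure risk-set rows at t:
        // store qn/qd at each cr row, multiply er rows below
        for (uword i = 0; i < m; ++i) {
          double qn = 1.0 - (xlag(i) == 1.0 ? p1 : p0);
          double qd = clamp01(1.0 - fitted(i));
          // multiply into sw where the row also sits in the exposure set
          if (std::isfinite(sw(cr[i]))) sw(cr[i]) *= qn / qd;
          else if (cens(rows(cr[i])) == 0.0) {
            // uncensored row lacking an exposure weight stays undefined
          }
        }
      }
    }
    if (failed) continue;

    // cumulative product per person; NaN poisons later waves
    vec w_cum(total);
    w_cum.fill(datum::nan);
    double acc = 1.0;
    bool dead_chain = false;
    for (uword i = 0; i < total; ++i) {
      if (i == 0 || person_of(i) != person_of(i - 1)) {
        acc = 1.0;
        dead_chain = false;
      }
      if (dead_chain || !std::isfinite(sw(i))) {
        dead_chain = true;
        continue;
      }
      acc *= sw(i);
      w_cum(i) = acc;
    }
    // keep only rows that enter the outcome model later AND are active
    // (w_cum is defined exactly for observed at-risk rows)

    // truncation bounds from pooled finite w_cum
    std::vector<double> pool;
    pool.reserve(total);
    for (uword i = 0; i < total; ++i) {
      if (std::isfinite(w_cum(i))) pool.push_back(w_cum(i));
    }
    if (pool.size() < 4) continue;
    vec pv(pool);
    pv = sort(pv);
    double lo = quantile7(pv, p_lo), hi = quantile7(pv, p_hi);

    // weighted least squares on y ~ a * t
    mat XtWX(4, 4, fill::zeros);
    vec XtWy(4, fill::zeros);
    uword used = 0;
    for (uword i = 0; i < total; ++i) {
      double w = w_cum(i);
      if (!std::isfinite(w)) continue;
      if (cap_mode) {
        w = w < lo ? lo : (w > hi ? hi : w);
      } else if (w < lo || w > hi) {
        continue;
      }
      uword r = rows(i);
      double y = outcome(r);
      if (!std::isfinite(y)) continue;
      double a = expo(r);
      if (a < 0) continue;
      double tt = time(r);
      double x[4] = {1.0, a, tt, a * tt};
      for (int u = 0; u < 4; ++u) {
        XtWy(u) += w * x[u] * y;
        for (int v = u; v < 4; ++v) XtWX(u, v) += w * x[u] * x[v];
      }
      ++used;
    }
    if (used < 8) continue;
    XtWX = symmatu(XtWX);
    vec beta;
    if (!solve(beta, XtWX, XtWy, solve_opts::no_approx)) continue;
    out(b, 0) = beta(1);
    out(b, 1) = beta(2);
    out(b, 2) = beta(3);
  }
  return out;
}
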