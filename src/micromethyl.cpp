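// Compiled kernels: pairwise community distances, deterministic PAM
// (BUILD + best-swap with smallest-index tie rules), iterated hypergeometric
// rarefaction, and per-CpG Huber IRLS fits. These are the inner loops of the
// leave-one-out and permutation procedures and must stay O(fast).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------- distances

// columns of `ra` are probability vectors (samples); metric:
// 0 = jsd, 1 = bray_curtis, 2 = jaccard (presence/absence)
// [[Rcpp::export]]
NumericMatrix cpp_pairwise_distance(const NumericMatrix& ra, int metric) {
  const int T = ra.nrow(), n = ra.ncol();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = 0.0;
      if (metric == 0) {
        double kl_p = 0.0, kl_q = 0.0;
        for (int t = 0; t < T; ++t) {
          const double p = ra(t, i), q = ra(t, j);
          const double a = 0.5 * (p + q);
          if (p > 0.0) kl_p += p * std::log(p / a);
          if (q > 0.0) kl_q += q * std::log(q / a);
        }
        d = 0.5 * kl_p + 0.5 * kl_q;
        if (d < 0.0) d = 0.0;  // guard tiny negative rounding
      } else if (metric == 1) {
        double num = 0.0, den = 0.0;
        for (int t = 0; t < T; ++t) {
          const double p = ra(t, i), q = ra(t, j);
          num += std::fabs(p - q);
          den += p + q;
        }
        d = (den > 0.0) ? num / den : 0.0;
      } else {
        int inter = 0, uni = 0;
        for (int t = 0; t < T; ++t) {
          const bool a = ra(t, i) > 0.0, b = ra(t, j) > 0.0;
          if (a && b) ++inter;
          if (a || b) ++uni;
        }
        d = (uni > 0) ? 1.0 - (double)inter / (double)uni : 0.0;
      }
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}

// ---------------------------------------------------------------------- PAM

static void nearest_two(const NumericMatrix& d, const std::vector<int>& med,
                        std::vector<int>& a1, std::vector<double>& d1,
                        std::vector<double>& d2) {
  const int n = d.nrow(), k = (int)med.size();
  for (int j = 0; j < n; ++j) {
    double b1 = R_PosInf, b2 = R_PosInf;
    int who = -1;
    for (int m = 0; m < k; ++m) {
      const double dd = d(j, med[m]);
      if (dd < b1) { b2 = b1; b1 = dd; who = med[m]; }
      else if (dd < b2) { b2 = dd; }
    }
    a1[j] = who; d1[j] = b1; d2[j] = b2;
  }
}

// best single swap from the current medoid set; scans medoids and candidates
// in ascending sample index so ties resolve to the smallest indices
static void best_swap(const NumericMatrix& d, const std::vector<int>& med,
                      const std::vector<bool>& is_med, double& best_dt,
                      int& bm, int& bh) {
  const int n = d.nrow(), k = (int)med.size();
  std::vector<int> a1(n);
  std::vector<double> d1(n), d2(n);
  nearest_two(d, med, a1, d1, d2);
  std::vector<int> msorted(med);
  std::sort(msorted.begin(), msorted.end());
  best_dt = R_PosInf; bm = -1; bh = -1;
  for (int mi = 0; mi < k; ++mi) {
    const int m = msorted[mi];
    for (int h = 0; h < n; ++h) {
      if (is_med[h]) continue;
      double dt = 0.0;
      for (int j = 0; j < n; ++j) {
        const double djh = d(j, h);
        if (a1[j] == m) dt += std::min(djh, d2[j]) - d1[j];
        else if (djh < d1[j]) dt += djh - d1[j];
      }
      if (dt < best_dt - 1e-12) { best_dt = dt; bm = m; bh = h; }
    }
  }
}

static void apply_swap(std::vector<int>& med, std::vector<bool>& is_med,
                       int m, int h) {
  is_med[m] = false; is_med[h] = true;
  for (size_t i = 0; i < med.size(); ++i) if (med[i] == m) med[i] = h;
}

// steepest-descent swap phase with deterministic tie-chain lookahead: when
// no single swap strictly improves, a zero-cost swap (smallest indices
// first) is taken only if it opens a strictly improving follow-up, so the
// total cost strictly decreases per accepted chain and the phase terminates
static void pam_swap_phase(const NumericMatrix& d, std::vector<int>& med,
                           std::vector<bool>& is_med) {
  const int n = d.nrow(), k = (int)med.size();
  for (int iter = 0; iter < 100000; ++iter) {
    double dt; int bm, bh;
    best_swap(d, med, is_med, dt, bm, bh);
    if (bm >= 0 && dt < -1e-12) { apply_swap(med, is_med, bm, bh); continue; }
    // no strict improvement: look for a tie swap enabling one
    std::vector<int> msorted(med);
    std::sort(msorted.begin(), msorted.end());
    std::vector<int> a1(n);
    std::vector<double> d1(n), d2(n);
    nearest_two(d, med, a1, d1, d2);
    bool chained = false;
    for (int mi = 0; mi < k && !chained; ++mi) {
      const int m = msorted[mi];
      for (int h = 0; h < n && !chained; ++h) {
        if (is_med[h]) continue;
        double tdt = 0.0;
        for (int j = 0; j < n; ++j) {
          const double djh = d(j, h);
          if (a1[j] == m) tdt += std::min(djh, d2[j]) - d1[j];
          else if (djh < d1[j]) tdt += djh - d1[j];
        }
        if (std::fabs(tdt) > 1e-12) continue;
        std::vector<int> med2(med);
        std::vector<bool> is_med2(is_med);
        apply_swap(med2, is_med2, m, h);
        double dt2; int bm2, bh2;
        best_swap(d, med2, is_med2, dt2, bm2, bh2);
        if (bm2 >= 0 && dt2 < -1e-12) {
          med = med2; is_med = is_med2;
          apply_swap(med, is_med, bm2, bh2);
          chained = true;
        }
      }
    }
    if (!chained) break;
  }
}

// Deterministic PAM: greedy BUILD, then repeatedly apply the single best
// strictly-improving medoid<->non-medoid swap (with a tie-chain escape for
// equal-cost plateaus); all ties broken by smallest sample index. Returns
// 1-based medoid ids, labels and the total cost.
// [[Rcpp::export]]
List cpp_pam(const NumericMatrix& d, int k) {
  const int n = d.nrow();
  std::vector<int> med;
  med.reserve(k);
  std::vector<bool> is_med(n, false);

  // BUILD: first medoid minimises the total distance
  {
    double best = R_PosInf; int who = 0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += d(j, i);
      if (s < best - 1e-15) { best = s; who = i; }
    }
    med.push_back(who); is_med[who] = true;
  }
  std::vector<double> near(n);
  for (int j = 0; j < n; ++j) near[j] = d(j, med[0]);

  while ((int)med.size() < k) {
    double best_gain = -1.0; int who = -1;
    for (int c = 0; c < n; ++c) {
      if (is_med[c]) continue;
      double gain = 0.0;
      for (int j = 0; j < n; ++j) {
        const double diff = near[j] - d(j, c);
        if (diff > 0.0) gain += diff;
      }
      if (gain > best_gain + 1e-15) { best_gain = gain; who = c; }
    }
    if (who < 0) {  // all remaining candidates give zero gain: smallest index
      for (int c = 0; c < n; ++c) if (!is_med[c]) { who = c; break; }
    }
    med.push_back(who); is_med[who] = true;
    for (int j = 0; j < n; ++j) near[j] = std::min(near[j], d(j, who));
  }

  // SWAP
  if (k < n) pam_swap_phase(d, med, is_med);

  std::sort(med.begin(), med.end());
  // labels: nearest medoid, ties to the smallest medoid sample index
  IntegerVector labels(n);
  double cost = 0.0;
  for (int j = 0; j < n; ++j) {
    double best = R_PosInf; int who = 0;
    for (int m = 0; m < (int)med.size(); ++m) {
      const double dd = d(j, med[m]);
      if (dd < best - 1e-15) { best = dd; who = m; }
    }
    labels[j] = who + 1;
    cost += best;
  }
  IntegerVector medoids(k);
  for (int m = 0; m < k; ++m) medoids[m] = med[m] + 1;
  return List::create(_["medoids"] = medoids, _["labels"] = labels,
                      _["cost"] = cost);
}

// -------------------------------------------------------------- rarefaction

// Mean over `iterations` of sampling L reads without replacement from each
// sample (sequential multivariate hypergeometric). Uses R's RNG.
// [[Rcpp::export]]
NumericMatrix cpp_rarefy_mean(const IntegerMatrix& counts, int L,
                              int iterations) {
  const int T = counts.nrow(), n = counts.ncol();
  NumericMatrix out(T, n);
  for (int s = 0; s < n; ++s) {
    long total = 0;
    for (int t = 0; t < T; ++t) total += counts(t, s);
    for (int it = 0; it < iterations; ++it) {
      long remaining = total;
      int to_draw = L;
      for (int t = 0; t < T && to_draw > 0; ++t) {
        const int ct = counts(t, s);
        const long rest = remaining - ct;
        int x;
        if (rest <= 0) x = to_draw;  // only this taxon left
        else x = (int)::Rf_rhyper((double)ct, (double)rest, (double)to_draw);
        out(t, s) += x;
        to_draw -= x;
        remaining -= ct;
      }
    }
    for (int t = 0; t < T; ++t) out(t, s) /= (double)iterations;
  }
  return out;
}

// -------------------------------------------------------------- Huber IRLS

// Per-row (per-CpG) iteratively reweighted least squares with Huber weights
// w = min(1, c / |r/s_hat|), s_hat = 1.4826 * median|r|. Returns coefficients,
// unscaled coefficient SDs, residual scale s (sqrt(sum w r^2/(n-p))), a
// convergence flag, and the unscaled covariance block for `cov_idx` columns.
// [[Rcpp::export]]
List cpp_huber_fit(const arma::mat& Y, const arma::mat& X,
                   const arma::uvec& cov_idx, double c_huber, int max_iter,
                   double tol) {
  const arma::uword G = Y.n_rows, n = X.n_rows, p = X.n_cols;
  const arma::uword q = cov_idx.n_elem;
  arma::mat coef(G, p), stdu(G, p);
  arma::vec sigma(G);
  arma::cube covu(q, q, G);
  LogicalVector converged(G);

  const arma::mat XtX = X.t() * X;
  arma::mat XtXinv;
  if (!arma::inv_sympd(XtXinv, XtX)) XtXinv = arma::pinv(XtX);
  for (arma::uword g = 0; g < G; ++g) {
    const arma::vec y = Y.row(g).t();
    arma::vec beta = arma::solve(XtX, X.t() * y, arma::solve_opts::likely_sympd);
    arma::vec w(n, arma::fill::ones);
    bool conv = false;
    for (int it = 0; it < max_iter; ++it) {
      const arma::vec r = y - X * beta;
      const double s_hat = 1.4826 * arma::median(arma::abs(r));
      if (s_hat < 1e-12) { conv = true; w.ones(); break; }
      for (arma::uword i = 0; i < n; ++i) {
        const double u = std::fabs(r(i)) / s_hat;
        w(i) = (u <= c_huber) ? 1.0 : c_huber / u;
      }
      const arma::mat Xw = X.each_col() % w;
      const arma::vec beta_new =
          arma::solve(X.t() * Xw, Xw.t() * y, arma::solve_opts::likely_sympd);
      const double delta = arma::abs(beta_new - beta).max();
      const double scale = 1.0 + arma::abs(beta).max();
      beta = beta_new;
      if (delta <= tol * scale) { conv = true; break; }
    }
    if (!conv) {  // fall back to OLS, flagged
      beta = arma::solve(XtX, X.t() * y, arma::solve_opts::likely_sympd);
      w.ones();
    }
    const arma::vec r = y - X * beta;
    // Huber's robust variance: Var(beta) = s_rob^2 (X'X)^{-1} with
    //   s_rob^2 = K^2 * shat^2 * sum(psi(u)^2)/(n-p) / mean(psi'(u))^2,
    //   K = 1 + (p/n) var(psi') / mean(psi')^2,
    // which reduces exactly to the OLS variance when no residual is
    // truncated (all psi' = 1)
    const double shat = 1.4826 * arma::median(arma::abs(r));
    double s2;
    if (shat < 1e-12) {
      s2 = arma::dot(r, r) / (double)(n - p);
    } else {
      const arma::vec u = r / shat;
      arma::vec psi = arma::clamp(u, -c_huber, c_huber);
      arma::vec dpsi(n);
      for (arma::uword i = 0; i < n; ++i)
        dpsi(i) = (std::fabs(u(i)) <= c_huber) ? 1.0 : 0.0;
      const double m1 = arma::mean(dpsi);
      const double v1 = arma::var(dpsi, 1);
      const double K = 1.0 + ((double)p / (double)n) * v1 / (m1 * m1);
      s2 = K * K * shat * shat * arma::dot(psi, psi) /
        (double)(n - p) / (m1 * m1);
    }
    coef.row(g) = beta.t();
    stdu.row(g) = arma::sqrt(XtXinv.diag()).t();
    sigma(g) = std::sqrt(std::max(s2, 0.0));
    covu.slice(g) = XtXinv.submat(cov_idx, cov_idx);
    converged[g] = conv;
  }
  return List::create(_["coefficients"] = coef, _["stdev_unscaled"] = stdu,
                      _["sigma"] = sigma, _["converged"] = converged,
                      _["cov_unscaled"] = covu, _["df_residual"] = (double)(n - p));
}
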