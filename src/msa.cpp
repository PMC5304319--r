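#include <Rcpp.h>
using namespace Rcpp;

// Method-of-successive-averages loops for the scheduler-vs-demon zero-sum
// game.  Single steps are also implemented in plain R (a0_step/a1_step);
// these loops must reproduce them exactly — tie-breaks use strict
// comparisons so the lowest index wins, matching the R reference.

namespace {

// index of smallest value, lowest index on ties
inline int argmin_vec(const std::vector<double>& x) {
  int k = 0;
  for (int j = 1; j < (int)x.size(); ++j) if (x[j] < x[k]) k = j;
  return k;
}

// certified L-inf bound on max(|p - p*|, |q - q*|) given V* in [lb, ub]:
// |x_j - phi_j V*| = phi_j |x_j U_j - V*| <= phi_j * max(|e_j - lb|, |ub - e_j|)
// (identical algebra for both players because p* = q* = phi V*)
inline double cert_bound(const std::vector<double>& p,
                         const std::vector<double>& q,
                         const std::vector<double>& U,
                         const std::vector<double>& phi,
                         double lb, double ub) {
  double cert = 0.0;
  for (size_t j = 0; j < p.size(); ++j) {
    double e = p[j] * U[j];
    double f = q[j] * U[j];
    double d = std::max(std::fabs(e - lb), std::fabs(ub - e));
    double dq = std::max(std::fabs(f - lb), std::fabs(ub - f));
    double c = phi[j] * std::max(d, dq);
    if (c > cert) cert = c;
  }
  return cert;
}

inline void bounds(const std::vector<double>& p, const std::vector<double>& q,
                   const std::vector<double>& U, double& ub, double& lb) {
  ub = 0.0; lb = R_PosInf;
  for (size_t j = 0; j < p.size(); ++j) {
    double e = p[j] * U[j]; if (e > ub) ub = e;
    double f = q[j] * U[j]; if (f < lb) lb = f;
  }
}

} // namespace

// criterion: 0 = duality gap (ub - lb <= tol), 1 = certified error bound
// (cert <= tol), 2 = both (gap <= tol AND cert <= tol2)
// [[Rcpp::export(name = ".msa_a0_cpp")]]
List msa_a0_cpp(NumericVector phi_in, NumericVector p0, NumericVector q0,
                int m0, double tol, double tol2, double max_steps,
                int criterion, int check_every, double trace_every) {
  const int n = phi_in.size();
  std::vector<double> phi(phi_in.begin(), phi_in.end());
  std::vector<double> U(n), p(p0.begin(), p0.end()), q(q0.begin(), q0.end());
  for (int j = 0; j < n; ++j) U[j] = 1.0 / phi[j];

  std::vector<double> tr_m, tr_ub, tr_lb;
  double ub = 0, lb = 0, cert = R_PosInf;
  bool converged = false;
  long long m = m0, steps = 0;
  const long long maxs = (long long)max_steps;

  std::vector<double> qU(n), pU(n);
  while (steps < maxs) {
    double a = 1.0 / (double)(m + 1);
    // Step 1: node with lowest weighted unfitness under the demon's weights
    for (int j = 0; j < n; ++j) qU[j] = q[j] * U[j];
    int jstar = argmin_vec(qU);
    // Step 2: move attachment probabilities toward e_{j*}
    for (int j = 0; j < n; ++j) p[j] *= (1.0 - a);
    p[jstar] += a;
    // Step 3: node with highest expected unfitness (post-update p)
    int istar = 0;
    for (int i = 0; i < n; ++i) { pU[i] = p[i] * U[i]; if (pU[i] > pU[istar]) istar = i; }
    // Step 4: move avoidance weights toward e_{i*}
    for (int i = 0; i < n; ++i) q[i] *= (1.0 - a);
    q[istar] += a;
    // Step 5
    ++m; ++steps;

    bool check = (check_every > 0 && steps % check_every == 0) || steps == maxs;
    long long te = (long long)trace_every;
    bool trace = te > 0 && steps % te == 0;
    if (check || trace) {
      bounds(p, q, U, ub, lb);
      if (trace) { tr_m.push_back((double)m - 1); tr_ub.push_back(ub); tr_lb.push_back(lb); }
      if (check) {
        if (criterion != 0) cert = cert_bound(p, q, U, phi, lb, ub);
        bool ok = (criterion == 0) ? (ub - lb <= tol)
                : (criterion == 1) ? (cert <= tol)
                : (ub - lb <= tol && cert <= tol2);
        if (ok) { converged = true; break; }
      }
    }
    if (steps % 1048576 == 0) Rcpp::checkUserInterrupt();
  }
  bounds(p, q, U, ub, lb);
  cert = cert_bound(p, q, U, phi, lb, ub);

  return List::create(
    _["p"] = NumericVector(p.begin(), p.end()),
    _["q"] = NumericVector(q.begin(), q.end()),
    _["m"] = (double)m, _["steps"] = (double)steps,
    _["upper"] = ub, _["lower"] = lb, _["gap"] = ub - lb,
    _["error_bound"] = cert, _["converged"] = converged,
    _["trace_m"] = NumericVector(tr_m.begin(), tr_m.end()),
    _["trace_upper"] = NumericVector(tr_ub.begin(), tr_ub.end()),
    _["trace_lower"] = NumericVector(tr_lb.begin(), tr_lb.end()));
}

// Tiered MSA.  phi_list: one fitness vector per tier; adj: list of K-1
// 0/1 matrices (rows = upstream tier k, cols = tier k+1) or NULL entries
// meaning complete bipartite adjacency between the pair.
// [[Rcpp::export(name = ".msa_a1_cpp")]]
List msa_a1_cpp(List phi_list, List p0, List q0, List adj,
                int m0, double tol, double tol2, double max_steps,
                int criterion, int check_every, double trace_every) {
  const int K = phi_list.size();
  std::vector<std::vector<double> > phi(K), U(K), p(K), q(K);
  std::vector<bool> complete(K - 1, true);
  std::vector<IntegerMatrix> A(K - 1);
  for (int k = 0; k < K; ++k) {
    NumericVector f = phi_list[k], pp = p0[k], qq = q0[k];
    phi[k].assign(f.begin(), f.end());
    p[k].assign(pp.begin(), pp.end());
    q[k].assign(qq.begin(), qq.end());
    U[k].resize(f.size());
    for (int j = 0; j < f.size(); ++j) U[k][j] = 1.0 / f[j];
  }
  for (int k = 0; k + 1 < K; ++k) {
    if (!Rf_isNull(adj[k])) { A[k] = as<IntegerMatrix>(adj[k]); complete[k] = false; }
  }

  std::vector<double> ub(K), lb(K), gap(K), cert(K, R_PosInf);
  std::vector<double> tr_m; std::vector<std::vector<double> > tr_ub(K), tr_lb(K);
  bool converged = false;
  long long m = m0, steps = 0;
  const long long maxs = (long long)max_steps;

  // DP workspace
  std::vector<std::vector<double> > best(K);
  std::vector<std::vector<int> > pred(K);
  for (int k = 0; k < K; ++k) { best[k].resize(phi[k].size()); pred[k].resize(phi[k].size()); }
  std::vector<int> path(K);

  while (steps < maxs) {
    double a = 1.0 / (double)(m + 1);
    // Step 1: least-unfit path under node weights q_jk * U_jk (layered DP)
    for (size_t j = 0; j < best[0].size(); ++j) { best[0][j] = q[0][j] * U[0][j]; pred[0][j] = -1; }
    for (int k = 1; k < K; ++k) {
      const size_t nk = best[k].size(), np = best[k - 1].size();
      if (complete[k - 1]) {
        int imin = argmin_vec(best[k - 1]);
        for (size_t j = 0; j < nk; ++j) {
          best[k][j] = best[k - 1][imin] + q[k][j] * U[k][j];
          pred[k][j] = imin;
        }
      } else {
        for (size_t j = 0; j < nk; ++j) {
          double b = R_PosInf; int pi = -1;
          for (size_t i = 0; i < np; ++i)
            if (A[k - 1]((int)i, (int)j) && best[k - 1][i] < b) { b = best[k - 1][i]; pi = (int)i; }
          best[k][j] = (pi < 0) ? R_PosInf : b + q[k][j] * U[k][j];
          pred[k][j] = pi;
        }
      }
    }
    int last = argmin_vec(best[K - 1]);
    if (!R_FINITE(best[K - 1][last])) stop("no feasible path through the tiers");
    for (int k = K - 1; k >= 0; --k) { path[k] = last; last = pred[k][last]; }
    // Steps 2-4 per tier
    for (int k = 0; k < K; ++k) {
      const size_t nk = p[k].size();
      for (size_t j = 0; j < nk; ++j) p[k][j] *= (1.0 - a);
      p[k][path[k]] += a;
      int istar = 0;
      for (size_t i = 0; i < nk; ++i)
        if (p[k][i] * U[k][i] > p[k][istar] * U[k][istar]) istar = (int)i;
      for (size_t i = 0; i < nk; ++i) q[k][i] *= (1.0 - a);
      q[k][istar] += a;
    }
    ++m; ++steps;

    bool check = (check_every > 0 && steps % check_every == 0) || steps == maxs;
    long long te = (long long)trace_every;
    bool trace = te > 0 && steps % te == 0;
    if (check || trace) {
      bool ok = true;
      for (int k = 0; k < K; ++k) {
        bounds(p[k], q[k], U[k], ub[k], lb[k]);
        gap[k] = ub[k] - lb[k];
        if (criterion != 0)
          cert[k] = cert_bound(p[k], q[k], U[k], phi[k], lb[k], ub[k]);
        bool tier_ok = (criterion == 0) ? (gap[k] <= tol)
                     : (criterion == 1) ? (cert[k] <= tol)
                     : (gap[k] <= tol && cert[k] <= tol2);
        if (!tier_ok) ok = false;
      }
      if (trace) {
        tr_m.push_back((double)m - 1);
        for (int k = 0; k < K; ++k) { tr_ub[k].push_back(ub[k]); tr_lb[k].push_back(lb[k]); }
      }
      if (check && ok) { converged = true; break; }
    }
    if (steps % 262144 == 0) Rcpp::checkUserInterrupt();
  }
  for (int k = 0; k < K; ++k) {
    bounds(p[k], q[k], U[k], ub[k], lb[k]);
    gap[k] = ub[k] - lb[k];
    cert[k] = cert_bound(p[k], q[k], U[k], phi[k], lb[k], ub[k]);
  }

  List pout(K), qout(K), trub(K), trlb(K);
  for (int k = 0; k < K; ++k) {
    pout[k] = NumericVector(p[k].begin(), p[k].end());
    qout[k] = NumericVector(q[k].begin(), q[k].end());
    trub[k] = NumericVector(tr_ub[k].begin(), tr_ub[k].end());
    trlb[k] = NumericVector(tr_lb[k].begin(), tr_lb[k].end());
  }
  return List::create(
    _["p"] = pout, _["q"] = qout,
    _["m"] = (double)m, _["steps"] = (double)steps,
    _["upper"] = NumericVector(ub.begin(), ub.end()),
    _["lower"] = NumericVector(lb.begin(), lb.end()),
    _["gap"] = NumericVector(gap.begin(), gap.end()),
    _["error_bound"] = NumericVector(cert.begin(), cert.end()),
    _["converged"] = converged,
    _["trace_m"] = NumericVector(tr_m.begin(), tr_m.end()),
    _["trace_upper"] = trub, _["trace_lower"] = trlb);
}
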