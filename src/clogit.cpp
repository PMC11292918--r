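// Penalized conditional logistic likelihood: Newton solvers and split search.
//
// Data layout contract (established by matched_data() on the R side):
// rows are sorted by stratum; sstart[i] / slen[i] give the 0-based first row
// and size of stratum i; y holds the 0/1 case indicator (one 1 per stratum).
//
// The conditional likelihood is invariant to per-stratum constant shifts of
// the linear predictor, so with the default tiny ridge the Hessian is
// singular along the all-ones direction of the node effects.  A fixed
// Tikhonov term (HESS_JITTER) conditions the Newton solve; iterates started
// at zero stay (numerically) on the minimum-norm representative.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const double HESS_JITTER = 1e-10;
static const double COEF_CAP = 50.0;

// conditional log-likelihood of eta (no penalty), overflow-safe
static double cond_loglik_eta(const arma::vec& eta,
                              const IntegerVector& sstart,
                              const IntegerVector& slen,
                              const IntegerVector& y) {
  double ll = 0.0;
  int n = sstart.size();
  for (int i = 0; i < n; ++i) {
    int a = sstart[i], m = slen[i];
    double mx = eta[a];
    for (int j = 1; j < m; ++j) mx = std::max(mx, eta[a + j]);
    double se = 0.0, ec = 0.0;
    for (int j = 0; j < m; ++j) {
      double e = std::exp(eta[a + j] - mx);
      se += e;
      if (y[a + j] == 1) ec = eta[a + j] - mx;
    }
    ll += ec - std::log(se);
  }
  return ll;
}

// per-row softmax probabilities within strata
static void softmax_rows(const arma::vec& eta,
                         const IntegerVector& sstart,
                         const IntegerVector& slen,
                         arma::vec& p) {
  int n = sstart.size();
  for (int i = 0; i < n; ++i) {
    int a = sstart[i], m = slen[i];
    double mx = eta[a];
    for (int j = 1; j < m; ++j) mx = std::max(mx, eta[a + j]);
    double se = 0.0;
    for (int j = 0; j < m; ++j) { p[a + j] = std::exp(eta[a + j] - mx); se += p[a + j]; }
    for (int j = 0; j < m; ++j) p[a + j] /= se;
  }
}

// ---------------------------------------------------------------------------
// Dense-design Newton fitter: maximize cond_loglik(X theta + offset)
//   - 0.5 * sum(lambda_j theta_j^2), with step-halving.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_clr_fit(const arma::mat& X,
                 const arma::vec& offset,
                 const IntegerVector& sstart,
                 const IntegerVector& slen,
                 const IntegerVector& y,
                 const arma::vec& lambda,
                 const arma::vec& init,
                 int maxit,
                 double tol_obj,
                 double tol_grad) {
  int nrow = X.n_rows, d = X.n_cols, nstr = sstart.size();
  arma::vec theta = init;
  arma::vec eta = X * theta + offset;
  arma::vec p(nrow);
  double ll = cond_loglik_eta(eta, sstart, slen, y);
  double obj = ll - 0.5 * arma::dot(lambda, theta % theta);
  bool converged = false, flagged = false;
  int iter = 0;
  double gmax = NA_REAL;

  for (iter = 0; iter < maxit; ++iter) {
    softmax_rows(eta, sstart, slen, p);
    arma::vec r(nrow);
    for (int k = 0; k < nrow; ++k) r[k] = (y[k] == 1 ? 1.0 : 0.0) - p[k];
    arma::vec g = X.t() * r - lambda % theta;
    gmax = arma::abs(g).max();
    if (gmax < tol_grad) { converged = true; break; }
    // Fisher information: sum_s Xs' diag(ps) Xs - (Xs' ps)(Xs' ps)'
    arma::mat F(d, d, arma::fill::zeros);
    for (int i = 0; i < nstr; ++i) {
      int a = sstart[i], m = slen[i];
      arma::mat Xs = X.rows(a, a + m - 1);
      arma::vec ps = p.subvec(a, a + m - 1);
      arma::vec u = Xs.t() * ps;
      F += Xs.t() * (Xs.each_col() % ps) - u * u.t();
    }
    F.diag() += lambda + HESS_JITTER;
    arma::vec step;
    bool ok = arma::solve(step, F, g, arma::solve_opts::likely_sympd);
    if (!ok) { flagged = true; break; }
    // step-halving on the penalized objective
    double t = 1.0, new_obj = obj;
    arma::vec theta_new = theta;
    bool improved = false;
    for (int h = 0; h < 30; ++h) {
      theta_new = theta + t * step;
      arma::vec eta_new = X * theta_new + offset;
      new_obj = cond_loglik_eta(eta_new, sstart, slen, y)
        - 0.5 * arma::dot(lambda, theta_new % theta_new);
      if (new_obj >= obj - 1e-14) { improved = true; eta = eta_new; break; }
      t *= 0.5;
    }
    if (!improved) { converged = true; break; }  // at numerical optimum
    // divergence guard for (quasi-)separated fits
    if (arma::abs(theta_new).max() > COEF_CAP) {
      theta_new = arma::clamp(theta_new, -COEF_CAP, COEF_CAP);
      eta = X * theta_new + offset;
      flagged = true;
    }
    double delta_obj = new_obj - obj;
    theta = theta_new;
    obj = new_obj;
    if (std::fabs(delta_obj) < tol_obj * (std::fabs(obj) + 1e-10)) {
      converged = true; ++iter; break;
    }
  }
  ll = cond_loglik_eta(eta, sstart, slen, y);
  return List::create(_["coef"] = theta, _["loglik"] = ll, _["objective"] = obj,
                      _["iter"] = iter, _["converged"] = converged,
                      _["flagged"] = flagged, _["grad_max"] = gmax);
}

// ---------------------------------------------------------------------------
// Grouped (tree) design: eta = delta[node[row]] + beta * x[row] + offset.
// Much cheaper than the dense fitter because gradient and Fisher information
// reduce to per-node sums.  theta = (delta_1..delta_t [, beta]).
// ---------------------------------------------------------------------------
struct GroupFit {
  arma::vec delta;
  double beta;
  double obj;
  double ll;
  bool converged;
  bool flagged;
};

static GroupFit grouped_newton(const arma::ivec& node, int t,
                               const arma::vec& x, bool has_beta,
                               const arma::vec& offset,
                               const IntegerVector& sstart,
                               const IntegerVector& slen,
                               const IntegerVector& y,
                               double lambda_delta, double lambda_beta,
                               arma::vec delta, double beta,
                               int maxit, double tol_obj, double tol_grad) {
  int nrow = node.n_elem, nstr = sstart.size();
  int d = t + (has_beta ? 1 : 0);
  arma::vec eta(nrow), p(nrow);
  arma::vec lam(d);
  lam.head(t).fill(lambda_delta);
  if (has_beta) lam[t] = lambda_beta;

  auto fill_eta = [&](const arma::vec& dl, double b) {
    for (int k = 0; k < nrow; ++k)
      eta[k] = dl[node[k]] + (has_beta ? b * x[k] : 0.0) + offset[k];
  };
  auto pen = [&](const arma::vec& dl, double b) {
    double s = 0.5 * lambda_delta * arma::dot(dl, dl);
    if (has_beta) s += 0.5 * lambda_beta * b * b;
    return s;
  };

  fill_eta(delta, beta);
  double obj = cond_loglik_eta(eta, sstart, slen, y) - pen(delta, beta);
  bool converged = false, flagged = false;

  arma::vec g(d), q(t), av(t);
  arma::mat F(d, d);
  for (int iter = 0; iter < maxit; ++iter) {
    softmax_rows(eta, sstart, slen, p);
    g.zeros();
    for (int k = 0; k < nrow; ++k) {
      double r = (y[k] == 1 ? 1.0 : 0.0) - p[k];
      g[node[k]] += r;
      if (has_beta) g[t] += x[k] * r;
    }
    for (int j = 0; j < t; ++j) g[j] -= lambda_delta * delta[j];
    if (has_beta) g[t] -= lambda_beta * beta;
    if (arma::abs(g).max() < tol_grad) { converged = true; break; }

    F.zeros();
    q.zeros(); av.zeros();
    std::vector<int> uniq;
    for (int i = 0; i < nstr; ++i) {
      int a = sstart[i], m = slen[i];
      uniq.clear();
      double sb = 0.0, sb2 = 0.0;
      for (int j = 0; j < m; ++j) {
        int k = a + j, nd = node[k];
        bool seen = false;
        for (size_t u = 0; u < uniq.size(); ++u) if (uniq[u] == nd) { seen = true; break; }
        if (!seen) uniq.push_back(nd);
        q[nd] += p[k];
        if (has_beta) {
          av[nd] += p[k] * x[k];
          sb += p[k] * x[k];
          sb2 += p[k] * x[k] * x[k];
        }
      }
      // block X_s' diag(p_s) X_s - (X_s' p_s)(X_s' p_s)' on the nodes present
      for (size_t u1 = 0; u1 < uniq.size(); ++u1) {
        int k1 = uniq[u1];
        F(k1, k1) += q[k1];
        for (size_t u2 = 0; u2 < uniq.size(); ++u2) {
          int k2 = uniq[u2];
          if (k2 >= k1) F(k1, k2) -= q[k1] * q[k2];
        }
        if (has_beta) F(k1, t) += av[k1] - q[k1] * sb;
      }
      if (has_beta) F(t, t) += sb2 - sb * sb;
      for (size_t u = 0; u < uniq.size(); ++u) { q[uniq[u]] = 0.0; av[uniq[u]] = 0.0; }
    }
    // upper triangle was filled; mirror it
    F = arma::symmatu(F);
    F.diag() += lam + HESS_JITTER;

    arma::vec step;
    if (!arma::solve(step, F, g, arma::solve_opts::likely_sympd)) { flagged = true; break; }
    double tstep = 1.0, new_obj = obj;
    arma::vec dnew = delta;
    double bnew = beta;
    bool improved = false;
    for (int h = 0; h < 30; ++h) {
      dnew = delta + tstep * step.head(t);
      bnew = has_beta ? beta + tstep * step[t] : 0.0;
      fill_eta(dnew, bnew);
      new_obj = cond_loglik_eta(eta, sstart, slen, y) - pen(dnew, bnew);
      if (new_obj >= obj - 1e-14) { improved = true; break; }
      tstep *= 0.5;
    }
    if (!improved) { fill_eta(delta, beta); converged = true; break; }
    if (arma::abs(dnew).max() > COEF_CAP || std::fabs(bnew) > COEF_CAP) {
      dnew = arma::clamp(dnew, -COEF_CAP, COEF_CAP);
      bnew = std::max(-COEF_CAP, std::min(COEF_CAP, bnew));
      fill_eta(dnew, bnew);
      new_obj = cond_loglik_eta(eta, sstart, slen, y) - pen(dnew, bnew);
      flagged = true;
    }
    double dobj = new_obj - obj;
    delta = dnew; beta = bnew; obj = new_obj;
    if (std::fabs(dobj) < tol_obj * (std::fabs(obj) + 1e-10)) { converged = true; break; }
  }
  GroupFit out;
  out.delta = delta; out.beta = beta; out.obj = obj;
  fill_eta(delta, beta);
  out.ll = cond_loglik_eta(eta, sstart, slen, y);
  out.converged = converged; out.flagged = flagged;
  return out;
}

// [[Rcpp::export]]
List cpp_tree_refit(const IntegerVector& node, int t,
                    const arma::vec& x, bool has_beta,
                    const arma::vec& offset,
                    const IntegerVector& sstart, const IntegerVector& slen,
                    const IntegerVector& y,
                    double lambda_delta, double lambda_beta,
                    const arma::vec& delta_init, double beta_init,
                    int maxit, double tol_obj, double tol_grad) {
  arma::ivec nd(node.size());
  for (int k = 0; k < node.size(); ++k) nd[k] = node[k];
  GroupFit f = grouped_newton(nd, t, x, has_beta, offset, sstart, slen, y,
                              lambda_delta, lambda_beta, delta_init, beta_init,
                              maxit, tol_obj, tol_grad);
  return List::create(_["delta"] = f.delta, _["beta"] = f.beta,
                      _["objective"] = f.obj, _["loglik"] = f.ll,
                      _["converged"] = f.converged, _["flagged"] = f.flagged);
}

// ---------------------------------------------------------------------------
// Exhaustive split search: for every (eligible node, candidate variable,
// midpoint threshold), jointly refit all node effects (and beta) on the
// augmented design and return the split with the largest penalized gain.
// Ties broken by lowest variable index, then smallest threshold, then node.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_search_split(const arma::mat& Z,
                      const IntegerVector& node, int t,
                      const arma::vec& x, bool has_beta,
                      const arma::vec& offset,
                      const IntegerVector& sstart, const IntegerVector& slen,
                      const IntegerVector& y,
                      const arma::vec& delta, double beta,
                      double lambda_delta, double lambda_beta,
                      double obj0,
                      const IntegerVector& cand_nodes,   // 0-based node ids
                      const IntegerVector& cand_vars,    // 0-based columns
                      int min_bucket,
                      int search_maxit, double tol_obj, double tol_grad) {
  int nrow = Z.n_rows;
  arma::ivec base(nrow), cand(nrow);
  for (int k = 0; k < nrow; ++k) base[k] = node[k];

  double best_gain = -std::numeric_limits<double>::infinity();
  int best_var = -1, best_node = -1;
  double best_thr = NA_REAL;
  arma::vec best_delta;
  double best_beta = beta;

  std::vector<int> vars(cand_vars.begin(), cand_vars.end());
  std::sort(vars.begin(), vars.end());
  std::vector<int> nds(cand_nodes.begin(), cand_nodes.end());
  std::sort(nds.begin(), nds.end());

  for (int v : vars) {
    for (int nd : nds) {
      // rows in this node and their values on v
      std::vector<std::pair<double,int>> vals;
      for (int k = 0; k < nrow; ++k)
        if (base[k] == nd) vals.push_back(std::make_pair(Z(k, v), k));
      int nk = (int) vals.size();
      if (nk < 2 * min_bucket) continue;
      std::sort(vals.begin(), vals.end());

      // warm start for the first threshold of this (v, node) scan
      arma::vec dw(t + 1);
      dw.head(t) = delta;
      dw[t] = delta[nd];
      double bw = beta;
      cand = base;
      // sweep thresholds left-to-right; rows move from right child (new id t)
      // to left child (id nd) as the threshold increases
      for (int k = 0; k < nk; ++k) cand[vals[k].second] = t;

      int nleft = 0;
      for (int k = 0; k < nk - 1; ++k) {
        cand[vals[k].second] = nd;
        ++nleft;
        if (vals[k + 1].first <= vals[k].first) continue;  // not a distinct gap
        int nright = nk - nleft;
        if (nleft < min_bucket) continue;
        if (nright < min_bucket) break;  // only shrinks further
        double thr = 0.5 * (vals[k].first + vals[k + 1].first);
        GroupFit f = grouped_newton(cand, t + 1, x, has_beta, offset,
                                    sstart, slen, y,
                                    lambda_delta, lambda_beta,
                                    dw, bw, search_maxit, tol_obj, tol_grad);
        dw = f.delta; bw = f.beta;  // sequential warm start
        double gain = f.obj - obj0;
        if (gain > best_gain) {
          best_gain = gain; best_var = v; best_thr = thr; best_node = nd;
          best_delta = f.delta; best_beta = f.beta;
        }
      }
    }
  }
  bool found = best_var >= 0;
  return List::create(_["found"] = found, _["var"] = best_var,
                      _["threshold"] = best_thr, _["node"] = best_node,
                      _["gain"] = best_gain, _["delta"] = best_delta,
                      _["beta"] = best_beta);
}

// [[Rcpp::export]]
double cpp_cond_loglik(const arma::vec& eta,
                       const IntegerVector& sstart, const IntegerVector& slen,
                       const IntegerVector& y) {
  return cond_loglik_eta(eta, sstart, slen, y);
}
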