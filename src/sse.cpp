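// State-dependent speciation-extinction core: coupled E/D ordinary
// differential equations integrated along each branch with an adaptive
// Cash-Karp Runge-Kutta scheme, combined by postorder pruning. The
// workspace is allocated once per likelihood call; branch integration
// works on raw buffers.
#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct SseRates {
  int n;                       // number of states
  std::vector<double> lambda;  // speciation, per state
  std::vector<double> mu;      // extinction, per state
  std::vector<double> q;       // transition matrix, row-major, diag ignored
  std::vector<double> qrow;    // row sums of off-diagonal q
};

// y holds [E_1..E_n, D_1..D_n]
inline void sse_deriv(const SseRates& r, const double* y, double* dy) {
  const int n = r.n;
  for (int i = 0; i < n; ++i) {
    const double Ei = y[i], Di = y[n + i];
    const double tot = r.lambda[i] + r.mu[i] + r.qrow[i];
    double qe = 0.0, qd = 0.0;
    const double* qi = &r.q[i * n];
    for (int j = 0; j < n; ++j) {
      qe += qi[j] * y[j];
      qd += qi[j] * y[n + j];
    }
    dy[i]     = r.mu[i] - tot * Ei + qe + r.lambda[i] * Ei * Ei;
    dy[n + i] = -tot * Di + qd + 2.0 * r.lambda[i] * Ei * Di;
  }
}

// Cash-Karp embedded Runge-Kutta 4(5) coefficients
const double b21 = 1.0 / 5.0;
const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
const double b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0;
const double b51 = -11.0 / 54.0, b52 = 5.0 / 2.0, b53 = -70.0 / 27.0,
             b54 = 35.0 / 27.0;
const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
             b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
             b65 = 253.0 / 4096.0;
const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0, c4 = 125.0 / 594.0,
             c6 = 512.0 / 1771.0;
const double dc1 = c1 - 2825.0 / 27648.0, dc3 = c3 - 18575.0 / 48384.0,
             dc4 = c4 - 13525.0 / 55296.0, dc5 = -277.0 / 14336.0,
             dc6 = c6 - 1.0 / 4.0;

struct Workspace {
  std::vector<double> buf;
  explicit Workspace(int m) : buf(8 * m) {}
};

// Integrate y (length 2n, modified in place) over [0, t].
bool integrate_branch(const SseRates& r, double* y, double t,
                      double rtol, double atol, Workspace& ws) {
  const int m = 2 * r.n;
  if (t <= 0.0) return true;
  double* k1 = &ws.buf[0];
  double* k2 = k1 + m;
  double* k3 = k2 + m;
  double* k4 = k3 + m;
  double* k5 = k4 + m;
  double* k6 = k5 + m;
  double* ytmp = k6 + m;
  double* y5 = ytmp + m;
  double s = 0.0;
  double h = t;
  const double hmin = t * 1e-12;
  long nstep = 0;
  while (s < t) {
    if (++nstep > 2000000L) return false;
    if (h > t - s) h = t - s;
    sse_deriv(r, y, k1);
    for (int i = 0; i < m; ++i) ytmp[i] = y[i] + h * b21 * k1[i];
    sse_deriv(r, ytmp, k2);
    for (int i = 0; i < m; ++i)
      ytmp[i] = y[i] + h * (b31 * k1[i] + b32 * k2[i]);
    sse_deriv(r, ytmp, k3);
    for (int i = 0; i < m; ++i)
      ytmp[i] = y[i] + h * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
    sse_deriv(r, ytmp, k4);
    for (int i = 0; i < m; ++i)
      ytmp[i] = y[i] + h * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i] +
                            b54 * k4[i]);
    sse_deriv(r, ytmp, k5);
    for (int i = 0; i < m; ++i)
      ytmp[i] = y[i] + h * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i] +
                            b64 * k4[i] + b65 * k5[i]);
    sse_deriv(r, ytmp, k6);
    double errmax = 0.0;
    bool bad = false;
    for (int i = 0; i < m; ++i) {
      y5[i] = y[i] + h * (c1 * k1[i] + c3 * k3[i] + c4 * k4[i] + c6 * k6[i]);
      if (!std::isfinite(y5[i])) bad = true;
      const double yerr = h * (dc1 * k1[i] + dc3 * k3[i] + dc4 * k4[i] +
                               dc5 * k5[i] + dc6 * k6[i]);
      const double sc = atol + rtol * std::max(std::fabs(y[i]),
                                               std::fabs(y5[i]));
      const double e = std::fabs(yerr) / sc;
      if (e > errmax) errmax = e;
    }
    if (!bad && errmax <= 1.0) {
      s += h;
      for (int i = 0; i < m; ++i) y[i] = y5[i];
      double fac = 0.9 * std::pow(std::max(errmax, 1e-10), -0.2);
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = bad ? 0.1 : 0.9 * std::pow(errmax, -0.25);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
      if (h < hmin) return false;
    }
  }
  for (int i = 0; i < m; ++i)
    if (!std::isfinite(y[i])) return false;
  // E must stay a probability (small tolerance for roundoff)
  for (int i = 0; i < r.n; ++i) {
    if (y[i] < -1e-6 || y[i] > 1.0 + 1e-6) return false;
    if (y[i] < 0.0) y[i] = 0.0;
    if (y[i] > 1.0) y[i] = 1.0;
  }
  return true;
}

SseRates make_rates(NumericVector lambda, NumericVector mu,
                    NumericMatrix Q) {
  SseRates r;
  r.n = lambda.size();
  r.lambda.assign(lambda.begin(), lambda.end());
  r.mu.assign(mu.begin(), mu.end());
  r.q.assign(r.n * r.n, 0.0);
  r.qrow.assign(r.n, 0.0);
  for (int i = 0; i < r.n; ++i)
    for (int j = 0; j < r.n; ++j) {
      if (i == j) continue;
      r.q[i * r.n + j] = Q(i, j);
      r.qrow[i] += Q(i, j);
    }
  return r;
}

}  // namespace

// [[Rcpp::export]]
List sse_integrate_cpp(NumericVector lambda, NumericVector mu,
                       NumericMatrix Q, NumericVector E0, NumericVector D0,
                       double t, double rtol, double atol) {
  SseRates r = make_rates(lambda, mu, Q);
  Workspace ws(2 * r.n);
  std::vector<double> y(2 * r.n);
  for (int i = 0; i < r.n; ++i) {
    y[i] = E0[i];
    y[r.n + i] = D0[i];
  }
  bool ok = integrate_branch(r, y.data(), t, rtol, atol, ws);
  NumericVector E(r.n), D(r.n);
  for (int i = 0; i < r.n; ++i) {
    E[i] = y[i];
    D[i] = y[r.n + i];
  }
  return List::create(_["E"] = E, _["D"] = D, _["ok"] = ok);
}

// Postorder pruning likelihood.
//   edge: 2-column matrix (parent, child), 1-based node ids in ape
//     convention (tips 1..ntip, root ntip+1), rows already in postorder;
//   tipD: ntip x nstate initial D at tips (sampling fraction times state
//     indicator); tipE: nstate vector of 1 - f;
//   rootw: nstate root weights; condition: divide by sum_i w_i lambda_i
//     (1-E_i)^2 (survival conditioning);
//   constrain_node: 1-based node id whose D is masked by `allowed` after
//     child combination (0 = none), used for marginal reconstructions.
// [[Rcpp::export]]
List sse_loglik_cpp(IntegerMatrix edge, NumericVector edge_length, int ntip,
                    NumericMatrix tipD, NumericVector tipE,
                    NumericVector lambda, NumericVector mu, NumericMatrix Q,
                    NumericVector rootw, bool condition, double rtol,
                    double atol, int constrain_node,
                    NumericVector allowed) {
  SseRates r = make_rates(lambda, mu, Q);
  const int n = r.n;
  const int nedge = edge.nrow();
  const int nnode = ntip + nedge / 2 + 2;  // generous bound on node ids
  Workspace ws(2 * n);
  std::vector<double> D(nnode * n), E(nnode * n), y(2 * n);
  std::vector<int> nchild(nnode, 0);
  std::vector<bool> seen(nnode, false);
  double loglik_scale = 0.0;

  for (int i = 0; i < ntip; ++i) {
    seen[i] = true;
    for (int s = 0; s < n; ++s) {
      D[i * n + s] = tipD(i, s);
      E[i * n + s] = tipE[s];
    }
  }

  int root = -1;
  for (int e = 0; e < nedge; ++e) {
    const int parent = edge(e, 0) - 1;
    const int child = edge(e, 1) - 1;
    root = parent;  // postorder: last parent seen is the root
    if (child >= ntip && nchild[child] != 2)
      return List::create(_["loglik"] = R_NegInf,
                          _["error"] = "polytomy or unresolved node");
    const bool mask_child = (child + 1 == constrain_node);
    for (int s = 0; s < n; ++s) {
      y[s] = E[child * n + s];
      y[n + s] = D[child * n + s] * (mask_child ? allowed[s] : 1.0);
    }
    if (!integrate_branch(r, y.data(), edge_length[e], rtol, atol, ws))
      return List::create(_["loglik"] = R_NegInf,
                          _["error"] = "integration failure",
                          _["branch"] = e + 1);
    double sum = 0.0;
    for (int s = 0; s < n; ++s) sum += y[n + s];
    if (!(sum > 0.0) || !std::isfinite(sum))
      return List::create(_["loglik"] = R_NegInf,
                          _["error"] = "vanishing likelihood",
                          _["branch"] = e + 1);
    if (!seen[parent]) {
      seen[parent] = true;
      for (int s = 0; s < n; ++s) {
        D[parent * n + s] = 1.0;
        E[parent * n + s] = 0.0;
      }
    }
    for (int s = 0; s < n; ++s) {
      D[parent * n + s] *= y[n + s] / sum;
      E[parent * n + s] = y[s];
    }
    loglik_scale += std::log(sum);
    nchild[parent] += 1;
    if (nchild[parent] == 2) {  // combine at a (binary) speciation node
      double psum = 0.0;
      const bool mask = (parent + 1 == constrain_node);
      for (int s = 0; s < n; ++s) {
        D[parent * n + s] *= r.lambda[s] * (mask ? allowed[s] : 1.0);
        psum += D[parent * n + s];
      }
      if (!(psum > 0.0) || !std::isfinite(psum))
        return List::create(_["loglik"] = R_NegInf,
                            _["error"] = "vanishing likelihood at node",
                            _["branch"] = parent + 1);
      for (int s = 0; s < n; ++s) D[parent * n + s] /= psum;
      loglik_scale += std::log(psum);
    } else if (nchild[parent] > 2) {
      return List::create(_["loglik"] = R_NegInf,
                          _["error"] = "polytomy");
    }
  }
  if (root < 0 || !seen[root])
    return List::create(_["loglik"] = R_NegInf, _["error"] = "empty tree");

  double lik = 0.0;
  for (int s = 0; s < n; ++s) lik += rootw[s] * D[root * n + s];
  if (condition) {
    double cond = 0.0;
    for (int s = 0; s < n; ++s) {
      const double surv = 1.0 - E[root * n + s];
      cond += rootw[s] * r.lambda[s] * surv * surv;
    }
    if (cond > 0.0) lik /= cond;
  }
  if (!(lik > 0.0) || !std::isfinite(lik))
    return List::create(_["loglik"] = R_NegInf,
                        _["error"] = "non-positive root likelihood");
  NumericVector Droot(n), Eroot(n);
  for (int s = 0; s < n; ++s) {
    Droot[s] = D[root * n + s];
    Eroot[s] = E[root * n + s];
  }
  return List::create(_["loglik"] = std::log(lik) + loglik_scale,
                      _["D_root"] = Droot, _["E_root"] = Eroot);
}
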