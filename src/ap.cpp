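#include <Rcpp.h>
#include <cfloat>
#include <vector>
using namespace Rcpp;

// Cache-blocked transpose: dst[k*n + i] = src[i*n + k].
static void blocked_transpose(const double* src, double* dst, int n) {
  const int B = 64;
  for (int ib = 0; ib < n; ib += B) {
    int imax = std::min(ib + B, n);
    for (int kb = 0; kb < n; kb += B) {
      int kmax = std::min(kb + B, n);
      for (int i = ib; i < imax; ++i)
        for (int k = kb; k < kmax; ++k)
          dst[(size_t)k * n + i] = src[(size_t)i * n + k];
    }
  }
}

// Affinity-propagation message passing on a dense similarity matrix.
//
// S must be square with its diagonal already set to the preference(s).
// Messages are damped as new = damping * old + (1 - damping) * computed.
// Convergence: the exemplar indicator vector (r(k,k) + a(k,k) > 0) is
// unchanged for conv_iter consecutive iterations.
//
// Internally the responsibility update streams row-contiguous buffers and
// the availability update column-contiguous ones, with blocked transposes
// in between, so every pass over the O(n^2) messages is sequential.
//
// Returns the exemplar indices (1-based), iteration count, convergence flag
// and the final criterion vector diag(A) + diag(R).
// [[Rcpp::export]]
List ap_core(NumericMatrix S, double damping, int max_iter, int conv_iter) {
  const int n = S.nrow();
  if (n != S.ncol()) stop("similarity matrix must be square");
  if (n == 0) stop("empty similarity matrix");
  const size_t nn = (size_t)n * n;

  // Sr[i*n + k] = s(i,k): row i contiguous
  std::vector<double> Sr(nn), Rr(nn, 0.0), Rc(nn, 0.0),
                      Ar(nn, 0.0), Ac(nn, 0.0);
  blocked_transpose(REAL(S), Sr.data(), n); // column-major -> row-contiguous

  std::vector<int> flag(n, 0), old_flag(n, -1);
  int stable = 0, iter = 0;
  bool converged = false;
  const double keep = damping, upd = 1.0 - damping;

  for (iter = 1; iter <= max_iter; ++iter) {
    // responsibilities: r(i,k) <- s(i,k) - max_{k' != k} [a(i,k') + s(i,k')]
    for (int i = 0; i < n; ++i) {
      const double* ai = &Ar[(size_t)i * n];
      const double* si = &Sr[(size_t)i * n];
      double* ri = &Rr[(size_t)i * n];
      double m1 = -DBL_MAX, m2 = -DBL_MAX;
      int i1 = -1;
      for (int k = 0; k < n; ++k) {
        double v = ai[k] + si[k];
        if (v > m1) { m2 = m1; m1 = v; i1 = k; }
        else if (v > m2) { m2 = v; }
      }
      for (int k = 0; k < n; ++k) {
        double rnew = si[k] - (k == i1 ? m2 : m1);
        ri[k] = keep * ri[k] + upd * rnew;
      }
    }
    blocked_transpose(Rr.data(), Rc.data(), n);
    // availabilities:
    //   a(i,k) <- min(0, r(k,k) + sum_{i' not in {i,k}} max(0, r(i',k)))
    //   a(k,k) <- sum_{i' != k} max(0, r(i',k))
    for (int k = 0; k < n; ++k) {
      const double* rk = &Rc[(size_t)k * n];
      double* ak = &Ac[(size_t)k * n];
      double pos = 0.0;
      for (int i = 0; i < n; ++i)
        if (i != k) pos += std::max(0.0, rk[i]);
      const double rkk = rk[k];
      for (int i = 0; i < n; ++i) {
        double anew;
        if (i == k) {
          anew = pos;
        } else {
          anew = rkk + pos - std::max(0.0, rk[i]);
          if (anew > 0.0) anew = 0.0;
        }
        ak[i] = keep * ak[i] + upd * anew;
      }
    }
    blocked_transpose(Ac.data(), Ar.data(), n);
    // exemplar indicator and convergence bookkeeping
    bool same = true;
    for (int k = 0; k < n; ++k) {
      size_t d = (size_t)k * n + k;
      int e = (Ac[d] + Rr[d]) > 0.0 ? 1 : 0;
      if (e != old_flag[k]) same = false;
      flag[k] = e;
    }
    std::copy(flag.begin(), flag.end(), old_flag.begin());
    if (same) {
      if (++stable >= conv_iter) { converged = true; break; }
    } else {
      stable = 0;
    }
    if (iter % 64 == 0) Rcpp::checkUserInterrupt();
  }
  if (iter > max_iter) iter = max_iter;

  std::vector<int> exemplars;
  NumericVector crit(n);
  for (int k = 0; k < n; ++k) {
    size_t d = (size_t)k * n + k;
    crit[k] = Ac[d] + Rr[d];
    if (flag[k]) exemplars.push_back(k + 1);
  }
  return List::create(_["exemplars"] = wrap(exemplars),
                      _["iterations"] = iter,
                      _["converged"] = converged,
                      _["criterion"] = crit);
}
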