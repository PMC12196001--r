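#include <Rcpp.h>
using namespace Rcpp;

// Dynamic Time Warping under the symmetric2 step pattern:
//   D(1,1) = c(1,1)
//   D(i,j) = min(D(i-1,j-1) + 2 c(i,j), D(i-1,j) + c(i,j), D(i,j-1) + c(i,j))
// with local cost c(i,j) = |x_i - y_j| and an optional Sakoe-Chiba band
// |i - j| <= band on the (1-based) indices. The normalization constant of
// this pattern is N + M, the combined length of the two series.
//
// Distance-only queries use a two-row rolling buffer; full-matrix storage is
// kept only when the warping path is requested. Backtracking prefers the
// diagonal step on ties so the reported path is deterministic.

static double dtw_total_rolling(const double* x, const double* y,
                                int n, int m, int band) {
  const double INF = R_PosInf;
  std::vector<double> prev(m, INF), cur(m, INF);
  for (int i = 0; i < n; ++i) {
    int jlo = 0, jhi = m - 1;
    if (band >= 0) {
      jlo = std::max(0, i - band);
      jhi = std::min(m - 1, i + band);
      if (jlo > jhi) return INF;
    }
    std::fill(cur.begin(), cur.end(), INF);
    const double xi = x[i];
    for (int j = jlo; j <= jhi; ++j) {
      const double c = std::abs(xi - y[j]);
      double best;
      if (i == 0 && j == 0) {
        best = c;
      } else {
        best = INF;
        if (i > 0 && j > 0 && prev[j - 1] < INF) best = prev[j - 1] + 2.0 * c;
        if (i > 0 && prev[j] < INF) {
          const double v = prev[j] + c;
          if (v < best) best = v;
        }
        if (j > 0 && cur[j - 1] < INF) {
          const double v = cur[j - 1] + c;
          if (v < best) best = v;
        }
      }
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// [[Rcpp::export]]
List dtw_cpp(NumericVector x, NumericVector y, int band = -1,
             bool keep_path = false) {
  const int n = x.size(), m = y.size();
  const double INF = R_PosInf;

  if (!keep_path) {
    double total = dtw_total_rolling(REAL(x), REAL(y), n, m, band);
    return List::create(_["total"] = total, _["feasible"] = R_finite(total));
  }

  std::vector<double> D((size_t)n * m, INF);
  auto at = [m](int i, int j) { return (size_t)i * m + j; };
  for (int i = 0; i < n; ++i) {
    int jlo = 0, jhi = m - 1;
    if (band >= 0) {
      jlo = std::max(0, i - band);
      jhi = std::min(m - 1, i + band);
    }
    for (int j = jlo; j <= jhi; ++j) {
      double c = std::abs(x[i] - y[j]);
      if (i == 0 && j == 0) { D[at(i, j)] = c; continue; }
      double best = INF;
      if (i > 0 && j > 0 && D[at(i - 1, j - 1)] < INF)
        best = D[at(i - 1, j - 1)] + 2.0 * c;
      if (i > 0 && D[at(i - 1, j)] < INF)
        best = std::min(best, D[at(i - 1, j)] + c);
      if (j > 0 && D[at(i, j - 1)] < INF)
        best = std::min(best, D[at(i, j - 1)] + c);
      D[at(i, j)] = best;
    }
  }

  double total = D[at(n - 1, m - 1)];
  if (!R_finite(total)) {
    return List::create(_["total"] = total, _["feasible"] = false);
  }

  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i + 1); pj.push_back(j + 1);
  while (i > 0 || j > 0) {
    double c = std::abs(x[i] - y[j]);
    double here = D[at(i, j)];
    // diagonal preferred on ties
    if (i > 0 && j > 0 && D[at(i - 1, j - 1)] < INF &&
        here == D[at(i - 1, j - 1)] + 2.0 * c) {
      --i; --j;
    } else if (i > 0 && D[at(i - 1, j)] < INF &&
               here == D[at(i - 1, j)] + c) {
      --i;
    } else {
      --j;
    }
    pi.push_back(i + 1); pj.push_back(j + 1);
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  return List::create(_["total"] = total, _["feasible"] = true,
                      _["path_i"] = wrap(pi), _["path_j"] = wrap(pj));
}
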