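#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Kraskov-style k-nearest-neighbour estimator of the conditional mutual
// information I(y[n]; X_m(n - l*dn) | Y_h(n - dn)) in nats (Frenzel-Pompe
// variant of KSG algorithm 1, max-norm):
//   TE = psi(k) + < psi(n_z + 1) - psi(n_yz + 1) - psi(n_xz + 1) >
// where z is the conditioning target past, yz the (target, target-past)
// subspace and xz the (source-past, target-past) subspace; counts are taken
// within the distance to the k-th neighbour in the full joint space.
//
// The interaction delay l is scanned inside the kernel: the target-side
// distances do not depend on l and are computed once. All candidates use
// the common alignment implied by the largest l so the estimates are
// comparable across the scan.

static double digamma_(double x) {
  double result = 0.0;
  while (x < 6.0) { result -= 1.0 / x; x += 1.0; }
  const double x1 = 1.0 / x, x2 = x1 * x1;
  result += std::log(x) - 0.5 * x1
            - x2 * (1.0 / 12.0 - x2 * (1.0 / 120.0 - x2 / 252.0));
  return result;
}

// [[Rcpp::export(name = ".te_ksg_scan")]]
NumericVector te_ksg_scan(NumericVector x, NumericVector y, int m, int h,
                          int dn, IntegerVector l_set, int k) {
  const int n = x.size();
  const int l_max = *std::max_element(l_set.begin(), l_set.end());
  const int start = std::max((l_max + m - 1) * dn, h * dn);
  const int N = n - start;
  if (N <= k + 1) stop("insufficient samples for the chosen embedding");

  // target-side embedded coordinates (l-independent)
  std::vector<double> yv(N);
  std::vector<double> Yp(static_cast<size_t>(N) * h);
  for (int i = 0; i < N; ++i) {
    const int t = start + i;
    yv[i] = y[t];
    for (int j = 0; j < h; ++j)
      Yp[static_cast<size_t>(i) * h + j] = y[t - (j + 1) * dn];
  }
  // pairwise distances in the y and Y-past subspaces, cached
  std::vector<float> Dy(static_cast<size_t>(N) * N);
  std::vector<float> Dz(static_cast<size_t>(N) * N);
  for (int i = 0; i < N; ++i) {
    for (int q = 0; q < N; ++q) {
      Dy[static_cast<size_t>(i) * N + q] = std::fabs(yv[i] - yv[q]);
      double b = 0.0;
      for (int j = 0; j < h; ++j) {
        const double d = std::fabs(Yp[static_cast<size_t>(i) * h + j] -
                                   Yp[static_cast<size_t>(q) * h + j]);
        if (d > b) b = d;
      }
      Dz[static_cast<size_t>(i) * N + q] = b;
    }
  }

  NumericVector out(l_set.size());
  std::vector<double> Xp(static_cast<size_t>(N) * m);
  std::vector<double> dx(N), djoint(N), tmp(N);
  for (int li = 0; li < l_set.size(); ++li) {
    const int l = l_set[li];
    for (int i = 0; i < N; ++i) {
      const int t = start + i;
      for (int j = 0; j < m; ++j)
        Xp[static_cast<size_t>(i) * m + j] = x[t - (l + j) * dn];
    }
    double acc = 0.0;
    for (int i = 0; i < N; ++i) {
      const float *dyi = &Dy[static_cast<size_t>(i) * N];
      const float *dzi = &Dz[static_cast<size_t>(i) * N];
      const double *xi = &Xp[static_cast<size_t>(i) * m];
      for (int q = 0; q < N; ++q) {
        const double *xq = &Xp[static_cast<size_t>(q) * m];
        double c = 0.0;
        for (int j = 0; j < m; ++j) {
          const double d = std::fabs(xi[j] - xq[j]);
          if (d > c) c = d;
        }
        dx[q] = c;
        double dj = dzi[q] > dyi[q] ? dzi[q] : dyi[q];
        if (c > dj) dj = c;
        djoint[q] = dj;
      }
      std::copy(djoint.begin(), djoint.end(), tmp.begin());
      std::nth_element(tmp.begin(), tmp.begin() + k, tmp.end());
      const double eps = tmp[k];  // self occupies rank 0
      int n_z = 0, n_yz = 0, n_xz = 0;
      for (int q = 0; q < N; ++q) {
        if (q == i) continue;
        const double dzq = dzi[q];
        if (dzq < eps) {
          ++n_z;
          if (dyi[q] < eps) ++n_yz;   // max(dz, dy) < eps given dz < eps
          if (dx[q] < eps) ++n_xz;
        }
      }
      acc += digamma_(n_z + 1) - digamma_(n_yz + 1) - digamma_(n_xz + 1);
    }
    out[li] = digamma_(k) + acc / N;
  }
  return out;
}
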