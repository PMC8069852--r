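#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Forward-Euler integration of a network of four-population neural mass
// regions. Each region holds eight second-order synaptic filters
//   w' = G*omega*u - 2*omega*w - omega^2*y ,  y' = w
// feeding the population potentials
//   v_p = y[pe] - y[ps] - y[pf]
//   v_e = y[ee]
//   v_s = y[se]
//   v_f = y[fe] - y[fs] - y[ff]
// Filter order (per region): 0 p<-exc, 1 p<-slow, 2 p<-fast, 3 e<-exc,
// 4 s<-exc, 5 f<-exc, 6 f<-slow, 7 f<-fast.
// Long-range drive and external input/noise enter the glutamatergic filters:
// u_p (into filter 0) = I_p + noise + sum_k Wexc[k,j] z_p[k]
// u_f (into filter 5) = I_f        + sum_k Winh[k,j] z_p[k]
// Noise is drawn from R's RNG so that set.seed() fully determines a run.

static inline double sigm(double v, double e0, double r, double v0) {
  return 2.0 * e0 / (1.0 + std::exp(r * (v0 - v)));
}

// [[Rcpp::export(name = ".nmm_integrate")]]
List nmm_integrate(NumericMatrix C,        // 8 x nroi internal couplings
                   NumericVector Ge, NumericVector we,
                   NumericVector Gs, NumericVector ws,
                   NumericVector Gf, NumericVector wf,
                   NumericVector e0, NumericVector r, NumericVector v0,
                   NumericVector Ip, NumericVector If,
                   NumericMatrix Wexc,     // nroi x nroi, [source, target]
                   NumericMatrix Winh,
                   NumericVector noise_sd, // per-step SD, per region
                   double dt, int nsteps, int keep_every) {
  const int n = Ge.size();
  if (C.nrow() != 8 || C.ncol() != n)
    stop("C must be an 8 x nroi matrix");
  const int nkeep = nsteps / keep_every;
  NumericMatrix vp(nkeep, n), zp(nkeep, n);

  std::vector<double> y(8 * n, 0.0), w(8 * n, 0.0);
  std::vector<double> G(8 * n), om(8 * n);
  for (int j = 0; j < n; ++j) {
    const int o = 8 * j;
    // excitatory filters 0,3,4,5 ; slow 1,6 ; fast 2,7
    G[o + 0] = Ge[j]; om[o + 0] = we[j];
    G[o + 3] = Ge[j]; om[o + 3] = we[j];
    G[o + 4] = Ge[j]; om[o + 4] = we[j];
    G[o + 5] = Ge[j]; om[o + 5] = we[j];
    G[o + 1] = Gs[j]; om[o + 1] = ws[j];
    G[o + 6] = Gs[j]; om[o + 6] = ws[j];
    G[o + 2] = Gf[j]; om[o + 2] = wf[j];
    G[o + 7] = Gf[j]; om[o + 7] = wf[j];
  }

  std::vector<double> z_p(n), z_e(n), z_s(n), z_f(n), u(8 * n);
  int kept = 0;
  for (int s = 0; s < nsteps; ++s) {
    // population potentials and rates
    for (int j = 0; j < n; ++j) {
      const int o = 8 * j;
      const double vpj = y[o + 0] - y[o + 1] - y[o + 2];
      const double vej = y[o + 3];
      const double vsj = y[o + 4];
      const double vfj = y[o + 5] - y[o + 6] - y[o + 7];
      if (!std::isfinite(vpj))
        stop("state diverged (non-finite v_p) at step %d in region %d",
             s + 1, j + 1);
      z_p[j] = sigm(vpj, e0[j], r[j], v0[j]);
      z_e[j] = sigm(vej, e0[j], r[j], v0[j]);
      z_s[j] = sigm(vsj, e0[j], r[j], v0[j]);
      z_f[j] = sigm(vfj, e0[j], r[j], v0[j]);
      if ((s % keep_every) == 0 && kept < nkeep) {
        vp(kept, j) = vpj;
        zp(kept, j) = z_p[j];
      }
    }
    if ((s % keep_every) == 0) ++kept;

    // filter inputs
    for (int j = 0; j < n; ++j) {
      const int o = 8 * j;
      double lr_exc = 0.0, lr_inh = 0.0;
      for (int k = 0; k < n; ++k) {
        lr_exc += Wexc(k, j) * z_p[k];
        lr_inh += Winh(k, j) * z_p[k];
      }
      const double np = (noise_sd[j] > 0.0) ? noise_sd[j] * norm_rand() : 0.0;
      u[o + 0] = C(0, j) * z_e[j] + Ip[j] + np + lr_exc;
      u[o + 1] = C(1, j) * z_s[j];
      u[o + 2] = C(2, j) * z_f[j];
      u[o + 3] = C(3, j) * z_p[j];
      u[o + 4] = C(4, j) * z_p[j];
      u[o + 5] = C(5, j) * z_p[j] + If[j] + lr_inh;
      u[o + 6] = C(6, j) * z_s[j];
      u[o + 7] = C(7, j) * z_f[j];
    }

    // Euler update of all second-order filters
    for (int i = 0; i < 8 * n; ++i) {
      const double dw = G[i] * om[i] * u[i] - 2.0 * om[i] * w[i]
                        - om[i] * om[i] * y[i];
      y[i] += dt * w[i];
      w[i] += dt * dw;
    }
  }

  return List::create(_["v_p"] = vp, _["z_p"] = zp);
}
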