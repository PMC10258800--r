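#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double mi(double d, double box) {
  return d - box * std::nearbyint(d / box);
}

// Unwrap wrapped coordinates by accumulating minimum-image frame-to-frame
// displacements (valid while per-snapshot displacements stay below box/2).
// [[Rcpp::export(".unwrap_cpp")]]
NumericVector unwrap_cpp(NumericVector coords, double box) {
  IntegerVector dim = coords.attr("dim");
  int n = dim[0], nf = dim[2];
  NumericVector out(Dimension(n, 3, nf));
  R_xlen_t stride = (R_xlen_t)3 * n;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) out[i + (R_xlen_t)k * n] = coords[i + (R_xlen_t)k * n];
  for (int f = 1; f < nf; ++f) {
    R_xlen_t o1 = (R_xlen_t)f * stride, o0 = o1 - stride;
    for (int k = 0; k < 3; ++k) {
      R_xlen_t ok = (R_xlen_t)k * n;
      for (int i = 0; i < n; ++i) {
        double d = mi(coords[i + ok + o1] - coords[i + ok + o0], box);
        out[i + ok + o1] = out[i + ok + o0] + d;
      }
    }
  }
  return out;
}

// Shell-resolved intermolecular dipolar correlation function
//   G_s(t) = < sum_{k in shell s at t0} P2(cos theta_k) / (r_k(t0)^3 r_k(t0+t)^3) >_{t0}
// fw: wrapped fluorine coords (nF x 3 x nT), hw: wrapped reference-hydrogen
// path (nT x 3).  Pairs are selected by origin-frame distance (min image);
// lagged separations follow the unwrapped relative displacement so the
// dipolar vector is min-image consistent.  origins/lags are 0-based frame
// indices; shell_breaks are ascending upper bounds, last = cutoff.
// [[Rcpp::export(".dipolar_corr_cpp")]]
List dipolar_corr_cpp(NumericVector fw, NumericMatrix hw, double box,
                      IntegerVector origins, IntegerVector lags,
                      NumericVector shell_breaks) {
  IntegerVector dim = fw.attr("dim");
  const int nF = dim[0], nT = dim[2];
  const int nL = lags.size(), nS = shell_breaks.size();
  const double cutoff = shell_breaks[nS - 1];
  const R_xlen_t stride = (R_xlen_t)3 * nF;

  NumericVector funw = unwrap_cpp(fw, box);
  // unwrap the hydrogen path
  std::vector<double> hx(nT), hy(nT), hz(nT);
  hx[0] = hw(0, 0); hy[0] = hw(0, 1); hz[0] = hw(0, 2);
  for (int f = 1; f < nT; ++f) {
    hx[f] = hx[f - 1] + mi(hw(f, 0) - hw(f - 1, 0), box);
    hy[f] = hy[f - 1] + mi(hw(f, 1) - hw(f - 1, 1), box);
    hz[f] = hz[f - 1] + mi(hw(f, 2) - hw(f - 1, 2), box);
  }

  std::vector<double> acc(nL * nS, 0.0), accsq(nL * nS, 0.0);
  std::vector<double> npair(nL * nS, 0.0);
  std::vector<double> cur(nL * nS);
  std::vector<double> v0x(nF), v0y(nF), v0z(nF), ir03(nF), r02(nF);
  std::vector<int> sel(nF), shl(nF);
  int n_origins = 0;

  for (int oi = 0; oi < origins.size(); ++oi) {
    int t0 = origins[oi];
    R_xlen_t o0 = (R_xlen_t)t0 * stride;
    int nsel = 0;
    for (int i = 0; i < nF; ++i) {
      double dx = mi(fw[i + o0] - hw(t0, 0), box);
      double dy = mi(fw[i + nF + o0] - hw(t0, 1), box);
      double dz = mi(fw[i + 2L * nF + o0] - hw(t0, 2), box);
      double r2 = dx * dx + dy * dy + dz * dz;
      double r = std::sqrt(r2);
      if (r <= cutoff && r > 0) {
        int s = 0;
        while (r >= shell_breaks[s]) ++s;  // r < cutoff guarantees s < nS
        sel[nsel] = i; shl[nsel] = s;
        v0x[nsel] = dx; v0y[nsel] = dy; v0z[nsel] = dz;
        r02[nsel] = r2; ir03[nsel] = 1.0 / (r2 * r);
        ++nsel;
      }
    }
    if (nsel == 0) continue;
    ++n_origins;
    std::fill(cur.begin(), cur.end(), 0.0);
    for (int li = 0; li < nL; ++li) {
      int t1 = t0 + lags[li];
      R_xlen_t o1 = (R_xlen_t)t1 * stride;
      double hdx = hx[t1] - hx[t0], hdy = hy[t1] - hy[t0],
             hdz = hz[t1] - hz[t0];
      for (int j = 0; j < nsel; ++j) {
        int i = sel[j];
        double vx = v0x[j] + funw[i + o1] - funw[i + o0] - hdx;
        double vy = v0y[j] + funw[i + nF + o1] - funw[i + nF + o0] - hdy;
        double vz = v0z[j] + funw[i + 2L * nF + o1] - funw[i + 2L * nF + o0] - hdz;
        double rt2 = vx * vx + vy * vy + vz * vz;
        double rt = std::sqrt(rt2);
        double dot = vx * v0x[j] + vy * v0y[j] + vz * v0z[j];
        // P2(cos th)/(r0^3 rt^3) = (1.5 dot^2 - 0.5 r0^2 rt^2)/(r0^5 rt^5)
        double irt3 = 1.0 / (rt2 * rt);
        double term = (1.5 * dot * dot - 0.5 * r02[j] * rt2) * ir03[j] *
                      irt3 / (r02[j] * rt2);
        int idx = li * nS + shl[j];
        cur[idx] += term;
        npair[idx] += 1.0;
      }
    }
    for (int q = 0; q < nL * nS; ++q) {
      acc[q] += cur[q];
      accsq[q] += cur[q] * cur[q];
    }
  }

  NumericMatrix G(nL, nS), SE(nL, nS), NP(nL, nS);
  for (int li = 0; li < nL; ++li)
    for (int s = 0; s < nS; ++s) {
      int q = li * nS + s;
      if (n_origins > 0) {
        double m = acc[q] / n_origins;
        G(li, s) = m;
        NP(li, s) = npair[q];
        if (n_origins > 1) {
          double var = (accsq[q] - n_origins * m * m) / (n_origins - 1.0);
          SE(li, s) = std::sqrt(std::max(var, 0.0) / n_origins);
        } else {
          SE(li, s) = NA_REAL;
        }
      }
    }
  return List::create(Named("G") = G, Named("se") = SE,
                      Named("n_pairs") = NP,
                      Named("n_origins") = n_origins);
}
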