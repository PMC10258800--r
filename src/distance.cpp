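#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double mi(double d, double box) {
  return d - box * std::nearbyint(d / box);
}

// Minimum-image distance of selected atoms (0-based indices) to a reference
// atom, per frame.  Returns an (nT x nsel) matrix in nm.
// [[Rcpp::export(".dist_to_ref_cpp")]]
NumericMatrix dist_to_ref_cpp(NumericVector coords, int ref,
                              IntegerVector sel, double box) {
  IntegerVector dim = coords.attr("dim");
  const int nA = dim[0], nT = dim[2];
  const int ns = sel.size();
  const R_xlen_t stride = (R_xlen_t)3 * nA;
  NumericMatrix out(nT, ns);
  for (int f = 0; f < nT; ++f) {
    R_xlen_t off = (R_xlen_t)f * stride;
    double rx = coords[ref + off], ry = coords[ref + nA + off],
           rz = coords[ref + 2L * nA + off];
    for (int j = 0; j < ns; ++j) {
      int i = sel[j];
      double dx = mi(coords[i + off] - rx, box);
      double dy = mi(coords[i + nA + off] - ry, box);
      double dz = mi(coords[i + 2L * nA + off] - rz, box);
      out(f, j) = std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  }
  return out;
}

// Mean squared displacement per atom over time origins (origin stride
// given), for a set of lags (in frames), from *unwrapped* coordinates.
// Returns an (nlag x natom) matrix of nm^2.
// [[Rcpp::export(".msd_cpp")]]
NumericMatrix msd_cpp(NumericVector unw, IntegerVector lags,
                      int origin_stride) {
  IntegerVector dim = unw.attr("dim");
  const int nA = dim[0], nT = dim[2];
  const int nL = lags.size();
  const R_xlen_t stride = (R_xlen_t)3 * nA;
  NumericMatrix out(nL, nA);
  for (int li = 0; li < nL; ++li) {
    int lag = lags[li];
    for (int i = 0; i < nA; ++i) {
      double s = 0.0;
      int cnt = 0;
      for (int t0 = 0; t0 + lag < nT; t0 += origin_stride) {
        R_xlen_t o0 = (R_xlen_t)t0 * stride,
                 o1 = (R_xlen_t)(t0 + lag) * stride;
        double dx = unw[i + o1] - unw[i + o0];
        double dy = unw[i + nA + o1] - unw[i + nA + o0];
        double dz = unw[i + 2L * nA + o1] - unw[i + 2L * nA + o0];
        s += dx * dx + dy * dy + dz * dz;
        ++cnt;
      }
      out(li, i) = cnt > 0 ? s / cnt : NA_REAL;
    }
  }
  return out;
}

// Edges (i,j) of the molecule-contact graph in one frame: molecules are
// linked when their minimum interatomic (min-image) distance <= cutoff.
// mol: 1-based molecule id per atom.  Returns a 2-column matrix of mol ids.
// [[Rcpp::export(".contact_edges_cpp")]]
IntegerMatrix contact_edges_cpp(NumericMatrix frame, IntegerVector mol,
                                double box, double cutoff) {
  const int nA = frame.nrow();
  const double c2 = cutoff * cutoff;
  std::vector<int> ei, ej;
  for (int a = 0; a < nA; ++a) {
    for (int b2 = a + 1; b2 < nA; ++b2) {
      if (mol[a] == mol[b2]) continue;
      double dx = mi(frame(a, 0) - frame(b2, 0), box);
      if (dx * dx > c2) continue;
      double dy = mi(frame(a, 1) - frame(b2, 1), box);
      double dz = mi(frame(a, 2) - frame(b2, 2), box);
      if (dx * dx + dy * dy + dz * dz <= c2) {
        int mi_ = mol[a], mj = mol[b2];
        if (mi_ > mj) std::swap(mi_, mj);
        ei.push_back(mi_);
        ej.push_back(mj);
      }
    }
  }
  IntegerMatrix out(ei.size(), 2);
  for (size_t k = 0; k < ei.size(); ++k) {
    out(k, 0) = ei[k];
    out(k, 1) = ej[k];
  }
  return out;
}
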