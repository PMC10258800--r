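#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double wrap1(double x, double box) {
  x -= box * std::floor(x / box);
  if (x >= box) x -= box;
  return x;
}

// piecewise-constant diffusion scale: scales[i] applies for r < breaks[i]
// (breaks ascending); unit scale beyond the last break
static inline double profile_scale(double r, const NumericVector& breaks,
                                   const NumericVector& scales) {
  for (int i = 0; i < breaks.size(); ++i)
    if (r < breaks[i]) return scales[i];
  return 1.0;
}

// Brownian random walk of n independent point particles in a cubic periodic
// box with a reflecting sphere of radius b at the box centre.  Optional
// "sticky" mode: a particle whose centre enters the annulus [b, bound_outer]
// binds (diffusion scaled by bound_scale, confined to the annulus by
// specular reflection at both radii) and unbinds as a Poisson process with
// rate k_off; after unbinding it is refractory until its centre leaves the
// capture radius.  Uses R's RNG stream (driven by set.seed()).
// [[Rcpp::export(".gen_species_cpp")]]
List gen_species_cpp(int n, int n_frames, int substeps, double dt, double D,
                     double box, double b, NumericVector prof_breaks,
                     NumericVector prof_scales, bool sticky, double k_off_ps,
                     double capture, double bound_scale, double bound_outer,
                     bool mirror) {
  const double c0 = box / 2.0;
  const double dts = dt / substeps;
  const bool has_profile = prof_breaks.size() > 0;
  NumericVector coords(Dimension(n, 3, n_frames));

  std::vector<double> px(n), py(n), pz(n), pr(n), bind_time(n, -1.0);
  std::vector<int> bound(n, 0), refractory(n, 0);
  std::vector<int> ev_mol, ev_cens;
  std::vector<double> ev_start, ev_end;

  // initial configuration: uniform outside the solute sphere
  for (int i = 0; i < n; ++i) {
    double x, y, z, r;
    do {
      x = unif_rand() * box;
      y = unif_rand() * box;
      z = unif_rand() * box;
      r = std::sqrt((x - c0) * (x - c0) + (y - c0) * (y - c0) +
                    (z - c0) * (z - c0));
    } while (r < b);
    px[i] = x; py[i] = y; pz[i] = z; pr[i] = r;
    if (sticky && r <= capture) refractory[i] = 1;
  }

  for (int f = 0; f < n_frames; ++f) {
    R_xlen_t off = (R_xlen_t)f * 3L * n;
    for (int i = 0; i < n; ++i) {
      coords[i + off] = px[i];
      coords[i + n + off] = py[i];
      coords[i + 2L * n + off] = pz[i];
    }
    if (f == n_frames - 1) break;
    for (int s = 0; s < substeps; ++s) {
      double tnow = f * dt + s * dts;
      double tnext = tnow + dts;
      for (int i = 0; i < n; ++i) {
        if (sticky && bound[i]) {
          double p_off = 1.0 - std::exp(-k_off_ps * dts);
          if (unif_rand() < p_off) {
            bound[i] = 0;
            refractory[i] = 1;
            ev_mol.push_back(i + 1);
            ev_start.push_back(bind_time[i]);
            ev_end.push_back(tnow);
            ev_cens.push_back(0);
            bind_time[i] = -1.0;
          }
        }
        double scale = has_profile
                           ? profile_scale(pr[i], prof_breaks, prof_scales)
                           : 1.0;
        if (sticky && bound[i]) scale *= bound_scale;
        double sig = std::sqrt(2.0 * D * scale * dts);
        double x = px[i] + sig * norm_rand();
        double y = py[i] + sig * norm_rand();
        double z = pz[i] + sig * norm_rand();
        x = wrap1(x, box); y = wrap1(y, box); z = wrap1(z, box);
        double rx = x - c0, ry = y - c0, rz = z - c0;
        double r = std::sqrt(rx * rx + ry * ry + rz * rz);
        if (r < b && r > 0) {
          if (mirror) {  // specular radial-mirror reflection
            double fac = (2.0 * b - r) / r;
            x = c0 + rx * fac; y = c0 + ry * fac; z = c0 + rz * fac;
            r = 2.0 * b - r;
          } else {       // Metropolis stay-put rejection (exact equilibrium)
            x = px[i]; y = py[i]; z = pz[i]; r = pr[i];
          }
        }
        if (sticky && bound[i] && r > bound_outer) {
          if (mirror) {
            double rr = 2.0 * bound_outer - r;
            if (rr < b) rr = b;  // pathological oversized step
            double fac = rr / r;
            x = c0 + (x - c0) * fac; y = c0 + (y - c0) * fac;
            z = c0 + (z - c0) * fac;
            r = rr;
          } else {
            x = px[i]; y = py[i]; z = pz[i]; r = pr[i];
          }
        }
        px[i] = x; py[i] = y; pz[i] = z; pr[i] = r;
        if (sticky && !bound[i]) {
          if (refractory[i] && r > capture) refractory[i] = 0;
          if (!refractory[i] && r <= bound_outer) {
            bound[i] = 1;
            bind_time[i] = tnext;
          }
        }
      }
    }
  }

  // close still-open events as end-censored
  if (sticky) {
    double t_end = (double)(n_frames - 1) * dt;
    for (int i = 0; i < n; ++i) {
      if (bound[i]) {
        ev_mol.push_back(i + 1);
        ev_start.push_back(bind_time[i]);
        ev_end.push_back(t_end);
        ev_cens.push_back(1);
      }
    }
  }
  DataFrame events = DataFrame::create(
      Named("mol_id") = wrap(ev_mol), Named("start_ps") = wrap(ev_start),
      Named("end_ps") = wrap(ev_end), Named("censored_end") = wrap(ev_cens));
  return List::create(Named("coords") = coords, Named("events") = events);
}

// rigid fluorine sites: site j (grouped by molecule) sits at
// centre_{j / sites_per_mol} + offset_j, wrapped into the box
// [[Rcpp::export(".place_sites_cpp")]]
NumericVector place_sites_cpp(NumericVector centers, NumericMatrix offsets,
                              int sites_per_mol, double box) {
  IntegerVector dim = centers.attr("dim");
  int n = dim[0], nf = dim[2];
  int ns = offsets.nrow();
  NumericVector out(Dimension(ns, 3, nf));
  for (int f = 0; f < nf; ++f) {
    R_xlen_t offc = (R_xlen_t)f * 3L * n;
    R_xlen_t offs = (R_xlen_t)f * 3L * ns;
    for (int j = 0; j < ns; ++j) {
      int m = j / sites_per_mol;
      for (int k = 0; k < 3; ++k) {
        double v = centers[m + (R_xlen_t)k * n + offc] + offsets(j, k);
        out[j + (R_xlen_t)k * ns + offs] = wrap1(v, box);
      }
    }
  }
  return out;
}
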