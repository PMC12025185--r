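#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Per-atom solvent-accessible surface area by Shrake-Rupley quadrature.
// `points` is a deterministic unit-sphere point set (golden spiral),
// generated on the R side so tests can reuse it. A quadrature point on
// atom i (scaled to r_i + probe) is accessible when it lies outside the
// expanded sphere of every neighbouring atom.
// [[Rcpp::export(name = ".sasa_per_atom")]]
NumericVector sasa_per_atom(NumericMatrix coords, NumericVector radii,
                            double probe, NumericMatrix points) {
  const int n = coords.nrow();
  const int np = points.nrow();
  NumericVector out(n);
  std::vector<double> rexp(n);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) {
    rexp[i] = radii[i] + probe;
    if (rexp[i] > rmax) rmax = rexp[i];
  }
  std::vector<int> nbr;
  nbr.reserve(64);
  for (int i = 0; i < n; ++i) {
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    const double ri = rexp[i];
    nbr.clear();
    const double reach = ri + rmax;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = coords(j, 0) - xi;
      const double dy = coords(j, 1) - yi;
      const double dz = coords(j, 2) - zi;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 >= reach * reach) continue;           // cheap bound
      const double cut = ri + rexp[j];
      if (d2 < cut * cut) nbr.push_back(j);
    }
    int acc = 0;
    for (int p = 0; p < np; ++p) {
      const double px = xi + ri * points(p, 0);
      const double py = yi + ri * points(p, 1);
      const double pz = zi + ri * points(p, 2);
      bool free_point = true;
      for (size_t k = 0; k < nbr.size(); ++k) {
        const int j = nbr[k];
        const double dx = px - coords(j, 0);
        const double dy = py - coords(j, 1);
        const double dz = pz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < rexp[j] * rexp[j]) {
          free_point = false;
          break;
        }
      }
      if (free_point) ++acc;
    }
    out[i] = 4.0 * M_PI * ri * ri * ((double)acc / (double)np);
  }
  return out;
}
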