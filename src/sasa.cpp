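#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area on a deterministic Fibonacci
// sphere lattice. For each atom, test points are placed on a sphere of radius
// r_i + probe; a point is accessible when it lies outside every neighbour's
// expanded sphere. Per-atom area = 4*pi*(r_i+probe)^2 * accessible fraction.
// Coincident atoms of identical radius occlude each other's lattice points
// only on strict interior tests, so both keep their full area.
//
// Two standard accelerations: neighbour coordinates are cached contiguously
// per atom, and the neighbour that buried the previous lattice point is
// tested first (consecutive Fibonacci points are spatially close, so the
// same blocker usually rejects runs of points).

// [[Rcpp::export(name = ".sasa_shrake_rupley_cpp")]]
NumericVector sasa_shrake_rupley_cpp(NumericMatrix coords,
                                     NumericVector radii,
                                     double probe,
                                     int n_points) {
  const int n = coords.nrow();
  const double golden = M_PI * (3.0 - std::sqrt(5.0));

  std::vector<double> ux(n_points), uy(n_points), uz(n_points);
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - (2.0 * k + 1.0) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = golden * k;
    ux[k] = r * std::cos(phi);
    uy[k] = r * std::sin(phi);
    uz[k] = z;
  }

  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords(i, 0);
    y[i] = coords(i, 1);
    z[i] = coords(i, 2);
  }

  NumericVector area(n);
  std::vector<double> nx, ny, nz, nr2;
  nx.reserve(n); ny.reserve(n); nz.reserve(n); nr2.reserve(n);
  for (int i = 0; i < n; ++i) {
    const double ri = radii[i] + probe;
    nx.clear(); ny.clear(); nz.clear(); nr2.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double rj = radii[j] + probe;
      const double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double rsum = ri + rj;
      if (d2 < rsum * rsum) {
        nx.push_back(dx);  // neighbour position relative to atom i
        ny.push_back(dy);
        nz.push_back(dz);
        nr2.push_back(rj * rj * (1.0 - 1e-12));
      }
    }
    const int nnb = static_cast<int>(nx.size());
    int accessible = 0;
    int last = 0;
    for (int k = 0; k < n_points; ++k) {
      const double px = ri * ux[k];
      const double py = ri * uy[k];
      const double pz = ri * uz[k];
      bool free_point = true;
      for (int mm = 0; mm < nnb; ++mm) {
        const int m = (mm == 0) ? last : (mm <= last ? mm - 1 : mm);
        const double dx = px - nx[m], dy = py - ny[m], dz = pz - nz[m];
        if (dx * dx + dy * dy + dz * dz < nr2[m]) {
          free_point = false;
          last = m;
          break;
        }
      }
      if (free_point) ++accessible;
    }
    area[i] = 4.0 * M_PI * ri * ri * accessible / n_points;
  }
  return area;
}
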