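#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley rolling-probe SASA for one frame.
//
// coords:  n x 3 context-atom coordinates (Angstrom)
// radii:   n vdW radii (Angstrom)
// region:  1-based indices of the atoms whose area is wanted
// sphere:  p x 3 unit vectors (quasi-uniform test points)
// probe:   probe radius (Angstrom)
//
// Returns the accessible area (Angstrom^2) of each region atom.
// [[Rcpp::export]]
NumericVector sasa_frame_cpp(NumericMatrix coords, NumericVector radii,
                             IntegerVector region, NumericMatrix sphere,
                             double probe) {
  const int n = coords.nrow();
  const int p = sphere.nrow();
  NumericVector out(region.size());

  std::vector<double> rp(n);
  for (int j = 0; j < n; ++j) rp[j] = radii[j] + probe;

  std::vector<int> nb;
  nb.reserve(n);

  for (int k = 0; k < region.size(); ++k) {
    const int i = region[k] - 1;
    const double ri = rp[i];
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);

    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi,
                   dz = coords(j, 2) - zi;
      const double cut = ri + rp[j];
      if (dx * dx + dy * dy + dz * dz < cut * cut) nb.push_back(j);
    }

    int acc = 0;
    for (int q = 0; q < p; ++q) {
      const double px = xi + ri * sphere(q, 0);
      const double py = yi + ri * sphere(q, 1);
      const double pz = zi + ri * sphere(q, 2);
      bool buried = false;
      for (size_t t = 0; t < nb.size(); ++t) {
        const int j = nb[t];
        const double dx = coords(j, 0) - px, dy = coords(j, 1) - py,
                     dz = coords(j, 2) - pz;
        if (dx * dx + dy * dy + dz * dz < rp[j] * rp[j]) {
          buried = true;
          break;
        }
      }
      if (!buried) ++acc;
    }
    out[k] = 4.0 * M_PI * ri * ri * static_cast<double>(acc) / p;
  }
  return out;
}
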