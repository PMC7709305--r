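#include <Rcpp.h>
using namespace Rcpp;

// Directed Hausdorff distance h(a -> b) = max over a of min over b of the
// Euclidean distance between voxel coordinates (rows of a and b, possibly
// scaled by spacing beforehand). Early exit on the inner loop: once the
// running minimum for a point drops to or below the current overall maximum
// that point cannot change the result.
// [[Rcpp::export]]
double cpp_hausdorff_directed(const NumericMatrix& a, const NumericMatrix& b) {
  const int na = a.nrow(), nb = b.nrow();
  double cmax2 = 0.0;
  for (int i = 0; i < na; ++i) {
    double cmin2 = std::numeric_limits<double>::infinity();
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    for (int j = 0; j < nb; ++j) {
      const double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < cmin2) {
        cmin2 = d2;
        if (cmin2 <= cmax2) break;
      }
    }
    if (cmin2 > cmax2) cmax2 = cmin2;
  }
  return std::sqrt(cmax2);
}
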