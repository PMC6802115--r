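#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Directed neighbour counts in concentric distance shells
// [bin_width*i, bin_width*(i+1)), i = i_min..i_max, using a uniform cell list
// with cell side = outer radius. Counts are directed: each unordered pair at
// an in-range distance contributes 2.
// [[Rcpp::export]]
IntegerVector shell_counts_cpp(NumericMatrix pts, double bin_width,
                               int i_min, int i_max) {
  const int n = pts.nrow();
  const int nb = i_max - i_min + 1;
  IntegerVector out(nb);
  if (n < 2) return out;

  const double rmax = bin_width * (i_max + 1);
  const double rmin = bin_width * i_min;
  const double r2max = rmax * rmax, r2min = rmin * rmin;

  double lo[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = pts(0, a);
    for (int i = 1; i < n; ++i) if (pts(i, a) < lo[a]) lo[a] = pts(i, a);
  }

  std::vector<long long> key(n);
  std::unordered_map<long long, std::vector<int> > cells;
  cells.reserve(n);
  const long long M = 1 << 20;  // per-axis cell index capacity
  for (int i = 0; i < n; ++i) {
    long long cx = (long long)std::floor((pts(i, 0) - lo[0]) / rmax);
    long long cy = (long long)std::floor((pts(i, 1) - lo[1]) / rmax);
    long long cz = (long long)std::floor((pts(i, 2) - lo[2]) / rmax);
    key[i] = (cx * M + cy) * M + cz;
    cells[key[i]].push_back(i);
  }

  std::vector<long long> counts(nb, 0);
  for (int i = 0; i < n; ++i) {
    const long long cz = key[i] % M;
    const long long cy = (key[i] / M) % M;
    const long long cx = key[i] / (M * M);
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          std::unordered_map<long long, std::vector<int> >::const_iterator it =
            cells.find(((cx + dx) * M + cy + dy) * M + cz + dz);
          if (it == cells.end()) continue;
          const std::vector<int>& v = it->second;
          for (size_t q = 0; q < v.size(); ++q) {
            const int j = v[q];
            if (j == i) continue;
            const double ddx = pts(i, 0) - pts(j, 0);
            const double ddy = pts(i, 1) - pts(j, 1);
            const double ddz = pts(i, 2) - pts(j, 2);
            const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 < r2min || d2 >= r2max) continue;
            const int b = (int)std::floor(std::sqrt(d2) / bin_width) - i_min;
            if (b >= 0 && b < nb) ++counts[b];
          }
        }
  }
  for (int b = 0; b < nb; ++b) out[b] = (int)counts[b];
  return out;
}
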