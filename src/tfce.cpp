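#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Threshold-free cluster enhancement of a 3D statistic map.
//
// For each voxel v: TFCE(v) = sum over thresholds h = dh, 2dh, ... <= s_v
// of extent(cluster containing v at height h)^E * h^H * dh, clusters taken
// over the mask with 6- or 26-neighbourhood connectivity. Only positive
// statistic values are enhanced; the caller enhances -stat for the
// negative tail.
// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector dims,
                       LogicalVector mask, double H, double E, double dh,
                       int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int V = nx * ny * nz;
  NumericVector out(V);

  double mx = 0.0;
  for (int v = 0; v < V; ++v)
    if (mask[v] && stat[v] > mx) mx = stat[v];
  if (mx <= 0.0 || dh <= 0.0) return out;

  // neighbour offsets
  std::vector<int> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        off.push_back(dx + nx * (dy + ny * dz));
      }

  std::vector<int> seen(V, -1);
  std::vector<int> stack, members;
  stack.reserve(V);
  members.reserve(V);

  const int nsteps = (int)std::floor(mx / dh + 1e-12);
  for (int s = 1; s <= nsteps; ++s) {
    const double h = s * dh;
    const double hH = std::pow(h, H) * dh;
    for (int v = 0; v < V; ++v) {
      if (!mask[v] || stat[v] < h || seen[v] == s) continue;
      // flood fill the cluster containing v at threshold h
      members.clear();
      stack.clear();
      stack.push_back(v);
      seen[v] = s;
      while (!stack.empty()) {
        int u = stack.back();
        stack.pop_back();
        members.push_back(u);
        int ux = u % nx, uy = (u / nx) % ny, uz = u / (nx * ny);
        for (size_t k = 0; k < off.size(); ++k) {
          int w = u + off[k];
          if (w < 0 || w >= V || seen[w] == s) continue;
          if (!mask[w] || stat[w] < h) continue;
          // guard against wrapping across array edges
          int wx = w % nx, wy = (w / nx) % ny, wz = w / (nx * ny);
          if (std::abs(wx - ux) > 1 || std::abs(wy - uy) > 1 ||
              std::abs(wz - uz) > 1) continue;
          seen[w] = s;
          stack.push_back(w);
        }
      }
      const double add = std::pow((double)members.size(), E) * hH;
      for (size_t k = 0; k < members.size(); ++k) out[members[k]] += add;
    }
  }
  return out;
}
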