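#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Deterministic golden-spiral point set on the unit sphere.
// Same n always yields the same points, so SASA is reproducible bit-for-bit.
static std::vector<double> golden_spiral(const int n) {
  std::vector<double> pts(3 * n);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = ga * k;
    pts[3 * k]     = r * std::cos(phi);
    pts[3 * k + 1] = r * std::sin(phi);
    pts[3 * k + 2] = z;
  }
  return pts;
}

// Shrake-Rupley SASA: per-atom accessible area over the expanded
// (vdw + probe) sphere, sampled at n_points spiral points. When `subset`
// is non-empty (1-based indices), areas are computed only for those
// atoms (all atoms still occlude); other entries are returned as 0.
// [[Rcpp::export(name = ".cpp_sasa")]]
NumericVector cpp_sasa(NumericMatrix coords, NumericVector radii,
                       double probe, int n_points,
                       IntegerVector subset = IntegerVector::create()) {
  const int n = coords.nrow();
  NumericVector area(n);
  if (n == 0) return area;
  std::vector<double> pts = golden_spiral(n_points);
  std::vector<double> x(n), y(n), z(n), er(n), er2(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords(i, 0);
    y[i] = coords(i, 1);
    z[i] = coords(i, 2);
    er[i] = radii[i] + probe;
    er2[i] = er[i] * er[i];
  }
  std::vector<int> targets;
  if (subset.size() == 0) {
    targets.resize(n);
    for (int i = 0; i < n; ++i) targets[i] = i;
  } else {
    for (int k = 0; k < subset.size(); ++k)
      targets.push_back(subset[k] - 1);
  }
  std::vector<double> nx, ny, nz, nr2, nd2;
  std::vector<size_t> ord;
  for (size_t t = 0; t < targets.size(); ++t) {
    const int i = targets[t];
    const double xi = x[i], yi = y[i], zi = z[i], ri = er[i];
    nx.clear(); ny.clear(); nz.clear(); nr2.clear(); nd2.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[j] - xi, dy = y[j] - yi, dz = z[j] - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      double cut = ri + er[j];
      if (d2 < cut * cut) {
        nx.push_back(x[j]); ny.push_back(y[j]); nz.push_back(z[j]);
        nr2.push_back(er2[j]); nd2.push_back(d2);
      }
    }
    // closest occluders first: buried points exit the scan early
    const size_t m = nx.size();
    ord.resize(m);
    for (size_t u = 0; u < m; ++u) ord[u] = u;
    std::sort(ord.begin(), ord.end(),
              [&nd2](size_t a, size_t b) { return nd2[a] < nd2[b]; });
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double px = xi + ri * pts[3 * k];
      double py = yi + ri * pts[3 * k + 1];
      double pz = zi + ri * pts[3 * k + 2];
      bool free_pt = true;
      for (size_t u = 0; u < m; ++u) {
        const size_t j = ord[u];
        double dx = px - nx[j], dy = py - ny[j], dz = pz - nz[j];
        if (dx * dx + dy * dy + dz * dz < nr2[j]) {
          free_pt = false;
          break;
        }
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * static_cast<double>(acc) / n_points;
  }
  return area;
}

static inline long long cell_key(int cx, int cy, int cz) {
  // pack three small signed ints into one key
  return (static_cast<long long>(cx + 1048576) << 42) |
         (static_cast<long long>(cy + 1048576) << 21) |
         static_cast<long long>(cz + 1048576);
}

// Steric-clash pair enumeration with a cell grid. Pair (i,j) clashes iff
// d < r_i + r_j - tol. Exemptions: atoms of the same residue (covalently
// bonded), and backbone-backbone pairs of residues adjacent in the chain.
// Cell size >= max pair cutoff, so the grid reproduces the O(n^2)
// definition exactly.
// [[Rcpp::export(name = ".cpp_clash_pairs")]]
DataFrame cpp_clash_pairs(NumericMatrix coords, NumericVector radii,
                          IntegerVector res_idx, IntegerVector chain_idx,
                          LogicalVector backbone, double tol) {
  const int n = coords.nrow();
  std::vector<int> ii, jj;
  std::vector<double> dd;
  if (n > 0) {
    double rmax = 0.0;
    for (int i = 0; i < n; ++i)
      if (radii[i] > rmax) rmax = radii[i];
    double cut = std::max(2.0 * rmax - tol, 0.5);
    std::unordered_map<long long, std::vector<int> > grid;
    grid.reserve(n * 2);
    std::vector<int> cx(n), cy(n), cz(n);
    for (int i = 0; i < n; ++i) {
      cx[i] = static_cast<int>(std::floor(coords(i, 0) / cut));
      cy[i] = static_cast<int>(std::floor(coords(i, 1) / cut));
      cz[i] = static_cast<int>(std::floor(coords(i, 2) / cut));
      grid[cell_key(cx[i], cy[i], cz[i])].push_back(i);
    }
    for (int i = 0; i < n; ++i) {
      for (int ax = -1; ax <= 1; ++ax)
        for (int ay = -1; ay <= 1; ++ay)
          for (int az = -1; az <= 1; ++az) {
            std::unordered_map<long long, std::vector<int> >::iterator it =
              grid.find(cell_key(cx[i] + ax, cy[i] + ay, cz[i] + az));
            if (it == grid.end()) continue;
            const std::vector<int>& cell = it->second;
            for (size_t m = 0; m < cell.size(); ++m) {
              int j = cell[m];
              if (j <= i) continue;
              if (res_idx[i] == res_idx[j]) continue;
              if (chain_idx[i] == chain_idx[j] &&
                  std::abs(res_idx[i] - res_idx[j]) == 1 &&
                  backbone[i] && backbone[j])
                continue;
              double thr = radii[i] + radii[j] - tol;
              if (thr <= 0) continue;
              double dx = coords(i, 0) - coords(j, 0);
              double dy = coords(i, 1) - coords(j, 1);
              double dz = coords(i, 2) - coords(j, 2);
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < thr * thr) {
                ii.push_back(i + 1);
                jj.push_back(j + 1);
                dd.push_back(std::sqrt(d2));
              }
            }
          }
    }
  }
  return DataFrame::create(Named("i") = ii, Named("j") = jj,
                           Named("dist") = dd);
}

// All pairs (i in A, j in B) with d < cutoff. Brute force; the pools this
// package feeds it are a few hundred atoms.
// [[Rcpp::export(name = ".cpp_close_pairs")]]
DataFrame cpp_close_pairs(NumericMatrix A, NumericMatrix B, double cutoff) {
  std::vector<int> ii, jj;
  std::vector<double> dd;
  const double c2 = cutoff * cutoff;
  for (int i = 0; i < A.nrow(); ++i) {
    for (int j = 0; j < B.nrow(); ++j) {
      double dx = A(i, 0) - B(j, 0);
      double dy = A(i, 1) - B(j, 1);
      double dz = A(i, 2) - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < c2) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
        dd.push_back(std::sqrt(d2));
      }
    }
  }
  return DataFrame::create(Named("i") = ii, Named("j") = jj,
                           Named("dist") = dd);
}
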